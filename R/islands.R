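# HRR/ROH islands: per-SNP run incidence within a group of individuals, and
# maximal supra-threshold stretches of consecutive markers.

#' Per-SNP run incidence for a group
#'
#' For every marker, the fraction of group members having at least one run
#' whose `[start_bp, end_bp]` interval contains the marker position.
#'
#' @param runs run table from [detect_all_runs()].
#' @param dataset the [genotype_dataset()] the runs were detected on (supplies
#'   the marker map and group membership).
#' @param group a herd id, or a character vector of individual ids.
#' @return data.frame with columns `chrom`, `pos_bp`, `snp_id`, `incidence`;
#'   attributes `group_id`, `group_size`, `run_type`.
#' @export
snp_incidence <- function(runs, dataset, group) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  ids <- .resolve_group(dataset, group)
  if (length(ids) == 0L) stop("group of size 0")
  gi <- .marker_global_index(dataset$map)
  rr <- runs[runs$individual_id %in% ids, , drop = FALSE]
  cov <- .coverage_counts(rr, gi)
  track <- data.frame(chrom = dataset$map$chrom, pos_bp = dataset$map$pos_bp,
                      snp_id = dataset$map$snp_id,
                      incidence = cov / length(ids),
                      stringsAsFactors = FALSE)
  attr(track, "group_id") <- if (length(group) == 1L) group else NA_character_
  attr(track, "group_size") <- length(ids)
  attr(track, "run_type") <- if (nrow(rr)) rr$run_type[1] else NA_character_
  track
}

.resolve_group <- function(dataset, group) {
  ind <- dataset$individuals
  if (length(group) == 1L && group %in% ind$herd_id &&
      !(group %in% ind$individual_id)) {
    return(ind$individual_id[ind$herd_id == group])
  }
  unknown <- setdiff(group, ind$individual_id)
  if (length(unknown)) stop("unknown individual(s) in group: ", unknown[1])
  group
}

# Precompute the per-run global marker index ranges so that permutation
# replicates can recompute incidence without touching genotypes.
.marker_global_index <- function(map) {
  ranges <- .chrom_index_ranges(map)
  list(map = map, ranges = ranges, n = nrow(map))
}

# Number of covering runs per marker (counts individuals, since one
# individual's accepted runs on a chromosome are disjoint).
.coverage_counts <- function(runs, gi) {
  n <- gi$n
  if (nrow(runs) == 0L) return(numeric(n))
  ir <- .run_index_ranges(runs, gi)
  inc <- tabulate(ir$i1, nbins = n + 1L) - tabulate(ir$i2 + 1L, nbins = n + 1L)
  cumsum(inc[seq_len(n)])
}

# Global marker index of each run's first/last covered marker.
.run_index_ranges <- function(runs, gi) {
  map <- gi$map; ranges <- gi$ranges
  k <- match(runs$chromosome, ranges$chrom)
  if (anyNA(k)) stop("run on chromosome absent from map: ",
                     runs$chromosome[is.na(k)][1])
  i1 <- integer(nrow(runs)); i2 <- integer(nrow(runs))
  for (u in unique(k)) {
    sel <- which(k == u)
    idx <- ranges$from[u]:ranges$to[u]
    pos <- map$pos_bp[idx]
    # first marker at or after start; last marker at or before end
    i1[sel] <- ranges$from[u] + findInterval(runs$start_bp[sel] - 0.5, pos)
    i2[sel] <- ranges$from[u] - 1L + findInterval(runs$end_bp[sel] + 0.5, pos)
  }
  bad <- i1 > i2
  if (any(bad)) stop("run covering no mapped marker (map/run mismatch)")
  list(i1 = i1, i2 = i2)
}

#' Call islands from an incidence track
#'
#' Maximal stretches of consecutive markers with incidence at or above the
#' threshold become islands; two supra-threshold stretches separated by at
#' least one sub-threshold marker stay separate. Island boundaries are the
#' first/last member SNP positions and `support` is the peak incidence inside.
#'
#' @param track incidence track from [snp_incidence()].
#' @param threshold calling threshold in `(0, 1]` (`mode = "threshold"`).
#' @param mode `"threshold"` for a fixed incidence cutoff, `"quantile"` to use
#'   the `top_quantile` of the track's incidence distribution as the cutoff.
#' @param top_quantile quantile used when `mode = "quantile"`.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `n_snps`,
#'   `support`, `group`, `run_type`.
#' @export
call_islands <- function(track, threshold = 0.4, mode = c("threshold", "quantile"),
                         top_quantile = 0.999) {
  mode <- match.arg(mode)
  if (mode == "quantile") {
    threshold <- as.numeric(stats::quantile(track$incidence, top_quantile,
                                            names = FALSE))
    threshold <- max(threshold, .Machine$double.eps)
  }
  stopifnot(threshold > 0, threshold <= 1)
  isl <- .call_islands_core(track$incidence, track$chrom, track$pos_bp, threshold)
  isl$group <- rep(attr(track, "group_id") %||% NA_character_, nrow(isl))
  isl$run_type <- rep(attr(track, "run_type") %||% NA_character_, nrow(isl))
  isl
}

.call_islands_core <- function(incidence, chrom, pos, threshold) {
  above <- incidence >= threshold
  # break stretches at chromosome boundaries
  key <- cumsum(c(TRUE, diff(chrom) != 0) | c(TRUE, diff(above) != 0))
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- above[starts]
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    chrom = chrom[starts],
    start_bp = pos[starts],
    end_bp = pos[ends],
    n_snps = ends - starts + 1L,
    support = vapply(seq_along(starts),
                     function(j) max(incidence[starts[j]:ends[j]]), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Island length in kb
#'
#' `(end_bp - start_bp) / 1000`, rounded half-up to one decimal — the
#' convention under which printed island lengths reproduce their coordinate
#' pairs exactly.
#'
#' @param island one-row island data.frame, or anything with `start_bp` and
#'   `end_bp` fields.
#' @return numeric kb value(s) with one decimal.
#' @export
island_length_kb <- function(island) {
  round_half_up((island$end_bp - island$start_bp) / 1000, 1)
}

#' Match an island against candidates
#'
#' Among candidates on the same chromosome with at least 1 bp of interval
#' overlap, returns the index of the one with the largest overlap (first on
#' ties); `NA` when none overlaps.
#'
#' @param island one-row island data.frame.
#' @param candidate_islands island data.frame to search.
#' @return integer row index into `candidate_islands`, or `NA`.
#' @export
match_islands <- function(island, candidate_islands) {
  if (nrow(candidate_islands) == 0L) return(NA_integer_)
  same <- candidate_islands$chrom == island$chrom
  ov <- pmin(candidate_islands$end_bp, island$end_bp) -
    pmax(candidate_islands$start_bp, island$start_bp)
  ov[!same] <- -Inf
  if (all(ov <= 0)) return(NA_integer_)
  which.max(ov)
}

#' Write islands as BED-like TSV
#'
#' @param islands island table from [call_islands()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_islands_tsv <- function(islands, path) {
  write_tsv(islands, path)
}
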