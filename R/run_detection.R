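# Consecutive-runs detection of heterozygosity-rich regions (HRRs) and runs
# of homozygosity (ROHs).
#
# A run is a stretch of consecutive markers whose calls match the target state
# (het for HRR; either homozygote for ROH), tolerating up to `max_missing`
# missing and `max_opposite` opposite calls in its interior. A run is broken
# by exceeding either tolerance or by an inter-marker gap above `max_gap_bp`,
# never starts or ends on a non-target call, and is accepted when it carries
# at least `min_snps` target SNPs and spans at least `min_length_bp`
# (length = end_bp - start_bp).
#
# Scan semantics: greedy by start with maximal extension. The scanner stands
# at the leftmost eligible target SNP and takes the furthest end reachable
# within the budgets; an accepted run moves the cursor past its end, a
# rejected candidate advances the cursor by one target SNP so that longer
# windows starting inside a rejected candidate are still found. Accepted runs
# of one individual on one chromosome never overlap, and the output equals an
# exhaustive enumeration of maximal budget-satisfying windows.

#' Run-detection parameter set
#'
#' @param target_state `"het"` (HRR) or `"hom"` (ROH; either homozygote
#'   matches).
#' @param min_snps minimum number of target-state SNPs in an accepted run.
#' @param max_opposite opposite-state calls tolerated inside a run (the study
#'   design fixes this to 0 for both run types).
#' @param max_missing missing calls tolerated inside a run.
#' @param min_length_bp minimum accepted span in bp.
#' @param max_gap_bp maximum distance between adjacent SNPs inside a run.
#' @return a list of class `run_params`.
#' @seealso [hrr_params()], [roh_params()] for the standard parameterizations.
#' @export
run_params <- function(target_state = c("het", "hom"), min_snps, max_opposite = 0L,
                       max_missing = 1L, min_length_bp, max_gap_bp = 1e6) {
  target_state <- match.arg(target_state)
  stopifnot(min_snps >= 1, max_opposite >= 0, max_missing >= 0,
            min_length_bp > 0, max_gap_bp >= 0)
  structure(list(target_state = target_state, min_snps = as.integer(min_snps),
                 max_opposite = as.integer(max_opposite),
                 max_missing = as.integer(max_missing),
                 min_length_bp = as.numeric(min_length_bp),
                 max_gap_bp = as.numeric(max_gap_bp)),
            class = "run_params")
}

#' Standard HRR parameters
#'
#' Five heterozygous SNPs minimum, no homozygous calls allowed, minimum span
#' 50 kb (or 250 kb for the long-segment scan), maximum inter-SNP gap 1 Mb.
#'
#' @param min_length_bp 50000 or 250000.
#' @param max_missing missing calls tolerated inside a run.
#' @return a [run_params()] list.
#' @export
hrr_params <- function(min_length_bp = 50000, max_missing = 1L) {
  run_params("het", min_snps = 5L, max_opposite = 0L, max_missing = max_missing,
             min_length_bp = min_length_bp)
}

#' Standard ROH parameters
#'
#' Ten homozygous SNPs minimum, no heterozygous calls allowed, minimum span
#' 250 kb, maximum inter-SNP gap 1 Mb.
#'
#' @inheritParams hrr_params
#' @return a [run_params()] list.
#' @export
roh_params <- function(min_length_bp = 250000, max_missing = 1L) {
  run_params("hom", min_snps = 10L, max_opposite = 0L, max_missing = max_missing,
             min_length_bp = min_length_bp)
}

# Core scanner on one chromosome.
# typ: integer vector, 1 = target, 0 = missing, -1 = opposite; pos: bp.
# Returns list(start_idx, end_idx, n_snps).
scan_state_runs <- function(typ, pos, params) {
  m <- length(typ)
  empty <- list(start_idx = integer(0), end_idx = integer(0),
                n_snps = integer(0))
  if (m == 0L) return(empty)
  tgt <- which(typ == 1L)
  nt <- length(tgt)
  if (nt == 0L) return(empty)
  max_missing <- params$max_missing
  max_opposite <- params$max_opposite
  min_snps <- params$min_snps
  min_length_bp <- params$min_length_bp

  miss_idx <- which(typ == 0L)
  opp_idx <- which(typ == -1L)
  n_miss <- length(miss_idx)
  n_opp <- length(opp_idx)
  cum_miss <- cumsum(typ == 0L)
  cum_opp <- cumsum(typ == -1L)
  cum_tgt <- cumsum(typ == 1L)
  idx_or_zero <- integer(m); idx_or_zero[tgt] <- tgt
  last_tgt_upto <- cummax(idx_or_zero)
  # last index of the gap-free segment containing each marker
  seg_ends <- c(which(diff(pos) > params$max_gap_bp), m)
  seg_end_vec <- rep(seg_ends, times = diff(c(0L, seg_ends)))

  starts <- ends <- counts <- integer(0)
  ti <- 1L
  while (ti <= nt) {
    s <- tgt[ti]
    nm <- cum_miss[s]
    lim <- if (nm + max_missing + 1L <= n_miss)
      miss_idx[nm + max_missing + 1L] - 1L else m
    no <- cum_opp[s]
    lim_opp <- if (no + max_opposite + 1L <= n_opp)
      opp_idx[no + max_opposite + 1L] - 1L else m
    if (lim_opp < lim) lim <- lim_opp
    if (seg_end_vec[s] < lim) lim <- seg_end_vec[s]
    e <- last_tgt_upto[lim]
    n_snps <- cum_tgt[e] - cum_tgt[s] + 1L
    if (n_snps >= min_snps && (pos[e] - pos[s]) >= min_length_bp) {
      starts <- c(starts, s); ends <- c(ends, e); counts <- c(counts, n_snps)
      skip_to <- e
    } else {
      # any start between s and the next non-target marker (within the same
      # gap-free segment) reaches the same end with a smaller window, so it
      # is rejected too; skip straight past that blocker
      skip_to <- if (nm + 1L <= n_miss) miss_idx[nm + 1L] else m
      nxt_opp <- if (no + 1L <= n_opp) opp_idx[no + 1L] else m
      if (nxt_opp < skip_to) skip_to <- nxt_opp
      if (seg_end_vec[s] < skip_to) skip_to <- seg_end_vec[s]
    }
    while (ti <= nt && tgt[ti] <= skip_to) ti <- ti + 1L
  }
  list(start_idx = starts, end_idx = ends, n_snps = counts)
}

.state_vector <- function(calls_row, target_state) {
  typ <- rep(0L, length(calls_row))
  if (target_state == "het") {
    typ[!is.na(calls_row) & calls_row == 1L] <- 1L
    typ[!is.na(calls_row) & calls_row != 1L] <- -1L
  } else {
    typ[!is.na(calls_row) & calls_row != 1L] <- 1L
    typ[!is.na(calls_row) & calls_row == 1L] <- -1L
  }
  typ
}

.check_sorted_map <- function(map) {
  bad <- vapply(split(map$pos_bp, map$chrom),
                function(p) is.unsorted(p, strictly = TRUE), logical(1))
  if (any(bad)) {
    stop("map not sorted by position on chromosome ",
         names(bad)[bad][1])
  }
  invisible(TRUE)
}

.chrom_index_ranges <- function(map) {
  r <- rle(map$chrom)
  ends <- cumsum(r$lengths)
  data.frame(chrom = r$values, from = c(1L, head(ends, -1L) + 1L), to = ends)
}

#' Detect runs for one individual
#'
#' Scans each chromosome left to right with the consecutive-runs method (see
#' the package vignette for the exact scan semantics).
#'
#' @param dataset a [genotype_dataset()] with markers sorted by position.
#' @param individual individual id.
#' @param params a [run_params()] list.
#' @return data.frame with columns `individual_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_snps`, `length_bp`, `run_type`.
#' @export
detect_runs <- function(dataset, individual, params) {
  stopifnot(inherits(dataset, "genotype_dataset"), inherits(params, "run_params"))
  i <- match(individual, dataset$individuals$individual_id)
  if (is.na(i)) stop("unknown individual: ", individual)
  .check_sorted_map(dataset$map)
  .detect_runs_row(dataset, i, params)
}

# Vector accumulator per individual (data.frame assembly happens once, in
# the callers; at array scale this dominates runtime otherwise).
.detect_runs_vectors <- function(dataset, i, params, ranges) {
  map <- dataset$map
  row <- dataset$calls[i, ]
  chrv <- startv <- endv <- nv <- list()
  for (k in seq_len(nrow(ranges))) {
    idx <- ranges$from[k]:ranges$to[k]
    pos <- map$pos_bp[idx]
    typ <- .state_vector(row[idx], params$target_state)
    seg <- scan_state_runs(typ, pos, params)
    if (length(seg$start_idx) > 0L) {
      j <- length(chrv) + 1L
      chrv[[j]] <- rep(ranges$chrom[k], length(seg$start_idx))
      startv[[j]] <- pos[seg$start_idx]
      endv[[j]] <- pos[seg$end_idx]
      nv[[j]] <- seg$n_snps
    }
  }
  list(chromosome = unlist(chrv) %||% integer(0),
       start_bp = unlist(startv) %||% numeric(0),
       end_bp = unlist(endv) %||% numeric(0),
       n_snps = unlist(nv) %||% integer(0))
}

.runs_as_df <- function(id, v, run_type) {
  n <- length(v$chromosome)
  data.frame(individual_id = rep(id, n), chromosome = v$chromosome,
             start_bp = v$start_bp, end_bp = v$end_bp, n_snps = v$n_snps,
             length_bp = v$end_bp - v$start_bp,
             run_type = rep(run_type, n), stringsAsFactors = FALSE)
}

.detect_runs_row <- function(dataset, i, params) {
  ranges <- .chrom_index_ranges(dataset$map)
  v <- .detect_runs_vectors(dataset, i, params, ranges)
  .runs_as_df(dataset$individuals$individual_id[i], v,
              if (params$target_state == "het") "HRR" else "ROH")
}

#' Detect runs for every individual
#'
#' Concatenation of [detect_runs()] over all individuals, in deterministic
#' order (individual, chromosome, start). Adds the herd label.
#'
#' @inheritParams detect_runs
#' @return data.frame as in [detect_runs()] plus a `herd_id` column.
#' @export
detect_all_runs <- function(dataset, params) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  n <- nrow(dataset$individuals)
  .check_sorted_map(dataset$map)
  ranges <- .chrom_index_ranges(dataset$map)
  run_type <- if (params$target_state == "het") "HRR" else "ROH"
  out <- vector("list", n)
  for (i in seq_len(n)) {
    v <- .detect_runs_vectors(dataset, i, params, ranges)
    v$individual_id <- rep(dataset$individuals$individual_id[i],
                           length(v$chromosome))
    out[[i]] <- v
  }
  runs <- data.frame(
    individual_id = unlist(lapply(out, `[[`, "individual_id")) %||% character(0),
    chromosome = unlist(lapply(out, `[[`, "chromosome")) %||% integer(0),
    start_bp = unlist(lapply(out, `[[`, "start_bp")) %||% numeric(0),
    end_bp = unlist(lapply(out, `[[`, "end_bp")) %||% numeric(0),
    n_snps = unlist(lapply(out, `[[`, "n_snps")) %||% integer(0),
    stringsAsFactors = FALSE)
  runs$length_bp <- runs$end_bp - runs$start_bp
  runs$run_type <- rep(run_type, nrow(runs))
  runs$herd_id <- dataset$individuals$herd_id[
    match(runs$individual_id, dataset$individuals$individual_id)]
  rownames(runs) <- NULL
  runs
}

#' Total run length for one individual
#'
#' @param runs a run table from [detect_all_runs()] (one run type).
#' @param individual individual id.
#' @return total bp covered by the individual's runs (0 when none).
#' @export
total_run_length <- function(runs, individual) {
  if (length(unique(runs$run_type)) > 1) {
    stop("runs table mixes run types; pass a single run type")
  }
  sum(runs$length_bp[runs$individual_id == individual])
}

#' Write a run table as TSV
#'
#' Column layout compatible with consecutive-runs detection tools:
#' individual, herd, chromosome, start, end, SNP count, length, type.
#'
#' @param runs run table from [detect_all_runs()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_runs_tsv <- function(runs, path) {
  cols <- c("individual_id", "herd_id", "chromosome", "start_bp", "end_bp",
            "n_snps", "length_bp", "run_type")
  write_tsv(runs[, intersect(cols, names(runs))], path)
}
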