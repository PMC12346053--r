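# Windowed Tajima's D scan with per-chromosome SD-based outlier flagging, and
# repeat-element coverage comparison between HRR and ROH island classes.

#' Tajima test constants
#'
#' The standard constants for n sequences: `a1 = sum 1/i`, `a2 = sum 1/i^2`
#' (i = 1..n-1), `b1 = (n+1)/(3(n-1))`, `b2 = 2(n^2+n+3)/(9n(n-1))`,
#' `c1 = b1 - 1/a1`, `c2 = b2 - (n+2)/(a1 n) + a2/a1^2`, `e1 = c1/a1`,
#' `e2 = c2/(a1^2 + a2)`.
#'
#' @param n number of sequences (2 x individuals for genotype data); at
#'   least 2.
#' @return a list of class `tajima_constants`.
#' @export
tajima_constants <- function(n) {
  if (n < 2) stop("need at least 2 sequences")
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  structure(list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
                 c1 = c1, c2 = c2, e1 = e1, e2 = e2),
            class = "tajima_constants")
}

#' Tajima's D for one window of genotypes
#'
#' Genotypes are treated as 2N sequences through per-site allele counts:
#' `pi = sum_site 2 p (1 - p) n_site / (n_site - 1)` (the mean number of
#' pairwise differences, with `n_site` the non-missing allele count at the
#' site), S is the number of segregating sites, and
#' `D = (pi - S / a1) / sqrt(e1 S + e2 S (S - 1))`. Undefined (NA, with
#' attribute) when S = 0.
#'
#' @param window_genotypes integer matrix individuals x sites coded 0/1/2/NA
#'   (biallelic sites).
#' @param constants optional [tajima_constants()] for `2 * nrow()` sequences.
#' @return list with `S`, `pi`, `D` (`D = NA` when S = 0).
#' @export
tajima_d <- function(window_genotypes, constants = NULL) {
  g <- as.matrix(window_genotypes)
  if (any(g > 2 | g < 0, na.rm = TRUE)) stop("non-biallelic site (calls outside 0/1/2)")
  n_seq <- 2 * nrow(g)
  if (is.null(constants)) constants <- tajima_constants(n_seq)
  k <- colSums(g, na.rm = TRUE)                  # alt allele count per site
  nn <- 2 * colSums(!is.na(g))                   # non-missing alleles per site
  seg <- nn > 0 & k > 0 & k < nn
  S <- sum(seg)
  if (S == 0) {
    return(list(S = 0L, pi = 0, D = NA_real_))
  }
  p <- k[seg] / nn[seg]
  pi <- sum(2 * p * (1 - p) * nn[seg] / (nn[seg] - 1))
  theta_w <- S / constants$a1
  D <- (pi - theta_w) / sqrt(constants$e1 * S + constants$e2 * S * (S - 1))
  list(S = as.integer(S), pi = pi, D = D)
}

#' Tajima scan configuration
#'
#' @param window_bp window (frame) width; windows are anchored at position 0
#'   in half-open coordinates `[k w, (k+1) w)` and tile each chromosome.
#' @param sd_multiplier outlier threshold is `sd_multiplier * SD` of the
#'   chromosome's D values (the near-zero-mean reading of a "3 SD" rule);
#'   windows with D above it are flagged.
#' @return a list of class `tajima_scan_config`.
#' @export
tajima_scan_config <- function(window_bp = 100000, sd_multiplier = 3) {
  stopifnot(window_bp > 0, sd_multiplier > 0)
  structure(list(window_bp = as.numeric(window_bp),
                 sd_multiplier = as.numeric(sd_multiplier)),
            class = "tajima_scan_config")
}

#' Windowed Tajima's D scan
#'
#' Tiles each chromosome with `window_bp` frames, computes D per window from
#' the group's genotypes, and per chromosome reports the SD of the defined D
#' values, the `sd_multiplier x SD` threshold, the number of windows
#' exceeding it and the maximum D.
#'
#' @param dataset post-QC [genotype_dataset()].
#' @param group herd id or vector of individual ids (at least 2 individuals).
#' @param config a [tajima_scan_config()].
#' @param chromosomes optional subset of chromosomes to scan.
#' @return list with `windows` (one row per window with >= 1 SNP: `chrom`,
#'   `start_bp`, `end_bp`, `n_sites`, `S`, `pi`, `D`, `outlier`) and `report`
#'   (per chromosome: `sd_d`, `threshold`, `n_exceeding`, `max_d`).
#' @export
scan_tajima <- function(dataset, group, config = tajima_scan_config(),
                        chromosomes = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  ids <- .resolve_group(dataset, group)
  if (length(ids) < 2) stop("group must have at least 2 individuals")
  rows <- match(ids, dataset$individuals$individual_id)
  g <- dataset$calls[rows, , drop = FALSE]
  map <- dataset$map
  chroms <- chromosomes %||% unique(map$chrom)
  const <- tajima_constants(2 * length(ids))
  w <- config$window_bp

  win_list <- list(); rep_list <- list()
  for (ch in chroms) {
    on_ch <- which(map$chrom == ch)
    if (length(on_ch) == 0L) {
      rep_list[[length(rep_list) + 1]] <- data.frame(
        chrom = ch, n_windows = 0L, sd_d = NA_real_, threshold = NA_real_,
        n_exceeding = NA_integer_, max_d = NA_real_)
      next
    }
    wk <- floor(map$pos_bp[on_ch] / w)   # half-open [k w, (k+1) w)
    ks <- sort(unique(wk))
    dvals <- rep(NA_real_, length(ks))
    wdf <- data.frame(chrom = ch, start_bp = ks * w, end_bp = (ks + 1) * w,
                      n_sites = NA_integer_, S = NA_integer_, pi = NA_real_,
                      D = NA_real_)
    for (q in seq_along(ks)) {
      sites <- on_ch[wk == ks[q]]
      td <- tajima_d(g[, sites, drop = FALSE], const)
      wdf$n_sites[q] <- length(sites)
      wdf$S[q] <- td$S; wdf$pi[q] <- td$pi; wdf$D[q] <- td$D
      dvals[q] <- td$D
    }
    defined <- !is.na(dvals)
    if (sum(defined) >= 2) {
      sd_d <- stats::sd(dvals[defined])
      thr <- config$sd_multiplier * sd_d
      wdf$outlier <- !is.na(wdf$D) & wdf$D > thr
      rep_list[[length(rep_list) + 1]] <- data.frame(
        chrom = ch, n_windows = sum(defined), sd_d = sd_d, threshold = thr,
        n_exceeding = sum(wdf$outlier), max_d = max(dvals[defined]))
    } else {
      wdf$outlier <- FALSE
      rep_list[[length(rep_list) + 1]] <- data.frame(
        chrom = ch, n_windows = sum(defined), sd_d = NA_real_,
        threshold = NA_real_, n_exceeding = NA_integer_,
        max_d = if (any(defined)) max(dvals[defined]) else NA_real_)
    }
    win_list[[length(win_list) + 1]] <- wdf
  }
  list(windows = if (length(win_list)) do.call(rbind, win_list) else data.frame(),
       report = do.call(rbind, rep_list))
}

#' Read a BED file of repeat-element intervals
#'
#' BED is 0-based half-open; intervals are converted to the package's 1-based
#' inclusive convention. Lines are `chrom  start  end` with an optional
#' fourth name column.
#'
#' @param path BED path.
#' @param element_type label attached to every interval (e.g. `"LINE"`).
#' @return data.frame with `chrom`, `start_bp`, `end_bp` (1-based inclusive),
#'   `element_type`.
#' @export
read_element_bed <- function(path, element_type) {
  b <- utils::read.table(path, header = FALSE, sep = "", stringsAsFactors = FALSE)
  if (ncol(b) < 3) stop("malformed BED (need >= 3 columns): ", path)
  chrom <- suppressWarnings(as.integer(sub("^chr", "", b[[1]])))
  if (anyNA(chrom)) stop("non-numeric chromosome in BED at line ",
                         which(is.na(chrom))[1])
  start0 <- as.numeric(b[[2]]); end0 <- as.numeric(b[[3]])
  if (any(end0 <= start0)) stop("malformed interval (end <= start) at BED line ",
                                which(end0 <= start0)[1])
  data.frame(chrom = chrom, start_bp = start0 + 1, end_bp = end0,
             element_type = element_type, stringsAsFactors = FALSE)
}

#' Repeat-element coverage fraction of an island
#'
#' Per element type, intervals are merged (union) first, then intersected
#' with the island; the fraction is the overlap in bp divided by the island
#' length in bp (the per-kb length-fraction normalization).
#'
#' @param island one-row island data.frame (`chrom`, `start_bp`, `end_bp`).
#' @param element_intervals data.frame from [read_element_bed()] (possibly
#'   several types concatenated).
#' @return data.frame with one row per element type present: `element_type`,
#'   `overlap_bp`, `fraction`.
#' @export
element_fraction <- function(island, element_intervals) {
  len <- island$end_bp - island$start_bp
  if (len <= 0) stop("island of non-positive length")
  # the island segment [start, end) in bp, so full coverage gives exactly 1
  isl_rng <- IRanges::IRanges(start = island$start_bp, width = len)
  types <- unique(element_intervals$element_type)
  out <- lapply(types, function(tp) {
    e <- element_intervals[element_intervals$element_type == tp &
                             element_intervals$chrom == island$chrom, , drop = FALSE]
    if (nrow(e) == 0) {
      return(data.frame(element_type = tp, overlap_bp = 0, fraction = 0))
    }
    rng <- IRanges::reduce(IRanges::IRanges(start = e$start_bp, end = e$end_bp))
    ov <- IRanges::intersect(rng, isl_rng)
    bp <- sum(IRanges::width(ov))
    data.frame(element_type = tp, overlap_bp = bp, fraction = bp / len,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare element enrichment between island classes
#'
#' Two-sided Mann-Whitney (exact for small samples) on per-island coverage
#' fractions of one element type, HRR islands vs ROH islands.
#'
#' @param hrr_records,roh_records data.frames with columns `element_type` and
#'   `fraction` (one row per island x type), e.g. stacked [element_fraction()]
#'   outputs.
#' @param element_type the element class to compare.
#' @return the p-value.
#' @export
compare_enrichment <- function(hrr_records, roh_records, element_type) {
  x <- hrr_records$fraction[hrr_records$element_type == element_type]
  y <- roh_records$fraction[roh_records$element_type == element_type]
  if (length(x) == 0 || length(y) == 0) stop("empty side for element type ", element_type)
  mwu_exact(x, y)
}
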