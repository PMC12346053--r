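# Herd-level aggregation, length-class spectra, chromosome saturation ranks,
# the coefficient of extended heterozygosity and correlation diagnostics.

#' Mean and standard error across herds
#'
#' Arithmetic mean and sample-SD-based standard error (`sd(x)/sqrt(n)`, n-1
#' denominator) — the convention under which the per-herd table cells
#' reproduce their printed "mean +/- SE" values.
#'
#' @param values numeric vector of per-herd values (at least 2 for an SE).
#' @return named numeric vector `c(mean = , se = )`; `se` is `NA` (with a
#'   warning) for fewer than 2 values.
#' @export
herd_mean_se <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    warning("standard error undefined for fewer than 2 values")
    return(c(mean = mean(values), se = NA_real_))
  }
  c(mean = mean(values), se = stats::sd(values) / sqrt(length(values)))
}

#' Length-class edges
#'
#' Half-open classes `[lo, hi)` in Mb, the last class open-ended. The 50 kb
#' scan uses classes 0.05-0.2, 0.2-0.4, 0.4-0.8, 0.8-1.6, >1.6 Mb; the 250 kb
#' scan starts at 0.25 Mb.
#'
#' @param scan `"50kb"` or `"250kb"`.
#' @return numeric vector of class lower edges in bp.
#' @export
class_edges <- function(scan = c("50kb", "250kb")) {
  scan <- match.arg(scan)
  mb <- if (scan == "50kb") c(0.05, 0.2, 0.4, 0.8, 1.6) else c(0.25, 0.4, 0.8, 1.6)
  mb * 1e6
}

.class_labels <- function(edges_bp) {
  mb <- edges_bp / 1e6
  c(paste0(head(mb, -1), "-", mb[-1]), paste0(">", mb[length(mb)]))
}

#' Run counts by length class and herd
#'
#' Each run falls in exactly one half-open class by `length_bp`; per-herd
#' totals are aggregated to mean +/- SE across herds per class, plus the mean
#' proportion per class.
#'
#' @param runs run table with `length_bp` and `herd_id`.
#' @param edges class lower edges in bp ([class_edges()]).
#' @param herds herd ids to tabulate (default: those present, sorted).
#' @return list with `counts` (class x herd matrix), `summary` (per class:
#'   mean, se, proportion).
#' @export
class_counts <- function(runs, edges = class_edges("50kb"), herds = NULL) {
  stopifnot(!is.unsorted(edges, strictly = TRUE))
  if (nrow(runs) > 0 && any(runs$length_bp < edges[1])) {
    stop("run shorter than the first class edge (violates detection min length)")
  }
  herds <- herds %||% sort(unique(runs$herd_id))
  labs <- .class_labels(edges)
  cls <- findInterval(runs$length_bp, edges)   # 1..K by construction
  counts <- matrix(0L, length(labs), length(herds),
                   dimnames = list(labs, herds))
  if (nrow(runs) > 0) {
    tab <- table(factor(cls, levels = seq_along(labs)),
                 factor(runs$herd_id, levels = herds))
    counts[] <- as.integer(tab)
  }
  ms <- t(apply(counts, 1, herd_mean_se))
  props <- if (sum(ms[, "mean"]) > 0) class_proportions(ms[, "mean"])
           else rep(NA_real_, nrow(ms))
  summary <- data.frame(class_mb = labs, mean = ms[, "mean"], se = ms[, "se"],
                        proportion = props, row.names = NULL)
  list(counts = counts, summary = summary)
}

#' Class proportions from class means
#'
#' Each class mean divided by the sum of class means.
#'
#' @param class_means non-negative numeric vector, not all zero.
#' @return fractions summing to 1.
#' @export
class_proportions <- function(class_means) {
  stopifnot(all(class_means >= 0, na.rm = TRUE))
  s <- sum(class_means)
  if (!is.finite(s) || s == 0) stop("all class means are zero")
  class_means / s
}

#' Chromosome saturation rank
#'
#' For chromosome i with N_i runs of T total and length L_i of L_genome:
#' `rank_i = (N_i / T) / (L_i / L_genome)`; 1 means the chromosome carries
#' runs proportionally to its length. Chromosomes whose rank deviates from
#' the mean rank by more than 2 SD of the rank distribution are flagged.
#'
#' @param runs run table with a `chromosome` column.
#' @param build genome build from [genome_build()].
#' @return data.frame per chromosome: `chrom`, `n_runs`, `length_bp`,
#'   `run_share`, `length_share`, `rank`, `outlier`.
#' @export
chromosome_rank <- function(runs, build) {
  T_runs <- nrow(runs)
  if (T_runs == 0) stop("zero total runs")
  n_i <- vapply(build$chrom, function(ch) sum(runs$chromosome == ch), numeric(1))
  L <- build$length_bp
  run_share <- n_i / T_runs
  length_share <- L / sum(L)
  rank <- run_share / length_share
  dev <- abs(rank - mean(rank))
  data.frame(chrom = build$chrom, n_runs = as.integer(n_i), length_bp = L,
             run_share = run_share, length_share = length_share, rank = rank,
             outlier = dev > 2 * stats::sd(rank))
}

#' Coefficient of extended heterozygosity
#'
#' Per individual: total HRR length in autosomes divided by the SNP-covered
#' autosome length (sum over chromosomes of last-minus-first SNP position on
#' the post-QC map). The homozygous analogue (on ROH runs) is the genomic
#' inbreeding coefficient F_ROH.
#'
#' @param runs run table (one run type).
#' @param dataset the post-QC [genotype_dataset()] (supplies the covered
#'   length and the individual roster; individuals without runs get 0).
#' @return named numeric vector, one coefficient per individual.
#' @export
extended_het_coefficient <- function(runs, dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  cov <- sum(covered_length(dataset)$covered_bp)
  if (cov <= 0) stop("zero SNP-covered length")
  tot <- tapply(runs$length_bp, runs$individual_id, sum)
  ids <- dataset$individuals$individual_id
  out <- rep(0, length(ids))
  names(out) <- ids
  out[names(tot)] <- tot
  out / cov
}

#' Correlation between run share and length share across chromosomes
#'
#' Pearson on the values; Spearman on midranks; two-sided p-values from the
#' t approximation with n - 2 degrees of freedom.
#'
#' @param run_share per-chromosome share of runs.
#' @param length_share per-chromosome share of genome length.
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`.
#' @export
rank_correlations <- function(run_share, length_share) {
  stopifnot(length(run_share) == length(length_share))
  if (stats::sd(run_share) == 0 || stats::sd(length_share) == 0) {
    stop("constant vector: correlation undefined")
  }
  n <- length(run_share)
  t_p <- function(r) {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  r <- stats::cor(run_share, length_share)
  rho <- stats::cor(rank(run_share), rank(length_share))
  list(pearson_r = r, pearson_p = t_p(r),
       spearman_rho = rho, spearman_p = t_p(rho))
}
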