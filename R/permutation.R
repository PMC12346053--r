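# Permutation null for island significance: shuffle individuals across herds,
# rebuild groups, re-call islands from the *precomputed* runs, match against
# the observed islands, and compare support proportions.

#' Permutation configuration
#'
#' @param n_permutations number of label permutations (the study design used
#'   10,000; the default is sized for interactive use and scales freely).
#' @param n_groups number of permuted groups per replicate.
#' @param group_sizes sizes of the permuted groups; `NULL` uses the observed
#'   herd sizes so that every individual is assigned. The study's
#'   "six groups of sixty" mode is `rep(60, 6)` (six cows idle per replicate
#'   with 366 cows).
#' @param seed master RNG seed; per-replicate streams are derived by counter.
#' @param min_matched_groups an island matched in fewer permuted groups than
#'   this is marked not evaluable and gets no p-values.
#' @return a list of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000, n_groups = 6,
                               group_sizes = NULL, seed = 1,
                               min_matched_groups = 3) {
  stopifnot(n_permutations >= 0, n_groups >= 1,
            is.null(group_sizes) || length(group_sizes) == n_groups)
  structure(list(n_permutations = as.integer(n_permutations),
                 n_groups = as.integer(n_groups),
                 group_sizes = group_sizes, seed = as.integer(seed),
                 min_matched_groups = as.integer(min_matched_groups)),
            class = "permutation_config")
}

#' Shuffle individuals into permuted groups
#'
#' A uniformly random permutation of the individuals split into the configured
#' group sizes; individuals beyond `sum(group_sizes)` stay unassigned for the
#' replicate. Deterministic given `(config$seed, replicate_index)`.
#'
#' @param individuals character vector of individual ids.
#' @param config a [permutation_config()]; `group_sizes = NULL` splits as
#'   evenly as possible into `n_groups`.
#' @param replicate_index replicate counter (1-based).
#' @return list of id vectors, one per group, with attribute `unassigned`.
#' @export
shuffle_groups <- function(individuals, config, replicate_index) {
  n <- length(individuals)
  sizes <- config$group_sizes
  if (is.null(sizes)) {
    base <- n %/% config$n_groups
    sizes <- rep(base, config$n_groups)
    extra <- n - base * config$n_groups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  }
  if (sum(sizes) > n) stop("group sizes exceed population (", sum(sizes), " > ", n, ")")
  perm <- with_seed(config$seed + as.integer(replicate_index), sample(individuals))
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1L) + 1L)
  groups <- lapply(seq_along(sizes), function(g) perm[starts[g]:ends[g]])
  attr(groups, "unassigned") <- if (sum(sizes) < n) perm[(sum(sizes) + 1L):n] else character(0)
  groups
}

#' Exact Mann-Whitney U test
#'
#' Two-sample rank test. For pooled sample size at most `exact_limit` the
#' p-value is computed by exhaustive enumeration of all rank assignments
#' (valid under ties, where the classical exact distribution is not); above
#' that, the tie-corrected normal approximation is used. The two-sided exact
#' p is the permutation probability of a U at least as far from its null mean
#' as observed.
#'
#' @param x,y numeric samples (both non-empty).
#' @param alternative `"two.sided"`, `"greater"` (x tends larger) or `"less"`.
#' @param exact_limit pooled-size cutoff for exhaustive enumeration.
#' @return the p-value.
#' @export
mwu_exact <- function(x, y, alternative = c("two.sided", "greater", "less"),
                      exact_limit = 20) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  eps <- 1e-9
  if (N <= exact_limit) {
    combs <- utils::combn(N, n1)
    Us <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
    switch(alternative,
           two.sided = mean(abs(Us - mu) >= abs(U - mu) - eps),
           greater = mean(Us >= U - eps),
           less = mean(Us <= U + eps))
  } else {
    tie <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie^3 - tie) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)
    z <- (U - mu) / sqrt(sigma2)
    switch(alternative,
           two.sided = min(1, 2 * stats::pnorm(-abs(z))),
           greater = stats::pnorm(z, lower.tail = FALSE),
           less = stats::pnorm(z))
  }
}

#' Permutation null and significance for observed islands
#'
#' For every replicate, individuals are shuffled into permuted groups; per
#' group the incidence track is rebuilt from the precomputed runs (runs are
#' a property of the individual, so group membership changes incidence only
#' — `detect_runs` is never re-executed), islands are re-called at the same
#' threshold, and each observed island is matched by largest overlap. Matched
#' supports are aggregated per group index (the convention under which 10,000
#' permutations collapse to one value per permuted herd): the per-group value
#' is the mean matched support across replicates. Per observed island the
#' permutation mean/SE are taken across those per-group values, the
#' Mann-Whitney p compares the observed support against them, and the
#' empirical p is `(1 + #{permuted support >= observed}) / (1 + #permuted)`
#' over the full matched distribution.
#'
#' @param dataset the post-QC [genotype_dataset()].
#' @param runs precomputed run table from [detect_all_runs()] (one run type).
#' @param observed_islands island table (one row per observed island, with
#'   `chrom`, `start_bp`, `end_bp`, `support`).
#' @param island_threshold calling threshold used for the permuted groups
#'   (use the threshold the observed islands were called at).
#' @param config a [permutation_config()].
#' @return data.frame with one row per observed island: observed support,
#'   per-group permuted mean supports, permutation mean and SE, exact
#'   Mann-Whitney and empirical p-values, the number of matched groups and the
#'   evaluable flag. The full replicate-by-group support array is attached as
#'   attribute `"replicate_supports"`.
#' @export
build_null <- function(dataset, runs, observed_islands, island_threshold, config) {
  stopifnot(inherits(dataset, "genotype_dataset"),
            inherits(config, "permutation_config"))
  n_isl <- nrow(observed_islands)
  if (n_isl == 0L) {
    return(data.frame())
  }
  ids <- dataset$individuals$individual_id
  gi <- .marker_global_index(dataset$map)
  ir <- .run_index_ranges(runs, gi)
  run_ind <- runs$individual_id
  chrom <- dataset$map$chrom
  pos <- dataset$map$pos_bp
  n_rep <- config$n_permutations
  n_grp <- config$n_groups

  sup <- array(NA_real_, dim = c(n_isl, n_grp, max(n_rep, 1L)))
  if (n_rep > 0L) {
    # index runs by individual once
    run_rows_by_ind <- split(seq_along(run_ind), run_ind)
    for (r in seq_len(n_rep)) {
      part <- shuffle_groups(ids, config, r)
      for (g in seq_len(n_grp)) {
        members <- part[[g]]
        rows <- unlist(run_rows_by_ind[members], use.names = FALSE)
        inc <- .coverage_fast(ir$i1[rows], ir$i2[rows], gi$n) / length(members)
        isl <- .call_islands_core(inc, chrom, pos, island_threshold)
        if (nrow(isl) == 0L) next
        for (j in seq_len(n_isl)) {
          mj <- match_islands(observed_islands[j, ], isl)
          if (!is.na(mj)) sup[j, g, r] <- isl$support[mj]
        }
      }
    }
  }

  obs <- observed_islands$support
  grp_means <- matrix(NA_real_, n_isl, n_grp)
  perm_mean <- perm_se <- p_mwu <- p_emp <- rep(NA_real_, n_isl)
  n_matched_groups <- integer(n_isl)
  evaluable <- rep(NA, n_isl)
  for (j in seq_len(n_isl)) {
    if (n_rep == 0L) next
    gm <- rowMeans(matrix(sup[j, , ], nrow = n_grp), na.rm = TRUE)
    gm[is.nan(gm)] <- NA_real_
    grp_means[j, ] <- gm
    matched <- !is.na(gm)
    n_matched_groups[j] <- sum(matched)
    evaluable[j] <- n_matched_groups[j] >= config$min_matched_groups
    if (evaluable[j]) {
      ms <- herd_mean_se(gm[matched])
      perm_mean[j] <- ms[["mean"]]
      perm_se[j] <- ms[["se"]]
      p_mwu[j] <- mwu_exact(obs[j], gm[matched])
      all_sup <- sup[j, , ]
      all_sup <- all_sup[!is.na(all_sup)]
      p_emp[j] <- (1 + sum(all_sup >= obs[j] - 1e-12)) / (1 + length(all_sup))
    }
  }
  res <- data.frame(
    chrom = observed_islands$chrom,
    start_bp = observed_islands$start_bp,
    end_bp = observed_islands$end_bp,
    n_snps = observed_islands$n_snps %||% rep(NA_integer_, n_isl),
    length_kb = island_length_kb(observed_islands),
    group = observed_islands$group %||% rep(NA_character_, n_isl),
    observed_support = obs,
    stringsAsFactors = FALSE)
  colnames(grp_means) <- paste0("perm_group_", seq_len(n_grp))
  res <- cbind(res, as.data.frame(grp_means))
  res$perm_mean <- perm_mean
  res$perm_se <- perm_se
  res$p_mwu <- p_mwu
  res$p_empirical <- p_emp
  res$n_matched_groups <- n_matched_groups
  res$evaluable <- evaluable
  attr(res, "replicate_supports") <- sup
  res
}

# diff-trick coverage from precomputed global index ranges
.coverage_fast <- function(i1, i2, n) {
  if (length(i1) == 0L) return(numeric(n))
  inc <- tabulate(i1, nbins = n + 1L) - tabulate(i2 + 1L, nbins = n + 1L)
  cumsum(inc[seq_len(n)])
}
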