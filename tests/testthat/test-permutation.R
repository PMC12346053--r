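# Group shuffling, the exact Mann-Whitney test and the permutation null.

test_that("shuffle_groups is deterministic and respects group sizes", {
  ids <- sprintf("cow_%03d", 1:366)
  cfg <- permutation_config(n_permutations = 10, n_groups = 6,
                            group_sizes = rep(60, 6), seed = 9)
  g1 <- shuffle_groups(ids, cfg, 3)
  g2 <- shuffle_groups(ids, cfg, 3)
  expect_identical(g1, g2)
  expect_false(identical(g1, shuffle_groups(ids, cfg, 4)))
  expect_identical(lengths(g1), rep(60L, 6))
  expect_identical(length(attr(g1, "unassigned")), 6L)
  expect_identical(sort(c(unlist(g1), attr(g1, "unassigned"))), sort(ids))

  # observed herd sizes assign everyone
  sizes <- c(57, 85, 73, 44, 58, 54)
  cfg2 <- permutation_config(n_groups = 6, group_sizes = sizes, seed = 9)
  g3 <- shuffle_groups(sprintf("c%03d", seq_len(sum(sizes))), cfg2, 1)
  expect_identical(lengths(g3), as.integer(sizes))
  expect_identical(length(attr(g3, "unassigned")), 0L)

  expect_error(shuffle_groups(ids[1:100], cfg, 1), "exceed")
})

test_that("shuffling does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(shuffle_groups(letters, permutation_config(seed = 1), 1))
  expect_identical(runif(1), a)
})

test_that("mwu_exact matches hand-derived and enumerated p-values", {
  expect_identical(mwu_exact(c(1, 2, 3), c(1, 2, 3)), 1)
  # one value against six: U uniform on 0..6, two-sided p = 6/7
  expect_equal(mwu_exact(5, c(1, 2, 3, 4, 6, 7)), 6 / 7)
  # fully separated 3 vs 3: p = 2 / choose(6,3)
  expect_equal(mwu_exact(c(0.9, 0.8, 0.85), c(0.1, 0.2, 0.15)), 0.1)

  set.seed(303)
  for (trial in 1:50) {
    x <- sample(1:6, 4, replace = TRUE) / 2   # ties likely
    y <- sample(1:6, 5, replace = TRUE) / 2
    expect_equal(mwu_exact(x, y), mwu_brute(x, y), info = paste("trial", trial))
  }
  expect_error(mwu_exact(numeric(0), 1), "empty sample")
})

test_that("mwu_exact agrees with wilcox.test where both are exact", {
  set.seed(404)
  for (trial in 1:20) {
    x <- rnorm(5); y <- rnorm(6)   # continuous, no ties
    w <- wilcox.test(x, y, exact = TRUE)$p.value
    expect_equal(mwu_exact(x, y), w, tolerance = 1e-12)
  }
  # large samples: tie-corrected normal approximation
  x <- rnorm(30); y <- rnorm(25) + 0.5
  w <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
  expect_equal(mwu_exact(x, y), w, tolerance = 1e-12)
})

make_two_herd_sim <- function(seed, h = 0.7, herds = "1") {
  sim_config(seed = seed, herd_sizes = c(20, 20),
             build = data.frame(chrom = 1L, length_bp = 8e6),
             n_markers = 160, fst = 0.01, missing_rate = 0.002,
             islands = data.frame(chrom = 1L, start_bp = 3e6, end_bp = 3.5e6,
                                  herds = herds, h = h, stringsAsFactors = FALSE),
             roh_tracts = NULL)
}

test_that("build_null separates a single-herd island from a shared one", {
  # island carried by herd 1 only: high observed support vs diluted permuted
  sim <- simulate_dataset(make_two_herd_sim(515))
  ds <- sim$dataset
  runs <- detect_all_runs(ds, hrr_params())
  tr <- snp_incidence(runs, ds, "herd_1")
  isl <- call_islands(tr, 0.25)
  truth <- sim$truth$islands
  keep <- !is.na(match_islands(
    data.frame(chrom = truth$chrom, start_bp = truth$start_bp,
               end_bp = truth$end_bp), isl))
  expect_true(keep)
  cfg <- permutation_config(n_permutations = 200, n_groups = 2,
                            group_sizes = c(20, 20), seed = 7,
                            min_matched_groups = 2)
  sig <- build_null(ds, runs, isl, 0.25, cfg)
  planted_row <- match_islands(
    data.frame(chrom = truth$chrom, start_bp = truth$start_bp,
               end_bp = truth$end_bp), isl)
  expect_true(sig$evaluable[planted_row])
  expect_lt(sig$p_empirical[planted_row], 0.05)

  # island carried by every cow of both herds: permuted support = observed,
  # p near 1 by symmetry
  sim2 <- simulate_dataset(make_two_herd_sim(516, h = 1, herds = "1,2"))
  ds2 <- sim2$dataset
  runs2 <- detect_all_runs(ds2, hrr_params())
  tr2 <- snp_incidence(runs2, ds2, "herd_1")
  isl2 <- call_islands(tr2, 0.25)
  row2 <- match_islands(
    data.frame(chrom = 1L, start_bp = 3e6, end_bp = 3.5e6), isl2)
  sig2 <- build_null(ds2, runs2, isl2, 0.25, cfg)
  expect_true(sig2$evaluable[row2])
  expect_gt(sig2$p_empirical[row2], 0.5)
  expect_equal(sig2$perm_mean[row2], sig2$observed_support[row2],
               tolerance = 0.1)
})

test_that("islands matched in too few groups are not evaluable", {
  sim <- simulate_dataset(make_two_herd_sim(517))
  ds <- sim$dataset
  runs <- detect_all_runs(ds, hrr_params())
  tr <- snp_incidence(runs, ds, "herd_1")
  isl <- call_islands(tr, 0.25)
  # islands called at 0.55: permuted mixed groups dilute the single-herd
  # signal below the threshold, so matches are impossible and the island
  # cannot be evaluated
  strong <- call_islands(tr, 0.55)
  expect_gt(nrow(strong), 0)
  cfg <- permutation_config(n_permutations = 50, n_groups = 2,
                            group_sizes = c(20, 20), seed = 7,
                            min_matched_groups = 2)
  sig <- build_null(ds, runs, strong, 0.55, cfg)
  expect_true(any(!sig$evaluable))
  expect_true(all(is.na(sig$p_empirical[!sig$evaluable])))
  expect_true(all(is.na(sig$p_mwu[!sig$evaluable])))

  # zero observed islands is an empty result, not an error
  expect_identical(nrow(build_null(ds, runs, isl[0, ], 0.25, cfg)), 0L)
})

test_that("build_null never re-runs detection", {
  sim <- simulate_dataset(make_two_herd_sim(518))
  ds <- sim$dataset
  runs <- detect_all_runs(ds, hrr_params())
  isl <- call_islands(snp_incidence(runs, ds, "herd_1"), 0.25)
  calls <- 0L
  testthat::local_mocked_bindings(
    detect_runs = function(...) { calls <<- calls + 1L; stop("not allowed") },
    detect_all_runs = function(...) { calls <<- calls + 1L; stop("not allowed") },
    .package = "hrrscan")
  cfg <- permutation_config(n_permutations = 5, n_groups = 2,
                            group_sizes = c(20, 20), seed = 1,
                            min_matched_groups = 2)
  sig <- build_null(ds, runs, isl, 0.25, cfg)
  expect_identical(calls, 0L)
})
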