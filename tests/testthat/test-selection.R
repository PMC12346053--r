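# Tajima's D scan and repeat-element enrichment.

test_that("tajima_constants match direct summation", {
  expect_identical(tajima_constants(2)$a1, 1)
  expect_equal(tajima_constants(4)$a1, 1 + 1 / 2 + 1 / 3)
  tc <- tajima_constants(10)
  n <- 10
  a1 <- sum(1 / 1:9); a2 <- sum(1 / (1:9)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  expect_equal(tc$e1, c1 / a1)
  expect_equal(tc$e2, c2 / (a1^2 + a2))
  expect_error(tajima_constants(1), "at least 2")
})

test_that("tajima_d equals the pairwise-difference oracle", {
  # S = 0 window is flagged undefined
  expect_true(is.na(tajima_d(matrix(0L, 3, 4))$D))
  # single site, both individuals heterozygous
  got <- tajima_d(matrix(1L, 2, 1))
  want <- tajima_oracle(matrix(1L, 2, 1))
  expect_equal(got$pi, want$pi)
  expect_equal(got$D, want$D)

  set.seed(99)
  for (trial in 1:50) {
    g <- matrix(sample(0:2, 8 * 20, replace = TRUE), 8, 20)
    got <- tajima_d(g)
    want <- tajima_oracle(g)
    expect_identical(got$S, as.integer(want$S))
    expect_equal(got$pi, want$pi, tolerance = 1e-9)
    if (want$S > 0) expect_equal(got$D, want$D, tolerance = 1e-9)
  }
})

test_that("D is positive for balanced frequencies, negative for rare variants", {
  # many sites near frequency 0.5 -> excess pairwise diversity
  bal <- matrix(1L, 10, 30)
  expect_gt(tajima_d(bal)$D, 0)
  # singleton-like sites: one het individual per site
  rare <- matrix(0L, 10, 30)
  rare[cbind(rep(1L, 30), 1:30)] <- 1L
  expect_lt(tajima_d(rare)$D, 0)
})

test_that("scan_tajima tiles chromosomes and flags against 3 SD", {
  set.seed(7)
  calls <- matrix(sample(0:2, 20 * 60, replace = TRUE, prob = c(.35, .3, .35)),
                  20, 60)
  ds <- make_dataset(calls, pos = sort(sample(1:1.2e6, 60)))
  sc <- scan_tajima(ds, "herd_1", tajima_scan_config(window_bp = 1e5))
  # every SNP belongs to exactly one window
  expect_identical(sum(sc$windows$n_sites), 60L)
  expect_true(all(sc$windows$end_bp - sc$windows$start_bp == 1e5))
  expect_true(all(ds$map$pos_bp %/% 1e5 %in% (sc$windows$start_bp / 1e5)))
  # flags recompute from the report threshold
  thr <- sc$report$threshold[1]
  expect_identical(sc$windows$outlier,
                   !is.na(sc$windows$D) & sc$windows$D > thr)
  expect_identical(sc$report$n_exceeding[1], sum(sc$windows$outlier))
  expect_identical(sc$report$max_d[1], max(sc$windows$D, na.rm = TRUE))
  expect_error(scan_tajima(ds, ds$individuals$individual_id[1]), "at least 2")
})

test_that("an engineered balanced window is flagged above 3 SD", {
  set.seed(8)
  m <- 320   # 40 windows x 8 SNPs
  n_ind <- 24
  p <- runif(m, 0.15, 0.5)
  calls <- matrix(rbinom(n_ind * m, 2L, rep(p, each = n_ind)), n_ind, m)
  # one window stuffed with half-frequency, all-heterozygous sites
  hot <- 161:168
  calls[, hot] <- 1L
  pos <- seq(5000, by = 12500, length.out = m)  # 8 SNPs per 100 kb window
  ds <- make_dataset(calls, pos = pos)
  sc <- scan_tajima(ds, "herd_1", tajima_scan_config())
  hot_window <- floor(pos[hot[1]] / 1e5) * 1e5
  row <- sc$windows[sc$windows$start_bp == hot_window, ]
  expect_true(row$outlier)
  expect_identical(sc$report$max_d, row$D)
})

test_that("element_fraction merges intervals before intersecting", {
  island <- data.frame(chrom = 1L, start_bp = 1001, end_bp = 2001)  # 1000 bp
  # no overlap
  far <- data.frame(chrom = 1L, start_bp = 5001, end_bp = 6000,
                    element_type = "LINE")
  expect_identical(element_fraction(island, far)$fraction, 0)
  # full coverage
  full <- data.frame(chrom = 1L, start_bp = 500, end_bp = 2500,
                     element_type = "LINE")
  expect_identical(element_fraction(island, full)$fraction, 1)
  # two overlapping intervals covering 600 bp after merging
  two <- data.frame(chrom = 1L, start_bp = c(1001, 1301), end_bp = c(1500, 1600),
                    element_type = "SINE")
  expect_equal(element_fraction(island, two)$fraction, 0.6)
  # invariant to fragmentation and order
  frag <- data.frame(chrom = 1L,
                     start_bp = c(1301, 1001, 1101, 1451), end_bp = c(1600, 1100, 1500, 1600),
                     element_type = "SINE")
  expect_equal(element_fraction(island, frag)$fraction, 0.6)
  # other chromosome does not count
  other <- data.frame(chrom = 2L, start_bp = 1001, end_bp = 2000,
                      element_type = "LTR")
  expect_identical(element_fraction(island, other)$fraction, 0)
})

test_that("read_element_bed converts 0-based half-open to 1-based inclusive", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("1\t999\t2000\tL1", "chr2\t0\t100\tL2"), bed)
  b <- read_element_bed(bed, "LINE")
  expect_identical(b$start_bp, c(1000, 1))
  expect_identical(b$end_bp, c(2000, 100))
  expect_identical(b$element_type, rep("LINE", 2))
  writeLines("1\t200\t100", bed)
  expect_error(read_element_bed(bed, "LINE"), "end <= start")
})

test_that("compare_enrichment runs the exact test on island fractions", {
  recs <- function(f, tp = "LINE") data.frame(element_type = tp, fraction = f)
  expect_identical(compare_enrichment(recs(c(.2, .3, .4)), recs(c(.2, .3, .4)),
                                      "LINE"), 1)
  expect_equal(compare_enrichment(recs(c(0.9, 0.8, 0.85)),
                                  recs(c(0.1, 0.2, 0.15)), "LINE"), 0.1)
  none <- data.frame(element_type = character(0), fraction = numeric(0))
  expect_error(compare_enrichment(none, recs(0.5), "LINE"), "empty side")

  # a planted shift of +0.15 at n = 20 per side is detected
  set.seed(77)
  hrr <- recs(pmin(1, pmax(0, rnorm(20, 0.55, 0.1))))
  roh <- recs(pmin(1, pmax(0, rnorm(20, 0.40, 0.1))))
  expect_lt(compare_enrichment(hrr, roh, "LINE"), 0.05)
})
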