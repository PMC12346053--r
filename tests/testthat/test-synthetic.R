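# The herd-genotype simulator and its truth table.

test_that("fixtures are deterministic and dialect-compatible", {
  a <- emit_fixture("mini-island")
  b <- emit_fixture("mini-island")
  expect_identical(a$dataset$calls, b$dataset$calls)
  expect_identical(a$dataset$map, b$dataset$map)
  expect_identical(a$truth$islands, b$truth$islands)
  # written files are byte-identical too
  f1 <- tempfile(); f2 <- tempfile()
  write_ped_map(a$dataset, paste0(f1, ".ped"), paste0(f1, ".map"))
  write_ped_map(b$dataset, paste0(f2, ".ped"), paste0(f2, ".map"))
  expect_identical(readLines(paste0(f1, ".ped")), readLines(paste0(f2, ".ped")))
  expect_error(emit_fixture("no-such"), "arg")
})

test_that("simulated genotypes pass QC at the configured rates", {
  sim <- simulate_dataset(sim_config(seed = 21, herd_sizes = c(40, 40),
                                     build = data.frame(chrom = 1:2,
                                                        length_bp = c(4e7, 4e7)),
                                     n_markers = 2000, islands = NULL,
                                     roh_tracts = NULL))
  ds <- sim$dataset
  # genotyping rate above 0.99
  expect_gt(mean(!is.na(ds$calls)), 0.99)
  qc <- apply_qc(ds, qc_params())
  expect_identical(ncol(qc$calls), 2000L)
  # roughly 10% of markers below MAF 0.01 in the ancestral spectrum
  rare <- mean(pmin(sim$truth$ancestral_freq, 1 - sim$truth$ancestral_freq) < 0.01)
  expect_gt(rare, 0.05); expect_lt(rare, 0.15)
})

test_that("within-herd genotypes are Hardy-Weinberg consistent", {
  sim <- simulate_dataset(sim_config(seed = 22, herd_sizes = c(120),
                                     build = data.frame(chrom = 1L, length_bp = 8e7),
                                     n_markers = 1500, fst = 0,
                                     missing_rate = 0, islands = NULL,
                                     roh_tracts = NULL))
  calls <- sim$dataset$calls
  maf <- compute_maf(sim$dataset)
  test_one <- function(j) {
    g <- calls[, j]
    p <- mean(g) / 2
    expd <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    obs <- tabulate(g + 1L, 3L)
    keep <- expd > 0
    sum((obs[keep] - expd[keep])^2 / expd[keep])
  }
  informative <- which(!is.na(maf) & maf > 0.05)
  stat <- vapply(informative, test_one, numeric(1))
  # chi-square GOF, 1 df; non-rejection rate at alpha = 0.01 must be >= 90%
  reject <- mean(stat > qchisq(0.99, df = 1))
  expect_lt(reject, 0.10)
})

test_that("planted islands raise carrier heterozygosity to at least h", {
  cfg <- sim_config(seed = 23, herd_sizes = c(50, 50),
                    build = data.frame(chrom = 1L, length_bp = 1e7),
                    n_markers = 200, missing_rate = 0,
                    islands = data.frame(chrom = 1L, start_bp = 4e6,
                                         end_bp = 5e6, herds = "1", h = 0.6,
                                         stringsAsFactors = FALSE),
                    roh_tracts = NULL)
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  mk <- ds$map$pos_bp >= 4e6 & ds$map$pos_bp <= 5e6
  carriers <- ds$individuals$herd_id == "herd_1"
  het <- mean(ds$calls[carriers, mk] == 1L)
  expect_gte(het, 0.6 - 0.05)
  # non-carriers stay at background heterozygosity
  expect_lt(mean(ds$calls[!carriers, mk] == 1L), 0.5)
  # truth records expressors consistent with the genotypes
  expr_ids <- strsplit(sim$truth$islands$expressors, ",")[[1]]
  rows <- match(expr_ids, ds$individuals$individual_id)
  expect_true(all(ds$calls[rows, mk] == 1L))
})

test_that("planted ROH tracts are shared homozygous haplotypes", {
  cfg <- sim_config(seed = 24, herd_sizes = c(30),
                    build = data.frame(chrom = 1L, length_bp = 1e7),
                    n_markers = 150, missing_rate = 0, islands = NULL,
                    roh_tracts = data.frame(chrom = 1L, start_bp = 2e6,
                                            end_bp = 6e6, herds = "1",
                                            freq = 1, stringsAsFactors = FALSE))
  sim <- simulate_dataset(cfg)
  ds <- sim$dataset
  mk <- which(ds$map$pos_bp >= 2e6 & ds$map$pos_bp <= 6e6)
  seg <- ds$calls[, mk]
  expect_true(all(seg %in% c(0L, 2L)))
  # one shared haplotype: every carrier identical
  expect_true(all(apply(seg, 2, function(col) length(unique(col)) == 1L)))
  runs <- detect_all_runs(ds, roh_params())
  covers <- vapply(ds$individuals$individual_id, function(id) {
    mine <- runs[runs$individual_id == id, ]
    any(mine$start_bp <= 2e6 + 1e5 & mine$end_bp >= 6e6 - 1e5)
  }, logical(1))
  expect_true(all(covers))
})

test_that("realized Fst tracks the Balding-Nichols parameter", {
  base <- function(f, seed) {
    sim_config(seed = seed, herd_sizes = rep(60, 6),
               build = data.frame(chrom = 1L, length_bp = 2.5e8),
               n_markers = 5000, fst = f, missing_rate = 0,
               islands = NULL, roh_tracts = NULL)
  }
  # no-differentiation limit
  f0 <- wc_fst(simulate_dataset(base(0, 31))$dataset)
  expect_lt(abs(f0), 0.01)
  # F = 0.05 recovers within [0.03, 0.07]
  f5 <- wc_fst(simulate_dataset(base(0.05, 32))$dataset)
  expect_gt(f5, 0.03); expect_lt(f5, 0.07)
})

test_that("default configuration reproduces the study shape", {
  cfg <- sim_config(seed = 1)
  expect_identical(cfg$herd_sizes, c(57L, 85L, 73L, 44L, 58L, 54L))
  expect_identical(cfg$n_markers, 48108L)
  expect_identical(nrow(cfg$build), 29L)
  expect_true(all(cfg$islands$end_bp - cfg$islands$start_bp >= 250000))
  expect_true(all(cfg$roh_tracts$end_bp - cfg$roh_tracts$start_bp >= 1e6))
  expect_error(sim_config(seed = 1, islands = data.frame(
    chrom = 1L, start_bp = 1, end_bp = 9e9, herds = "1", h = 0.5)),
    "outside chromosome bounds")
})
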