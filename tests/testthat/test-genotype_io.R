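# PED/MAP parsing, QC filtering and allele-frequency computation.

write_lines_tmp <- function(lines, ext) {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

test_that("PED parsing keeps pseudo-phenotypes verbatim and codes calls", {
  map <- write_lines_tmp(c("1\tsnpA\t0\t1000", "1\tsnpB\t0\t2000"), ".map")
  ped <- write_lines_tmp(c(
    "h1 cow1 0 0 0 2.1 A A A G",
    "h1 cow2 0 0 0 -8 A G 0 0"), ".ped")
  ds <- read_ped_map(ped, map)
  expect_identical(ds$individuals$pheno, c("2.1", "-8"))
  expect_true(is.character(ds$individuals$pheno))
  expect_identical(unname(ds$calls[1, ]), c(0L, 1L))
  expect_identical(unname(ds$calls[2, ]), c(1L, NA_integer_))
  expect_identical(ds$map$allele_a, c("A", "A"))
  expect_identical(ds$map$allele_b, c("G", "G"))
})

test_that("malformed PED input produces named parse/coding errors", {
  map <- write_lines_tmp(c("1\tsnpA\t0\t1000", "1\tsnpB\t0\t2000"), ".map")
  expect_error(read_ped_map(write_lines_tmp(character(0), ".ped"), map),
               "empty PED")
  expect_error(read_ped_map(write_lines_tmp("h1 cow1 0 0 0 1 A A", ".ped"), map),
               "line 1")
  expect_error(read_ped_map(
    write_lines_tmp("h1 cow1 0 0 0 1 A A X G", ".ped"), map),
    "coding error.*'X'")
  expect_error(read_ped_map(
    write_lines_tmp("h1 cow1 0 0 0 1 A 0 G G", ".ped"), map),
    "half-missing")
  badmap <- write_lines_tmp(c("1\tdup\t0\t1000", "1\tdup\t0\t2000"), ".map")
  expect_error(read_ped_map(
    write_lines_tmp("h1 cow1 0 0 0 1 A A G G", ".ped"), badmap),
    "duplicate marker")
})

test_that("write/read round-trips datasets exactly and writes 0 0 for missing", {
  fx <- emit_fixture("mini-island")
  ped <- tempfile(fileext = ".ped"); map <- tempfile(fileext = ".map")
  write_ped_map(fx$dataset, ped, map)
  back <- read_ped_map(ped, map)
  expect_identical(unname(back$calls), unname(fx$dataset$calls))
  expect_identical(back$map$pos_bp, fx$dataset$map$pos_bp)
  expect_identical(back$map$snp_id, fx$dataset$map$snp_id)
  expect_identical(back$individuals, fx$dataset$individuals)

  # idempotence: a second write/read cycle is a fixed point
  ped2 <- tempfile(fileext = ".ped"); map2 <- tempfile(fileext = ".map")
  write_ped_map(back, ped2, map2)
  expect_identical(readLines(ped2), readLines(ped))
  expect_identical(readLines(map2), readLines(map))

  # PLINK missing convention
  calls <- rbind(c(1L, NA_integer_), c(0L, 2L))
  ds <- make_dataset(calls)
  write_ped_map(ds, ped, map)
  expect_match(readLines(ped)[1], "0 0$")
})

test_that("QC filters in the documented order and matches brute force", {
  # 10 markers x 4 individuals with a known missingness pattern
  set.seed(42)
  calls <- matrix(sample(0:2, 40, replace = TRUE), 4, 10)
  calls[1, 1:3] <- NA     # marker 1-3 get 25% missing
  calls[2:4, 4] <- NA     # marker 4: 75% missing
  calls[2, ] <- NA        # individual 2: all missing
  ds <- make_dataset(calls)
  par <- qc_params(max_snp_missing = 0.5, max_ind_missing = 0.5)
  out <- apply_qc(ds, par)

  # brute force: marker filter first, then individual filter
  keep_m <- colMeans(is.na(calls)) <= 0.5
  keep_i <- rowMeans(is.na(calls[, keep_m])) <= 0.5
  expect_identical(ncol(out$calls), sum(keep_m))
  expect_identical(nrow(out$calls), sum(keep_i))
  expect_identical(unname(out$calls), unname(calls[keep_i, keep_m]))

  # idempotence
  again <- apply_qc(out, par)
  expect_identical(again$calls, out$calls)
  expect_identical(again$map, out$map)
})

test_that("marker/individual thresholds are inclusive and MAF variant drops monomorphics", {
  # 6% missing marker at threshold 0.05: removed
  calls <- matrix(1L, 50, 2)
  calls[1:3, 1] <- NA   # 6% missing
  ds <- make_dataset(calls)
  out <- apply_qc(ds, qc_params(max_snp_missing = 0.05, max_ind_missing = 1))
  expect_identical(ncol(out$calls), 1L)

  # monomorphic marker: removed under min_maf = 0.01, kept without
  calls <- cbind(rep(0L, 10), rep(1L, 10))
  ds <- make_dataset(calls)
  expect_identical(ncol(apply_qc(ds, qc_params())$calls), 2L)
  out <- apply_qc(ds, qc_params(min_maf = 0.01))
  expect_identical(out$map$snp_id, "t_snp_002")

  # survivors all satisfy MAF >= 0.01
  expect_true(all(compute_maf(out) >= 0.01))

  # all markers removed -> explicit error
  mono <- make_dataset(matrix(0L, 5, 3))
  expect_error(apply_qc(mono, qc_params(min_maf = 0.01)), "empty after QC")

  # non-autosomes dropped
  ds30 <- make_dataset(matrix(1L, 4, 2), chrom = 30L)
  expect_error(apply_qc(ds30, qc_params()), "no autosomal markers")
})

test_that("compute_maf counts non-missing alleles only", {
  # AA AA AA AA -> 0; AA AB BB AB -> 0.5
  expect_identical(compute_maf(make_dataset(matrix(0L, 4, 1))), 0)
  expect_identical(compute_maf(make_dataset(matrix(c(0L, 1L, 2L, 1L), 4, 1))), 0.5)
  # AA AA AB + one missing -> counts 5:1 -> 1/6
  ds <- make_dataset(matrix(c(0L, 0L, 1L, NA), 4, 1))
  expect_equal(compute_maf(ds), 1 / 6)
  # all missing -> NA with warning
  expect_warning(maf <- compute_maf(make_dataset(matrix(NA_integer_, 3, 1))),
                 "undefined")
  expect_true(is.na(maf))
  expect_error(compute_maf(ds, "no_such_marker"), "unknown marker")
})

test_that("genome build and covered length are consistent", {
  build <- genome_build()
  expect_identical(build$chrom, 1:29)
  expect_true(all(build$length_bp > 4e7))
  fx <- emit_fixture("null")
  cov <- covered_length(fx$dataset)
  expect_identical(cov$chrom, c(1L, 2L))
  for (ch in 1:2) {
    p <- fx$dataset$map$pos_bp[fx$dataset$map$chrom == ch]
    expect_equal(cov$covered_bp[ch], max(p) - min(p))
  }
})
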