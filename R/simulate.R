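# Herd-structured SNP-array genotype simulator.
#
# Between-herd differentiation follows the Balding-Nichols model: for a
# marker with ancestral allele frequency p and differentiation F, each herd
# draws its frequency from Beta(p (1-F)/F, (1-p)(1-F)/F), and genotypes are
# Hardy-Weinberg within herd. Planted heterozygote islands and shared
# homozygous tracts overlay this background, and a truth table records them.

#' Simulation configuration
#'
#' Defaults emulate the study population: 366 cows in six herds of
#' 57/85/73/44/58/54, ~48,108 autosomal SNPs spread over 29 bovine autosomes
#' proportionally to chromosome length with gamma-distributed spacing
#' (mean ~= length / markers, shape 4, so the 1 Mb gap rule is exercised),
#' ~10% of SNPs rare (ancestral MAF < 0.01, half of those monomorphic),
#' Balding-Nichols F = 0.05 (within the observed pairwise herd-Fst band of
#' 0.003-0.12), genotyping missingness 0.005, heterozygote islands planted at
#' the study's island coordinates and multi-Mb homozygous tracts on a few
#' chromosomes.
#'
#' @param seed master RNG seed (all randomness flows from it).
#' @param herd_sizes integer vector, one herd size per herd.
#' @param n_markers total markers across all chromosomes.
#' @param build genome build data.frame (`chrom`, `length_bp`); defaults to
#'   the bundled bovine autosomes. `n_chromosomes` truncates it.
#' @param n_chromosomes number of chromosomes to keep from `build`.
#' @param rare_frac fraction of markers with ancestral MAF below 0.01.
#' @param mono_frac fraction of the rare markers that are strictly
#'   monomorphic.
#' @param fst Balding-Nichols differentiation parameter F.
#' @param missing_rate per-call missing probability.
#' @param spacing_shape gamma shape for inter-marker spacing.
#' @param islands data.frame of planted heterozygote islands (`chrom`,
#'   `start_bp`, `end_bp`, `herds` comma-separated herd indices, `h`
#'   expressor probability); `NULL` for none.
#' @param roh_tracts data.frame of planted homozygous tracts (`chrom`,
#'   `start_bp`, `end_bp`, `herds`, `freq` carrier frequency); `NULL` for
#'   none.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       herd_sizes = c(57, 85, 73, 44, 58, 54),
                       n_markers = 48108,
                       build = NULL,
                       n_chromosomes = NULL,
                       rare_frac = 0.10,
                       mono_frac = 0.5,
                       fst = 0.05,
                       missing_rate = 0.005,
                       spacing_shape = 4,
                       islands = default_planted_islands(),
                       roh_tracts = default_roh_tracts()) {
  build <- build %||% genome_build()
  if (!is.null(n_chromosomes)) build <- build[seq_len(n_chromosomes), , drop = FALSE]
  stopifnot(all(herd_sizes > 0), n_markers >= length(build$chrom),
            rare_frac >= 0, rare_frac <= 1, fst >= 0, fst < 1,
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(islands) && nrow(islands) > 0) {
    stopifnot(all(c("chrom", "start_bp", "end_bp", "herds", "h") %in% names(islands)),
              all(islands$h > 0), all(islands$h <= 1))
    ok <- islands$chrom %in% build$chrom &
      islands$end_bp <= build$length_bp[match(islands$chrom, build$chrom)]
    if (!all(ok)) stop("planted island outside chromosome bounds")
  }
  if (!is.null(roh_tracts) && nrow(roh_tracts) > 0) {
    ok <- roh_tracts$chrom %in% build$chrom &
      roh_tracts$end_bp <= build$length_bp[match(roh_tracts$chrom, build$chrom)]
    if (!all(ok)) stop("planted tract outside chromosome bounds")
  }
  structure(list(seed = as.integer(seed), herd_sizes = as.integer(herd_sizes),
                 n_markers = as.integer(n_markers), build = build,
                 rare_frac = rare_frac, mono_frac = mono_frac, fst = fst,
                 missing_rate = missing_rate, spacing_shape = spacing_shape,
                 islands = islands, roh_tracts = roh_tracts),
            class = "sim_config")
}

#' Default planted heterozygote islands
#'
#' Eight islands anchored at the study's reported island coordinates on
#' BTA1/9/10/11/20/21/29, symmetrically widened to at least 400 kb so each
#' contains enough array SNPs to be expressed as a detectable run. `h` is the
#' probability that a cow of an elevated (carrier) herd expresses the island
#' as a heterozygous tract, set to the reported herd support proportions;
#' `baseline_h` is the expression probability in every other herd, set to the
#' reported whole-population support, so the islands are population-wide
#' features with herd-specific elevation as in the study.
#'
#' @return data.frame of planted islands.
#' @export
default_planted_islands <- function() {
  isl <- data.frame(
    chrom    = c(1L, 1L, 10L, 20L, 21L, 29L, 9L, 11L),
    start_bp = c(66483743, 103675933, 45465423, 40831029, 2938326,
                 40025469, 43945908, 34205857),
    end_bp   = c(66668755, 103728420, 45564676, 40986540, 2985827,
                 40281016, 44323878, 34482175),
    herds    = c("1,2,4", "1", "1,4", "3", "4", "1,4,5", "5", "2"),
    h        = c(0.57, 0.50, 0.59, 0.62, 0.56, 0.50, 0.48, 0.42),
    # chosen so that the population-wide support (carrier and non-carrier
    # herds together) matches the reported whole-set proportions
    baseline_h = c(0.39, 0.43, 0.47, 0.47, 0.49, 0.36, 0.42, 0.32),
    stringsAsFactors = FALSE)
  # the expressed heterozygous tract must hold >= 5 array SNPs at ~60 kb
  # spacing to be detectable as a run on its own
  widen <- pmax(0, 400000 - (isl$end_bp - isl$start_bp)) / 2
  isl$start_bp <- floor(isl$start_bp - widen)
  isl$end_bp <- ceiling(isl$end_bp + widen)
  isl
}

#' Default planted homozygous tracts
#'
#' Multi-Mb shared-haplotype tracts on a few chromosomes (the most
#' ROH-saturated ones in cattle), carried by half of the listed herds'
#' members.
#'
#' @return data.frame of planted tracts.
#' @export
default_roh_tracts <- function() {
  data.frame(
    chrom    = c(14L, 16L, 7L, 26L),
    start_bp = c(25000000, 40000000, 50000000, 10000000),
    end_bp   = c(27500000, 42000000, 51500000, 11200000),
    herds    = c("1,2,3,4,5,6", "2,3", "1,5", "4"),
    freq     = c(0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
}

.parse_herds <- function(s) as.integer(strsplit(s, ",")[[1]])

#' Simulate a herd-structured genotype dataset
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [genotype_dataset()]) and `truth` (planted
#'   features with carrier/expressor ids, ancestral and herd allele
#'   frequencies, and the seed).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, .simulate_dataset_impl(config))
}

.simulate_dataset_impl <- function(config) {
  build <- config$build
  n_chr <- nrow(build)
  n_herd <- length(config$herd_sizes)
  n_ind <- sum(config$herd_sizes)

  # ---- map: markers per chromosome proportional to length, gamma spacing
  alloc <- round(as.numeric(config$n_markers) * build$length_bp / sum(build$length_bp))
  alloc[1] <- alloc[1] + (config$n_markers - sum(alloc))
  map_list <- vector("list", n_chr)
  for (c_i in seq_len(n_chr)) {
    m <- alloc[c_i]
    sp <- stats::rgamma(m + 1, shape = config$spacing_shape,
                        rate = config$spacing_shape)
    pos <- round(cumsum(sp)[seq_len(m)] / sum(sp) * (build$length_bp[c_i] - 1)) + 1
    pos <- cumsum(pmax(1, diff(c(0, pos))))   # enforce strict increase
    map_list[[c_i]] <- data.frame(chrom = build$chrom[c_i],
                                  pos_bp = as.integer(pos))
  }
  map <- do.call(rbind, map_list)
  m_tot <- nrow(map)
  map$snp_id <- sprintf("snp_%d_%d", map$chrom, map$pos_bp)
  map$cm <- 0
  map$allele_a <- "A"
  map$allele_b <- "G"

  # ---- ancestral frequencies: ~rare_frac below MAF 0.01, rest uniform
  rare <- stats::runif(m_tot) < config$rare_frac
  maf <- ifelse(rare, stats::runif(m_tot, 0, 0.01),
                stats::runif(m_tot, 0.01, 0.5))
  mono <- rare & (stats::runif(m_tot) < config$mono_frac)
  maf[mono] <- 0
  side <- stats::runif(m_tot) < 0.5
  p_anc <- ifelse(side, maf, 1 - maf)   # frequency of allele_b

  # ---- herd frequencies (Balding-Nichols)
  Fst <- config$fst
  herd_freq <- matrix(0, m_tot, n_herd)
  for (h in seq_len(n_herd)) {
    if (Fst < 1e-12) {
      herd_freq[, h] <- p_anc
    } else {
      a <- p_anc * (1 - Fst) / Fst
      b <- (1 - p_anc) * (1 - Fst) / Fst
      ok <- p_anc > 0 & p_anc < 1
      q <- p_anc
      q[ok] <- stats::rbeta(sum(ok), a[ok], b[ok])
      herd_freq[, h] <- q
    }
  }

  # ---- genotypes: HWE within herd
  herd_of <- rep(seq_len(n_herd), times = config$herd_sizes)
  calls <- matrix(NA_integer_, n_ind, m_tot)
  for (h in seq_len(n_herd)) {
    rows <- which(herd_of == h)
    nh <- length(rows)
    calls[rows, ] <- matrix(
      stats::rbinom(nh * m_tot, 2L, rep(herd_freq[, h], each = nh)),
      nrow = nh)
  }

  ids <- sprintf("cow_%03d", seq_len(n_ind))
  individuals <- data.frame(individual_id = ids,
                            herd_id = sprintf("herd_%d", herd_of),
                            pheno = as.character(seq_len(n_ind)),
                            stringsAsFactors = FALSE)

  # ---- planted heterozygote islands: carrier-herd cows express the island
  # as a fully heterozygous tract with probability h (correlation within the
  # tract is what makes it a run; markers stay independent elsewhere)
  island_truth <- list()
  if (!is.null(config$islands) && nrow(config$islands) > 0) {
    for (j in seq_len(nrow(config$islands))) {
      isl <- config$islands[j, ]
      mk <- which(map$chrom == isl$chrom & map$pos_bp >= isl$start_bp &
                    map$pos_bp <= isl$end_bp)
      carrier_herds <- .parse_herds(isl$herds)
      carriers <- which(herd_of %in% carrier_herds)
      base_h <- if (!is.null(isl$baseline_h) && !is.na(isl$baseline_h))
        isl$baseline_h else 0
      others <- which(!(herd_of %in% carrier_herds))
      expressed <- c(carriers[stats::runif(length(carriers)) < isl$h],
                     others[stats::runif(length(others)) < base_h])
      if (length(mk) > 0 && length(expressed) > 0) {
        calls[expressed, mk] <- 1L
      }
      island_truth[[j]] <- data.frame(
        chrom = isl$chrom, start_bp = isl$start_bp, end_bp = isl$end_bp,
        h = isl$h, baseline_h = base_h, n_markers = length(mk),
        carrier_herds = isl$herds,
        carriers = paste(ids[carriers], collapse = ","),
        expressors = paste(ids[expressed], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  # ---- planted homozygous tracts: carriers homozygous for one shared
  # haplotype drawn from the herd frequencies
  tract_truth <- list()
  if (!is.null(config$roh_tracts) && nrow(config$roh_tracts) > 0) {
    for (j in seq_len(nrow(config$roh_tracts))) {
      tr <- config$roh_tracts[j, ]
      mk <- which(map$chrom == tr$chrom & map$pos_bp >= tr$start_bp &
                    map$pos_bp <= tr$end_bp)
      carrier_herds <- .parse_herds(tr$herds)
      pool <- which(herd_of %in% carrier_herds)
      carriers <- pool[stats::runif(length(pool)) < tr$freq]
      if (length(mk) > 0 && length(carriers) > 0) {
        hap <- stats::rbinom(length(mk), 1L, p_anc[mk])
        calls[carriers, mk] <- rep(2L * hap, each = length(carriers))
      }
      tract_truth[[j]] <- data.frame(
        chrom = tr$chrom, start_bp = tr$start_bp, end_bp = tr$end_bp,
        freq = tr$freq, n_markers = length(mk),
        carrier_herds = tr$herds,
        carriers = paste(ids[carriers], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }

  # ---- missingness
  if (config$missing_rate > 0) {
    calls[stats::runif(length(calls)) < config$missing_rate] <- NA_integer_
  }

  dataset <- canonicalize_alleles(genotype_dataset(
    map = map[, c("chrom", "snp_id", "cm", "pos_bp", "allele_a", "allele_b")],
    calls = calls, individuals = individuals))
  truth <- list(
    seed = config$seed,
    islands = if (length(island_truth)) do.call(rbind, island_truth) else NULL,
    roh_tracts = if (length(tract_truth)) do.call(rbind, tract_truth) else NULL,
    ancestral_freq = p_anc,
    herd_freq = herd_freq,
    herd_of = herd_of)
  list(dataset = dataset, truth = truth)
}

#' Deterministic bundled fixtures
#'
#' Tiny datasets for unit tests, regenerated identically on every call:
#' * `"mini-island"` — 2 herds x 10 cows, ~200 markers on 2 small
#'   chromosomes, one heterozygote island planted in herd 1 (h = 0.7).
#' * `"null"` — same shape, nothing planted.
#' * `"maf-split"` — 1 herd x 12 cows on one chromosome where long
#'   heterozygous tracts are interrupted by monomorphic markers, so removing
#'   MAF < 0.01 markers merges sub-threshold fragments into detectable HRRs.
#'
#' @param name fixture name.
#' @return list with `dataset` and `truth`.
#' @export
emit_fixture <- function(name = c("mini-island", "null", "maf-split")) {
  name <- match.arg(name)
  build2 <- data.frame(chrom = 1:2, length_bp = c(5e6, 5e6))
  if (name == "mini-island") {
    cfg <- sim_config(
      seed = 20240101, herd_sizes = c(10, 10), n_markers = 200,
      build = build2, rare_frac = 0.1, fst = 0.02, missing_rate = 0.002,
      islands = data.frame(chrom = 1L, start_bp = 2.0e6, end_bp = 2.4e6,
                           herds = "1", h = 0.7, stringsAsFactors = FALSE),
      roh_tracts = NULL)
    return(simulate_dataset(cfg))
  }
  if (name == "null") {
    cfg <- sim_config(
      seed = 20240102, herd_sizes = c(10, 10), n_markers = 200,
      build = build2, rare_frac = 0.1, fst = 0.02, missing_rate = 0.002,
      islands = NULL, roh_tracts = NULL)
    return(simulate_dataset(cfg))
  }
  # maf-split: hand-built pattern, no RNG
  n_ind <- 12L
  pos <- seq(10000L, by = 20000L, length.out = 60L)
  map <- data.frame(chrom = 1L, snp_id = sprintf("fix_%02d", seq_along(pos)),
                    cm = 0, pos_bp = pos, allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  calls <- matrix(0L, n_ind, length(pos))   # background hom_a
  # two long het tracts, each interrupted by monomorphic hom markers so the
  # het fragments (3-4 SNPs) fall below the 5-SNP minimum until the
  # monomorphic markers are removed
  het_block <- function(from, to) calls[, from:to] <<- 1L
  mono_at <- integer(0)
  het_block(5, 16); mono <- c(9, 13); calls[, mono] <- 0L; mono_at <- c(mono_at, mono)
  het_block(30, 41); mono <- c(34, 38); calls[, mono] <- 0L; mono_at <- c(mono_at, mono)
  # make non-mono markers polymorphic overall so only the planted interrupts
  # fail a MAF 0.01 filter: give one cow a het at every background marker
  bg <- setdiff(seq_along(pos), c(5:16, 30:41))
  calls[1L, bg] <- 1L
  calls[2L, bg] <- 1L
  individuals <- data.frame(individual_id = sprintf("fix_cow_%02d", 1:n_ind),
                            herd_id = "herd_1",
                            pheno = as.character(1:n_ind),
                            stringsAsFactors = FALSE)
  dataset <- canonicalize_alleles(genotype_dataset(map, calls, individuals))
  truth <- list(mono_markers = map$snp_id[mono_at],
                het_tracts = data.frame(chrom = 1L,
                                        start_bp = pos[c(5, 30)],
                                        end_bp = pos[c(16, 41)]))
  list(dataset = dataset, truth = truth)
}

#' Weir-Cockerham Fst across herds
#'
#' Multi-population Weir-Cockerham (1984) theta, computed per marker from
#' sample sizes, allele frequencies and observed heterozygosity, and combined
#' as the ratio of summed variance components. Used as the simulator's
#' differentiation diagnostic.
#'
#' @param dataset a [genotype_dataset()].
#' @return overall theta (weighted across markers).
#' @export
wc_fst <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  herds <- unique(dataset$individuals$herd_id)
  r <- length(herds)
  if (r < 2) stop("need at least 2 herds")
  m <- ncol(dataset$calls)
  n_mat <- p_mat <- h_mat <- matrix(0, m, r)
  for (k in seq_len(r)) {
    rows <- dataset$individuals$herd_id == herds[k]
    g <- dataset$calls[rows, , drop = FALSE]
    n_mat[, k] <- colSums(!is.na(g))
    p_mat[, k] <- ifelse(n_mat[, k] > 0, colSums(g, na.rm = TRUE) / (2 * n_mat[, k]), NA)
    h_mat[, k] <- ifelse(n_mat[, k] > 0, colMeans(g == 1L, na.rm = TRUE), NA)
  }
  n_bar <- rowMeans(n_mat)
  n_tot <- rowSums(n_mat)
  nc <- (n_tot - rowSums(n_mat^2) / n_tot) / (r - 1)
  p_bar <- rowSums(n_mat * p_mat) / n_tot
  s2 <- rowSums(n_mat * (p_mat - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_mat * h_mat) / n_tot
  a <- n_bar / nc * (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- n_bar / (n_bar - 1) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2
  use <- is.finite(a) & is.finite(b) & is.finite(cc) & (a + b + cc) != 0 &
    p_bar > 0 & p_bar < 1
  sum(a[use]) / sum(a[use] + b[use] + cc[use])
}
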