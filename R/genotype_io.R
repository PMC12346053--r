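# PLINK-text genotype ingestion, QC and the genome build.
#
# A genotype_dataset holds three pieces:
#   map         -- data.frame(chrom, snp_id, cm, pos_bp, allele_a, allele_b),
#                  sorted by (chrom, pos_bp); coordinates are 1-based bp.
#   calls       -- integer matrix individuals x markers; 0 = hom for allele_a,
#                  1 = het, 2 = hom for allele_b, NA = missing.
#   individuals -- data.frame(individual_id, herd_id, pheno); pheno is the
#                  pseudo-phenotype label kept verbatim as a string (labels
#                  such as "2.1" or "-8" must never be coerced to numbers).

VALID_ALLELES <- c("0", "A", "C", "G", "T")

#' Construct a genotype dataset
#'
#' Low-level constructor used by the reader and the simulator. Validates that
#' the map is sorted, marker ids are unique and dimensions agree.
#'
#' @param map data.frame with columns `chrom` (integer), `snp_id`, `cm`,
#'   `pos_bp` (1-based integer), `allele_a`, `allele_b`.
#' @param calls integer matrix individuals x markers coded 0/1/2/NA.
#' @param individuals data.frame with columns `individual_id`, `herd_id`,
#'   `pheno`.
#' @return an object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(map, calls, individuals) {
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  stopifnot(
    all(c("chrom", "snp_id", "pos_bp") %in% names(map)),
    all(c("individual_id", "herd_id", "pheno") %in% names(individuals))
  )
  if (is.null(map$cm)) map$cm <- 0
  if (is.null(map$allele_a)) map$allele_a <- NA_character_
  if (is.null(map$allele_b)) map$allele_b <- NA_character_
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate marker id: ", map$snp_id[duplicated(map$snp_id)][1])
  }
  o <- order(map$chrom, map$pos_bp)
  if (!identical(o, seq_len(nrow(map)))) {
    map <- map[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  bad <- unlist(lapply(split(map$pos_bp, map$chrom), function(p) any(diff(p) <= 0)))
  if (any(bad)) {
    stop("positions not strictly increasing on chromosome(s): ",
         paste(names(bad)[bad], collapse = ", "))
  }
  calls <- matrix(as.integer(calls), nrow = nrow(individuals),
                  dimnames = list(individuals$individual_id, map$snp_id))
  rownames(map) <- NULL
  structure(list(map = map, calls = calls, individuals = individuals),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d individuals (%d herds) x %d markers on %d chromosome(s)\n",
              nrow(x$individuals), length(unique(x$individuals$herd_id)),
              nrow(x$map), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Read PLINK text PED/MAP files
#'
#' Parses the whitespace-separated PLINK text dialect: the MAP file has four
#' columns (chromosome, marker id, genetic distance, bp position); each PED
#' row has six leading columns (family/herd, individual, father, mother, sex,
#' phenotype) followed by two allele columns per marker. Missing genotypes are
#' `0 0`. The first PED column is taken as the herd label and the sixth as a
#' verbatim pseudo-phenotype string. Per-marker alleles are labelled
#' alphabetically: `allele_a` is the lexicographically first allele observed.
#'
#' @param ped_path,map_path file paths.
#' @return a [genotype_dataset()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map_raw <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                               colClasses = "character")
  if (ncol(map_raw) != 4) {
    stop("malformed MAP file (expected 4 columns, got ", ncol(map_raw), "): ", map_path)
  }
  chrom <- suppressWarnings(as.integer(map_raw[[1]]))
  if (anyNA(chrom)) {
    stop("non-numeric chromosome code at MAP line ", which(is.na(chrom))[1])
  }
  map <- data.frame(chrom = chrom, snp_id = map_raw[[2]],
                    cm = suppressWarnings(as.numeric(map_raw[[3]])),
                    pos_bp = as.integer(map_raw[[4]]),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$snp_id)) {
    stop("duplicate marker id in MAP: ", map$snp_id[duplicated(map$snp_id)][1])
  }
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("parse error: empty PED file (zero individuals): ", ped_path)

  n <- length(lines)
  fam <- id <- pheno <- character(n)
  # allele codes per individual: integer in 0..4 indexing VALID_ALLELES (0-based)
  a1 <- matrix(0L, n, m)
  a2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) != 6 + 2 * m) {
      stop(sprintf("parse error at PED line %d: expected %d fields, got %d",
                   i, 6 + 2 * m, length(tok)))
    }
    fam[i] <- tok[1]; id[i] <- tok[2]; pheno[i] <- tok[6]
    g1 <- tok[seq(7, length(tok), by = 2)]
    g2 <- tok[seq(8, length(tok), by = 2)]
    c1 <- match(g1, VALID_ALLELES) - 1L
    c2 <- match(g2, VALID_ALLELES) - 1L
    if (anyNA(c1) || anyNA(c2)) {
      bad <- c(g1[is.na(c1)], g2[is.na(c2)])[1]
      stop(sprintf("coding error at PED line %d: allele '%s' not in {A,C,G,T,0}", i, bad))
    }
    if (any(xor(c1 == 0L, c2 == 0L))) {
      stop(sprintf("parse error at PED line %d: half-missing genotype", i))
    }
    a1[i, ] <- c1; a2[i, ] <- c2
  }
  if (anyDuplicated(id)) stop("duplicate individual id in PED: ", id[duplicated(id)][1])

  # per-marker allele inventory (alphabetical assignment)
  present <- matrix(FALSE, 4L, m)
  for (k in 1:4) present[k, ] <- colSums(a1 == k | a2 == k) > 0L
  n_alleles <- colSums(present)
  if (any(n_alleles > 2)) {
    stop("coding error: more than two alleles at marker ",
         map$snp_id[which(n_alleles > 2)[1]])
  }
  first_idx <- apply(present, 2, function(p) if (any(p)) which(p)[1] else NA_integer_)
  second_idx <- apply(present, 2, function(p) if (sum(p) > 1) which(p)[2] else NA_integer_)
  map$allele_a <- VALID_ALLELES[first_idx + 1L]
  map$allele_b <- VALID_ALLELES[second_idx + 1L]

  fa <- matrix(rep(first_idx, each = n), n, m)
  calls <- matrix(NA_integer_, n, m)
  nonmiss <- a1 != 0L  # both-or-neither is guaranteed above
  het <- nonmiss & (a1 != a2)
  calls[het] <- 1L
  homa <- nonmiss & !het & (a1 == fa)
  calls[homa] <- 0L
  homb <- nonmiss & !het & (a1 != fa)
  calls[homb] <- 2L

  genotype_dataset(
    map = map,
    calls = calls,
    individuals = data.frame(individual_id = id, herd_id = fam, pheno = pheno,
                             stringsAsFactors = FALSE)
  )
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: a write/read cycle reproduces the call matrix,
#' marker order and labels exactly. Missing calls are written `0 0`. Markers
#' with no observed minor allele are written as homozygous for `allele_a`.
#'
#' @param dataset a [genotype_dataset()].
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  map <- dataset$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id,
               ifelse(is.na(map$cm), 0, map$cm), map$pos_bp),
    map_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

  aa <- map$allele_a
  bb <- map$allele_b
  any_call <- colSums(!is.na(dataset$calls)) > 0
  if (any(is.na(aa) & any_call)) {
    stop("marker carries calls but allele_a is unknown")
  }
  if (any(is.na(bb) & colSums(dataset$calls >= 1L, na.rm = TRUE) > 0)) {
    stop("marker carries het/hom_b calls but allele_b is unknown")
  }
  aa[is.na(aa)] <- "0"
  bb[is.na(bb)] <- "0"
  n <- nrow(dataset$calls); m <- ncol(dataset$calls)
  out <- character(n)
  ind <- dataset$individuals
  for (i in seq_len(n)) {
    g <- dataset$calls[i, ]
    g1 <- ifelse(is.na(g), "0", ifelse(g == 2L, bb, aa))
    g2 <- ifelse(is.na(g), "0", ifelse(g == 0L, aa, bb))
    # first field is the family/herd label
    out[i] <- paste(c(ind$herd_id[i], ind$individual_id[i], "0", "0", "0",
                      ind$pheno[i], rbind(g1, g2)), collapse = " ")
  }
  writeLines(out, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Canonicalize allele labels
#'
#' Re-labels each marker's alleles the way [read_ped_map()] infers them from
#' PED text: `allele_a` is the alphabetically first allele actually observed
#' in the calls, unobserved alleles become `NA`, and hom calls are recoded to
#' match. After canonicalization a write/read cycle reproduces the dataset
#' exactly; the function is idempotent.
#'
#' @param dataset a [genotype_dataset()].
#' @return the dataset with canonical allele labels and recoded calls.
#' @export
canonicalize_alleles <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  calls <- dataset$calls
  has_a <- colSums(calls == 0L | calls == 1L, na.rm = TRUE) > 0
  has_b <- colSums(calls == 2L | calls == 1L, na.rm = TRUE) > 0
  aa <- dataset$map$allele_a
  bb <- dataset$map$allele_b
  # markers where only the 'b' allele is observed: flip so it becomes 'a'
  flip <- !has_a & has_b
  if (any(flip)) {
    calls[, flip] <- 2L - calls[, flip]
    tmp <- aa[flip]; aa[flip] <- bb[flip]; bb[flip] <- tmp
    has_a[flip] <- TRUE; has_b[flip] <- FALSE
  }
  bb[!has_b] <- NA_character_
  aa[!has_a] <- NA_character_
  # where both alleles are observed, order them alphabetically
  both <- has_a & has_b & !is.na(aa) & !is.na(bb) & aa > bb
  if (any(both)) {
    calls[, both] <- 2L - calls[, both]
    tmp <- aa[both]; aa[both] <- bb[both]; bb[both] <- tmp
  }
  dataset$map$allele_a <- aa
  dataset$map$allele_b <- bb
  dataset$calls <- matrix(calls, nrow = nrow(calls),
                          dimnames = dimnames(dataset$calls))
  dataset
}

#' QC parameter set
#'
#' Defaults follow standard array QC: markers with more than 5% missing calls
#' are removed, then individuals with more than 5% missing calls, then
#' (optionally) markers with minor allele frequency below `min_maf`; only
#' autosomes are retained.
#'
#' @param max_snp_missing maximum per-marker missing fraction.
#' @param max_ind_missing maximum per-individual missing fraction.
#' @param min_maf minimum minor allele frequency, or `NULL` to keep all MAFs.
#' @param autosomes_only drop markers outside `autosomes`.
#' @param autosomes integer vector of autosome codes (bovine default 1:29).
#' @return a list of class `qc_params`.
#' @export
qc_params <- function(max_snp_missing = 0.05, max_ind_missing = 0.05,
                      min_maf = NULL, autosomes_only = TRUE, autosomes = 1:29) {
  stopifnot(max_snp_missing >= 0, max_snp_missing <= 1,
            max_ind_missing >= 0, max_ind_missing <= 1,
            is.null(min_maf) || (min_maf >= 0 && min_maf <= 1))
  structure(list(max_snp_missing = max_snp_missing,
                 max_ind_missing = max_ind_missing,
                 min_maf = min_maf, autosomes_only = autosomes_only,
                 autosomes = autosomes),
            class = "qc_params")
}

#' Apply quality control
#'
#' Filter order is fixed: non-autosomes are dropped, then markers above the
#' missingness threshold, then individuals above theirs, then markers below
#' `min_maf` (when requested). A per-stage removal report is attached as
#' attribute `"qc_report"`.
#'
#' @param dataset a [genotype_dataset()].
#' @param params a [qc_params()] list.
#' @return the filtered dataset.
#' @export
apply_qc <- function(dataset, params = qc_params()) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (nrow(dataset$map) == 0 || nrow(dataset$individuals) == 0) {
    stop("empty dataset")
  }
  report <- list()
  note <- function(stage, removed, markers, individuals) {
    report[[length(report) + 1]] <<- data.frame(
      stage = stage, removed = removed,
      markers_left = markers, individuals_left = individuals)
  }

  if (isTRUE(params$autosomes_only)) {
    keep <- dataset$map$chrom %in% params$autosomes
    note("autosomes", sum(!keep), sum(keep), nrow(dataset$individuals))
    dataset$map <- dataset$map[keep, , drop = FALSE]
    dataset$calls <- dataset$calls[, keep, drop = FALSE]
  }
  if (ncol(dataset$calls) == 0) stop("empty after QC: no autosomal markers")

  miss_m <- colMeans(is.na(dataset$calls))
  keep <- miss_m <= params$max_snp_missing
  note("marker_missingness", sum(!keep), sum(keep), nrow(dataset$individuals))
  dataset$map <- dataset$map[keep, , drop = FALSE]
  dataset$calls <- dataset$calls[, keep, drop = FALSE]
  if (ncol(dataset$calls) == 0) stop("empty after QC: all markers exceeded geno threshold")

  miss_i <- rowMeans(is.na(dataset$calls))
  keep_i <- miss_i <= params$max_ind_missing
  note("individual_missingness", sum(!keep_i), ncol(dataset$calls), sum(keep_i))
  dataset$individuals <- dataset$individuals[keep_i, , drop = FALSE]
  dataset$calls <- dataset$calls[keep_i, , drop = FALSE]
  if (nrow(dataset$calls) == 0) stop("empty after QC: all individuals exceeded mind threshold")

  if (!is.null(params$min_maf)) {
    maf <- compute_maf(dataset)
    keep <- !is.na(maf) & maf >= params$min_maf
    note("maf", sum(!keep), sum(keep), nrow(dataset$individuals))
    dataset$map <- dataset$map[keep, , drop = FALSE]
    dataset$calls <- dataset$calls[, keep, drop = FALSE]
    if (ncol(dataset$calls) == 0) stop("empty after QC: all markers below MAF threshold")
  }
  rownames(dataset$map) <- NULL
  rownames(dataset$individuals) <- NULL
  attr(dataset, "qc_report") <- do.call(rbind, report)
  dataset
}

#' Minor allele frequency
#'
#' MAF per marker over non-missing alleles only (PLINK convention). Markers
#' with all calls missing return `NA` with a warning.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker optional marker id(s) or column index(es); default all.
#' @return numeric vector of MAFs in `[0, 0.5]`.
#' @export
compute_maf <- function(dataset, marker = NULL) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  calls <- dataset$calls
  if (!is.null(marker)) {
    if (is.character(marker)) {
      idx <- match(marker, dataset$map$snp_id)
      if (anyNA(idx)) stop("unknown marker: ", marker[is.na(idx)][1])
    } else idx <- marker
    calls <- calls[, idx, drop = FALSE]
  }
  nb <- colSums(calls, na.rm = TRUE)              # dose of allele_b
  nn <- 2 * colSums(!is.na(calls))                # non-missing allele count
  f <- ifelse(nn > 0, nb / nn, NA_real_)
  if (anyNA(f)) warning("MAF undefined for marker(s) with all calls missing")
  unname(pmin(f, 1 - f))
}

#' Reference genome build (autosome lengths)
#'
#' Reads a two-column TSV (`chrom`, `length_bp`). The default ships the bovine
#' ARS-UCD autosome lengths; any build may be supplied for other species or
#' assemblies.
#'
#' @param path TSV path, or `NULL` for the bundled bovine default.
#' @return data.frame with columns `chrom`, `length_bp`.
#' @export
genome_build <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ars_ucd_autosomes.tsv", package = "hrrscan")
  }
  b <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "length_bp") %in% names(b)))
  b[order(b$chrom), c("chrom", "length_bp")]
}

#' SNP-covered length per chromosome
#'
#' The span from first to last SNP per chromosome on the current (post-QC)
#' map; the sum over autosomes is the denominator of the coefficient of
#' extended heterozygosity.
#'
#' @param dataset a [genotype_dataset()].
#' @return data.frame with columns `chrom`, `covered_bp`.
#' @export
covered_length <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  sp <- split(dataset$map$pos_bp, dataset$map$chrom)
  data.frame(chrom = as.integer(names(sp)),
             covered_bp = vapply(sp, function(p) max(p) - min(p), numeric(1)),
             row.names = NULL)
}
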