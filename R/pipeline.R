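# End-to-end orchestration: QC -> run detection (HRR 50 kb / HRR 250 kb /
# ROH, with and without the MAF filter) -> per-herd islands -> permutation
# significance -> genome summaries -> Tajima scan on island chromosomes ->
# optional repeat-element enrichment.

#' Pipeline configuration
#'
#' @param dataset a [genotype_dataset()], or `NULL` to read from `ped`/`map`.
#' @param ped,map PLINK text paths (used when `dataset` is `NULL`).
#' @param build genome build ([genome_build()]).
#' @param qc QC parameters ([qc_params()]); the MAF-removed variant reapplies
#'   them with `min_maf = 0.01`.
#' @param maf_variants subset of `c("all", "maf01")`.
#' @param scans subset of `c("hrr50", "hrr250", "roh")`.
#' @param island_threshold incidence threshold for island calling.
#' @param island_mode `"threshold"` or `"quantile"` (see [call_islands()]).
#' @param permutation a [permutation_config()]; `n_permutations = 0` skips
#'   significance (islands are still reported, flagged unevaluated).
#' @param tajima a [tajima_scan_config()].
#' @param elements optional data.frame of repeat-element intervals
#'   ([read_element_bed()]) for the enrichment comparison.
#' @param significance_alpha empirical-p cutoff selecting the chromosomes
#'   scanned with Tajima's D.
#' @param out_dir optional directory; when given, every table is written as
#'   TSV plus a run log.
#' @param max_missing_in_run missing-call tolerance inside runs.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(dataset = NULL, ped = NULL, map = NULL,
                            build = NULL,
                            qc = qc_params(),
                            maf_variants = c("all", "maf01"),
                            scans = c("hrr50", "hrr250", "roh"),
                            island_threshold = 0.4,
                            island_mode = "threshold",
                            permutation = permutation_config(),
                            tajima = tajima_scan_config(),
                            elements = NULL,
                            significance_alpha = 0.05,
                            out_dir = NULL,
                            max_missing_in_run = 1L) {
  maf_variants <- match.arg(maf_variants, several.ok = TRUE)
  scans <- match.arg(scans, several.ok = TRUE)
  structure(list(dataset = dataset, ped = ped, map = map,
                 build = build %||% genome_build(),
                 qc = qc, maf_variants = maf_variants, scans = scans,
                 island_threshold = island_threshold, island_mode = island_mode,
                 permutation = permutation, tajima = tajima,
                 elements = elements, significance_alpha = significance_alpha,
                 out_dir = out_dir, max_missing_in_run = max_missing_in_run),
            class = "pipeline_config")
}

#' Build a configuration from a YAML file
#'
#' Reads a YAML mapping of argument names and applies them to the matching
#' constructor ([sim_config()], [pipeline_config()], [permutation_config()] or
#' [tajima_scan_config()]). Data-frame arguments (planted islands/tracts) may
#' be given as YAML lists of records.
#'
#' @param path YAML file path.
#' @param what which configuration to build.
#' @return the configuration object.
#' @export
config_from_yaml <- function(path, what = c("sim", "pipeline", "permutation",
                                            "tajima")) {
  what <- match.arg(what)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for YAML configs")
  }
  args <- yaml::read_yaml(path)
  for (nm in intersect(names(args), c("islands", "roh_tracts"))) {
    if (is.list(args[[nm]]) && !is.data.frame(args[[nm]])) {
      args[[nm]] <- do.call(rbind, lapply(args[[nm]], as.data.frame))
    }
  }
  ctor <- switch(what, sim = sim_config, pipeline = pipeline_config,
                 permutation = permutation_config, tajima = tajima_scan_config)
  do.call(ctor, args)
}

.scan_params <- function(scan, max_missing) {
  switch(scan,
         hrr50 = hrr_params(50000, max_missing = max_missing),
         hrr250 = hrr_params(250000, max_missing = max_missing),
         roh = roh_params(250000, max_missing = max_missing),
         stop("unknown scan: ", scan))
}

.scan_edges <- function(scan) {
  if (scan == "hrr50") class_edges("50kb") else class_edges("250kb")
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage and returns the report bundle as a nested
#' list; with `out_dir` set, all tables are also written as TSV together with
#' a log of parameters, seeds and per-stage counts. Any stage error aborts
#' with the stage name; tables already written stay on disk.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a named list: `qc`, one entry per MAF variant with
#'   runs / islands / significance / summaries per scan, `tajima`, and
#'   `enrichment` when elements were supplied.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  log_lines <- c("hrrscan pipeline run log",
                 sprintf("permutation seed: %d, replicates: %d",
                         config$permutation$seed, config$permutation$n_permutations))
  emit <- function(tbl, name) {
    if (!is.null(out_dir)) write_tsv(tbl, file.path(out_dir, paste0(name, ".tsv")))
    tbl
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  raw <- stage("input", {
    if (!is.null(config$dataset)) config$dataset
    else read_ped_map(config$ped, config$map)
  })

  report <- list()
  for (variant in config$maf_variants) {
    qc_par <- config$qc
    if (variant == "maf01") qc_par$min_maf <- 0.01
    ds <- stage(paste0("qc_", variant), apply_qc(raw, qc_par))
    report[[variant]]$qc_report <- attr(ds, "qc_report")
    report[[variant]]$n_markers <- ncol(ds$calls)
    report[[variant]]$n_individuals <- nrow(ds$calls)
    log_lines <- c(log_lines, sprintf(
      "variant %s: %d markers, %d individuals after QC",
      variant, ncol(ds$calls), nrow(ds$calls)))
    herds <- sort(unique(ds$individuals$herd_id))

    # default permuted groups mirror the observed herds, so every individual
    # is assigned in every replicate
    perm_cfg <- config$permutation
    if (is.null(perm_cfg$group_sizes)) {
      perm_cfg$n_groups <- length(herds)
      perm_cfg$group_sizes <- as.integer(table(
        factor(ds$individuals$herd_id, levels = herds)))
    }

    for (scan in config$scans) {
      key <- paste0(variant, "_", scan)
      par <- .scan_params(scan, config$max_missing_in_run)
      runs <- stage(paste0("runs_", key), detect_all_runs(ds, par))
      report[[variant]][[scan]]$params <- par
      report[[variant]][[scan]]$runs <- runs
      if (!is.null(out_dir)) write_runs_tsv(runs, file.path(out_dir, paste0("runs_", key, ".tsv")))
      log_lines <- c(log_lines, sprintf(
        "%s: %d runs (min_snps=%d, max_opposite=%d, max_missing=%d, min_length=%g bp, max_gap=%g bp)",
        key, nrow(runs), par$min_snps, par$max_opposite, par$max_missing,
        par$min_length_bp, par$max_gap_bp))

      # per-herd counts and length classes
      per_cow <- table(factor(runs$individual_id,
                              levels = ds$individuals$individual_id))
      herd_means <- vapply(herds, function(h) {
        mean(per_cow[ds$individuals$herd_id == h])
      }, numeric(1))
      report[[variant]][[scan]]$herd_mean_counts <-
        emit(data.frame(herd = herds, mean_runs = herd_means),
             paste0("herd_counts_", key))
      report[[variant]][[scan]]$overall_mean_se <- herd_mean_se(herd_means)
      cc <- stage(paste0("classes_", key),
                  class_counts(runs, .scan_edges(scan), herds))
      report[[variant]][[scan]]$class_summary <- emit(cc$summary, paste0("classes_", key))
      report[[variant]][[scan]]$class_counts <- cc$counts

      # chromosome ranks and correlations
      cr <- stage(paste0("rank_", key), chromosome_rank(runs, config$build))
      report[[variant]][[scan]]$chrom_rank <- emit(cr, paste0("chrom_rank_", key))
      report[[variant]][[scan]]$correlations <- tryCatch(
        rank_correlations(cr$run_share, cr$length_share),
        error = function(e) NULL)   # undefined for constant shares

      # coefficient of extended heterozygosity (HRR scans)
      if (par$target_state == "het") {
        coefs <- extended_het_coefficient(runs, ds)
        hc <- vapply(herds, function(h)
          mean(coefs[ds$individuals$herd_id == h]), numeric(1))
        report[[variant]][[scan]]$ext_het <- list(
          per_individual = coefs,
          herd_means = hc,
          overall = herd_mean_se(hc))
      }

      # per-herd islands
      islands <- stage(paste0("islands_", key), {
        do.call(rbind, lapply(herds, function(h) {
          tr <- snp_incidence(runs, ds, h)
          call_islands(tr, config$island_threshold, config$island_mode)
        }))
      })
      report[[variant]][[scan]]$islands <- emit(islands, paste0("islands_", key))
      log_lines <- c(log_lines, sprintf("%s: %d islands at threshold %.3g",
                                        key, nrow(islands), config$island_threshold))

      # permutation significance
      if (config$permutation$n_permutations > 0 && nrow(islands) > 0) {
        sig <- stage(paste0("permtest_", key),
                     build_null(ds, runs, islands, config$island_threshold,
                                perm_cfg))
        attr(sig, "replicate_supports") <- NULL
        report[[variant]][[scan]]$significance <- emit(sig, paste0("significance_", key))
      } else if (nrow(islands) > 0) {
        sig <- islands
        sig$observed_support <- islands$support
        sig$perm_mean <- NA_real_; sig$perm_se <- NA_real_
        sig$p_mwu <- NA_real_; sig$p_empirical <- NA_real_
        sig$evaluable <- NA
        report[[variant]][[scan]]$significance <- emit(sig, paste0("significance_", key))
      }
    }
  }

  # Tajima scan on chromosomes carrying significant islands, within the herd
  # in which the island was found
  taj_out <- list()
  for (variant in names(report)) {
    qc_par <- config$qc
    if (variant == "maf01") qc_par$min_maf <- 0.01
    ds <- apply_qc(raw, qc_par)
    for (scan in intersect(config$scans, names(report[[variant]]))) {
      sig <- report[[variant]][[scan]]$significance
      if (is.null(sig) || !nrow(sig) || !("p_empirical" %in% names(sig))) next
      hit <- sig[!is.na(sig$p_empirical) &
                   sig$p_empirical < config$significance_alpha, , drop = FALSE]
      if (!nrow(hit)) next
      for (j in seq_len(nrow(hit))) {
        grp <- hit$group[j]
        if (is.na(grp)) next
        ts <- stage("tajima", scan_tajima(ds, grp, config$tajima,
                                          chromosomes = hit$chrom[j]))
        rep_row <- ts$report
        rep_row$variant <- variant; rep_row$scan <- scan
        rep_row$herd <- grp
        rep_row$island_start <- hit$start_bp[j]; rep_row$island_end <- hit$end_bp[j]
        taj_out[[length(taj_out) + 1]] <- rep_row
      }
    }
  }
  if (length(taj_out)) {
    report$tajima <- emit(do.call(rbind, taj_out), "tajima_report")
  }

  # repeat-element enrichment: HRR islands vs ROH islands
  if (!is.null(config$elements)) {
    report$enrichment <- stage("enrich", {
      frac_for <- function(isl_tbl) {
        if (is.null(isl_tbl)) return(NULL)
        # single-SNP islands have no interval to intersect
        isl_tbl <- isl_tbl[isl_tbl$end_bp > isl_tbl$start_bp, , drop = FALSE]
        if (!nrow(isl_tbl)) return(NULL)
        do.call(rbind, lapply(seq_len(nrow(isl_tbl)), function(j)
          element_fraction(isl_tbl[j, ], config$elements)))
      }
      first_variant <- config$maf_variants[1]
      hrr_isl <- report[[first_variant]][["hrr50"]]$islands %||%
        report[[first_variant]][["hrr250"]]$islands
      roh_isl <- report[[first_variant]][["roh"]]$islands
      hrr_rec <- frac_for(hrr_isl); roh_rec <- frac_for(roh_isl)
      if (is.null(hrr_rec) || is.null(roh_rec)) NULL else {
        types <- intersect(unique(hrr_rec$element_type), unique(roh_rec$element_type))
        emit(data.frame(
          element_type = types,
          hrr_mean = vapply(types, function(tp)
            mean(hrr_rec$fraction[hrr_rec$element_type == tp]), numeric(1)),
          roh_mean = vapply(types, function(tp)
            mean(roh_rec$fraction[roh_rec$element_type == tp]), numeric(1)),
          p_mwu = vapply(types, function(tp)
            compare_enrichment(hrr_rec, roh_rec, tp), numeric(1))),
          "enrichment")
      }
    })
  }

  if (!is.null(out_dir)) {
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(report)
}
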