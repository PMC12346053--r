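#!/usr/bin/env Rscript
# Step 3 — descriptive genome summaries.
#
# Per-herd run counts (mean +/- SE across herds), length-class spectra,
# chromosome saturation ranks with 2-SD outliers, run-share vs length-share
# correlations, and the coefficient of extended heterozygosity.
#
# Reads:  results/sim/study.{ped,map}, results/runs/runs_*.tsv
# Writes: results/summaries/*.tsv

library(hrrscan)

ds_raw <- read_ped_map("results/sim/study.ped", "results/sim/study.map")
build <- genome_build()
out <- "results/summaries"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (variant in c("all", "maf01")) {
  par_qc <- if (variant == "maf01") qc_params(min_maf = 0.01) else qc_params()
  ds <- apply_qc(ds_raw, par_qc)
  herds <- sort(unique(ds$individuals$herd_id))
  for (scan in c("hrr50", "hrr250", "roh")) {
    runs <- read.table(sprintf("results/runs/runs_%s_%s.tsv", variant, scan),
                       header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    key <- paste0(variant, "_", scan)

    per_cow <- table(factor(runs$individual_id, levels = ds$individuals$individual_id))
    herd_means <- vapply(herds, function(h) mean(per_cow[ds$individuals$herd_id == h]),
                         numeric(1))
    ms <- herd_mean_se(herd_means)
    message(sprintf("%s: mean runs per cow across herds %.0f +/- %.0f",
                    key, ms[["mean"]], ms[["se"]]))

    edges <- if (scan == "hrr50") class_edges("50kb") else class_edges("250kb")
    cc <- class_counts(runs, edges, herds)
    write.table(cc$summary, file.path(out, paste0("classes_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)

    cr <- chromosome_rank(runs, build)
    write.table(cr, file.path(out, paste0("chrom_rank_", key, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    rc <- rank_correlations(cr$run_share, cr$length_share)
    message(sprintf("  rank outliers (>2 SD): %s; spearman rho = %.2f (p = %.2g)",
                    paste(cr$chrom[cr$outlier], collapse = ","),
                    rc$spearman_rho, rc$spearman_p))

    if (startsWith(scan, "hrr")) {
      coefs <- extended_het_coefficient(runs, ds)
      hm <- vapply(herds, function(h) mean(coefs[ds$individuals$herd_id == h]),
                   numeric(1))
      msc <- herd_mean_se(hm)
      message(sprintf("  coefficient of extended heterozygosity: %.4f +/- %.4f",
                      msc[["mean"]], msc[["se"]]))
    }
  }
}
message("written to ", out)
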