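#!/usr/bin/env Rscript
# Step 5 — windowed Tajima's D on island chromosomes.
#
# For every island with empirical p < 0.05, scans that chromosome in the herd
# the island was found in with 100 kb frames; per chromosome the SD of the D
# values defines a 3-SD threshold, and windows above it are flagged as
# balancing-selection candidates.
#
# Reads:  results/sim/study.{ped,map}, results/islands/significance_*.tsv
# Writes: results/tajima/{windows,report}.tsv

library(hrrscan)

ds_raw <- read_ped_map("results/sim/study.ped", "results/sim/study.map")
out <- "results/tajima"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

win_all <- list(); rep_all <- list()
for (variant in c("all", "maf01")) {
  par_qc <- if (variant == "maf01") qc_params(min_maf = 0.01) else qc_params()
  ds <- apply_qc(ds_raw, par_qc)
  for (scan in c("hrr50", "hrr250")) {
    path <- sprintf("results/islands/significance_%s_%s.tsv", variant, scan)
    if (!file.exists(path)) next
    sig <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    hits <- sig[!is.na(sig$p_empirical) & sig$p_empirical < 0.05, , drop = FALSE]
    for (j in seq_len(nrow(hits))) {
      sc <- scan_tajima(ds, hits$group[j], tajima_scan_config(),
                        chromosomes = hits$chrom[j])
      w <- sc$windows; r <- sc$report
      w$variant <- r$variant <- variant
      w$scan <- r$scan <- scan
      w$herd <- r$herd <- hits$group[j]
      win_all[[length(win_all) + 1]] <- w
      rep_all[[length(rep_all) + 1]] <- r
      message(sprintf(
        "%s %s BTA%d (%s): sd(D) = %.2f, 3 SD = %.2f, %d windows exceed, max D = %.2f",
        variant, scan, hits$chrom[j], hits$group[j],
        r$sd_d, r$threshold, r$n_exceeding, r$max_d))
    }
  }
}
if (length(rep_all)) {
  write.table(do.call(rbind, win_all), file.path(out, "windows.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(do.call(rbind, rep_all), file.path(out, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  message("written to ", out)
} else {
  message("no significant islands; nothing to scan")
}
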