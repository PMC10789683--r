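#!/usr/bin/env Rscript

## Agreement analysis: repeated-measures correlations and Bland-Altman
## bias / precision / limits of agreement, overall and stratified by
## intravascular volume and chest-wall state, plus the condition-level
## summary table. Writes tables and figures.

suppressPackageStartupMessages(library(pplcvp))

report <- if (file.exists("results/report.rds")) {
  readRDS("results/report.rds")
} else {
  suppressWarnings(run_study(study_config(n_subjects = 10,
                                          master_seed = 20240115)))
}

for (cmp in names(report$rmcorr)) {
  r <- report$rmcorr[[cmp]]
  cat(sprintf("%-14s rmcorr r = %.3f (df = %d, p = %.2g)\n",
              cmp, r$r, r$df, r$p))
}
ov <- report$agreement[report$agreement$stratum == "overall", ]
for (i in seq_len(nrow(ov))) {
  cat(sprintf("%-14s bias %+.2f, precision %.2f, LoA [%.2f, %.2f] cmH2O (n=%d)\n",
              ov$comparison[i], ov$bias[i], ov$precision[i],
              ov$loa_low[i], ov$loa_high[i], ov$n[i]))
}

write_report(report, "results/report")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)
for (cmp in c("cdcvp_vs_dppl", "pes_vs_dppl")) {
  ggplot2::ggsave(sprintf("results/figures/ba_%s.pdf", cmp),
                  plot_bland_altman(report, cmp), width = 5, height = 4)
  ggplot2::ggsave(sprintf("results/figures/rmcorr_%s.pdf", cmp),
                  plot_rmcorr(report, cmp), width = 5, height = 4)
}
cat("wrote results/report/ and results/figures/\n")
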