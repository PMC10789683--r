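#!/usr/bin/env Rscript

## Simulate the default study: 10 subjects x 6 conditions (three
## intravascular volume states x two chest-wall states) under
## volume-controlled ventilation, with an occlusion test, an expiratory
## hold and an inspiratory hold in every condition. Writes a handful of
## example waveform records and the drawn ground-truth parameters.

suppressPackageStartupMessages(library(pplcvp))

out_dir <- "results/waveforms"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

master_seed <- 20240115
study <- draw_study(n_subjects = 10, master_seed = master_seed)
params <- attr(study, "params")

cat(sprintf("simulated %d records (%d subjects x 6 conditions), seed %d\n",
            length(study), max(params$subject), master_seed))
cat(sprintf("tidal volume %.0f-%.0f mL, true kappa %.2f-%.2f\n",
            min(params$tidal_volume), max(params$tidal_volume),
            min(1 / params$transmission), max(1 / params$transmission)))

## persist the first subject's six records as CSV + JSON examples
for (i in 1:6) {
  write_record(study[[i]], file.path(out_dir, sprintf("subject1_cond%d", i)))
}
readr::write_tsv(params, "results/true_parameters.tsv", progress = FALSE)
cat("wrote 6 example records to", out_dir,
    "and results/true_parameters.tsv\n")
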