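#!/usr/bin/env Rscript

# Stage 5: the full end-to-end run and recovery assessment.
#
# Runs the complete pipeline (association -> stratification -> location
# classification -> affinity -> accessibility/histone coverage) over the
# stage-1 bundle in one call, writes every stage output plus report.json
# under results/analysis, and scores the run against the bundle's planted
# ground truth.

suppressMessages(library(chromloops))

bdir <- "results/bundle"
if (!file.exists(file.path(bdir, "truth.json"))) {
  stop("run analysis/01_simulate.R first")
}

report <- run_analysis(pipeline_config_from_bundle(bdir, "results/analysis"))
print(report)

truth <- jsonlite::fromJSON(file.path(bdir, "truth.json"))
key <- function(df) paste(df$bait, df$target, df$anchor_peak,
                          df$partner_peak, df$stratum)
ck <- key(report$candidates)
tk <- key(as.data.frame(truth$planted_loops))
message(sprintf("loop recovery: precision %.4f, recall %.4f",
                mean(ck %in% tk), mean(tk %in% ck)))

atac <- report$atac_regions
acc <- mean(atac$klass == unname(unlist(truth$true_atac_labels)[atac$region]))
message(sprintf("ATAC label accuracy vs truth: %.4f", acc))
message("all outputs under results/analysis; provenance in report.json")
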