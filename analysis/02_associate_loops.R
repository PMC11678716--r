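#!/usr/bin/env Rscript

# Stage 2: associate TF peaks with the Capture-C catalogue and assemble
# distance-stratified loop candidates.
#
# Reads the bundle from stage 1, overlaps anchor-TF peaks with baits and
# partner-TF peaks with targets, reports the bound fractions (the study's
# "~10% of baits and targets are bound" observation), and stratifies
# bound-bait x bound-target pairs by edge-to-edge distance into 0/10/20/30/
# 40/50 kb classes, each pair assigned to its smallest qualifying distance.

suppressMessages(library(chromloops))

bdir <- "results/bundle"
if (!file.exists(file.path(bdir, "baits.bed"))) {
  stop("run analysis/01_simulate.R first (no bundle under results/bundle)")
}

baits <- read_peaks(file.path(bdir, "baits.bed"), "bed6")
targets <- read_peaks(file.path(bdir, "targets.bed"), "bed6")
anchor <- read_peaks(file.path(bdir, "anchor_peaks.narrowPeak"), "narrowpeak",
                     source_tf = "anchor")
partner <- read_peaks(file.path(bdir, "partner_peaks.narrowPeak"),
                      "narrowpeak", source_tf = "partner")
cfg <- yaml::read_yaml(file.path(bdir, "config.yaml"))

assoc_b <- associate_anchor_peaks(anchor, baits)
assoc_t <- associate_target_peaks(partner, targets)
message(sprintf("bound baits:   %d / %d (%.3f)", length(assoc_b$bound),
                length(baits), assoc_b$bound_fraction))
message(sprintf("bound targets: %d / %d (%.3f)", length(assoc_t$bound),
                length(targets), assoc_t$bound_fraction))

cand <- build_loop_candidates(assoc_b$bound, assoc_t$bound, anchor, partner,
                              bounds = cfg$strata_bounds)
dir.create("results/loops", showWarnings = FALSE, recursive = TRUE)
write.table(cand, "results/loops/loop_candidates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

counts <- table(factor(cand$stratum, levels = cfg$strata_bounds))
message("loop candidates per stratum (bp bound -> n):")
for (i in seq_along(counts)) {
  message(sprintf("  %6s kb: %d", as.numeric(names(counts)[i]) / 1000,
                  counts[i]))
}
message("candidate table: results/loops/loop_candidates.tsv (",
        nrow(cand), " records)")
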