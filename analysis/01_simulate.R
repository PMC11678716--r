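#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs.
#
# Emits a complete input bundle under results/bundle: genome FASTA, gene
# models, the Capture-C bait/target catalogue, anchor- and partner-TF peaks,
# ATAC pseudo-bulk signals, histone-mark peaks, the affinity model, and the
# planted ground truth. The default configuration mirrors the study scale:
# 600 baits, 20,000 targets, ~10% of each bound, loop strata from direct
# overlap to 50 kb, planted site affinity decreasing with loop distance.

suppressMessages(library(chromloops))

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- sim_config(seed = seed)
bundle <- generate_bundle(cfg, "results/bundle")

tr <- bundle$truth
message("bundle written to results/bundle (seed ", seed, ")")
message("  bound baits:   ", length(tr$true_bound_baits), " / ", cfg$n_baits)
message("  bound targets: ", length(tr$true_bound_targets), " / ",
        cfg$n_targets)
message("  planted loop records: ", nrow(as.data.frame(tr$planted_loops)))
message("  ATAC regions: ", length(tr$true_atac_labels))
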