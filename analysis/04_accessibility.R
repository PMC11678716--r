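#!/usr/bin/env Rscript

# Stage 4: chromatin-context profiling of the candidate loop anchors.
#
# Classifies ATAC pseudo-bulk regions into noDA / loss / gain by mutant-over-
# wild-type log2 fold change, then measures how bound baits and bound targets
# are covered by each accessibility class and by active (H3K27ac-like) versus
# repressed (H3K27me3-like) histone-mark peaks.

suppressMessages(library(chromloops))

bdir <- "results/bundle"
if (!file.exists(file.path(bdir, "atac_regions.tsv"))) {
  stop("run analysis/01_simulate.R first")
}

baits <- read_peaks(file.path(bdir, "baits.bed"), "bed6")
targets <- read_peaks(file.path(bdir, "targets.bed"), "bed6")
anchor <- read_peaks(file.path(bdir, "anchor_peaks.narrowPeak"), "narrowpeak")
partner <- read_peaks(file.path(bdir, "partner_peaks.narrowPeak"),
                      "narrowpeak")
cfg <- yaml::read_yaml(file.path(bdir, "config.yaml"))

bound_baits <- associate_anchor_peaks(anchor, baits)$bound
bound_targets <- associate_target_peaks(partner, targets)$bound

atac <- classify_atac(read_atac_regions(file.path(bdir, "atac_regions.tsv")),
                      lfc_threshold = cfg$lfc_threshold,
                      pseudocount = cfg$pseudocount)
message("ATAC classes: ", paste(names(table(atac$klass)),
                                table(atac$klass), collapse = ", "))

dir.create("results/accessibility", showWarnings = FALSE, recursive = TRUE)
write.table(atac, "results/accessibility/atac_classes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cov_atac <- rbind(
  coverage_vs_classes(bound_baits, atac, query_label = "bound_baits"),
  coverage_vs_classes(bound_targets, atac, query_label = "bound_targets"))
write.table(cov_atac, "results/accessibility/coverage_atac.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

act <- read_peaks(file.path(bdir, "histone_active.bed"), "bed6")
repr <- read_peaks(file.path(bdir, "histone_repressed.bed"), "bed6")
cov_hist <- rbind(
  coverage_vs_histone(bound_baits, act, repr, query_label = "bound_baits"),
  coverage_vs_histone(bound_targets, act, repr,
                      query_label = "bound_targets"))
write.table(cov_hist, "results/accessibility/coverage_histone.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (q in unique(cov_hist$query_label)) {
  sub <- cov_hist[cov_hist$query_label == q, ]
  m <- tapply(sub$fraction, sub$subject_class, mean)
  message(sprintf("%s: mean coverage active %.3f, repressed %.3f",
                  q, m[["active"]], m[["repressed"]]))
}
message("coverage tables under results/accessibility/")
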