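#!/usr/bin/env Rscript

# Stage 3: low-affinity binding-site scanning of bound bait regions.
#
# Scans each anchor-bound bait with the position-specific affinity model
# (top 10 windows per region, forward and reverse strand), groups baits by
# their minimum loop distance, compares per-stratum affinity distributions
# with two-sided Wilcoxon rank-sum tests (BH-adjusted), and correlates peak
# summit heights with region affinity.

suppressMessages(library(chromloops))

bdir <- "results/bundle"
cand_path <- "results/loops/loop_candidates.tsv"
if (!file.exists(cand_path)) {
  stop("run analysis/02_associate_loops.R first")
}

baits <- read_peaks(file.path(bdir, "baits.bed"), "bed6")
anchor <- read_peaks(file.path(bdir, "anchor_peaks.narrowPeak"), "narrowpeak")
model <- read_affinity_model(file.path(bdir, "affinity_model.tsv"))
genome <- Biostrings::readDNAStringSet(file.path(bdir, "genome.fa"))
names(genome) <- sub("\\s.*$", "", names(genome))
cand <- read.delim(cand_path)

assoc_b <- associate_anchor_peaks(anchor, baits)
profiles <- scan_regions(assoc_b$bound, genome, model, k = 10)

dir.create("results/affinity", showWarnings = FALSE, recursive = TRUE)
write_profiles(profiles, "results/affinity/affinity_profiles.tsv")
export_region_fasta(assoc_b$bound, genome,
                    "results/affinity/bait_regions.fa")

bait_stratum <- tapply(cand$stratum, cand$bait, min)
pt <- profile_table(profiles)
pt$stratum <- unname(bait_stratum[pt$region_id])
pt <- pt[!is.na(pt$stratum), ]

med <- tapply(pt$summary_score, pt$stratum, median)
message("median affinity summary score by loop distance:")
for (i in seq_along(med)) {
  message(sprintf("  %6s kb: %.4f", as.numeric(names(med)[i]) / 1000, med[i]))
}
message(sprintf("rank correlation (distance vs median score): %.3f",
                cor(as.numeric(names(med)), as.numeric(med),
                    method = "spearman")))

groups <- split(pt$summary_score, paste0(pt$stratum / 1000, "kb"))
groups <- groups[order(as.numeric(sub("kb$", "", names(groups))))]
cmp <- suppressWarnings(compare_affinity_groups(groups))
write.table(cmp, "results/affinity/affinity_comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("pairwise Wilcoxon comparisons: results/affinity/affinity_comparisons.tsv")

sa <- summit_affinity_correlation(anchor, profiles, regions = assoc_b$bound)
message(sprintf("summit-affinity Pearson r = %.3f (n = %d)", sa$r, sa$n))
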