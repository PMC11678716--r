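# chromloops

Distance-stratified chromatin-loop candidate prediction and low-affinity
binding-site analysis for transcription-factor "loop blocking" studies.

## The problem

During mesoderm development, a tissue-specific factor (a Mef2-like MADS-box
protein) binds distal enhancers early and holds them against
promoter-proximal regions through chromatin loops. A Hox factor (a Ubx-like
homeodomain protein) arriving later at low concentration cannot occupy its
sites inside the looped anchors; higher dosage displaces the partner and
breaks the loop. `chromloops` is for genomicists who want to test this
blocking model from standard desk data: two ChIP peak sets, a Capture-C
bait/target catalogue, gene models, a genome FASTA with a quantitative
binding-affinity model, and (optionally) ATAC pseudo-bulk signals plus
histone-mark peaks.

The pipeline answers, in order:

1. Which baits are bound by the anchor factor, which targets by the partner
   factor, and what fraction of each (region counted once, >= 1 base
   overlap)?
2. Which bound-bait x bound-target pairs form **loop candidates**, stratified
   by edge-to-edge distance into 0/10/20/30/40/50 kb classes, each pair
   assigned to its smallest qualifying bound?
3. Do the anchor regions carry **low-affinity sites**? Each region is scanned
   with a position-specific affinity matrix (PSAM); a window of length *L*
   scores

   *S(w) = prod over i of A[i, w_i]*, with max-normalised columns so the
   consensus scores exactly 1,

   on both strands, and the top *k* = 10 windows per region are kept. Scores
   are compared across distance strata with two-sided Wilcoxon rank-sum tests
   (Benjamini-Hochberg adjusted), and summit height is correlated with
   region affinity (Pearson).
4. Does the chromatin context change? Accessibility classes follow
   *L = log2((mut + pc)/(wt + pc))*: `gain` if *L >= t*, `loss` if
   *L <= -t*, else `noDA` (defaults *t* = 1, *pc* = 1); coverage of
   candidate anchors is profiled against the three classes and against
   active/repressed histone-mark sets.

A seeded synthetic-data generator emits a complete input bundle with planted
ground truth (bound fractions, loop set, distance-decaying site affinities,
summit coupling, accessibility labels), so every stage is testable without
downloads. See `vignettes/loop-blocking.Rmd` for the methods account.

## Worked example

Generate a small synthetic bundle and run the whole analysis:

```r
library(chromloops)

dir <- tempfile()
cfg <- sim_config_tiny(seed = 7)          # 1 x 800 kb, 32 baits, 300 targets
bundle <- generate_bundle(cfg, dir)
report <- run_analysis(pipeline_config_from_bundle(dir, file.path(dir, "out")))
print(report)
#> loop_run_report
#>   bound baits:   14 / 32 (0.438)
#>   bound targets: 84 / 300 (0.280)
#>   loop candidates: 170
#>   per stratum: 0kb=80 2kb=24 4kb=20 6kb=18 8kb=14 10kb=14
#>   summit-affinity r = 0.825 (n = 14)
```

14 of 32 baits overlap an anchor peak and 84 of 300 targets a partner peak
(the tiny profile plants ~25% bound); their cross pairs within 10 kb form
170 loop candidates, most in the direct-overlap stratum. The positive
summit-affinity correlation (r = 0.825 over the 14 bound baits) reflects the
planted coupling between site affinity and peak summit height. Pairwise
stratum comparisons sit in `report$affinity_comparisons`:

```r
head(report$affinity_comparisons[, c("group_a", "group_b", "n_a", "n_b",
                                     "p_value", "p_adjusted")], 4)
#>   group_a group_b n_a n_b   p_value p_adjusted
#> 1     0kb     2kb   3   3 0.0765225  0.3333333
#> 2     0kb     4kb   3   2 0.1386406  0.3333333
#> 3     0kb     6kb   3   2 0.1386406  0.3333333
#> 4     0kb     8kb   3   2 0.1386406  0.3333333
```

At 2-3 regions per stratum the tiny profile cannot reach significance --
these columns become informative at the default scale (`sim_config()`,
600 baits / 20,000 targets), where per-stratum medians decrease strictly
with loop distance (Spearman rank correlation -1 between stratum bound and
median score).

The numbered scripts under `analysis/` run the same stages as a narrative
workflow at the default scale, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1        # bundle -> results/bundle
Rscript analysis/02_associate_loops.R   # bound fractions, candidates
Rscript analysis/03_affinity.R          # scanning, strata comparison, summits
Rscript analysis/04_accessibility.R     # ATAC classes, histone coverage
Rscript analysis/05_report.R            # end-to-end run + recovery scores
```

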