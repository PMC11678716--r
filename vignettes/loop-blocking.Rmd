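---
title: "Methods: distance-stratified loop candidates and low-affinity site scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-stratified loop candidates and low-affinity site scanning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromloops)
```

## The question the pipeline answers

A recurring regulatory motif in developmental genomics is *competitive
blocking*: a tissue-specific transcription factor (here a Mef2-like MADS-box
factor) occupies distal enhancers early, and those enhancers are held
against promoter-proximal regions by chromatin loops. A Hox factor (here a
Ubx-like homeodomain protein) arriving later at low concentration cannot
bind its sites inside the looped anchors; only at higher dosage does it
displace the partner and break the loop. Two genomic signatures make this
hypothesis testable from standard data:

1. The two factors rarely co-bind the same regions, yet converge on shared
   target genes via bait-target (promoter-enhancer) contacts recorded in a
   Capture-C catalogue.
2. The anchor regions carry *low-affinity* binding sites -- sequences scoring
   well below the consensus under a quantitative affinity model -- and the
   affinity decreases with loop distance, as does ChIP summit height.

`chromloops` implements the full analysis: interval arithmetic and distance
stratification over the Capture-C catalogue, peak-location classification
against gene models, position-specific affinity scanning, accessibility and
histone-mark context, the supporting nonparametric statistics, and a seeded
synthetic-data generator that plants all of the above so the whole chain is
verifiable end to end.

## Interval model and distance stratification

All interval logic runs on `GRanges` with 1-based inclusive coordinates;
BED-family readers convert from 0-based half-open on input and back on
output. Overlap queries are evaluated per chromosome with the IRanges
NCList engine.

Distance between two intervals is the **edge-to-edge gap in bases**: 0 when
they overlap *or abut* (half-open abutment leaves zero bases between), else
the count of intervening bases. `window_join(a, b, d)` returns all
same-chromosome pairs with gap at most `d`; `intersect_intervals` requires
at least `min_overlap` shared bases (default 1 -- the catalogue association
uses plain single-base overlap, since no reciprocal-overlap requirement is
imposed anywhere in the analysis).

`stratify_by_distance` reproduces incremental windowing: given bounds
(default 0, 10, 20, 30, 40, 50 kb) each qualifying pair is assigned to the
*smallest* bound admitting it, so strata are disjoint and their union equals
one window at the largest bound. Stratum 0 is the direct-overlap class (gap
0, which includes abutment -- a deliberate, documented consequence of the
edge-gap definition). Whether bait-target distance should be measured
edge-to-edge or midpoint-to-midpoint is genuinely open; edge gap is used
because it matches the windowing semantics of the standard BED toolkits the
rest of the interval layer mirrors.

## Peak anchoring and location classes

A peak is anchored at its summit (narrowPeak column 10) when present,
otherwise at its midpoint. The anchor is tested against five mutually
exclusive location classes in fixed priority order:

| class | definition | order |
|---|---|---|
| promoter | within −1000..+10 bases of a TSS (strand-aware), or in a 5′ UTR | 1 |
| distal_enhancer | −2000..−1001 of a TSS, in a 3′ UTR, or ≤1000 bases past the TES | 2 |
| other | in an exon | 3 |
| intron | elsewhere in the gene body | 4 |
| intergenic | none of the above (nearest-TSS gene still reported) | 5 |

The "downstream" bound (1000 bases past the TES) and the priority order are
package choices: the class vocabulary implies mutual exclusivity but no
precedence, and no downstream bound is stated anywhere, so the promoter-side
window is mirrored. Multi-transcript genes collapse to the exon union with
the most upstream TSS; UTR membership is tested on the anchor, like every
other class. Gene association (`peaks_to_genes`) maps each anchor to the
nearest TSS within 50 kb -- the largest loop stratum -- reporting all genes on
ties.

## Loop candidates

`associate_anchor_peaks` / `associate_target_peaks` mark a bait or target as
bound when ≥1 TF peak overlaps it by ≥1 base; a region counts once however
many peaks hit it. `build_loop_candidates` stratifies bound baits against
bound targets and expands every pair with all overlapping anchor and partner
peaks (cartesian product), since region/peak multiplicity has no canonical
resolution. A candidate record is therefore (bait, target, anchor peak,
partner peak, gap, stratum). Bait-target association is by proximity
(the stratified window), not by membership in a shared Capture-C interaction
record -- the catalogue is consumed as two interval sets.

For per-region distance grouping (summit and affinity comparisons), a bait's
loop distance is the *smallest* stratum among its candidates, matching the
incremental remove-then-collect windowing of the candidate assembly.

## Affinity model and scanning

The scoring engine is a mononucleotide position-specific affinity matrix
(PSAM): for each of L positions, a relative affinity in (0, 1] per base,
max-normalised so the consensus scores exactly 1. A window's score is the
product of its per-position weights -- an affinity relative to the optimal
site. The published biophysical model this stands in for is only ever used
here for *scoring*; model training is explicitly out of scope, and any model
file honouring the position x base contract is accepted (including
externally supplied reference motifs).

`scan_region` scores every offset on both strands (per-offset score =
max(forward, reverse-complement); ties prefer smaller offset, then the
forward strand) and keeps the top k = 10 windows -- the region's catalogue of
low-affinity sites. No low-affinity threshold is imposed: scores are
compared distributionally across strata. The per-region `summary_score` is
the mean of the top-k window scores; windows containing `N` score 0 and
never enter the top k, so regions in masked sequence can return fewer than k
windows. Only `N` is supported among ambiguity codes.

Cross-stratum comparison runs two-sided Wilcoxon rank-sum tests on the
summary scores of every group pair, with Benjamini-Hochberg adjustment
applied within that comparison family; raw p-values are retained alongside,
since box-plot captions conventionally report them unadjusted. Summit-height
versus affinity uses the Pearson product-moment correlation over regions
matched to their highest overlapping peak summit.

## Accessibility and histone context

The published single-cell ATAC pseudo-bulk behind the three
differential-accessibility classes does not document its clustering
thresholds, so the package applies a transparent stand-in rule on per-region
wild-type/mutant signals:

L = log2((mut + pc) / (wt + pc)), gain if L ≥ t, loss if L ≤ −t, else noDA,

with defaults t = 1 and pc = 1. Pre-labelled region files (a `klass` column)
bypass the rule untouched. Coverage profiling reuses
`coverage_fraction` -- per query region, the fraction of bases under the
union of the subject set -- against the three ATAC classes and against
active/repressed histone-mark peak sets.

## Nonparametric statistics

The Wilcoxon rank-sum test uses the exact permutation distribution when the
combined sample size is ≤ 12 and there are no ties, otherwise the normal
approximation with tie and continuity correction; the variant used is
recorded in each result. The cut-off keeps every call deterministic and
bounded in time, and ties always force the corrected approximation. Fisher's
exact test (two-sided, hypergeometric tail mass ≤ observed) and BH
adjustment are provided for overlap enrichment summaries. One property worth
noting: BH is *not* idempotent in general (re-adjusting adjusted values can
inflate them); the test suite checks the step-up arithmetic and
monotonicity instead.

## The synthetic-data generator

`sim_config()` defaults define the study conditions: 600 baits, 20,000
targets, 10% bound fractions (Bernoulli per region), strata 0-50 kb, a
14-base consensus with per-mismatch penalty 0.5, per-stratum mean planted
scores 0.5, 0.25, ..., 0.015625 (strictly decreasing with distance), 10
planted sites per bound bait, summit height = 10 + 100 x (mean planted
score) + Normal(0, 12), 3000 background ATAC regions at proportions
0.8/0.1/0.1 (noDA/loss/gain), and 90% of bound regions under active marks.

Layout is the one structural liberty the generator takes: bound baits are
placed in "loop blocks" spaced more than twice the largest stratum bound
apart, and each bait's bound targets are drawn at gaps inside its assigned
stratum. This guarantees that a bait's minimum loop distance equals its
assigned stratum, which is what makes the distance-decay planting testable.
Fitting ~60 such blocks requires 2 chromosomes x 6 Mb (the package's chosen
default scale; at 2 Mb the blocks cannot be separated). The tiny test
profile (`sim_config_tiny`: 1 x 800 kb, 32 baits, 300 targets, strata 0-10
kb in 2 kb steps, bound fractions 0.25) keeps every stratum populated at
unit-test scale and runs in seconds.

Two details make the planted structure exactly recoverable rather than
approximately:

* **Ground truth by independent enumeration.** The truth file's loop list is
  computed inside the generator by direct all-pairs gap arithmetic over the
  emitted intervals (including cartesian peak expansion), not by the
  package's overlap engine -- so "pipeline output equals planted truth" is a
  genuine two-route check.
* **Score quantisation.** `degrade_consensus` plants the minimal number m of
  mismatches with penalty^m ≤ target, so each site's true score is known
  exactly (penalty^m); a Bernoulli(0.4) extra mismatch per site spreads
  scores within a stratum so per-stratum summit-affinity correlations are
  not degenerate.

What the generator deliberately does **not** emulate: realistic base
composition (background is i.i.d. uniform ACGT), read-level noise (no
FASTQ/BAM; the pipeline starts from called peaks, as the analysis it
implements did), overlapping gene structures, irregular bait spacing, or
Capture-C false positives. Passing the end-to-end tests therefore
demonstrates that the *computational chain* is correct under planted
conditions -- not that the biological signal would be as clean in real data,
where association is noisy and affinity decay is a trend rather than a
construction.

## Numerical choices and degenerate inputs

* Window scores are computed in log space and exponentiated; planted-score
  comparisons in the tests use penalty 0.5, for which products are exact
  binary fractions.
* Deterministic ordering everywhere: pair tables sort by (chromosome, start,
  end, index) of query then subject; top-k ties break by offset then strand;
  equidistant TSS ties report all genes sorted.
* Degenerate inputs have defined behaviour rather than crashes: empty peak
  files produce zero-candidate reports with success status; empty
  accessibility classes yield zero coverage with a warning; correlations on
  fewer than 3 pairs or zero-variance inputs raise informative errors;
  malformed records are reported with file line numbers.
* All randomness in the generator flows from the single config seed; the
  analysis itself is deterministic, and report provenance hashes a
  path-normalised view of the configuration so identical runs are
  byte-identical wherever they execute.

## Problem sizes

The test suite validates the interval engine against all-pairs/base-counting
oracles on 1000 randomised instances of up to 200 intervals, the scanner
against exhaustive enumeration on 100 regions up to 1 kb, the exact Wilcoxon
against full enumeration for all splits with n1 + n2 ≤ 10 plus a
10,000-replicate null calibration, and the end-to-end recovery on the
default-scale bundle (600 baits / 20,000 targets). These sizes were chosen
to exercise every code path at full study scale while keeping a complete
run in the low minutes on a single CPU.

## Known limitations

* The accessibility rule is a declared stand-in for an undocumented
  upstream clustering; with pre-labelled regions it is bypassed entirely.
* Only mononucleotide PSAMs are supported -- no dinucleotide or shape terms,
  and no model fitting.
* Bait-target association is proximity-based; if a catalogue encodes paired
  interaction records, that pairing is not consulted.
* The peak-location vocabulary places 5′ UTRs with promoters and 3′ UTRs
  with distal enhancers by definition; peaks in unannotated UTRs (e.g. from
  BED12 input, which carries none) fall through to exon/intron classes.
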