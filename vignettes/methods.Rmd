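---
title: "Methods: from probe-level aCGH ratios to Ki67-response candidate genes"
author: "cnaki67"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from probe-level aCGH ratios to Ki67-response candidate genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnaki67)
```

# The analysis problem

Estrogen-receptor-positive breast tumours treated with neoadjuvant aromatase
inhibitors (AIs) show heterogeneous proliferative responses, conventionally
read out as the fall in the Ki67 labelling index after two weeks of therapy.
`cnaki67` implements an integrative screen that asks: *which genes are
recurrently amplified, overexpressed when amplified, and carried at higher
copy number in the tumours whose Ki67 falls least?* Such genes are candidate
modulators of de novo AI resistance.

The pipeline runs from probe-level array-CGH log2 ratios (a ~32,000-clone
tiled BAC grid at roughly 100 kb resolution) through segmentation, categorical
state calling, genome-instability metrics and genomic-pattern classification,
to a three-branch statistical integration with expression and clinical data,
plus a matched pre/post-treatment comparison for cohorts profiled at two
timepoints.

# Segmentation

Raw per-probe log2 ratios are segmented per chromosome by a self-contained
circular-binary-segmentation variant. Within the current window the method
finds the changepoint pair $(i, j)$ maximising the pooled two-sample
$|t|$ between the "arc" $y_{i+1..j}$ and its complement; a boundary arc
degenerates to a single split. The observed maximal $|t|$ is referred to a
permutation null (probes shuffled within the window, default
`n_perm = 200`), and the split is accepted when $p < \alpha$ (default
`0.01`), recursing into up to three children. There is no wrap across window
boundaries and no prune/undo step.

Two design points deserve a note:

* **Why the two-changepoint arc, not a single binary split?** A focal
  amplicon in the middle of a chromosome barely moves either half's mean
  while inflating the pooled variance, so a single-split statistic has
  essentially no power against exactly the feature — localized
  amplification — that the downstream pattern classifier and
  private-amplicon detector depend on. The arc statistic tests the amplicon
  against its flanks directly. The same argument applies to alternating
  gain/loss ("sawtooth") chromosomes.
* **Permutation early stopping.** Permutations stop as soon as the number of
  exceedances forces the final p-value above $\alpha$; this leaves accepted
  splits untouched and cuts the cost of the (overwhelmingly more common)
  rejected ones. Permutations draw from R's RNG, so results are reproducible
  under `set.seed()`.

Changepoints closer to a window edge than `min_width` (default 3 probes) are
not searchable — a known property of minimum-width segmentation; planted
features in the synthetic cohorts are therefore kept at least `min_width`
probes from chromosome ends.

Missing probe ratios are dropped per sample before segmentation (the probe
keeps `NA` segment, cbs ratio and state) and counted in the QC log; probes
missing in more than 10% of samples are flagged.

A pure-R reference implementation (`cbs_segment_r`) with the identical
criterion is kept in the package and compared against the C++ path in the
test suite.

# State calling and instability metrics

Each probe inherits its segment-mean ("cbs") log2 ratio, thresholded into
four ordinal states: loss (≤ −0.12), no change, gain (≥ +0.12) and
amplification (≥ +0.45). These defaults mirror common practice for ~32K BAC
platforms but are plain configuration (`state_thresholds()`); nothing in the
package hard-codes them. The *proportion of the genome altered* — the
fraction of (non-missing) probes in a non-NC state — serves as the
genome-instability index; base-pair weighting is available for non-uniform
grids.

# Genomic pattern classification

Profiles are labelled with the classical genomic patterns: **simplex** (few
broad, near-whole-chromosome changes), **sawtooth** (many narrow changes
across most chromosomes) and **firestorm** (a simplex-like background plus at
least one localized amplification). The published criteria are verbal; the
rule set here is an explicit operationalization with every numeric exposed in
`pattern_params()`:

| parameter | default | meaning |
|---|---|---|
| `broad_fraction` | 0.5 | segment counts as broad at ≥ 50% of its chromosome |
| `sawtooth_min_segments_per_chrom` | 5 | narrow altered segments for a fragmented chromosome |
| `sawtooth_chrom_fraction` | 0.8 | fragmented chromosomes needed for sawtooth |
| `firestorm_focal_width` | 20 Mb | maximal focal-amplicon span |
| `firestorm_min_amp_probes` | 3 | minimal focal-amplicon probe count |

Rule precedence is firestorm > sawtooth > simplex, because a firestorm is
defined as simplex-plus-amplicon: the presence of a qualifying amplicon must
dominate. Broadness is judged per chromosome (no centromere table is
shipped). The defaults are non-canonical and the classifier reports its full
evidence (amplicon counts, fragmented-chromosome fractions) with every call.
The CLI can sweep `firestorm_focal_width` and report label flips.

# Statistical primitives

All test statistics are implemented in the package and verified against
brute-force oracles in the test suite:

* **Pearson** r with the $t_{n-2}$ tail; **Spearman** rho on average ranks
  with an exact permutation p-value for $n \le 9$ (full enumeration of the
  $n!$ orderings) and the t-approximation otherwise.
* **Mann-Whitney U** (min-U convention): exact two-sided p by an own
  counting recurrence over all labelings for tie-free samples with
  $n_a + n_b \le 16$; otherwise a normal approximation with tie correction
  and continuity correction. The continuity correction is switchable
  (`correct = FALSE`) because the two-group Kruskal-Wallis test is
  mathematically identical to the *uncorrected* normal approximation, and
  that equivalence is part of the test suite.
* **Kruskal-Wallis** H with tie correction, chi-square tail.
* **Benjamini-Hochberg** step-up FDR ("adjusted P" throughout the pipeline);
  NAs pass through without counting towards $m$. Note that BH is *not*
  idempotent on its own output (re-adjusting adjusted values can change them
  when tied plateaus shift ranks) — the suite asserts the true properties:
  oracle equality, $q \ge p$, monotonicity.
* **Ward clustering** by the direct $O(n^3)$ minimum-variance algorithm on
  Euclidean distances, lowest-index tie-break, heights on the
  `hclust(method = "ward.D2")` scale (the suite checks agreement to 1e-9).
  Categorical states are encoded loss = −1, NC = 0, gain = +1, amp = +2 for
  clustering, preserving the ordinal ratio scale.

Two-sided tests are used everywhere.

# The integrative screen

Probe-level copy number is mapped to genes as the **median cbs ratio of all
probes overlapping the gene's interval** (half-open overlap; genes in probe
deserts may fall back to the nearest probe within a configurable distance,
flagged). Gene-level states come from thresholding that median — not from a
majority vote of probe states — so gene calls stay on the continuous ratio
scale.

Three branches then run across samples:

1. **Copy-number-regulated genes**: per-gene Pearson correlation of
   gene-level cbs ratio with expression, BH across all tested genes, flagged
   at $q < 0.05$.
2. **Overexpressed-when-amplified genes**: per-gene Mann-Whitney with the
   amplification state as the grouping variable (at least 3 samples per arm),
   BH-adjusted, flagged only when the amplified-group median is the higher
   one.
3. **Copy number vs Ki67 response**: per-probe Spearman correlation of cbs
   ratio with the two-week Ki67 decrease (%), BH-adjusted; significant
   probes of one sign are merged into loci, bridging at most 2 interleaved
   non-significant probes within 1 Mb. Negative rho — higher copy number,
   smaller Ki67 fall — marks the poor-response direction. Genes are assigned
   to loci by full interval containment.

A **candidate** is a gene flagged in branches 1 and 2 that lies inside a
poor-response branch-3 locus. An optional resistance-model filter retains
candidates whose expression fold change in a long-term estrogen-deprived
(LTED) line over its parental line is ≥ 1.5 (the threshold is configuration;
genes without model data are kept but flagged, or dropped on request).

The responder rule is strict: a responder's Ki67 falls by *more than* 50% at
two weeks; a fall of exactly 50% is a non-response.

# Paired pre/post analysis

For cohorts with matched pre- and post-treatment profiles on one grid:

* **Grouped frequency comparison**: per probe and per aberration class
  (gain-or-amp, loss, amp-only) an exact McNemar test — a two-sided binomial
  on the discordant pairs — BH-adjusted. Probes with zero discordant pairs
  carry NA (the paired test is undefined there) and do not enter the
  adjustment.
* **Clustering**: Ward/Euclidean on the encoded states of all $2n$ samples;
  a pair counts as *adjacent* when its two members merge as singletons
  before touching any other sample.
* **Private amplicons**: amplified runs (≥ 3 probes) in one member are
  reported only when the other member's mean cbs over the same interval
  stays below `gain_min − margin` (default margin 0.05 log2 units). The
  margin guards against the near-threshold artifact where both members
  straddle the gain cutoff and only one crosses it. Reporting is
  descriptive — no per-event p-value — matching how such events are
  typically presented.

# The synthetic cohort generator

No patient microarrays ship with the package, so every downstream stage is
validated against synthetic cohorts with planted ground truth
(`generate_cohort()`, `generate_matched_pairs()`). The generator emulates:

* a 32,000-probe, 23-chromosome, 100 kb-pitch BAC grid (tests and the
  acceptance script scale the grid down to 460–1,840 probes to keep runtimes
  in minutes; grid size is configuration, and the planted effects do not
  depend on it);
* per-sample background profiles drawn from the three pattern archetypes in
  the proportions 13:23:48 (the simplex:sawtooth:firestorm split of the
  motivating 84-sample cohort);
* recurrent aberration regions of varying magnitude
  (Unif(0.4, 1.2) log2 units in carriers), one of which — the *resistance
  amplicon*, placed on chromosome 11 in echo of the common 11q13 amplicon —
  is carried by 30% of samples and always exceeds the amplification
  threshold;
* expression with cis-dosage coupling at 20 planted genes
  (1.5 expression units per log2-ratio unit; exactly one of them, the
  planted resistance gene, lies inside the resistance amplicon);
* Ki67: baseline LogNormal(log 20, 0.5) percent; two-week decrease Normal,
  mean 60 for non-carriers, attenuated by 30 points for resistance-amplicon
  carriers, truncated to [−100, 100].

Design choices worth recording:

* **Carrier counts are planted exactly** (`round(fraction × n)` samples),
  not drawn Bernoulli: recovery rates should measure the detector, not
  binomial fluctuation of the plant itself.
* **Ki67 decrease sd defaults to 10**, making the planted 30-point
  attenuation a 3-sd effect. With a wider spread the planted signal is not
  recoverable after FDR adjustment over ~2,000 probes at n = 50 — i.e. the
  generator would plant a signal its own pipeline is specified to find; the
  narrower spread keeps the planted effect unambiguous. Real two-week Ki67
  falls are more dispersed; parameter-recovery results here do not certify
  power at any particular clinical effect size.
* **Sawtooth archetypes are irregular**: six alternating-sign segments per
  fragmented chromosome with random widths (≥ 6 probes) and asymmetric
  depths (gains Unif(0.2, 0.4), losses Unif(0.2, 0.7)). A balanced square
  wave is an adversarial, unrealistic special case: under permutation its
  bimodal marginals cluster by chance, leaving the max-|t| null almost as
  heavy as the alternative.
* **Seed discipline**: one master seed; stage seeds are derived from it in
  fixed order (`derive_seeds()`), so adding a later stage never perturbs
  earlier stages, and every output is byte-reproducible.

What the generator does **not** emulate: two-channel intensity artifacts, dye
bias, GC waves, batch effects, tumour purity/ploidy, spatial heterogeneity,
or realistic linkage between instability and Ki67. Passing recovery tests
therefore demonstrates the pipeline's correctness on its stated model, not
clinical performance.

# Problem sizes and runtime

The test suite and acceptance script run, on one CPU, in a few minutes
total, using: 50-sample cohorts on 23 × 80-probe grids (1,840 probes, 1,000
genes) for integration recovery across 50 seeds; 100 replicates for
segmentation recovery; 90 archetypes for classification; 200 permutation
replicates for null calibration; 19 matched pairs for the paired analysis.
The full 32,000-probe default grid is practical for single cohorts (the
per-chromosome arc search is quadratic in probes per chromosome, so ~1,400
probes per chromosome is noticeably slower than the test grids, on the order
of seconds per sample per chromosome for the permutation tests).

# Coordinates and formats

Internally and in probe/annotation tables, coordinates are 0-based half-open
(BED dialect); SEG output converts to 1-based inclusive at the boundary.
Chromosome order is lexicographic, so synthetic chromosomes are zero-padded
(`chr01` … `chr23`). Probe tables are TSV (probe, chrom, start, end, one
column per sample), expression is TSV (gene × sample), clinical is CSV,
configuration is YAML, and every `run_pipeline()` bundle carries a
`report.json` with the config hash, the seed and per-stage counts.

# Known limitations

* The segmentation has no prune/undo step; very long chromosomes with many
  weak changepoints may over- or under-segment relative to full CBS.
* Gain/loss/amplification thresholds, pattern-rule numerics, locus-merge
  gaps and the LTED fold-change cutoff are field-plausible defaults, not
  canonical values; conclusions can be sensitive to them and all are exposed
  as configuration.
* Branch 3 is computed per probe and merged to loci; computing it per
  predefined region would weight evidence differently.
* Arm-level broadness (with a centromere table) is not implemented;
  chromosome-level broadness stands in.
* The paired analysis assumes both members of a pair are profiled on the
  identical grid.
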