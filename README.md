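# cnaki67

Integrative copy-number / gene-expression / Ki67-response analysis for
aromatase-inhibitor (AI) treated, estrogen-receptor-positive breast cancer
cohorts.

## What it does, and for whom

Neoadjuvant AI trials read out proliferative response as the fall in the
Ki67 labelling index after two weeks of therapy; a fall of more than 50%
defines a responder. Given probe-level array-CGH log2 ratios (a tiled BAC
grid of ~32,000 clones), a gene-expression matrix and baseline/2-week Ki67
values, `cnaki67` identifies genes that are **amplified, overexpressed when
amplified, and associated with a poor Ki67 response when carried at higher
copy number** — candidate modulators of de novo AI resistance. It is aimed
at computational biologists analysing neoadjuvant endocrine-therapy cohorts
or benchmarking integrative copy-number/expression methods.

The pipeline:

1. **Segmentation** — a self-contained circular-binary-segmentation variant:
   per chromosome, recursively accept the changepoint pair ("arc" vs its
   complement) maximising the pooled two-sample |t|, gated by a permutation
   p-value (`alpha = 0.01`); every probe inherits its segment-mean ("cbs")
   log2 ratio. Implemented in C++ with a pure-R reference path.
2. **State calling** — cbs ratios thresholded into loss / NC / gain /
   amplification (defaults −0.12 / +0.12 / +0.45, all configurable), plus
   the *proportion of the genome altered* instability index and per-probe
   cohort aberration frequencies.
3. **Pattern classification** — explicit rules for the classical genomic
   patterns: *simplex* (few broad changes), *sawtooth* (many narrow changes
   on most chromosomes), *firestorm* (simplex background + ≥1 focal
   amplicon), with every numeric threshold exposed and an evidence trail on
   each call.
4. **Integrative screen** — three branches across samples:
   gene-level cbs ratio vs expression (Pearson, BH-FDR);
   expression by amplification status (Mann-Whitney, BH-FDR, amplified
   median must be higher); probe-level cbs ratio vs 2-week Ki67 decrease
   (Spearman, BH-FDR, merged into signed loci). Candidates = branch-1 ∩
   branch-2 genes inside a poor-response (negative-rho) locus, optionally
   filtered by fold-change in an AI-resistance cell model (LTED).
5. **Paired analysis** — for matched pre/post-treatment profiles: per-probe
   exact McNemar frequency comparison, Ward/Euclidean clustering of
   categorical states with pair-adjacency reporting, and detection of
   amplicons private to one member of a pair (with a near-cutoff margin
   guard).
6. **Synthetic cohorts** — a generator with planted ground truth (dosage
   coupling, recurrent amplicons, a response-attenuating resistance
   amplicon, pattern archetypes) so every stage has a parameter-recovery
   test.

The statistical primitives (Pearson, Spearman with exact small-n
permutation p, exact Mann-Whitney, Kruskal-Wallis, Benjamini-Hochberg, Ward
clustering) are implemented in the package and verified against brute-force
enumeration oracles and the base-R references in the test suite.

## Worked example

```r
library(cnaki67)

# a synthetic 40-sample cohort with planted truth
cfg    <- sim_config(n_samples = 40, n_probes = 1840, n_chromosomes = 23,
                     seed = 2024)
sim    <- generate_cohort(cfg)
cohort <- call_states(segment_cohort(sim$cohort, seed = 2025))
summary(cohort)
#> cna_cohort: 1840 probes on 23 chromosomes, 40 sample(s)
#>   segmented: TRUE  states called: TRUE
#>   proportion of genome altered: median 0.145 (range 0.047-0.921)

res <- run_integration(cohort, sim$expression, sim$clinical, sim$genes)
print(res)
#> integrative copy-number / expression / Ki67 screen
#>   branch 1 (CN-regulated):            21 genes flagged
#>   branch 2 (overexpressed-when-amp):  20 genes flagged
#>   branch 3 (CN vs dKi67):             1 loci (1 poor-response)
#> candidate_report: 1000 genes; branch1 21, branch2 20, branch3 17, candidates 1
#>   candidates: g0458

sim$truth$resistance_gene
#> [1] "g0458"
```

The single candidate is exactly the planted resistance gene: it is
dosage-coupled (branch-1 r = 0.86, q = 2.5e-10), overexpressed when
amplified (branch-2 q = 2.7e-05, amplified in 27.5% of samples), and sits in
the one locus whose copy number correlates negatively with the Ki67 fall.

Pattern classification on planted archetypes:

```r
grid <- cohort$grid
for (pat in c("simplex", "sawtooth", "firestorm")) {
  prof <- generate_archetype_profile(pat, grid, noise_sd = 0.05, seed = 3)
  co <- cna_cohort(grid, matrix(prof$ratio, dimnames = list(grid$probe, "s")))
  co <- call_states(segment_cohort(co, seed = 4))
  cat(sprintf("planted %-9s -> classified %s\n", pat,
              classify_pattern(co)$label))
}
#> planted simplex   -> classified simplex
#> planted sawtooth  -> classified sawtooth
#> planted firestorm -> classified firestorm
```

A thin command-line wrapper over the same functions ships at
`inst/cli/cnaki67.R` (subcommands `simulate`, `segment`, `call-states`,
`metrics`, `classify-pattern`, `integrate`, `paired`, `run-all`).

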