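# gsihap

Evaluation machinery for **genetic stock identification (GSI)** baselines
built from amplicon sequencing, written for the kind of mixed-stock
monitoring done for Snake River basin steelhead (*Oncorhynchus mykiss*):
ten management reporting units containing 44 genetic populations that must
be told apart at weak differentiation (per-locus Weir–Cockerham θ around
0.03). The package is aimed at conservation-genetics practitioners who
build or revise GSI baselines and need a reproducible way to ask: *did
adding loci, adding populations, or calling microhaplotypes instead of
single SNPs actually improve assignment?*

It provides, as testable R functions:

* **Microhaplotype-aware genotype calling** from per-allele read counts: a
  multinomial likelihood in which each read comes from one of the two gene
  copies and errs to any other allele with per-read probability ε = 0.01,
  a uniform prior over the K(K+1)/2 unordered genotypes, and calls only
  when posterior > 0.99 and depth ≥ 10 — plus amplicon reference selection
  and a candidate-SNP column scan with a cap of 8 candidates per locus.
* **Locus/individual QC**: permutation tests of Hardy–Weinberg proportions
  (probability-ordering statistic, (b+1)/(n+1) p-values) with
  Benjamini–Yekutieli FDR control across loci within collections and
  removal when significant in ≥ 2 collections; heterozygote allele-balance
  paralog flags; strict >90% genotyping-rate and genetic-duplicate filters.
* **Per-locus multi-allelic Weir–Cockerham F_ST** (variance components
  a, b, c; θ = Σa/Σ(a+b+c)) with panel-level mean/range/SD summaries.
* **Leave-one-out self-assignment**: each individual's gene copies are
  withheld from its own population's Dirichlet-smoothed (pseudocount 1/K)
  allele counts; scaled likelihoods over populations, reporting-unit
  probability by summation, top call with no threshold.
* **Bayesian mixture inference**: Gibbs sampling of origin indicators and
  mixing proportions (Dirichlet(1/P) prior, 2000 burn-in + 4000 reps by
  default), and **simulated-mixture bias assessment** with Dirichlet(1.5)
  truth and leave-one-out resampling of baseline members.
* **Evaluation**: PIT-tag detection concordance, 2×2 chi-square and
  rank-based comparisons between baseline/panel configurations, and
  summary report grids.
* A **synthetic generator** (hierarchical Balding–Nichols F-model) whose
  `snake_river_v4` preset reproduces the emulated study's structure —
  10 units / 44 populations / 3150 individuals, 334 loci with 91
  microhaplotypes — so everything above runs with no external data.

## Worked example

```r
library(gsihap)

sim <- simulate_snake_river_v4(seed = 42, size_factor = 0.25)
sim$baseline
#> gsi_baseline: 786 individuals, 44 collections, 44 populations, 10 reporting units, 334 loci

summary(self_assign(sim$baseline))
#> Overall correct-assignment rate: 92.2% (786 individuals)
#> Per reporting unit:
#> GRROND IMNAHA LOCLWR LOSALM LSNAKE MFSALM SFCLWR SFSALM UPCLWR UPSALM
#>   99.3   87.5   90.8   50.0  100.0   90.9   80.4   85.7   91.6   98.2

panel_fst_summary(sim$baseline)
#>         mean          min        max         sd n_loci n_excluded
#> 1 0.02867423 -0.006376832 0.08535761 0.01315717    334          0

fit <- infer_mixture(sim$baseline, sim$mixture$geno,
                     burn_in = 1000, reps = 2000, seed = 1)
round(sort(coef(fit), decreasing = TRUE), 3)[1:4]
#> LOSALM UPSALM SFCLWR LSNAKE
#>  0.270  0.175  0.169  0.104     # true: 0.265 0.191 0.185 0.100

concordance(fit$top_unit, sim$detections)
#> concordance_report: 86.0% concordant (250 detections, 0 without genotype)
```

Read as: at a quarter of the full baseline size the emulated 334-locus
microhaplotype panel assigns 92% of individuals back to their reporting
unit under leave-one-out; the panel-wide mean θ of 0.029 matches the weak
differentiation the preset targets; the Gibbs sampler recovers the true
mixture proportions to within ~0.02; and with a 2% stray rate the PIT/GSI
concordance lands in the mid-80s, concordance being bounded by assignment
accuracy times site fidelity.

The marker-panel comparisons of the motivating study are one call away:
`collapse_microhaps()` re-expresses every microhaplotype as its component
SNP, and `subset_loci()` cuts panels down, after which
`compare_runs()`/`make_reports()` produce the chi-square and rank-based
comparisons between configurations.

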