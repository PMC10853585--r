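---
title: "Methods: genotyping, baseline QC, and stock-assignment evaluation in gsihap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotyping, baseline QC, and stock-assignment evaluation in gsihap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gsihap` implements, end to end, the evaluation machinery used to judge
genetic stock identification (GSI) baselines built from amplicon (GT-seq
style) sequencing: microhaplotype-aware genotype calling from per-allele
read counts, locus and individual quality control, per-locus multi-allelic
Weir--Cockerham $F_{ST}$, leave-one-out self-assignment, Bayesian mixture
inference, simulated-mixture bias assessment, concordance against an
independent physical-tag record, and the between-configuration statistical
comparisons. The motivating system is steelhead (*Oncorhynchus mykiss*)
monitoring in the Snake River basin, where ten management-level reporting
units comprising 44 genetic populations must be told apart despite weak
differentiation (per-locus $\theta$ averaging roughly 0.03). A synthetic
generator reproduces that structure so every stage is testable with no
external data.

Sequencer-facing steps (library preparation, read alignment with a
general-purpose aligner, and pileup-based variant calling on real data) are
out of scope: the package starts from per-allele read counts, and its
reference-building / candidate-SNP scan operate on exactly placed synthetic
reads only.

# The genotype caller

At a locus with allele set of size $K$, a read originating from gene copy
$a$ is observed as allele $b$ with probability

$$P(b \mid a) = \begin{cases} 1 - \varepsilon & b = a \\
\varepsilon/(K-1) & b \ne a,\end{cases}$$

with $\varepsilon = 0.01$ per read by default: errors are equally likely to
be reads of any other allele. For an unordered genotype $g = \{a_1, a_2\}$
the emitting copy is chosen with probability $\tfrac12$, so a read is
allele $b$ with probability $\tfrac12 P(b \mid a_1) + \tfrac12 P(b \mid
a_2)$, and the read-count vector is multinomial. With a uniform prior over
the $K(K+1)/2$ unordered genotypes, the posterior is the normalized
likelihood; computation is in the log domain with log-sum-exp
normalization, since depths in the thousands underflow the linear domain.
A call is emitted iff depth $\ge 10$ (non-strict) *and* the maximum
posterior exceeds $0.99$ (strict); otherwise the cell is missing.

One modelling point is genuinely ambiguous in the informal description of
this class of callers: whether the two gene copies mix per read (as above)
or the depth is pre-split between copies. We implement the per-read
mixture, which is the only reading consistent with a single per-read error
rate; the alternative would change posteriors only at extreme allele
imbalance.

Reference construction picks, per locus, the unique read sequence of
highest multiplicity that begins with the forward primer and contains an
in-silico probe; ties are broken lexicographically (deterministic, logged).
The candidate-SNP scan is a column-wise count over placed reads: a position
is a candidate when at least two bases each reach 10 reads and 10% of
column depth. Both thresholds are exposed; they were chosen so that a 1%
per-read error process stays an order of magnitude below the trigger.
Loci with more than 8 candidate SNPs are treated as probable paralog
co-amplification and dropped.

# Quality control

**Hardy--Weinberg.** Within each collection, the test statistic is the
conditional probability of the observed genotype table given its allele
counts under random union of gametes; gene copies are permuted among
individuals and re-paired, and an arrangement counts as at least as extreme
when its probability is $\le$ the observed one. The p-value uses the
$(b+1)/(n_{perm}+1)$ correction, so it is never exactly zero and the
estimate is valid at any $n_{perm}$; the default is 10,000 permutations.
Like all exact-style conditional tests this is slightly conservative for
very discrete nulls (few alleles, small samples); at the multi-allelic loci
the microhaplotype-discovery stage actually screens, the attained level is
indistinguishable from nominal. FDR control across loci within a collection
uses Benjamini--Yekutieli (valid under arbitrary dependence, delegated to
`p.adjust`), and a locus is removed when significant (adjusted $p < 0.05$)
in two or more collections.

**Allele balance.** The published practice for spotting paralogs is visual
inspection of heterozygote read-count plots. Reproducibility requires a
computable rule, so the package flags a locus when heterozygotes' mean
balance deviates from 0.5 by more than 0.1, or when a two-group 1-D k-means
split separates balances by more than 0.2 with each group holding at least
20% of heterozygotes. All thresholds are arguments; defaults were fixed
once against the generative model (a true paralog duplicates one copy,
pushing balance toward 1/3 or 2/3) and are not tuned per dataset.

**Individuals.** Retention requires a genotyping rate strictly above 90% --
the wording of the rule is strict, so an individual at exactly 90.0% is
removed. Duplicate detection flags pairs sharing $\ge 95\%$ identical
genotypes over $\ge 100$ mutually typed loci and removes the lower-rate
member (ties keep the earlier record). The 0.95/100 duplicate rule is this
package's operationalization of "no genetic duplicates"; it follows common
GT-seq practice and is configurable.

# Population-genetic differentiation

Per-locus differentiation uses the Weir--Cockerham variance-component
estimator in its multi-allelic form: for each allele the among-population
($a$), among-individual ($b$) and within-individual ($c$) components are
computed and summed over alleles, with $\theta = \sum a / \sum(a+b+c)$.
$\theta$ can be slightly negative by sampling; loci monomorphic across all
populations (0/0) or typed in fewer than two populations are excluded from
panel summaries rather than coerced to a number. The biallelic case of the
general code agrees with the dedicated single-allele formula to machine
precision, which the tests verify against an independently coded oracle.
(The estimator is the 1984 variance-components $\theta$, the one computed
by the *hierfstat* `wc` routine that this literature cites.)

# Assignment and mixtures

**Conditional genotype likelihood.** Population allele frequencies are
never plugged in as point estimates: with per-allele pseudocount $1/K$ the
probability of drawing an unordered pair is the Dirichlet-multinomial
posterior predictive, $2\,\tilde p_a \tilde p_b'$ for heterozygotes and
$\tilde p_a \tilde p_a'$ for homozygotes, the primed factor conditioning on
the first draw. This is the documented default smoothing of the
conditional-GSI framework this package follows. Missing loci contribute
nothing to an individual's log-likelihood.

**Leave-one-out self-assignment.** Each baseline individual's two gene
copies per locus are subtracted from its own population's counts before its
likelihood for that population is computed; scaled likelihoods are the
softmax over populations with equal population priors, and the
reporting-unit probability is the sum over member populations. The summed
(rather than top-population) unit call is a deliberate choice where the
published description is silent; on structured baselines the two rarely
differ. Assignment takes the top unit with no probability threshold; ties
are broken by unit order in the baseline (deterministic). The whole
procedure is deterministic and invariant to individual ordering, which the
tests assert.

**Mixture inference.** The Gibbs sampler alternates origin indicators
$z_i \sim \mathrm{Cat}(\rho_p \cdot P(y_i \mid p))$ and proportions
$\rho \sim \mathrm{Dirichlet}(1/P + n)$, with posterior means over
post-burn-in sweeps (defaults: 2000 burn-in, 4000 reps). The $1/P$
proportion prior is the cited framework's documented default. Per-individual
reporting-unit posteriors are averages of unit-membership indicators.

**Simulated-mixture assessment.** Per replicate, reporting-unit proportions
are drawn $\mathrm{Dirichlet}(1.5)$ and, within each unit, population
sub-proportions $\mathrm{Dirichlet}(1.5)$ -- the within-unit draw is our
convention, as the published description specifies only the unit level.
Mixtures are built by resampling baseline members (with replacement),
withholding each sampled member's gene copies from the reference when its
own likelihood is computed -- gene-copy-level leave-one-out, chosen over
whole-individual withholding, which the source description leaves open.
Error is estimated minus true proportion per unit; errors sum to zero
within a replicate by construction, and the defaults (1000 replicates of
1000 individuals) match the published protocol.

# The synthetic generator

Allele frequencies follow a two-level hierarchical Balding--Nichols
F-model: unit frequencies are drawn
$\mathrm{Dirichlet}(\pi\,(1-F_{unit})/F_{unit})$ about ancestral $\pi$, and
population frequencies likewise about unit frequencies with $F_{pop}$. For
biallelic loci this is the classic Beta form; the Dirichlet generalization
keeps the one-parameter mapping from $F$ to expected differentiation.
Genotypes are two independent gene copies (Hardy--Weinberg within
population); loci are independent, as the GSI model itself assumes.
Ancestral frequencies are $\mathrm{Dirichlet}(2,\dots,2)$ floored at 0.02,
emulating markers ascertained to be commonly variable.

The `snake_river_v4` preset fixes the study conditions: the 10-unit /
44-population hierarchy with the real per-management-population sample
counts (3150 individuals, mean 72 per population), 334 loci of which 91 are
microhaplotypes carrying 3--6 alleles (about two thirds with three,
matching the panel emulated), negative-binomial read depth (mean 100,
dispersion 10), per-read error 0.01, $\mathrm{Dirichlet}(1.5)$ mixtures,
and detection cohorts split 894/1087 across two spawn years. Divergence
$F_{unit} = F_{pop} = 0.015$ was chosen once so the realized per-locus mean
$\theta$ lands near 0.03, the level reported for the real baseline; the
detection stray rate of 0.02 encodes the strong natal-stream fidelity the
concordance analysis assumes. None of these values is revisited after
seeing test outcomes.

What the generator does *not* emulate: linkage between amplicons, isolation
by distance (units are exchangeable draws, not spatially arranged),
hatchery introgression, genotyping-rate heterogeneity across plates, and
allele-frequency drift between baseline and mixture cohorts. Passing tests
therefore demonstrate correctness of the machinery under the stated model,
not field performance of any particular panel.

Marker-panel comparisons are constructed from one baseline:
`collapse_microhaps()` projects every microhaplotype onto its first
component SNP (the panels are built so that component is biallelic),
giving the all-SNP configuration over the same amplicons, and a seeded
176-locus subset of that gives the reduced panel. On the emulated baseline
the published qualitative ordering -- more loci help, and microhaplotype
calls beat their collapsed SNPs -- reproduces robustly.

# Numerical and engineering choices

* All likelihood work is in the log domain; posteriors and scaled
  likelihoods are normalized by log-sum-exp and checked to sum to 1 within
  $10^{-9}$ in tests.
* Zero emission probabilities (only possible at $\varepsilon = 0$) are
  floored at $e^{-10^{12}}$ inside matrix products so that zero counts
  contribute exactly zero, then restored to $-\infty$.
* Every stochastic routine takes an explicit seed; the preset derives all
  sub-seeds from one integer. Identical seeds give identical output,
  different seeds different streams.
* Degenerate inputs are typed results, not numbers: monomorphic loci give
  HWE $p = 1$ and excluded $\theta$; an all-missing individual is excluded
  from assignment rates but reported; an empty margin makes the chi-square
  test an error rather than NaN.
* The test suite and the acceptance script run reduced problem sizes (a
  0.25-scale baseline of 786 individuals, assessments of 30--100
  replicates, shortened MCMC of 500--1000 burn-in / 1000--2000 kept sweeps)
  chosen as the smallest sizes at which the assessed quantities are stable
  to well within their asserted tolerances; the full-scale defaults remain
  the documented study conditions.

# Known limitations

* The allele-balance rule is a proxy for expert visual review; unusual
  but genuine loci (e.g. strong reference bias) can be flagged.
* The duplicate filter is $O(n^2)$ in baseline size; at tens of thousands
  of individuals a hashing prefilter would be needed.
* `rank_sum_test` reports the test the published comparison names
  ("paired Mann--Whitney" is contradictory terminology; both modes are
  available, unpaired rank-sum being the default because pooled
  replicate-by-unit errors are not naturally paired).
* Published $\chi^2$ statistics cannot be reproduced exactly from rounded
  percentages, so the package's comparisons are validated against closed
  forms, not against printed test statistics.
* Reporting-unit probability sums member-population scaled likelihoods;
  the alternative (unit of the top population) can differ for borderline
  individuals and is not currently exposed.
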