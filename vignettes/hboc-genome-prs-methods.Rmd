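---
title: "Methods: polygenic risk scoring, cohort statistics and coverage QC for HBOC genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic risk scoring, cohort statistics and coverage QC for HBOC genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prspipe)
```

`prspipe` implements the analysis layer of a genome-first hereditary breast
and ovarian cancer (HBOC) diagnostic workflow: polygenic risk scoring from
VCF genotypes with control-cohort calibration, the cohort-level statistics a
lab reports alongside, and per-gene sequencing-gap quality control. This
vignette is the package's account of the underlying methods: the models and
their assumptions, the tunable parameters and their defaults, the numerical
conventions, and what the synthetic validation does and does not establish.

## Score models and harmonization

A score model is an ordered set of variants (chromosome, 1-based position,
effect allele, other allele, per-allele weight β, optional effect-allele
frequency f and rsID), read from a tab-separated PGS-Catalog-style scoring
file whose `#key=value` header carries the genome build. Position-based
matching requires GRCh38; files on other builds are rejected with a pointer
to pre-lifting, because coordinate liftover is deliberately out of scope —
rsID matching in `overlap_models()` is the cross-build fallback.

Matching a model variant against a decomposed biallelic VCF record yields
one of seven statuses. The effect allele can align with ALT (`exact`,
identity dosage transform) or REF (`swap`, d → 2−d), possibly after
reverse-complementing both alleles (`flip`, `flip_swap`) when the scoring
file was written against the opposite strand. Two safeguards depart from
naive string matching:

* **Palindromic variants** (A/T, C/G) cannot be resolved by alleles alone.
  They are resolved by frequency concordance: when |f − 0.5| > 0.08 and an
  observed ALT frequency is available, the orientation whose expected ALT
  frequency lies closer to the observed one wins; otherwise the variant is
  `ambiguous` and treated as missing. The 0.08 dead zone is the conventional
  safeguard width in PRS harmonization: inside it the two orientations are
  statistically indistinguishable at cohort scale.
* **Indels** are matched by exact allele-string equality only; a strand flip
  of an indel is not a well-defined operation.

When several decomposed records sit at one position, the best status wins
(`exact` before `swap` before `flip` before `flip_swap`); symbolic ALT
alleles (`<DEL>`, …) are skipped, and half-calls or `./.` genotypes count as
missing. Phase is ignored.

## Raw scores, calibration and percentiles

The raw score is S_i = Σ_j β_j d_ij. Missing dosages follow one of three
policies: `impute_af` (default) substitutes the Hardy–Weinberg expectation
2f_j, keeping scores comparable across samples with different callable sets
— the tolerant behaviour a diagnostic lab needs when a handful of model
variants is not callable on its platform; `omit` drops the term; `fail`
refuses. The summation is accumulated variant-by-variant in model order in
plain double precision, so results are bit-reproducible and independent of
the BLAS (a vendor `gemm` may reorder the sum).

Calibration standardizes raw scores against a control cohort:
z = (S − μ_c)/σ_c with the sample standard deviation (n−1 denominator, the
convention for cohort references). Percentiles are empirical midranks
against the control distribution, (#below + ½·#equal)/n_c, rather than the
normal-theory Φ(z): the reference cohort is an in-house sample, and the
empirical rank makes the "top decile" band exactly self-consistent — when
controls are banded against themselves, 10% of them land in it, which the
tests assert. A `method = "normal"` flag provides Φ(z) for users who prefer
the parametric reading. The top band defaults to the 90th percentile. The
CanRisk export writes the `##PRS=alpha=…,zscore=…` header line with fixed
4-decimal formatting; alpha is a property of the published score and is
never computed from data here.

## Cohort statistics

`two_sample_compare()` applies a Shapiro–Wilk gate per group at α = 0.05; if
both groups look Gaussian a Welch t-test is used, otherwise a Mann–Whitney U
test. The gate sees at most 5000 quantile-spaced values per group (the test
statistic degenerates for huge n); the subsample is deterministic so the
gate never consumes randomness. The rank branch uses midranks, the
tie-corrected variance, a normal approximation without continuity
correction, and reports the rank effect size r = |Z|/√N next to Cohen's D
(pooled SD, sign = first argument minus second). When both groups are
internally constant yet different, Cohen's D is undefined and reported as
NA while the rank test still applies; fully constant input is an error.

**Accuracy of the normal approximation.** Against complete permutation
enumeration over all tie-free instances with n₁+n₂ ≤ 10, the worst-case
absolute deviation of the approximate two-sided p is 0.188 (at n₁ = n₂ = 3,
near the centre of the U distribution); the tests therefore use 0.19 as the
documented tolerance at those sizes. The deviation shrinks rapidly with n
and is negligible at cohort scale, which is where the rank branch is
actually used.

The diagnostic-yield test compares the observed number of patients with a
pathogenic finding against per-patient prior probabilities (e.g. from a
family-history risk model). The default `poisson_binomial` mode respects
prior heterogeneity: mean Σp_i, variance Σp_i(1−p_i), z and two-sided normal
p, plus the exact tail by dynamic-programming convolution of the
Poisson-binomial mass (up to n = 10,000; the tail is taken in the direction
of the observed deviation). The cruder `binomial_mean` mode collapses the
priors to their mean; both are reported side by side by `run_stats()`, since
either reading of "a binomial approach" is defensible. The two modes give
identical z when all priors are equal.

Finding rates count *patients* (once each, however many qualifying variants
they carry) with at least one likely pathogenic / pathogenic variant in a
panel gene, over the screened patient list rather than the variant table —
so a patient with no variants still counts in the denominator. Gene panels
ship as editable text fixtures (the 13 HBOC core genes; an actionable-gene
list).

## Coverage QC

Depth tracks are bedGraph-style 0-based half-open intervals; overlapping
intervals are an error, never silently merged. Gene targets come from a BED
file whose name column is the gene symbol; a gene is the union of its
intervals (overlaps merged before counting), and target bases not covered by
any depth interval count at depth 0. The conventions partition cleanly:

* gap: depth **< 20** reads (strict);
* reviewable: **15 ≤ depth < 20** — gaps that can still be closed by visual
  inspection of the alignment;
* fail: depth **< 15** — would trigger re-sequencing;
* threshold coverage: depth **≥ t** (inclusive), default t = 30.

So `gap_fraction(t) + coverage_at(t) = 1` per gene exactly, band counts sum
to the target size, and splitting a target region and recombining the base
counts is lossless — all asserted as invariants. The gene verdict is `pass`
with no gap bases, `reviewable` when every gap base is in the reviewable
band, `fail` otherwise.

`compare_gap_cohorts()` compares per-sample gap fractions per gene between
two platform cohorts with the gated two-sample test and reports cohort means
as percentages (a `pooled` flag switches to pooled-base fractions; which of
the two a published table means is often ambiguous, so both are available).
Genes with no variation anywhere (e.g. zero gaps in both cohorts) are
reported as `degenerate` with p = 1 rather than erroring, since "no
difference" is the correct reading there.

## The synthetic study generator

The generator produces every input the pipeline consumes, deterministically
from (config, seed) — repeated runs are byte-identical, and no function
draws randomness without an explicit seed.

Genotypes are Hardy–Weinberg, g_ij ~ Binomial(2, f_j), in linkage
equilibrium — the scoring engine is LD-agnostic, so simulating LD would add
nothing testable. Disease follows a liability-threshold model: with the
standardized PRS P_i, liability L_i = √h²·P_i + √(1−h²)·e_i and an
individual is a case iff L_i > Φ⁻¹(1−K). Controls are sampled from the
non-cases (not from the population), mirroring a cancer-free control
cohort; this two-sided truncation gives the closed-form expected
case-minus-control mean of the standardized PRS

√h² · φ(t) · (1/K + 1/(1−K)),  t = Φ⁻¹(1−K),

implemented as `closed_form_shift()` and cross-checked against numeric
integration. The acceptance tests run the complete pipeline (simulated VCF →
dosage extraction → raw scores → control calibration → comparison) for
(h², K) ∈ {(0.05, 0.1), (0.1, 0.1), (0.2, 0.05)} at 2000+2000 samples and
require agreement within 3 Monte-Carlo standard errors. Note the calibrated
z-difference is the standardized shift divided by the control-cohort SD of
the standardized PRS, which truncation leaves marginally below 1; at the h²
values used the resulting bias (< 0.02) is well inside the Monte-Carlo band.

Defaults emulate the study conditions the pipeline is built for, chosen once
and not revisited: a 306-variant score; 661 cases vs 1000 controls;
prevalence K = 0.12 (the background breast-cancer prevalence); h² = 0.05,
placing the case/control separation at Cohen's D ≈ 0.4 (the 0.3–0.5 band
typical for current breast-cancer PRSs); per-patient priors Beta-distributed
with mean 0.13 and concentration 30, with carrier status drawn
Bernoulli(prior) so the yield test holds under its own null by construction;
secondary findings planted in actionable genes at 3% of cases. Depth tracks
are negative-binomial per base with mean 41.2x and size 200: that yields
P(depth < 20) ≈ 0.03% (comfortably below the 0.5% total gap budget of a
production genome) and P(depth ≥ 30) ≈ 95.8%. The overdispersed negative
binomial, rather than Poisson, makes sub-threshold excursions occur at
realistic rates at a 41x mean. Planted gap intervals overwrite the simulated
depth (and the remaining bases of that gene are kept clear of the gap band),
so ground-truth gap fractions are exact, and the coverage arm can be tested
for exact recovery rather than approximate agreement.

**What the simulation does not emulate** — and hence what passing tests do
not show about real data: linkage disequilibrium and imputation artefacts,
ancestry stratification (real PRS transferability depends on it), genotyping
and variant-calling error, platform-specific gap locations (real gaps
cluster in GC-rich exons; simulated ones are planted or uniform), and the
correlation structure of family-history-derived priors. The tests establish
the *computational* correctness of scoring, calibration, statistics and gap
accounting, not the clinical validity of any particular score.

## Numerical and design choices

* Score summation in fixed model order, plain double accumulation
  (BLAS-independent bit reproducibility).
* Best-status tie-break for multiple records at one position; a palindromic
  variant resolved by frequency is reported in the orientation implied
  (`exact`/`swap`), never as a strand flip, since the true strand is
  unknowable.
* Duplicate positions with distinct allele pairs are legal in a model; the
  full (chrom, pos, effect, other) 4-tuple is the key.
* `overlap_models()` matches by rsID first, then by position with
  reconcilable alleles, each variant at most once; palindromic same-allele
  pairs count as shared loci (they are the same variant even when the
  scoring orientation is ambiguous).
* Empty dosage sets under `omit` score 0 with a warning (empty-sum
  convention); under `impute_af` a variant without a frequency is an error
  naming the variant.
* Yield-test exact tail: P(X ≥ O) above the mean, P(X ≤ O) below, matching
  the direction of the z statistic.
* Exit codes of the CLI wrapper: 0 success, 2 validation error, 3
  data-consistency error; reports go to files, logs to standard error.

## Problem sizes

The test suite validates at sizes chosen to keep the full run under a
minute of statistics per property: 100 random 50-variant × 20-sample
scoring instances against the naive-loop oracle; 2000+2000-sample liability
recovery at three (h², K) settings; complete 2^n enumeration of the
Poisson-binomial up to n = 15; complete permutation enumeration of the rank
test up to n₁+n₂ = 10; 1000 seeded replicates of the yield test under its
null. `scripts/acceptance.R` runs the full pipeline at the study-shaped
default (306 variants, 661+1000 samples, 13-gene coverage panel) in well
under a minute.

## Known limitations

Liftover is out of scope (GRCh38 in, or rsID matching); the score
correlation parameter alpha for CanRisk export is user-supplied, never
estimated; genotype imputation from reference panels is not attempted —
missing model variants are frequency-imputed or dropped; the comparison of
two published score files requires the user to supply those files, which are
not redistributed with the package.
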