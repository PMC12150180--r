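# prspipe

Clinical genome sequencing is replacing exome and panel sequencing in
hereditary breast and ovarian cancer (HBOC) diagnostics. Beyond detecting
pathogenic variants in the core genes, a genome delivers the genome-wide SNPs
needed for a polygenic risk score (PRS), and its uniform coverage changes the
per-gene sequencing-gap profile that diagnostic labs must monitor. `prspipe`
implements that analysis layer, end to end, for R users in diagnostic and
research labs:

* **Score-model handling** — read/write PGS-Catalog-style scoring files,
  validate them, harmonize model variants against VCF records (REF/ALT
  orientation, strand flips, palindromic A/T and C/G variants resolved by
  frequency concordance), and count variants shared between two score models.
* **PRS computation** — per-sample effect-allele dosages from multi-sample
  VCFs, raw scores, control-cohort z-score calibration, empirical percentile
  banding, and CanRisk-compatible PRS export.
* **Cohort statistics** — normality-gated two-sample tests (Welch t /
  Mann–Whitney U), Cohen's D, rank effect size r, an expected-vs-observed
  diagnostic-yield test built on the exact Poisson-binomial distribution, and
  panel finding-rate summaries.
* **Coverage QC** — per-gene sequencing-gap fractions, pass / reviewable /
  fail depth bands and threshold coverage from bedGraph depth tracks over
  exon targets, with a per-gene two-cohort comparison table.
* **A synthetic study generator** — deterministic case/control cohorts under
  a liability-threshold disease model with known ground truth, used to
  validate every stage.

## The model

The raw score of sample *i* is the weighted effect-allele dosage sum over the
*m* variants of the score model,

S_i = Σ_j β_j · d_ij ,  d_ij ∈ [0, 2],

where missing dosages are imputed by their Hardy–Weinberg expectation
2·f_j (default), dropped, or refused. Scores are standardized against a
control cohort, z_i = (S_i − μ_c)/σ_c, with empirical midrank percentiles
against the control distribution and a top-decile flag at the 90th
percentile. The simulator draws genotypes g_ij ~ Binomial(2, f_j) and forms a
latent liability L_i = √h² · P_i + √(1−h²) · e_i from the standardized PRS
P_i; individuals with L_i above the threshold Φ⁻¹(1−K) are cases, controls
are sampled from the non-cases. The expected case-minus-control mean of the
standardized PRS is then √h² · φ(t) · (1/K + 1/(1−K)) — the closed form the
pipeline is validated against. The yield test compares the observed number
of pathogenic findings with per-patient prior probabilities p_i via
z = (O − Σp_i)/√(Σ p_i(1−p_i)) and the exact Poisson-binomial tail.

## Worked example

Generate a miniature synthetic study and run all three pipeline arms:

```r
library(prspipe)
dir <- file.path(tempdir(), "demo")
fx  <- make_fixture_study(dir, seed = 42, m_variants = 50,
                          n_cases = 120, n_controls = 150,
                          n_depth_samples = 4)
cfg <- run_config(score_model = fx$score_model, vcf = fx$vcf,
                  sample_sheet = fx$sample_sheet, variants = fx$variants,
                  targets = fx$targets, depth_manifest = fx$depth_manifest,
                  out_dir = file.path(dir, "out"))
sc <- run_score(cfg)
print(sc$dosages)
#> <dosage_matrix> 270 sample(s) x 50 model variant(s)
#>     exact      swap      flip flip_swap ambiguous  mismatch   missing
#>        25        25         0         0         0         0         0
head(sc$records, 3)
#>      sample        raw n_used n_imputed         z percentile top_decile
#> 1 case_0001 -0.4993161     50         0 1.0623164  0.8466667      FALSE
#> 2 case_0002 -0.6170315     50         0 0.7982108  0.8000000      FALSE
#> 3 case_0003 -0.3388716     50         0 1.4222890  0.9266667       TRUE
```

Every model variant was matched (half of the simulated VCF records are
written REF/ALT-swapped on purpose, and the harmonizer undoes that), and each
sample gets a calibrated z-score and control-cohort percentile. The cohort
statistics and the coverage comparison:

```r
st <- run_stats(cfg)
#> case vs control:
#> <two_sample_result> t test: statistic=4.485, p=1.101e-05
#>   Cohen's D=0.5477  (n1=120, n2=150)
#> yield:
#> <yield_test> (poisson_binomial) expected 15.23 +/- 3.57, observed 14
#>   z=-0.3433, two-sided p=0.7314, exact tail p=0.4317
#> core detection rate: 11.7% (14/120)

cv <- run_coverage(cfg)
head(cv$comparison[, 1:5], 4)
#>     gene gap_pct_srGS gap_pct_ES    p_value    test_used
#> 1  BRCA1   1.09375000   11.75347 0.02092134 mann_whitney
#> 2  BRCA2   0.01736111   12.17014 0.01796048 mann_whitney
#> 3  PALB2   0.01736111   11.11111 0.01796048 mann_whitney
#> 4 RAD51C   0.01736111   11.92708 0.01796048 mann_whitney
```

The liability-selected cases score significantly higher than the controls
(Cohen's D ≈ 0.55 in this small run); the observed carrier count (14) sits
well inside the Poisson-binomial expectation from the per-patient priors
(15.2 ± 3.6); and the genome-like depth cohort shows far smaller per-gene
gap percentages than the noisy exome-like cohort. The same functions run
from the shell via `inst/cli/prspipe.R` (subcommands `simulate`, `score`,
`stats`, `coverage`, `make-fixtures`).

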