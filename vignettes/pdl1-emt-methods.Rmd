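---
title: "Methods: PD-L1/EMT association analysis and the compound covariate classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PD-L1/EMT association analysis and the compound covariate classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PDL1EMT)
```

## The scientific question

Tumor PD-L1 expression marks candidates for immune-checkpoint blockade,
but its upstream drivers are heterogeneous. In head and neck squamous cell
carcinoma (HNSCC) two candidate drivers coexist: HPV infection (read out
by p16 immunohistochemistry) and the epithelial–mesenchymal transition
(EMT, read out by E-cadherin loss and vimentin gain). This package
implements the complete analysis chain for testing whether PD-L1
positivity associates with EMT independently of p16, and whether
PD-L1⁺/EMT⁺ disease has worse survival: deterministic IHC call rules,
contingency statistics, a probabilistic EMT signature classifier for
expression cohorts, and standard survival analysis.

## IHC scoring rules

A staining profile records the percentage of tumor cells at intensity
0/1+/2+/3+ (summing to 100). The H-score is the intensity-weighted sum
`1·p1 + 2·p2 + 3·p3`, ranging 0–300; it is linear in profile mixtures,
which the tests exploit as an invariant.

The binary calls, with their defaults:

| Call | Rule | Default |
|---|---|---|
| PD-L1⁺ | membranous staining in ≥ x% of cells | x = 5 |
| PD-L1 score | highest intensity category individually ≥ x% | 0–3 |
| EMT⁺ | E-cadherin H **<** a and vimentin H **>** b | a = 200, b = 30 |
| p16⁺ | diffuse strong staining in ≥ y% of cells | y = 70 |

Design notes. The PD-L1 rubric is phrased per intensity category; when
several categories each reach 5% we score the highest such category, and
when only the *combined* stained fraction reaches 5% we score 1 — this
keeps the score consistent with the positivity rule (positive ⇔ score
≥ 1), which is enforced as a property test. The EMT inequalities are
strict and the p16 threshold inclusive, exactly as the cutoffs are
defined. Profiles that do not sum to 100 (tolerance 1e-6) are rejected
with the offending row named, never renormalised: a bad scoring sheet
should fail loudly. A missing p16 fraction yields `NA`, never a silent
negative. How "diffuse" staining is operationalized beyond the ≥ 70%
fraction is not specified by the rule; the schema carries a single
fraction and leaves finer pathology distinctions out of scope.

## The Bayesian compound covariate predictor

Given a signature of *G* genes (nominally 75) and a labeled training
cohort, each gene receives the pooled-variance two-sample t-statistic
*t<sub>g</sub>* (mesenchymal − epithelial) as its weight; the classical
compound covariate formulation. A Welch variant is available behind a
flag for unequal-variance sensitivity analysis. The compound covariate of
sample *j* is *c<sub>j</sub>* = Σ<sub>g</sub>
*t<sub>g</sub>x<sub>gj</sub>*. Within each class *c* is modelled as
Gaussian with class mean *m<sub>E</sub>* or *m<sub>M</sub>* and a single
pooled SD *s* (equal-variance model; a class-specific-SD option exists but
the shared-SD model is the default and the one the tests characterise).
Bayes' rule with priors π (default 0.5/0.5, configurable) gives the
posterior mesenchymal probability; the binary call uses posterior > τ.

Numerical choices:

* posteriors are computed in log-density space, so far-separated samples
  saturate at exactly 0/1 instead of producing 0/0;
* genes with pooled SD below 1e-8 are dropped with a warning (their
  t-statistic is unbounded); if all genes are degenerate, fitting errors;
* genes with > 20% missing values are dropped, remaining missing values
  are mean-imputed with a message;
* each class must have ≥ 2 samples, otherwise fitting errors.

**LOOCV.** The robustness measure is the leave-one-out misclassification
rate in the training set: every fold refits the *entire* model — weights,
class means, pooled SD — on the remaining samples and classifies the
held-out sample at τ = 0.5. The signature gene list itself is treated as
given and is not reselected per fold. Folds that would leave a class with
fewer than two samples are skipped with a warning and counted.

**Threshold calibration.** τ = 0.5 is the default. `calibrateThreshold()`
keeps 0.5 whenever the resulting mesenchymal fraction lies in a reference
range — the literature range for the inflamed/mesenchymal fraction of
HNSCC, 19.2–37.4%, is the default — and otherwise picks the τ among the
observed posteriors whose called fraction comes closest to the nearest
bound, breaking ties toward the larger (more conservative) τ. This is one
defensible reading of "a cut-off of 0.5, optimized against a previously
reported proportion"; the exact original optimization was never specified,
so the package makes the rule explicit and deterministic.

**Cross-cohort application.** `harmonizeGenes()` restricts the model and
a target matrix to their shared genes and refuses to proceed below 80%
coverage of the model's genes (configurable). The compound-covariate
summaries (*m<sub>E</sub>*, *m<sub>M</sub>*, *s*) are kept from training,
so partial coverage makes posteriors approximate — the coverage floor
bounds that approximation. `standardizeMatrix()` (per-gene center/scale,
idempotent; constant genes zeroed with a warning) is provided for
cross-platform scale mismatches; the package deliberately does not guess
a cross-platform normalization beyond that.

## Association and survival statistics

Contingency analyses use the standard two-sided Fisher exact test
(probability-mass criterion), cross-product odds ratios with Wald 95%
intervals (Haldane–Anscombe 0.5 correction on zero cells, flagged;
undefined when a diagonal is entirely zero), and maximum-likelihood
logistic regression, whose single-binary-predictor odds ratio equals the
table cross-product — an identity the acceptance suite checks to 1e-6 on
1,000 random tables. Wald rather than profile-likelihood intervals are
used, matching intervals that are symmetric on the log scale. The
Wilcoxon rank-sum test enumerates exactly for combined n ≤ 20 without
ties and otherwise uses the tie- and continuity-corrected normal
approximation. Benjamini–Hochberg adjustment is available but off by
default: individually printed per-test p-values are unadjusted, and the
adjustment is meant for families of tests run in one pipeline pass.

Survival analysis is built on the survival package: Kaplan–Meier
curves (Greenwood variance, log-log intervals), landmark rates (returning
`NA` rather than extrapolating beyond follow-up), medians with
Brookmeyer–Crowley intervals, k-group log-rank tests, and Cox
proportional-hazards models with Efron tie handling by default (Breslow
behind a flag; printed hazard ratios from the original cohorts are not
reproducible anyway because individual-level times were never published,
so the tie method is documented rather than fitted). One deliberate
deviation from the survfit default: when the curve sits exactly at 0.5,
the median is reported as the *first* time reaching 0.5 rather than the
midpoint of the flat segment, matching the step-function definition
"smallest t with S(t) ≤ 0.5". Times are months throughout; unreached
medians serialize as the literal string `NR`.

The PD-L1 expression dichotomization for survival groups uses the median
log2 RPKM among mesenchymal-signature samples as the cutoff, midpoint
convention for even counts, boundary values classed high.

## Synthetic data: what it emulates, what it does not

`generateCohort()` draws the clinicopathologic covariates independently
at their marginal prevalences and assigns PD-L1 positivity from a
logistic model whose per-covariate log-odds ratios match the spec; the
intercept is solved numerically so the realized PD-L1 margin matches its
target in expectation. Default prevalences and odds ratios reproduce the
structure of a 50-patient training cohort (PD-L1⁺ 0.64, EMT 0.34, p16
0.30, oropharynx 0.32; odds ratios on PD-L1 of 7.06, 3.0 and 6.22 for
EMT, p16 and oropharyngeal site). Staining profiles are then synthesised
*consistently with the assigned calls*: H-scores are drawn uniformly
within the region implied by the call (e.g. EMT⁺ patients get E-cadherin
H < 200 and vimentin H > 30) and decomposed uniformly into a valid
p0..p3 profile, so `scoreIHC()` round-trips the intended calls exactly —
an invariant under test. Survival times are exponential with group
hazard ratios over the PD-L1/EMT composite groups (baseline median 50
months, hazard ratios 1 / 0.4 / 2.5, 40% censoring by an independent
exponential censoring process).

`generateExpression()` draws signature genes shifted by δ within-class
SDs between classes (default δ = 1.5, 75 genes, 30 per class, 40% of
signature genes shifted in the epithelial-high direction as real EMT
signatures mix both), background genes with no shift, and a PD-L1 gene
(`CD274`) up-shifted in the mesenchymal class. Per-gene baseline
abundance is a fixed spread around 8 log2 units that depends only on the
gene, not on the cohort draw, so independently seeded cohorts share a
"platform" and a model trained on one transfers to another — emulating
same-platform cross-cohort application. What the generator does *not*
emulate: read-count noise models and RPKM normalization from raw reads,
probe-to-gene mapping artifacts, batch effects, or correlated gene-gene
structure beyond the class shift. Passing tests on this generator
therefore demonstrate correctness of the estimators and calibration under
the stated model, not robustness to real cross-platform artifacts.

`fixtureFromCounts()` expands a published count table into one row per
patient, making `crossTab()` its exact inverse; `hnsccCountTables()`
carries the 2×2 cross-tabulations of the two HNSCC cohorts (n = 50 and
n = 91) reconstructed from printed group sizes, which is what desk-scale
reproduction of the printed Fisher tests and odds ratios runs on.

## Problem sizes and calibration checks

The test suite's simulation sizes were chosen once, as the smallest sizes
at which each check is statistically meaningful: classifier recovery at
75 genes and 30 samples/class (hold-out accuracy ≥ 0.95 at δ = 1.5 SD);
chance-level LOOCV under a null shift at n = 40 (rate within binomial
error of 0.5); prevalence calibration on a 564-sample mixture with true
mesenchymal prevalence 21.1%, predicted fraction within ±5 percentage
points at τ = 0.5; Cox recovery of a true hazard ratio of 3 at n = 400
with ~20% censoring; 3-group log-rank power over 200 replicates at
n = 100/group under hazard ratios (1, 1, 3); and null calibration of the
cohort generator over 200 replicates of n = 1000 — the size matters here
because Fisher exact p-values are discrete and conservative in small
samples, and only near the asymptotic regime is their null distribution
close enough to uniform for a Kolmogorov–Smirnov check to be a fair test
of the generator rather than of Fisher's discreteness.

## Known limitations

* The association between the printed two-sided convention and every
  printed p-value cannot be verified without the raw data; the package
  always computes the standard two-sided tests.
* Multivariate logistic/Cox results from the original cohorts are
  implemented as generic fits but cannot be checked against printed
  values, because the joint covariate cross-classifications were never
  published.
* `harmonizeGenes()` keeps training-time compound-covariate summaries;
  below full gene coverage the posterior is approximate (bounded by the
  coverage floor), and users crossing platforms should standardize first.
* The threshold calibration rule is a deterministic reconstruction of a
  procedure whose original details were unspecified.
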