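# PDL1EMT

Tools for asking a clinical-pathology question in head and neck squamous
cell carcinoma (HNSCC): is tumor PD-L1 expression driven by the
epithelial–mesenchymal transition (EMT), independently of HPV/p16 status,
and does PD-L1⁺/EMT⁺ disease carry a worse prognosis? The package is aimed
at translational researchers who have immunohistochemistry (IHC) scoring
sheets and/or bulk expression matrices and want the full analysis chain —
marker calling, association statistics, signature classification and
survival analysis — as tested, scriptable functions.

## What it implements

**IHC scoring.** Staining-intensity profiles (percent of tumor cells at
intensities 0/1+/2+/3+) are summarised as the H-score

    H = 1·(% weak) + 2·(% moderate) + 3·(% strong),  H ∈ [0, 300]

with the binary calls: PD-L1⁺ when ≥ 5% of tumor cells show membranous
staining (scored 0–3 by the highest intensity category reaching 5%);
EMT⁺ when E-cadherin H < 200 **and** vimentin H > 30 (strict
inequalities); p16⁺ when ≥ 70% of cells show diffuse strong staining.

**Bayesian compound covariate predictor (BCCP).** A two-class expression
classifier over a 75-gene EMT signature. Gene *g* gets weight
*t<sub>g</sub>*, its pooled-variance two-sample t-statistic (mesenchymal −
epithelial); sample *j* gets the compound covariate
*c<sub>j</sub>* = Σ<sub>g</sub> *t<sub>g</sub>x<sub>gj</sub>*; with
within-class Gaussian model *c* ~ N(*m<sub>k</sub>*, *s*²) and priors
π<sub>k</sub>, the posterior probability of a mesenchymal signature is

    P(M | c) = π_M φ(c; m_M, s) / [π_E φ(c; m_E, s) + π_M φ(c; m_M, s)]

Samples are called mesenchymal at posterior > τ (default 0.5, optionally
calibrated against the literature prevalence range 19.2–37.4% of HNSCC).
Leave-one-out cross-validation refits the whole model per fold.

**Association and survival statistics.** Two-sided Fisher exact tests,
cross-product odds ratios with Wald intervals, logistic regression,
Wilcoxon rank-sum, Benjamini–Hochberg adjustment; Kaplan–Meier curves,
landmark rates and medians (with the "NR" not-reached convention),
log-rank tests, Cox proportional-hazards models (Efron ties), and the
rule dichotomizing PD-L1 log2 RPKM at the median of the mesenchymal
samples.

**Synthetic data.** Generators for IHC cohorts with controllable
covariate→PD-L1 odds ratios and proportional-hazards survival, two-class
expression matrices with a tunable signature shift, and exact patient
tables expanded from published count tables
(`hnsccCountTables()` / `fixtureFromCounts()`).

## Worked example

```r
library(PDL1EMT)

# the published training-cohort EMT x PD-L1 cross-tabulation
tab <- hnsccCountTables("training")$emt
tab
#>           pdl1
#> emt        positive negative
#>   positive       15        2
#>   negative       17       16

fisherExact2x2(tab)
#> [1] 0.01328693
oddsRatio(tab)$or
#> [1] 7.058824

# the same association through logistic regression on the expanded table
d <- fixtureFromCounts(tab)
logisticFit(d$pdl1 == "positive", data.frame(emt = d$emt == "positive"))
#>      term     coef        se       or    ci_lo    ci_hi          p separated converged
#> 1 emtTRUE 1.954278 0.8294444 7.058824 1.389018 35.87209 0.01846648     FALSE      TRUE

# classifier on synthetic two-class expression (75 signature genes)
tr  <- generateExpression(expressionSpec(), seed = 1)
fit <- fitBCCP(tr$matrix[tr$signature, ], tr$labels)
fit
#> BCCPModel with 75 signature genes
#>   compound covariate: m_E = 550.5, m_M = 1225, pooled SD = 51.92
#>   priors: epithelial 0.5 / mesenchymal 0.5
loocvMisclassification(tr$matrix[tr$signature, ], tr$labels)
#> [1] 0
#> attr(,"skipped")
#> [1] 0
```

So EMT⁺ tumors have 7.1-fold higher odds of PD-L1 positivity
(p = 0.013 by Fisher's exact test, p = 0.018 by logistic Wald test), and
on clearly separated synthetic data the compound covariate classifier
cross-validates with zero misclassification.

The full pipeline (`runAll(pipelineConfig(...))`) chains IHC scoring →
crosstabs/Fisher/logistic → optional classifier → Kaplan–Meier/log-rank/
Cox, writing results CSVs and a run log with every threshold used.

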