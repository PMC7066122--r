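---
title: "Distributed training of radiomics models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed training of radiomics models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fedradiomics)
```

## The problem

Radiomic feature tables — hundreds of shape, intensity, texture and
wavelet descriptors per tumour — are strongly redundant, unevenly
distributed, and scattered across hospitals that cannot share patient-level
rows. This package trains and validates multivariate logistic models for a
binary clinical endpoint (e.g. tumour HPV status, or death within two
years) on such *horizontally partitioned* data: every site holds the same
feature columns for its own patients. The entire pipeline — quality
control, normalization, feature clustering, representative selection and
model fitting — is expressed through site-to-coordinator messages whose
dimensions depend only on the number of features, so no payload can be
linked back to an individual patient. A centralized implementation of every
stage is included as the reference against which the federated results are
compared.

## The federated pipeline, stage by stage

### Quality control

Each site summarizes every feature by its missing fraction and sample
skewness `g1 = m3 / m2^{3/2}` (central moments with denominator n, the
common default in scientific computing ecosystems). A feature is excluded
when its missing fraction strictly exceeds `missing_max = 0.20` or
|g1| strictly exceeds `skew_max = 5` — boundary values are retained. In
the federated mode both rules are applied *per site* and the union of the
per-site exclusions is removed everywhere; the union rule is deliberately
conservative (adding a site can only grow the excluded set) and protects
against selecting features that are broken at a single scanner. We compare
|g1| rather than signed g1, because extreme outliers can pull skewness in
either direction; a signed mode is available (`signed_skew = TRUE`).

### Normalization

Global per-feature statistics are assembled exactly from site-local
moments: with site means `μ_k`, sums of squared deviations `SS_k` and
counts `n_k`,

    μ = Σ n_k μ_k / N,   SS = Σ_k [ SS_k + n_k (μ_k − μ)² ],
    sd = sqrt(SS / (N − 1)).

This reproduces the concatenated-data mean and standard deviation to
floating-point accuracy (the test suite asserts 1e-12 relative agreement
against a concatenated oracle), so distributed z-scoring is not an
approximation.

### Correlation pooling and clustering

Site correlation matrices are pooled on the Fisher z-scale:
`r = tanh( Σ w_k atanh(r_k) / Σ w_k )` with `w_k = n_k − 3`, the inverse
variance of the z-transform (plain `n_k` weights are available). Site
coefficients are clipped to ±(1 − 1e-7) before `atanh` so degenerate
features cannot produce infinities, and sites with `n ≤ 3` are excluded
because their z-variance is undefined. Unlike moment pooling this *is* an
approximation — the tanh of an average is not the average correlation — but
on homogeneous cohorts the elementwise error stays well below 0.05
(property-tested on 4 × 200-patient federations).

Features are clustered by average-linkage agglomeration on the distance
`d = 1 − |r|`, cutting the dendrogram at height `1 − cutoff` with
`cutoff = 0.6`: features stay merged while their average absolute
correlation is at least 0.6. We cluster on |r| because strongly
anti-correlated features are just as redundant as correlated ones; a
signed-distance mode (`1 − r`) is available. Within-site correlations use
pairwise-complete observations, which maximizes data use under the MCAR
missingness the generator produces; a complete-case mode exists for
sensitivity checks.

### Representative selection

Centralized reference: univariate logistic regressions of the outcome on
every retained feature are fitted on the pooled rows;
Benjamini–Hochberg adjustment is applied across *all* retained features
(not only cluster winners — the univariate screen is a single family of
hypotheses); each cluster's max-AUC feature is selected iff its adjusted
p-value is below 0.05. Because the logistic link is monotone, the
univariate model's AUC equals the rank-statistic AUC of the raw feature
folded above one half, `max(a, 1 − a)`, which is how it is computed.

Federated: each site nominates its best feature per cluster by local AUC,
and a feature is selected when the cohorts nominating it carry at least 80%
(non-strict) of the total patients. There is deliberately no FDR gate on
this path — the weighted vote is its only filter — so with a single site
the federated selection reduces to per-cluster max AUC with weight 1. AUC
ties break to the lexicographically smallest feature identifier, making
selection deterministic across platforms.

### Model fitting (GLORE)

Both fitters run Newton–Raphson from `β = 0` and stop when the L∞ norm of
the coefficient update falls below `1e-8`; with at most 25 iterations. Per
iteration each site contributes its gradient `X'(y − p)`, Hessian
`X' diag(p(1−p)) X` and log-likelihood on its complete cases; the
coordinator sums them and updates `β ← β + (Σ H_k)⁻¹ Σ g_k`. These sums
equal the pooled-data quantities *exactly*, so the federated iterates — and
the fitted model — coincide with the centralized fit up to floating-point
summation order; the test suite observes disagreement around 1e-13 or
lower, far below the 1e-7 level at which the two solutions are considered
identical. Shared safeguards: a rank-deficient Hessian aborts with the
collinear columns named; a coefficient exceeding 30 in absolute value on
z-scored inputs aborts with a separation diagnosis (on standardized
features, |β| = 30 corresponds to odds ratios beyond e³⁰ per SD — only
reachable when no finite MLE exists); a Newton step that would decrease the
log-likelihood is halved up to 10 times, which keeps the likelihood
monotone without changing the fixed point. The tolerance 1e-8 was chosen
one order stricter than the 1e-7 coefficient-agreement level so that
convergence noise cannot masquerade as disagreement. Model rows are
complete cases on the selected (z-scored) features; no imputation is
performed anywhere.

### Validation statistics

- **AUC and DeLong machinery.** AUC is the positive-negative pair
  probability with ties counted 1/2; variances and the paired test use the
  DeLong structural components (computed via the `pROC` package; the test
  suite cross-checks AUCs against brute-force pair enumeration and the
  variance against a bootstrap). Identical score vectors — or any pair with
  identical rankings, since the statistic is rank-based — give p = 1.
- **Calibration.** The validation outcomes are regressed on
  `logit(prediction)`; the Wald test of slope = 1 follows the standard
  calibration-slope convention. Regressing on the raw probability is
  available, but slope = 1 is only a meaningful null on the logit scale.
- **Classification discrepancy.** Each model classifies at its own
  training-cohort median prediction (ties classify as high-risk); the
  discrepancy is the fraction of validation subjects assigned differently.
- **Survival.** Kaplan–Meier curves per risk group with the
  Fleming–Harrington G-rho test (ρ = 0 by default, i.e. the log-rank test),
  and the odds ratio of the group × event-by-2-years table with a Woolf
  95% interval (Haldane–Anscombe 0.5 correction when a cell is empty).

### The leave-one-cohort-out workflow

`run_leave_one_cohort_out()` holds out each cohort in turn, runs both
training arms on the remainder, and validates on the held-out cohort. For
the 2-year survival endpoint the modelling label is *event before 2 years*;
patients censored before 2 years without an event have unknown status and
are excluded from modelling (they still contribute to the KM curves through
their censored follow-up). Cluster overlap between the arms — for each
centralized cluster, the size of its largest distributed subcluster, summed
and divided by the feature count — is computed on the intersection of the
two retained feature sets, since the two QC paths may exclude slightly
different features. Selected-feature overlap is reported as Jaccard plus
both containment fractions, as "overlap" between differently-sized sets is
otherwise ambiguous.

## The synthetic cohort generator

`generate_federation()` emulates the statistical structure the workflow
assumes, with every default chosen to resemble a plausible multi-centre
radiomics cohort:

- **Block-correlated features** from a factor model: feature j in cluster c
  is `sqrt(ρ_b)·g + sqrt(ρ_w − ρ_b)·u_c + sqrt(1 − ρ_w)·ε_j` with standard
  normal factors, giving expected within-cluster correlation `ρ_w` and
  between-cluster correlation `ρ_b` exactly (verified empirically at
  n = 5000 within 0.03).
- **Outcome** drawn from a logistic model on one designated feature per
  chosen cluster. The linear predictor uses the standard-scale feature
  values *before* site mean shifts are added, so site heterogeneity
  perturbs the measured features without changing the outcome model —
  heterogeneity acts as a measurement-level nuisance, which is the scanner
  effect the workflow worries about.
- **Survival** times exponential with rate
  `baseline_event_rate × exp(linear predictor)`, administratively censored
  at 2 years. Any monotone-hazard family would serve; the workflow only
  consumes the 2-year binary label plus (time, event) for KM display.
- **Missingness** is MCAR, exactly `round(fraction × n)` entries per
  feature. Real cohort missingness is plausibly informative, but no
  mechanism is characterized for radiomics QC failures, and the QC filter
  only consumes marginal missing fractions.
- **Skew injection** replaces a feature by `exp(severity × z)`. One caveat
  discovered while testing: the sample skewness statistic g1 is bounded by
  roughly √n, so at n = 100 a lognormal feature shows g1 > 5 only about
  60–75% of the time even for severity ≥ 2; near-certain exceedance needs
  n around 500. Tests that rely on the skew rule firing use cohorts of that
  size.
- **Site imbalance and shifts**: cohort sizes are free per site;
  heterogeneity is additive per-site, per-feature mean shifts (scanner
  effects on radiomic features are commonly reported as location shifts;
  scale effects are deliberately out of scope).

What passing tests on this generator do *not* show: robustness to
informative missingness, to site-specific feature *scales*, to non-logistic
outcome mechanisms, or to the 981-feature wavelet-heavy catalogues of real
radiomics software — the generator's feature count is set per test
(typically 8–40) to keep the suite fast.

## Problem sizes and numerical choices

The test and acceptance suites run on deliberately modest problems —
federations of 2–5 sites with 100–400 patients each and 4–20 features,
50 random partitions for the log-likelihood equality check, 200 replicates
for coefficient recovery, 2000 replicates for the DeLong type-I error —
sizes at which every asserted property is already sharply testable.
Convergence of the federated fitter is measured on 4-cohort, 1120-patient,
10-feature problems with moderate effect sizes (|β| ≤ 0.8, balanced
outcome), where it consistently converges in about 6 Newton iterations.

Tie-breaks are deterministic everywhere (smallest feature id for AUC ties,
positive class for threshold ties); all generator randomness flows from a
single integer seed, and the pipeline itself is deterministic given the
data, so reports are byte-identical across repeated runs.

## Known limitations

- Fisher pooling assumes roughly homogeneous correlation structure across
  sites; strongly heterogeneous sites bias the pooled matrix toward the
  larger cohorts, and no heterogeneity diagnostic (e.g. a Q statistic) is
  computed.
- The federated arm deliberately omits an FDR gate, so with weak signals
  it can select features a centralized analysis would reject; the
  vote threshold is the only guard.
- The privacy argument is structural (aggregate-only messages, audited by
  serialization tests), not cryptographic: no encryption, authentication
  or secure aggregation is provided, and federation is simulated
  in-process.
- No recalibration is performed: the calibration slope is reported, and
  models failing it would need recalibration before deployment at a new
  site.
- Complete-case modelling throughout; under MCAR this is unbiased but
  wasteful, and under informative missingness it would bias coefficients.
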