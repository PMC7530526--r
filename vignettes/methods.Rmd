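---
title: "Methods: myogenesis signature scoring and biopsy regeneration statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: myogenesis signature scoring and biopsy regeneration statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoregen)
```

## The scientific setting

Muscular dystrophies such as facioscapulohumeral muscular dystrophy (FSHD)
and myotonic dystrophy type 2 (DM2) are slowly progressive myopathies in
which damaged muscle fibres are replaced by satellite-cell-driven
regeneration. Regenerating fibres transiently express developmental myosin
heavy chain (Dev MyHC), so the percentage of Dev MyHC-immunopositive fibres
in a biopsy section is a direct protein-level regeneration readout. At the
transcriptomic level, regeneration shows up as elevated expression of genes
engaged during myogenic differentiation.

`myoregen` implements both readouts as a tested pipeline:

1. **Transcriptomic arm.** A per-sample *Myogenesis score* — the mean
   normalized expression of a 200-gene myogenic differentiation signature —
   compared between dystrophic and control biopsies within each study,
   combined across studies by Fisher's method, and summarized by a pooled
   ROC/AUC.
2. **Histopathology arm.** Per-biopsy regeneration proportions and 12-point
   pathology severity scores, cohort summaries, and plain plus
   muscle-type-adjusted association analyses, computed from per-biopsy
   record tables shipped with the package.

## The Myogenesis score

For one study with expression matrix $X$ (rows probes or genes, columns
samples):

1. **Probe collapse.** Microarray probes mapping to the same gene identifier
   are arithmetically averaged (`collapse_probes()`); probes without a gene
   assignment are dropped, since only gene-level values are scored. RNA-seq
   matrices already keyed by gene pass through.
2. **Quantile log-normalization.** `quantile_log_normalize()` applies
   $\log_2(x+1)$ and then quantile normalization within the study: each
   column's ranks are mapped onto the reference distribution (the mean of
   row-sorted values). The transform and the scoring are per-study, so
   microarray intensities and RNA-seq quantifications never need a common
   absolute scale.
3. **Scoring.** The score of sample $j$ is the unweighted mean of its
   normalized values over the signature genes present on the platform
   (`myogenesis_score()`). Coverage (fraction of signature genes found) is
   recorded, with a warning below 0.5 by default.

Numerical choices worth stating:

* **Order of log and quantile steps.** The log transform is applied first:
  it is finite at zero for both platforms and makes the case shift additive
  on the scale where expression noise is approximately Gaussian. Because
  quantile normalization is rank-based, the two orders differ only through
  the reference distribution, but log-first keeps the reference on the
  interpretable log2 scale.
* **Ties.** A tie group occupying ranks $k..m$ in a column receives the mean
  of the reference values over those ranks. With this dialect the sorted
  values of all columns are bit-identical for tie-free data; when columns
  have different tie patterns, exact sorted identity is mathematically
  impossible under tie-averaging, but every column retains exactly the same
  total (and mean), which is what the tests assert for tied inputs.
* **Missing values.** Rows with any missing value are dropped before
  normalization (with a message), so ranks are always defined.
* **Single-sample matrices** are returned log-transformed with a warning:
  the quantile step is a no-op without a second column.

## Per-study inference and meta-analysis

Within a study, case and control scores are compared by a two-sided
Wilcoxon rank-sum test (`wilcoxon_test()`): exact enumeration when the
pooled sample size is at most 12 and tie-free, otherwise the normal
approximation with tie and continuity correction. Both paths are checked
against enumeration and permutation oracles in the test suite. The
*differential score* (mean case minus mean control) is reported with a
percentile-bootstrap 95% interval (`differential_score_ci()`, default
10,000 seeded replicates) — distribution-free and the standard forest-plot
companion when no parametric CI is implied by the test.

Across $k$ studies, Fisher's combined probability test
(`fisher_combined()`) uses $-2\sum_i \ln p_i \sim \chi^2_{2k}$. It assumes
independent studies and is checked against the closed-form even-df
chi-square tail. Discrimination is summarized by the pooled ROC
(`pooled_roc()`): the AUC is the Mann–Whitney pair-counting estimator
(ties 0.5), which is also the probability that a random case outscores a
random control. Pooling concatenates the per-study normalized scores
(`pooling = "raw"`); because every study was quantile-normalized to its own
reference, residual cross-platform location differences can remain, so
`pooling = "per_study_zscore"` optionally standardizes each study's scores
first. The default mirrors the plain "pooled" analysis; the switch exists
because the choice is genuinely underdetermined and can matter when
platforms differ strongly.

No per-study multiplicity correction is applied: the analysis reports
per-study p-values and one combined p, and no heterogeneity statistics
(this is deliberately Fisher-only, not a random-effects meta-analysis).

## The histopathology arm

Each biopsy record carries counts (`dev_myhc_count` of `fibre_count`
fibres) and four 0–3 pathology components: fibre size variation, central
nucleation, fibrosis, and necrosis/regeneration/inflammation (NRI), plus a
separate 0–1 necrosis flag. `derive_metrics()` computes:

* `proportion` $= 100 \cdot \texttt{dev\_myhc\_count}/\texttt{fibre\_count}$
  (full precision internally; rounding is display-only),
* `pathology_score` (0–12, the component sum) and `pathology_minus_nri`
  (0–9),
* `severity`: 1–4 mild, 5–8 moderate, 9–12 severe. A score of 0 falls
  outside the published bands and is labelled `none`.

Cohort summaries use per-biopsy means (never counts pooled across biopsies,
which would weight biopsies by section size), sample (n−1) SD, and
SEM = SD/√n — validated against the shipped tables' printed AVG/SD/SEM rows.

### Association analyses and the adjustment model

Continuous variables use the sample Pearson correlation with the exact
t-based p-value (`pearson_assoc()`). For binary variables,
`logistic_binary_assoc()` regresses the proportion on the indicator and
reports the coefficient's t/z statistic. Four variants are exposed because
the family genuinely changes the answer on overdispersed biopsy data:

| variant | model | statistic |
|---|---|---|
| `gaussian` (default) | linear model on the percent proportion | t (= pooled-variance two-sample t) |
| `binomial_counts` | successes/trials binomial GLM | Wald z |
| `quasibinomial_counts` | as above, dispersion estimated | t |
| `quasibinomial_prop` | unweighted quasi-likelihood on the proportion | t |

Validation against the shipped reference tables selects `gaussian` as the
default: it reproduces the published binary-variable statistics to three
decimals (muscle type t = 2.240 on all 54 biopsies, sex t = 1.685, DM2
muscle p = 0.98), whereas the fibre-level binomial z is an order of
magnitude larger (it ignores biopsy-level overdispersion) and the
quasi-likelihood ts land near 2.5–3.0. All variants remain available and
tested.

`adjusted_correlation()` removes the muscle-type difference before
correlating regeneration with pathology: a regression of the proportion on
muscle type is fitted, and its per-record residuals replace the raw
proportion in Pearson correlations. Here validation selects the
**binomial counts model with response-scale residuals** (observed minus
fitted proportion) as the default: fitted over the genetically confirmed
FSHD1 records (n = 40, excluding the four FSHD2 and one mosaic subject), it
reproduces the entire published adjusted block to ±0.003
(r = 0.365/0.649/0.609/0.417/0.647 against the five pathology targets).
The published p-values are themselves internally consistent with n = 40
(not the full 45), which is why the FSHD adjusted analyses in
`histology_report()` default to the FSHD1-only subset (`fshd1_only =
TRUE`). Pearson and deviance residuals are available as alternatives. When
the covariate is constant, the residuals are centred proportions and the
adjusted correlation equals the plain one (tested).

Two reference quantities deserve caveats. The published D4Z4 correlation
(r = −0.017) is reproduced only approximately (−0.027 from the packaged
counts; consistent with the original analysis using the 2-decimal rounded
proportion column). The DM2 adjusted block cannot be reproduced from the
nine DM2 records at all — its printed r/p pairs imply twelve degrees of
freedom — so the package asserts only the scientific conclusion (no
significant association in DM2).

## The synthetic-data generators

Public expression repositories are not accessed; `gen_expression_study()`
generates studies with known ground truth emulating the structure the
pipeline must handle: mixed platforms (multi-probe microarray with a probe
map vs gene-keyed RNA-seq), log-normal intensities, and a case shift
confined to signature genes.

* Log2 baselines are uniform on (2, 12) — the dynamic range typical of
  normalized array intensities; per-sample noise is Normal(0, 1) on the
  log2 scale, a realistic biopsy-to-biopsy spread; microarray probes add
  Normal(0, 0.25) probe-level noise, 1–4 probes per gene. Defaults use
  10 + 10 samples and 1000 genes; the effect `effect_delta` shifts
  signature genes in cases on the log2 scale.
* What it does **not** emulate: batch effects, GC/length bias,
  platform-specific backgrounds, count discreteness, or correlated gene
  modules. Passing tests therefore demonstrate correctness of the
  statistical machinery under clean known-truth conditions, not robustness
  to every real-data artefact.

`gen_biopsy_cohort()` draws a latent severity $z \sim N(0,1)$ per subject;
each pathology component thresholds a noisy copy of $z$ (mimicking the
strong inter-component correlation of real cohorts, which arises because
all four track one underlying disease process), and regeneration follows
$\text{dev} \sim \text{Binomial}(\text{fibres},
\text{logit}^{-1}(\beta_0 + \beta_m \cdot \text{tibialis} + \rho z))$.
Defaults mirror the shipped cohorts: fibre counts uniform on 100–2000,
$\beta_0 = -5.5$ (≈0.4% baseline regeneration, the quadriceps level),
$\beta_m = 1.3$ (tibialis anterior regenerates a few-fold more). With
$\rho = 0$ regeneration is independent of pathology — the null design
under which the adjusted correlation must average zero; with
$\beta_m \neq 0, \rho = 0$ muscle type is a pure confound, isolating
exactly what the adjustment has to remove.

## Problem sizes and determinism

Everything stochastic takes an explicit integer seed and restores the
caller's RNG state, so identical configurations give byte-identical output
files. The validation suite exercises the meta pipeline at small scale
chosen for thorough-but-quick iteration: 200 simulated three-study
meta-analyses for the type-I error check (rejection rate at α = 0.05 must
sit inside the binomial 95% band), 1000 null studies for the
p-uniformity Kolmogorov–Smirnov check, 300 repetitions for bootstrap CI
coverage, and 25–40 seeds per effect size for the AUC monotonicity and
signal-recovery checks. These sizes are the package's own trade-off between
Monte-Carlo resolution and suite runtime.

## Known limitations

* The transcriptomic arm is validated on simulated data only; applying it
  to real deposited studies requires the user to supply matrices,
  annotations and probe maps in the documented TSV dialect.
* Fisher's method assumes independent studies and is sensitive to a single
  very small p; no heterogeneity or random-effects machinery is provided.
* The adjustment residualizes only the outcome (proportion), matching the
  published procedure, rather than both variables (partial correlation).
* The severity banding of 0 as `none` is an extrapolation below the
  published 1–12 bands; no shipped record has score 0.
* The packaged 200-gene signature is a synthetic stand-in with the format
  and size of the published myogenesis gene set (see
  `inst/extdata/hallmark_myogenesis_synthetic.gmt`); analyses of real data
  should substitute the licensed original.
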