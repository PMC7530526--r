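# myoregen

Skeletal muscle regeneration analysis for muscular dystrophy cohorts, in two
arms:

* **Transcriptomic**: a per-sample *Myogenesis score* — the mean expression
  of a 200-gene myogenic differentiation signature after per-study
  `log2(x+1)` + quantile normalization and probe-to-gene collapse — compared
  between dystrophic (FSHD, DM2, DMD) and control muscle biopsies with
  Wilcoxon rank-sum tests, combined across studies with Fisher's method
  (−2·Σ ln pᵢ ~ χ²₂ₖ), and summarized by a pooled ROC whose AUC is the
  Mann–Whitney pair-counting estimator.
* **Histopathology**: per-biopsy regenerating-fibre proportions
  (100 × Dev MyHC⁺ fibres / fibres), 12-point pathology severity scores
  (four 0–3 components: fibre size variation, central nucleation, fibrosis,
  necrosis/regeneration/inflammation), cohort summaries, and plain plus
  muscle-type-adjusted correlation/regression analyses. The per-biopsy
  tables for 45 FSHD and 9 DM2 subjects ship as CSV fixtures in
  `inst/extdata/`.

Seeded simulators (`gen_expression_study()`, `gen_biopsy_cohort()`) generate
expression studies and biopsy cohorts with known ground truth, so the whole
pipeline is testable without external downloads.

The package is organised as an analysis workflow: all computation lives in
exported functions under `R/`, and the numbered scripts under `analysis/`
drive the analyses and write their tables under `results/`.

## Worked example

Histology arm, straight from the packaged biopsy tables:

```r
library(myoregen)
quad <- load_biopsy_table(system.file("extdata", "fshd_quadriceps.csv",
                                      package = "myoregen"))
regeneration_prevalence(quad)
#> $k [1] 26   $n [1] 34   $fraction [1] 0.7647059
cohort_summary(quad, "proportion")[c("mean", "sem")]
#> $mean [1] 0.4779325   $sem [1] 0.1511463
```

So 26 of 34 FSHD quadriceps biopsies (76.5%) contain at least one
regenerating fibre, with a mean of 0.48 ± 0.15% Dev MyHC⁺ fibres per biopsy.
The muscle-type-adjusted correlation between regeneration and the pathology
score over the genetically confirmed FSHD1 records:

```r
tib <- load_biopsy_table(system.file("extdata", "fshd_tibialis.csv",
                                     package = "myoregen"))
fshd1 <- subset(rbind(quad, tib), diagnosis == "FSHD1")
adjusted_correlation(fshd1, "pathology_score")
#>          variable         r      p_value  n
#>   pathology_score 0.6472634 6.370635e-06 40
```

i.e. muscle regeneration tracks pathological severity (r ≈ 0.65,
p ≈ 6 × 10⁻⁶) once the quadriceps/tibialis difference is removed.

Transcriptomic arm on simulated studies:

```r
gs <- read_gmt(system.file("extdata", "hallmark_myogenesis_synthetic.gmt",
                           package = "myoregen"))[[1]]
studies <- lapply(1:3, function(i)
  gen_expression_study(paste0("sim", i), gs, n_genes = 1000,
                       effect_delta = 1,
                       platform = c("rnaseq", "microarray")[1 + i %% 2],
                       seed = 100 + i))
run_meta(studies, gs, n_boot = 1000, seed = 1)
#> <meta_result> 3 studies | Fisher chi-sq = 51.647 (df 6), combined p = 2.2e-09 | pooled AUC = 1.000
```

The full workflow is scripted:

```sh
Rscript analysis/01_simulate_expression.R   # synthetic 3-study corpus
Rscript analysis/02_meta_analysis.R         # forest table, combined p, ROC
Rscript analysis/03_histology_tables.R      # cohort summaries
Rscript analysis/04_histology_associations.R# association blocks
```

See `vignettes/methods.Rmd` for the models, the adjustment-variant
validation, and the simulators' assumptions.

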