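Package: myoregen
Title: Myogenesis Signature Scoring and Muscle-Biopsy Regeneration Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-arm analysis of skeletal muscle regeneration in muscular
    dystrophy. The transcriptomic arm computes a per-sample Myogenesis score
    (mean expression of a 200-gene myogenic differentiation signature) from
    microarray or RNA-seq expression studies after per-study quantile
    log-normalization and probe-to-gene collapse, compares dystrophic and
    control biopsies with Wilcoxon rank-sum tests, combines evidence across
    studies with Fisher's combined probability test, and quantifies
    discrimination with pooled ROC/AUC. The histopathology arm derives
    regenerating-fibre proportions (developmental myosin heavy chain
    immunolabelling) and 12-point pathology severity scores from per-biopsy
    records, summarizes cohorts, and runs plain and muscle-type-adjusted
    correlation and regression analyses. Seeded simulators generate expression
    studies and biopsy cohorts with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    withr
Config/testthat/edition: 3
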