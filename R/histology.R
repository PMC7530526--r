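BIOPSY_COLUMNS <- c("subject_id", "diagnosis", "sex", "age", "d4z4_kb",
                    "muscle", "dev_myhc_count", "fibre_count",
                    "fibre_size_variation", "central_nuclei", "fibrosis",
                    "nri", "necrosis")

#' Load and validate a biopsy table
#'
#' Reads per-biopsy records as CSV with columns `subject_id`, `diagnosis`
#' (`FSHD1`, `FSHD2`, `FSHD1_mosaic`, `DM2`), `sex` (`M`/`F`), `age`,
#' `d4z4_kb` (EcoRI fragment size in kb; blank where not applicable),
#' `muscle` (`quadriceps`/`tibialis_anterior`), `dev_myhc_count` (fibres
#' immunopositive for developmental myosin heavy chain), `fibre_count`, the
#' four 0-3 pathology components (`fibre_size_variation`, `central_nuclei`,
#' `fibrosis`, `nri` = necrosis/regeneration/inflammation) and the separate
#' 0-1 `necrosis` flag. Row-level validation failures are reported with
#' their row numbers.
#'
#' @param path CSV path, or several paths whose records are pooled.
#' @return A validated data frame of biopsy records.
#' @export
load_biopsy_table <- function(path) {
  recs <- do.call(rbind, lapply(path, function(p) {
    if (!file.exists(p)) stop_fmt("biopsy table not found: %s", p)
    x <- utils::read.csv(p, stringsAsFactors = FALSE)
    missing <- setdiff(BIOPSY_COLUMNS, names(x))
    if (length(missing)) {
      stop_fmt("%s: missing column(s): %s", p, paste(missing, collapse = ", "))
    }
    x[BIOPSY_COLUMNS]
  }))
  validate_biopsy_records(recs)
  recs
}

#' Validate biopsy records
#'
#' Checks the record invariants (enums, score ranges, count consistency) and
#' fails with the offending row numbers.
#'
#' @param recs Biopsy record data frame.
#' @return The records, invisibly, when valid.
#' @export
validate_biopsy_records <- function(recs) {
  problems <- character()
  note <- function(rows, what) {
    if (length(rows)) {
      problems <<- c(problems,
                     sprintf("row %s: %s", paste(rows, collapse = ","), what))
    }
  }
  note(which(!recs$diagnosis %in% c("FSHD1", "FSHD2", "FSHD1_mosaic", "DM2")),
       "unknown diagnosis")
  note(which(!recs$sex %in% c("M", "F")), "sex must be M or F")
  note(which(!recs$muscle %in% c("quadriceps", "tibialis_anterior")),
       "unknown muscle")
  note(which(!is.finite(recs$age) | recs$age <= 0), "invalid age")
  note(which(!is.na(recs$d4z4_kb) & recs$d4z4_kb <= 0), "d4z4_kb must be positive")
  int_ok <- function(v) is.finite(v) & v == floor(v)
  note(which(!int_ok(recs$fibre_count) | recs$fibre_count < 1),
       "fibre_count must be a positive integer")
  note(which(!int_ok(recs$dev_myhc_count) | recs$dev_myhc_count < 0),
       "dev_myhc_count must be a non-negative integer")
  note(which(recs$dev_myhc_count > recs$fibre_count),
       "dev_myhc_count exceeds fibre_count")
  for (comp in c("fibre_size_variation", "central_nuclei", "fibrosis", "nri")) {
    note(which(!int_ok(recs[[comp]]) | recs[[comp]] < 0 | recs[[comp]] > 3),
         sprintf("%s outside 0-3", comp))
  }
  note(which(!int_ok(recs$necrosis) | recs$necrosis < 0 | recs$necrosis > 1),
       "necrosis outside 0-1")
  if (length(problems)) {
    stop_fmt("invalid biopsy record(s):\n  %s", paste(problems, collapse = "\n  "))
  }
  invisible(recs)
}

#' Derive per-biopsy regeneration and severity metrics
#'
#' Adds `proportion` (percent of fibres immunopositive for developmental
#' MyHC, `100 * dev_myhc_count / fibre_count`, full precision), the 0-12
#' `pathology_score` (sum of the four 0-3 components), `pathology_minus_nri`
#' (0-9) and the `severity` band: scores 1-4 mild, 5-8 moderate, 9-12
#' severe; a score of 0 is banded `none`.
#'
#' @param records Validated biopsy records (see [load_biopsy_table()]).
#' @return The records with derived columns appended.
#' @export
derive_metrics <- function(records) {
  validate_biopsy_records(records)
  records$proportion <- 100 * records$dev_myhc_count / records$fibre_count
  records$pathology_score <- records$fibre_size_variation +
    records$central_nuclei + records$fibrosis + records$nri
  records$pathology_minus_nri <- records$pathology_score - records$nri
  records$severity <- cut(records$pathology_score,
                          breaks = c(-0.5, 0.5, 4.5, 8.5, 12.5),
                          labels = c("none", "mild", "moderate", "severe"))
  records
}

#' Cohort summary of a biopsy metric
#'
#' Mean, sample (n-1) standard deviation, and standard error of the mean of
#' a per-biopsy metric, matching the AVG/SD/SEM/N convention of cohort
#' tables: the mean is over per-biopsy values (proportions are not pooled
#' across fibre counts). Regeneration prevalence (fraction of biopsies with
#' at least one Dev MyHC+ fibre) is computed on the same subset.
#'
#' @param records Biopsy records.
#' @param metric Column to summarize (default `"proportion"`); derived
#'   columns are computed if absent.
#' @param filter Optional logical vector selecting records.
#' @return List with `n`, `mean`, `sd`, `sem`, `prevalence`.
#' @export
cohort_summary <- function(records, metric = "proportion", filter = NULL) {
  if (!is.null(filter)) records <- records[filter, , drop = FALSE]
  if (nrow(records) == 0L) stop_fmt("empty cohort subset")
  if (!metric %in% names(records)) records <- derive_metrics(records)
  if (!metric %in% names(records)) stop_fmt("unknown metric '%s'", metric)
  v <- records[[metric]]
  n <- length(v)
  out <- list(n = n, mean = mean(v), sd = NA_real_, sem = NA_real_,
              prevalence = mean(records$dev_myhc_count > 0))
  if (n >= 2L) {
    out$sd <- stats::sd(v)
    out$sem <- out$sd / sqrt(n)
  } else {
    warn_fmt("single record: sd/sem undefined")
  }
  out
}

#' Regeneration prevalence
#'
#' Number and fraction of biopsies containing at least one regenerating
#' (Dev MyHC+) fibre.
#'
#' @param records Biopsy records.
#' @return List with `k` (positive biopsies), `n` and `fraction`.
#' @export
regeneration_prevalence <- function(records) {
  if (nrow(records) == 0L) stop_fmt("no records")
  k <- sum(records$dev_myhc_count >= 1)
  list(k = k, n = nrow(records), fraction = k / nrow(records))
}

new_assoc <- function(variable, kind, statistic, p_value, n, detail = NULL) {
  structure(list(variable = variable, kind = kind, statistic = statistic,
                 p_value = p_value, n = n, detail = detail),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> %s (%s): statistic = %.3f, p = %.3g, n = %d\n",
              x$variable, x$kind, x$statistic, x$p_value, x$n))
  invisible(x)
}

#' Pearson correlation with a continuous variable
#'
#' Sample Pearson correlation between a continuous per-biopsy variable and
#' the regenerating-fibre proportion (or another numeric column), with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Records with missing `x_field` are excluded.
#'
#' @param records Biopsy records.
#' @param x_field Continuous column (e.g. `"age"`, `"d4z4_kb"`).
#' @param y_field Numeric column, default `"proportion"`.
#' @return An `assoc_result` with `kind = "pearson"`; `statistic` is r.
#' @export
pearson_assoc <- function(records, x_field, y_field = "proportion") {
  if (!y_field %in% names(records)) records <- derive_metrics(records)
  x <- records[[x_field]]
  y <- records[[y_field]]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop_fmt("need >= 3 paired finite values for '%s'", x_field)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_fmt("correlation undefined: zero variance in '%s' pairing",
             x_field)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  new_assoc(x_field, "pearson", unname(ct$estimate), ct$p.value, length(x))
}

fit_regen_model <- function(records, rhs,
                            variant = c("gaussian", "binomial_counts",
                                        "quasibinomial_counts",
                                        "quasibinomial_prop")) {
  variant <- match.arg(variant)
  records <- if ("proportion" %in% names(records)) records else derive_metrics(records)
  dat <- records
  dat$.rhs <- rhs
  switch(variant,
    gaussian = stats::glm(proportion ~ .rhs, family = stats::gaussian(), data = dat),
    binomial_counts = stats::glm(
      cbind(dev_myhc_count, fibre_count - dev_myhc_count) ~ .rhs,
      family = stats::binomial(), data = dat),
    quasibinomial_counts = stats::glm(
      cbind(dev_myhc_count, fibre_count - dev_myhc_count) ~ .rhs,
      family = stats::quasibinomial(), data = dat),
    quasibinomial_prop = stats::glm(I(proportion / 100) ~ .rhs,
                                    family = stats::quasibinomial(), data = dat))
}

#' Association of regeneration with a binary variable
#'
#' Regresses the per-biopsy regenerating-fibre proportion on a two-level
#' variable (sex, muscle type, disease status) and reports the coefficient's
#' t (or z) statistic and two-sided p-value. Several model variants are
#' exposed because the regression family materially changes the statistic:
#'
#' * `"gaussian"` (default): linear model of the percent proportion on the
#'   indicator — the variant validated against the reference biopsy tables
#'   (its t equals the pooled-variance two-sample t).
#' * `"binomial_counts"`: binomial GLM where each biopsy contributes
#'   `dev_myhc_count` successes of `fibre_count` trials (Wald z; assumes no
#'   overdispersion, typically anticonservative for biopsy data).
#' * `"quasibinomial_counts"`: as above with overdispersion estimated
#'   (t statistic).
#' * `"quasibinomial_prop"`: unweighted quasi-likelihood fit on the
#'   proportion itself.
#'
#' @param records Biopsy records.
#' @param binary_field Two-level column (e.g. `"muscle"`, `"sex"`).
#' @param variant Model variant, see Details.
#' @return An `assoc_result` with `kind = "logistic"`; `statistic` is the
#'   coefficient's t/z value for the second factor level.
#' @export
logistic_binary_assoc <- function(records, binary_field,
                                  variant = c("gaussian", "binomial_counts",
                                              "quasibinomial_counts",
                                              "quasibinomial_prop")) {
  variant <- match.arg(variant)
  x <- factor(records[[binary_field]])
  if (nlevels(droplevels(x)) != 2L) {
    stop_fmt("'%s' must have exactly two observed levels", binary_field)
  }
  records <- derive_metrics(records)
  fit <- fit_regen_model(records, x, variant)
  if (variant == "binomial_counts" && !fit$converged) {
    warn_fmt("'%s': fit did not converge (possible complete separation); unregularized estimates unreliable", binary_field)
  }
  co <- summary(fit)$coefficients
  new_assoc(binary_field, "logistic", co[2, 3], co[2, 4], nrow(records),
            detail = list(variant = variant, levels = levels(x)))
}

#' Muscle-type-adjusted correlations
#'
#' Associations between the regenerating-fibre proportion and pathology
#' variables, independent of muscle type: a regression of the proportion on
#' the binary covariate is fitted, its per-record residuals replace the raw
#' proportion, and each target is Pearson-correlated with the residuals.
#'
#' The default model is the binomial counts GLM with response-scale
#' residuals (observed minus fitted proportion) — the configuration
#' validated against the reference tables; `residual_type` also offers
#' Pearson and deviance residuals, and `variant` any model from
#' [logistic_binary_assoc()]. When the covariate is constant the residuals
#' are centred proportions and the adjusted correlation equals the plain
#' one.
#'
#' @param records Biopsy records.
#' @param target_fields Character vector of numeric columns to correlate.
#' @param covariate_field Binary covariate column (default `"muscle"`).
#' @param variant Adjustment model (default `"binomial_counts"`).
#' @param residual_type `"response"` (default), `"pearson"` or `"deviance"`.
#' @return Data frame with one row per target: `variable`, `r`, `p_value`,
#'   `n`.
#' @export
adjusted_correlation <- function(records, target_fields,
                                 covariate_field = "muscle",
                                 variant = "binomial_counts",
                                 residual_type = c("response", "pearson",
                                                   "deviance")) {
  residual_type <- match.arg(residual_type)
  records <- derive_metrics(records)
  x <- factor(records[[covariate_field]])
  res <- if (nlevels(droplevels(x)) < 2L) {
    # constant covariate: intercept-only fit, residuals are centred values
    stats::residuals(fit_regen_model(records, rep(1, nrow(records)), variant),
                     type = residual_type)
  } else {
    stats::residuals(fit_regen_model(records, x, variant), type = residual_type)
  }
  out <- lapply(target_fields, function(tf) {
    y <- records[[tf]]
    if (is.null(y)) stop_fmt("unknown target field '%s'", tf)
    if (stats::sd(y) == 0 || stats::sd(res) == 0) {
      stop_fmt("correlation undefined: zero variance for '%s'", tf)
    }
    ct <- stats::cor.test(res, y, method = "pearson")
    data.frame(variable = tf, r = unname(ct$estimate), p_value = ct$p.value,
               n = length(y), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Wilcoxon test of regeneration by necrosis status
#'
#' Two-sided Mann-Whitney comparison of the regenerating-fibre proportion
#' between biopsies scored necrosis 1 versus necrosis 0.
#'
#' @param records Biopsy records.
#' @return Two-sided p-value.
#' @export
necrosis_wilcoxon <- function(records) {
  records <- derive_metrics(records)
  g1 <- records$proportion[records$necrosis == 1]
  g0 <- records$proportion[records$necrosis == 0]
  if (length(g1) == 0L || length(g0) == 0L) {
    stop_fmt("both necrosis groups must be non-empty")
  }
  wilcoxon_test(g1, g0)
}
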