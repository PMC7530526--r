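#' Score one expression study from files
#'
#' File-level wrapper over the scoring arm: reads a study, collapses probes,
#' quantile log-normalizes, computes Myogenesis scores and (optionally)
#' writes a per-sample score table TSV with columns `sample_id`, `score`,
#' `group`.
#'
#' @inheritParams read_expression_study
#' @param gmt_path GMT file; first set used unless `set_name` given.
#' @param out_path Optional TSV path for the score table.
#' @param set_name Optional gene-set name.
#' @param min_coverage Passed to [myogenesis_score()].
#' @return The `score_vector`, invisibly when `out_path` is given.
#' @export
score_study_files <- function(study_id, matrix_path, annotation_path,
                              gmt_path, platform = c("rnaseq", "microarray"),
                              probe_map_path = NULL, out_path = NULL,
                              set_name = NULL, min_coverage = 0.5) {
  platform <- match.arg(platform)
  study <- read_expression_study(study_id, matrix_path, annotation_path,
                                 platform, probe_map_path)
  sets <- read_gmt(gmt_path)
  gs <- if (is.null(set_name)) sets[[1]] else sets[[set_name]]
  if (is.null(gs)) stop_fmt("gene set '%s' not found in %s", set_name, gmt_path)
  sv <- myogenesis_score(quantile_log_normalize(collapse_probes(study)),
                         gs, min_coverage = min_coverage)
  if (!is.null(out_path)) {
    utils::write.table(as.data.frame(sv), out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(sv))
  }
  sv
}

#' Cohort summary table across biopsy groups
#'
#' One row per cohort with n, regeneration prevalence, and mean/sd/sem of
#' the regenerating-fibre proportion and of the pathology score — the
#' summary rows of per-cohort biopsy tables.
#'
#' @param cohorts Named list of biopsy record data frames.
#' @return Data frame with one row per cohort.
#' @export
cohort_summary_table <- function(cohorts) {
  rows <- lapply(names(cohorts), function(nm) {
    recs <- derive_metrics(cohorts[[nm]])
    pr <- cohort_summary(recs, "proportion")
    ps <- cohort_summary(recs, "pathology_score")
    prev <- regeneration_prevalence(recs)
    data.frame(cohort = nm, n = pr$n,
               regen_positive = prev$k, prevalence = prev$fraction,
               proportion_mean = pr$mean, proportion_sd = pr$sd,
               proportion_sem = pr$sem,
               pathology_mean = ps$mean, pathology_sd = ps$sd,
               pathology_sem = ps$sem, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

PATHOLOGY_TARGETS <- c("fibre_size_variation", "central_nuclei", "fibrosis",
                       "nri", "pathology_score")

#' Full histology association report
#'
#' Builds the three association blocks of the histology arm from pooled
#' biopsy records:
#'
#' 1. unadjusted associations of the regenerating-fibre proportion with age
#'    and D4Z4 fragment size (Pearson, over all records resp. the
#'    genetically confirmed FSHD1 subset) and with sex, disease status and
#'    muscle type (binary regression over all records);
#' 2. muscle-type-adjusted Pearson correlations of the proportion with the
#'    four pathology components and the total score over the FSHD1 subset;
#' 3. the same adjusted correlations over the DM2 subset.
#'
#' A block requiring both levels of a binary covariate is skipped with a
#' warning when only one level is present.
#'
#' @param records Pooled biopsy records (all cohorts).
#' @param binary_variant Model variant for binary associations (default
#'   `"gaussian"`, the validated one).
#' @param adjust_variant,residual_type Adjustment model configuration
#'   (defaults `"binomial_counts"`, `"response"`; the validated pair).
#' @param fshd1_only Use only genetically confirmed FSHD1 records (dropping
#'   FSHD2 and mosaic) for the D4Z4 correlation and the FSHD adjusted block,
#'   the subset validated against the reference tables (default `TRUE`).
#' @return List with data frames `unadjusted`, `fshd_adjusted`,
#'   `dm2_adjusted`.
#' @export
histology_report <- function(records, binary_variant = "gaussian",
                             adjust_variant = "binomial_counts",
                             residual_type = "response",
                             fshd1_only = TRUE) {
  records <- derive_metrics(records)
  is_dm2 <- records$diagnosis == "DM2"
  fshd <- records[!is_dm2, , drop = FALSE]
  fshd1 <- if (fshd1_only) {
    fshd[fshd$diagnosis == "FSHD1", , drop = FALSE]
  } else {
    fshd
  }
  unadj <- list()
  add_pearson <- function(recs, field, label) {
    a <- pearson_assoc(recs, field)
    data.frame(variable = label, kind = "pearson", statistic = a$statistic,
               p_value = a$p_value, n = a$n, stringsAsFactors = FALSE)
  }
  add_binary <- function(recs, field, label) {
    x <- droplevels(factor(recs[[field]]))
    if (nlevels(x) < 2L) {
      warn_fmt("'%s' has a single level; association skipped", label)
      return(NULL)
    }
    a <- logistic_binary_assoc(recs, field, variant = binary_variant)
    data.frame(variable = label, kind = "logistic", statistic = a$statistic,
               p_value = a$p_value, n = a$n, stringsAsFactors = FALSE)
  }
  unadj$age <- add_pearson(records, "age", "age")
  if (any(is.finite(fshd1$d4z4_kb))) {
    unadj$d4z4 <- add_pearson(fshd1, "d4z4_kb", "d4z4_fshd1")
  }
  records$disease <- ifelse(is_dm2, "DM2", "FSHD")
  unadj$sex <- add_binary(records, "sex", "sex")
  if (length(unique(records$disease)) == 2L) {
    unadj$disease <- add_binary(records, "disease", "fshd_vs_dm2")
  }
  unadj$muscle <- add_binary(records, "muscle", "muscle")
  adj_block <- function(recs) {
    if (nrow(recs) == 0L) return(NULL)
    adjusted_correlation(recs, PATHOLOGY_TARGETS, "muscle",
                         variant = adjust_variant,
                         residual_type = residual_type)
  }
  list(unadjusted = do.call(rbind, unadj),
       fshd_adjusted = adj_block(fshd1),
       dm2_adjusted = adj_block(records[is_dm2, , drop = FALSE]))
}

#' Write the histology report
#'
#' Writes `cohort_summaries.tsv` and the three association blocks
#' (`associations_unadjusted.tsv`, `associations_fshd_adjusted.tsv`,
#' `associations_dm2_adjusted.tsv`) plus a JSON digest under `out_dir`.
#'
#' @param cohorts Named list of biopsy record data frames.
#' @param out_dir Output directory (created if needed).
#' @param ... Passed to [histology_report()].
#' @return Invisibly, the report list.
#' @export
write_histology_report <- function(cohorts, out_dir, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summaries <- cohort_summary_table(cohorts)
  utils::write.table(summaries, file.path(out_dir, "cohort_summaries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pooled <- do.call(rbind, unname(cohorts))
  rep_ <- histology_report(pooled, ...)
  for (nm in names(rep_)) {
    if (!is.null(rep_[[nm]])) {
      utils::write.table(rep_[[nm]],
                         file.path(out_dir, sprintf("associations_%s.tsv", nm)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  jsonlite::write_json(list(cohorts = summaries, associations = rep_),
                       file.path(out_dir, "histology_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(rep_)
}
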