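#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Compares case against control scores within one study. The exact null
#' distribution is enumerated when the pooled sample size is at most 12 and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction is used. When every value in both groups is
#' identical the comparison is degenerate and `p = 1` is returned with a
#' message.
#'
#' @param case,control Numeric vectors of per-sample scores (each length
#'   >= 1, finite).
#' @return Two-sided p-value in `(0, 1]`.
#' @export
wilcoxon_test <- function(case, control) {
  if (length(case) < 1L || length(control) < 1L) {
    stop_fmt("both groups must be non-empty")
  }
  if (!all(is.finite(case)) || !all(is.finite(control))) {
    stop_fmt("scores must be finite")
  }
  pooled <- c(case, control)
  if (length(unique(pooled)) == 1L) {
    message("all values identical across groups; degenerate comparison, p = 1")
    return(1)
  }
  n <- length(pooled)
  exact <- n <= 12L && !anyDuplicated(pooled)
  res <- suppressWarnings(
    stats::wilcox.test(case, control, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  min(res$p.value, 1)
}

#' Differential score with percentile-bootstrap confidence interval
#'
#' The differential score of a study is `mean(case) - mean(control)`. The
#' 95% confidence interval is a percentile bootstrap: each group is resampled
#' with replacement `n_boot` times and the 2.5/97.5 percentiles of the
#' resampled differences are reported. Reproducible given `seed`.
#'
#' @inheritParams wilcoxon_test
#' @param n_boot Number of bootstrap replicates (>= 100; default 10000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param conf Confidence level (default 0.95).
#' @return List with `diff`, `ci_low`, `ci_high`.
#' @export
differential_score_ci <- function(case, control, n_boot = 10000L, seed = NULL,
                                  conf = 0.95) {
  if (length(case) < 1L || length(control) < 1L) {
    stop_fmt("both groups must be non-empty")
  }
  if (n_boot < 100L) stop_fmt("n_boot must be at least 100")
  if (length(case) == 1L || length(control) == 1L) {
    warn_fmt("group of size 1: bootstrap interval degenerate for that group")
  }
  d <- mean(case) - mean(control)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(case, replace = TRUE)) - mean(sample(control, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha)))
  list(diff = d, ci_low = ci[1], ci_high = ci[2])
}

#' Fisher's combined probability test
#'
#' Combines independent per-study p-values: the statistic `-2 * sum(log(p))`
#' follows a chi-square distribution with `2k` degrees of freedom under the
#' joint null, and the combined p-value is its upper tail.
#'
#' @param p_values Numeric vector of p-values, each in `(0, 1]`.
#' @return List with `stat`, `df` and `p_value`.
#' @export
fisher_combined <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (length(p_values) < 1L) stop_fmt("need at least one p-value")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop_fmt("all p-values must lie in (0, 1]")
  }
  stat <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  list(stat = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}

#' Pooled ROC curve and AUC
#'
#' The AUC is the Mann-Whitney pair-counting estimator: the fraction of
#' (case, control) pairs where the case scores higher, with ties counted
#' 0.5 — the probability that the score discriminates a randomly chosen case
#' from a randomly chosen control. The ROC curve is traced over all score
#' thresholds (predict case when `score >= t`).
#'
#' @param scores Numeric vector of scores.
#' @param labels Vector the same length as `scores`: `"case"`/`"control"`
#'   (or logical, `TRUE` = case).
#' @return List with `auc` and `roc_points`, a data frame of `fpr`, `tpr`
#'   starting at (0, 0) and ending at (1, 1), both coordinates non-decreasing.
#' @export
pooled_roc <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  labels <- as.character(labels)
  if (length(scores) != length(labels)) stop_fmt("scores and labels differ in length")
  if (!all(labels %in% c("case", "control"))) {
    stop_fmt("labels must be 'case' or 'control'")
  }
  is_case <- labels == "case"
  n1 <- sum(is_case)
  n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop_fmt("ROC undefined: need both classes")
  # rank-sum form of the pair-counting estimator; average ranks score ties 0.5
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & is_case) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !is_case) / n0, numeric(1))
  roc_points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  if (utils::tail(roc_points$fpr, 1) < 1 || utils::tail(roc_points$tpr, 1) < 1) {
    roc_points <- rbind(roc_points, data.frame(fpr = 1, tpr = 1))
  }
  list(auc = auc, roc_points = roc_points)
}

#' Run the Myogenesis-score meta-analysis across expression studies
#'
#' For each study: collapse probes to genes, quantile log-normalize within
#' the study, compute per-sample Myogenesis scores, then compare case vs
#' control (Wilcoxon p, differential score with bootstrap CI). Across
#' studies, per-study p-values are combined with Fisher's method and a pooled
#' ROC over the concatenated per-sample scores quantifies discrimination.
#'
#' Because each study is normalized separately, pooled scores are on
#' comparable within-study scales; `pooling = "per_study_zscore"`
#' standardizes each study's scores (overall mean/sd) before pooling for
#' platforms with residual scale differences.
#'
#' @param studies List of [expression_study()] objects.
#' @param gene_set A [gene_set()].
#' @param n_boot Bootstrap replicates for per-study confidence intervals.
#' @param seed Integer seed driving the bootstrap.
#' @param pooling `"raw"` (default) or `"per_study_zscore"`.
#' @param on_error `"abort"` (default) propagates a failing study's error
#'   with its study id; `"skip"` drops the study with a warning.
#' @param min_coverage Passed to [myogenesis_score()].
#' @return Object of class `meta_result`: `studies` (forest table data frame
#'   with `study_id`, `n_case`, `n_control`, `diff`, `ci_low`, `ci_high`,
#'   `p_value`), `combined_stat`, `combined_df`, `combined_p`, `pooled_auc`,
#'   `roc_points`, and `scores` (pooled per-sample score table).
#' @export
run_meta <- function(studies, gene_set, n_boot = 10000L, seed = NULL,
                     pooling = c("raw", "per_study_zscore"),
                     on_error = c("abort", "skip"), min_coverage = 0.5) {
  pooling <- match.arg(pooling)
  on_error <- match.arg(on_error)
  if (length(studies) < 1L) stop_fmt("need at least one study")
  rows <- list()
  pooled <- list()
  for (i in seq_along(studies)) {
    st <- studies[[i]]
    res <- tryCatch({
      sv <- myogenesis_score(quantile_log_normalize(collapse_probes(st)),
                             gene_set, min_coverage = min_coverage)
      case <- sv$score[sv$group == "case"]
      control <- sv$score[sv$group == "control"]
      ci <- differential_score_ci(case, control, n_boot = n_boot,
                                  seed = if (is.null(seed)) NULL else seed + i)
      list(sv = sv,
           row = data.frame(study_id = st$study_id,
                            n_case = length(case), n_control = length(control),
                            diff = ci$diff, ci_low = ci$ci_low,
                            ci_high = ci$ci_high,
                            p_value = wilcoxon_test(case, control),
                            stringsAsFactors = FALSE))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (on_error == "abort") {
        stop_fmt("study '%s' failed: %s", st$study_id, conditionMessage(res))
      }
      warn_fmt("study '%s' skipped: %s", st$study_id, conditionMessage(res))
      next
    }
    rows[[length(rows) + 1L]] <- res$row
    sv <- res$sv
    if (pooling == "per_study_zscore") {
      sv$score <- as.numeric(scale(sv$score))
    }
    sv$study_id <- st$study_id
    pooled[[length(pooled) + 1L]] <- as.data.frame(sv)
  }
  if (length(rows) == 0L) stop_fmt("no study could be analysed")
  forest <- do.call(rbind, rows)
  comb <- fisher_combined(forest$p_value)
  scores <- do.call(rbind, pooled)
  roc <- pooled_roc(scores$score, scores$group)
  structure(list(studies = forest,
                 combined_stat = comb$stat, combined_df = comb$df,
                 combined_p = comb$p_value,
                 pooled_auc = roc$auc, roc_points = roc$roc_points,
                 scores = scores, pooling = pooling),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> %d studies | Fisher chi-sq = %.3f (df %d), combined p = %.3g | pooled AUC = %.3f\n",
              nrow(x$studies), x$combined_stat, x$combined_df, x$combined_p,
              x$pooled_auc))
  print(x$studies, row.names = FALSE)
  invisible(x)
}

#' Read a study manifest
#'
#' TSV listing one expression study per row with columns `study_id`,
#' `platform`, `matrix`, `annotation` and optionally `probe_map` (blank for
#' RNA-seq). Relative paths are resolved against the manifest's directory.
#'
#' @param path Manifest TSV path.
#' @return List of [expression_study()] objects.
#' @export
read_study_manifest <- function(path) {
  man <- utils::read.delim(path, colClasses = "character")
  need <- c("study_id", "platform", "matrix", "annotation")
  if (!all(need %in% names(man))) {
    stop_fmt("manifest needs columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(man) == 0L) stop_fmt("manifest is empty")
  base <- dirname(path)
  resolve <- function(p) {
    if (grepl("^(/|[A-Za-z]:)", p) || file.exists(p)) p else file.path(base, p)
  }
  lapply(seq_len(nrow(man)), function(i) {
    pm <- if ("probe_map" %in% names(man) && nzchar(man$probe_map[i])) {
      resolve(man$probe_map[i])
    }
    read_expression_study(man$study_id[i], resolve(man$matrix[i]),
                          resolve(man$annotation[i]),
                          platform = man$platform[i], probe_map_path = pm)
  })
}

#' Run the meta-analysis from files and write its report
#'
#' Convenience wrapper tying the file interface together: reads a study
#' manifest and a GMT gene-set file, runs [run_meta()], and writes the forest
#' table, meta summary JSON and ROC points under `out_dir`.
#'
#' @param manifest_path Study manifest TSV (see [read_study_manifest()]).
#' @param gmt_path GMT file; the first gene set is used unless `set_name`
#'   selects one by name.
#' @param out_dir Output directory (created if needed).
#' @param set_name Optional gene-set name within the GMT file.
#' @param ... Passed to [run_meta()].
#' @return The `meta_result`, invisibly.
#' @export
run_meta_files <- function(manifest_path, gmt_path, out_dir, set_name = NULL, ...) {
  studies <- read_study_manifest(manifest_path)
  sets <- read_gmt(gmt_path)
  gs <- if (is.null(set_name)) sets[[1]] else sets[[set_name]]
  if (is.null(gs)) stop_fmt("gene set '%s' not found in %s", set_name, gmt_path)
  res <- run_meta(studies, gs, ...)
  write_meta_result(res, out_dir)
  invisible(res)
}

#' Write a meta-analysis report
#'
#' Writes `forest_table.tsv` (per-study differential scores, CIs,
#' Wilcoxon p), `meta_summary.json` (combined statistic, df, combined p,
#' pooled AUC) and `roc_points.tsv` under `out_dir`.
#'
#' @param result A `meta_result` from [run_meta()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_meta_result <- function(result, out_dir) {
  stopifnot(inherits(result, "meta_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(forest = file.path(out_dir, "forest_table.tsv"),
             summary = file.path(out_dir, "meta_summary.json"),
             roc = file.path(out_dir, "roc_points.tsv"))
  utils::write.table(result$studies, paths["forest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(combined_stat = result$combined_stat,
                            combined_df = result$combined_df,
                            combined_p = result$combined_p,
                            pooled_auc = result$pooled_auc,
                            pooling = result$pooling),
                       paths["summary"], auto_unbox = TRUE, digits = NA)
  utils::write.table(result$roc_points, paths["roc"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
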