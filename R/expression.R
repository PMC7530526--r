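#' Construct an expression study
#'
#' One study's probe/gene-by-sample expression matrix with case/control
#' labels, as deposited for a single microarray or RNA-seq experiment.
#' Microarray studies carry a probe-to-gene map and are collapsed to one row
#' per gene by [collapse_probes()]; RNA-seq matrices are expected to be
#' gene-keyed already.
#'
#' @param study_id Single string identifying the study.
#' @param values Non-negative numeric matrix, rows = probes or genes
#'   (rownames required), columns = samples (colnames required).
#' @param group Character vector (or factor) of per-sample labels, each
#'   `"case"` or `"control"`, aligned with `colnames(values)` (or named by
#'   sample).
#' @param platform `"microarray"` or `"rnaseq"`.
#' @param probe_map Optional data frame with columns `probe_id`, `gene_id`.
#'   Required for microarray studies.
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(study_id, values, group,
                             platform = c("rnaseq", "microarray"),
                             probe_map = NULL) {
  platform <- match.arg(platform)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_fmt("study '%s': values must be a numeric matrix", study_id)
  }
  if (nrow(values) < 1L) stop_fmt("study '%s': empty matrix", study_id)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_fmt("study '%s': values must have row and column names", study_id)
  }
  if (anyDuplicated(colnames(values))) {
    stop_fmt("study '%s': sample ids must be unique", study_id)
  }
  if (any(!is.na(values) & values < 0)) {
    stop_fmt("study '%s': expression values must be non-negative", study_id)
  }
  group <- as.character(group)
  if (!is.null(names(group))) group <- group[colnames(values)]
  if (length(group) != ncol(values)) {
    stop_fmt("study '%s': one group label per sample required", study_id)
  }
  if (!all(group %in% c("case", "control"))) {
    stop_fmt("study '%s': group labels must be 'case' or 'control'", study_id)
  }
  if (sum(group == "case") < 1L || sum(group == "control") < 1L) {
    stop_fmt("study '%s': need at least one case and one control sample", study_id)
  }
  if (platform == "microarray") {
    if (is.null(probe_map)) {
      stop_fmt("study '%s': microarray platform requires a probe_map", study_id)
    }
    if (!all(c("probe_id", "gene_id") %in% names(probe_map))) {
      stop_fmt("study '%s': probe_map needs columns probe_id, gene_id", study_id)
    }
  }
  structure(list(study_id = study_id, platform = platform, values = values,
                 group = stats::setNames(group, colnames(values)),
                 probe_map = probe_map),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("<expression_study> %s (%s): %d rows x %d samples (%d case / %d control)\n",
              x$study_id, x$platform, nrow(x$values), ncol(x$values),
              sum(x$group == "case"), sum(x$group == "control")))
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' Expects the matrix as TSV with row identifiers in the first column and
#' sample ids as header; the annotation as TSV with columns `sample_id` and
#' `group` (`case`/`control`); and, for microarray data, a probe map TSV with
#' columns `probe_id` and `gene_id`.
#'
#' @inheritParams expression_study
#' @param matrix_path,annotation_path,probe_map_path File paths.
#' @return An `expression_study`.
#' @export
read_expression_study <- function(study_id, matrix_path, annotation_path,
                                  platform = c("rnaseq", "microarray"),
                                  probe_map_path = NULL) {
  platform <- match.arg(platform)
  mat <- utils::read.delim(matrix_path, check.names = FALSE)
  values <- as.matrix(mat[, -1, drop = FALSE])
  rownames(values) <- as.character(mat[[1]])
  ann <- utils::read.delim(annotation_path, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(ann))) {
    stop_fmt("annotation %s needs columns sample_id, group", annotation_path)
  }
  missing <- setdiff(colnames(values), ann$sample_id)
  if (length(missing)) {
    stop_fmt("study '%s': samples without annotation: %s",
             study_id, paste(missing, collapse = ", "))
  }
  group <- stats::setNames(as.character(ann$group), ann$sample_id)[colnames(values)]
  probe_map <- if (!is.null(probe_map_path)) {
    utils::read.delim(probe_map_path, colClasses = "character")
  }
  expression_study(study_id, values, group, platform, probe_map)
}

#' Collapse probe-level rows to one row per gene
#'
#' Probes (or sequences) mapping to the same gene identifier are averaged
#' arithmetically. Probes absent from the probe map are dropped with a
#' message, since only gene-level values are scored. RNA-seq matrices whose
#' rows are already gene-keyed pass through unchanged.
#'
#' @param study An [expression_study()].
#' @return A `gene_matrix`: list with `study_id`, `values` (genes x samples),
#'   `group` and logical flag `normalized` (`FALSE`).
#' @export
collapse_probes <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  values <- study$values
  if (study$platform == "microarray") {
    map <- study$probe_map
    keep <- rownames(values) %in% map$probe_id
    if (!any(keep)) stop_fmt("study '%s': no mappable probes", study$study_id)
    if (!all(keep)) {
      message(sprintf("study '%s': dropping %d probe(s) absent from probe map",
                      study$study_id, sum(!keep)))
      values <- values[keep, , drop = FALSE]
    }
    gene <- stats::setNames(map$gene_id, map$probe_id)[rownames(values)]
    values <- rowsum(values, group = gene, reorder = TRUE) /
      as.vector(table(gene)[sort(unique(gene))])
  } else if (anyDuplicated(rownames(values))) {
    gene <- rownames(values)
    values <- rowsum(values, group = gene, reorder = TRUE) /
      as.vector(table(gene)[sort(unique(gene))])
  }
  structure(list(study_id = study$study_id, values = values,
                 group = study$group, normalized = FALSE),
            class = "gene_matrix")
}

# Quantile-normalize columns of `x`: each column's ranks are mapped onto the
# reference distribution (the mean of row-sorted values). A tie group
# occupying ranks k..m receives the mean of the reference values at those
# ranks.
quantile_normalize <- function(x) {
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  n <- nrow(x)
  for (j in seq_len(ncol(x))) {
    xj <- x[, j]
    r <- rank(xj, ties.method = "average")
    if (anyDuplicated(xj)) {
      v <- numeric(n)
      for (grp in split(seq_len(n), match(xj, xj))) {
        g <- length(grp)
        first <- r[grp[1]] - (g - 1) / 2  # tie groups occupy contiguous ranks
        v[grp] <- mean(ref[seq.int(first, first + g - 1)])
      }
      out[, j] <- v
    } else {
      out[, j] <- ref[r]
    }
  }
  out
}

#' Quantile log-normalize a gene matrix
#'
#' Applies `log2(x + 1)` and then quantile normalization across samples:
#' every column's ranks are mapped to the reference distribution defined by
#' the mean of row-sorted values, so all columns share an identical sorted
#' distribution afterwards. Ties within a column receive the mean of the
#' reference values over the tied ranks. Performed on each study separately,
#' this puts mixed microarray and RNA-seq studies on a comparable
#' within-study scale before signature scoring.
#'
#' Rows containing missing values are dropped (with a message) before
#' normalization. A single-sample matrix is returned log-transformed
#' unchanged with a warning, as the quantile step is then a no-op.
#'
#' @param gm A `gene_matrix` from [collapse_probes()], not yet normalized.
#' @return The `gene_matrix` with normalized values and `normalized = TRUE`.
#' @export
quantile_log_normalize <- function(gm) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (isTRUE(gm$normalized)) stop_fmt("matrix '%s' is already normalized", gm$study_id)
  values <- gm$values
  bad <- !stats::complete.cases(values)
  if (any(bad)) {
    message(sprintf("study '%s': dropping %d row(s) with missing values",
                    gm$study_id, sum(bad)))
    values <- values[!bad, , drop = FALSE]
  }
  if (any(values < 0)) stop_fmt("study '%s': negative values", gm$study_id)
  logged <- log2(values + 1)
  if (ncol(logged) == 1L) {
    warn_fmt("study '%s': single sample, quantile step skipped", gm$study_id)
    gm$values <- logged
  } else {
    gm$values <- quantile_normalize(logged)
  }
  gm$normalized <- TRUE
  gm
}

#' Per-sample Myogenesis score
#'
#' The score of a sample is the unweighted mean of its normalized expression
#' values over the genes of `gene_set` present in the matrix. Coverage is the
#' fraction of the gene set found on the platform; a warning is emitted when
#' it falls below `min_coverage`.
#'
#' @param gm A normalized `gene_matrix` (see [quantile_log_normalize()]).
#' @param gene_set A [gene_set()].
#' @param min_coverage Coverage warning threshold in `[0, 1]` (default 0.5).
#' @return A data frame of class `score_vector` with columns `sample_id`,
#'   `score` and, when the matrix carries labels, `group`; attributes
#'   `study_id` and `coverage`.
#' @export
myogenesis_score <- function(gm, gene_set, min_coverage = 0.5) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(gene_set, "gene_set"))
  if (!isTRUE(gm$normalized)) {
    stop_fmt("matrix '%s' must be normalized before scoring", gm$study_id)
  }
  hit <- intersect(gene_set$genes, rownames(gm$values))
  coverage <- length(hit) / length(gene_set$genes)
  if (length(hit) == 0L) {
    stop_fmt("study '%s': gene set absent from platform", gm$study_id)
  }
  if (coverage < min_coverage) {
    warn_fmt("study '%s': gene-set coverage %.2f below %.2f",
             gm$study_id, coverage, min_coverage)
  }
  scores <- colMeans(gm$values[hit, , drop = FALSE])
  out <- data.frame(sample_id = colnames(gm$values), score = unname(scores),
                    stringsAsFactors = FALSE)
  if (!is.null(gm$group)) out$group <- unname(gm$group[out$sample_id])
  attr(out, "study_id") <- gm$study_id
  attr(out, "coverage") <- coverage
  class(out) <- c("score_vector", "data.frame")
  out
}
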