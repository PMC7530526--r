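#' Construct a gene set
#'
#' A gene set is a named, order-free collection of unique gene identifiers
#' (gene symbols or EntrezGene-style IDs). The per-sample mean expression of
#' one such set — a 200-gene myogenic differentiation signature — is the
#' Myogenesis score computed by [myogenesis_score()].
#'
#' @param name Single string naming the set.
#' @param genes Character vector of gene identifiers. Duplicates are removed
#'   with a warning; gene order never affects any downstream result.
#' @param description Optional free-text description.
#' @return An object of class `gene_set` with elements `name`, `description`
#'   and `genes`.
#' @export
gene_set <- function(name, genes, description = "") {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_fmt("gene set name must be a non-empty string")
  }
  genes <- as.character(genes)
  if (length(genes) == 0L || any(!nzchar(genes))) {
    stop_fmt("gene set '%s' must contain at least one non-empty identifier", name)
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warn_fmt("gene set '%s': %d duplicate identifier(s) removed (%s)",
             name, length(dup), paste(utils::head(dup, 5L), collapse = ", "))
    genes <- unique(genes)
  }
  structure(list(name = name, description = description, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d genes\n", x$name, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read gene sets from a GMT file
#'
#' Parses the MSigDB GMT convention: one set per line, tab-separated fields
#' `name`, `description`, then one field per gene identifier.
#'
#' @param path Path to a GMT file.
#' @return A named list of [gene_set()] objects, one per line.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_fmt("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_fmt("GMT file is empty: %s", path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_fmt("malformed GMT line %d: expected >= 3 tab-separated fields, got %d",
               i, length(fields))
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    sets[[i]] <- gene_set(fields[[1]], genes, description = fields[[2]])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}
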