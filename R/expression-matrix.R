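#' Build an expression matrix object
#'
#' Wraps a genes-by-samples matrix of non-negative, linear-scale expression
#' values (normalized microarray intensities or qPCR relative expression)
#' together with per-sample metadata into a
#' [SummarizedExperiment::SummarizedExperiment], the container used by every
#' downstream stage of the pipeline. The single assay is named `"exprs"`.
#'
#' @param values Numeric matrix, genes as rows. Must have unique, non-empty
#'   rownames (gene ids) and colnames (sample ids); all values finite and
#'   >= 0.
#' @param metadata A `data.frame` with one row per sample. Must contain a
#'   `sample_id` column matching `colnames(values)`; typical further columns
#'   are `condition` (cell-type experiments), `tissue` and `patient`
#'   (human-panel experiments).
#' @return A `SummarizedExperiment` with assay `"exprs"`.
#' @examples
#' m <- matrix(1:6, nrow = 2, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' meta <- data.frame(sample_id = c("s1", "s2", "s3"), condition = "white")
#' se <- expression_matrix(m, meta)
#' @export
expression_matrix <- function(values, metadata) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("expression values must be numeric", call. = FALSE)
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("gene ids (rownames) must be present and unique", call. = FALSE)
  }
  if (is.null(colnames(values))) {
    stop("sample ids (colnames) must be present", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("expression values must be finite and non-negative", call. = FALSE)
  }
  metadata <- as.data.frame(metadata)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must contain a 'sample_id' column", call. = FALSE)
  }
  missing <- setdiff(colnames(values), metadata$sample_id)
  if (length(missing) > 0) {
    stop("samples without metadata: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(values), metadata$sample_id), , drop = FALSE]
  cd <- S4Vectors::DataFrame(metadata, row.names = metadata$sample_id)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = cd
  )
}

#' @rdname expression_matrix
#' @param x Object to extract the expression assay from.
#' @return `exprs_of()` returns the genes-by-samples numeric matrix.
#' @export
exprs_of <- function(x) {
  if (methods::is(x, "SummarizedExperiment")) {
    return(SummarizedExperiment::assay(x, "exprs"))
  }
  as.matrix(x)
}

#' Read and write expression matrices as TSV
#'
#' The on-disk convention: expression is a TSV with genes as rows, first
#' column `gene_id`, header row of sample ids; sample metadata is a second
#' TSV with a `sample_id` column and arbitrary label columns.
#'
#' @param se A `SummarizedExperiment` as built by [expression_matrix()].
#' @param expr_path Path of the expression TSV.
#' @param meta_path Path of the metadata TSV (optional for writing; when
#'   reading without one, minimal metadata with only `sample_id` is created).
#' @return `read_expression_tsv()` returns a `SummarizedExperiment`;
#'   `write_expression_tsv()` returns `expr_path` invisibly.
#' @export
write_expression_tsv <- function(se, expr_path, meta_path = NULL) {
  m <- exprs_of(se)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    cd <- as.data.frame(SummarizedExperiment::colData(se))
    utils::write.table(cd, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(expr_path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(expr_path, meta_path = NULL) {
  df <- utils::read.table(expr_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (is.null(meta_path)) {
    meta <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  } else {
    meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                              check.names = FALSE, stringsAsFactors = FALSE)
  }
  expression_matrix(m, meta)
}

#' Read and write marker gene sets in GMT format
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path File path.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled; defaults to the set names.
#' @return `read_gmt()` returns a named list of character vectors with the
#'   descriptions in `attr(, "description")`.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  attr(sets, "description") <- vapply(parts, `[[`, character(1), 2)
  sets
}
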