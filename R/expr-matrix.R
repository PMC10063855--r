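#' Expression matrix with sample metadata
#'
#' The central data container of the package: a features x samples numeric
#' matrix of log2-scale expression values together with a binary class label
#' (`"case"` = severe hypoxemia, `"control"` = mild) and a batch label for
#' every sample. The `level` flag records whether rows are array probes or
#' collapsed genes; downstream stages check it.
#'
#' @param values Numeric matrix, features in rows (rownames = feature IDs),
#'   samples in columns (colnames = sample IDs). No missing values allowed.
#' @param class_labels Character vector, one of `"case"`/`"control"` per
#'   sample, in column order.
#' @param batch Character/integer vector of batch labels per sample. Defaults
#'   to a single batch `"b1"`.
#' @param level `"probe"` or `"gene"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `class_labels`, `batch`, `level`.
#' @export
expr_matrix <- function(values, class_labels, batch = NULL,
                        level = c("probe", "gene")) {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (feature IDs) and colnames (sample IDs)")
  if (anyNA(values))
    stop("missing values in expression matrix; impute or filter before loading")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature IDs")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  class_labels <- as.character(class_labels)
  if (length(class_labels) != ncol(values))
    stop("one class label per sample required")
  if (!all(class_labels %in% c("case", "control")))
    stop("class labels must be 'case' or 'control'")
  if (is.null(batch)) batch <- rep("b1", ncol(values))
  batch <- as.character(batch)
  if (length(batch) != ncol(values))
    stop("one batch label per sample required")
  structure(
    list(values = values, class_labels = class_labels, batch = batch,
         level = level),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d %s features x %d samples (%d case / %d control, %d batch%s)\n",
    nrow(x$values), x$level, ncol(x$values),
    sum(x$class_labels == "case"), sum(x$class_labels == "control"),
    length(unique(x$batch)), if (length(unique(x$batch)) == 1) "" else "es"))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Numeric class encoding used throughout: case = 1, control = 0
#' @param m An `expr_matrix` or character label vector.
#' @return Integer vector of 0/1.
#' @export
class_numeric <- function(m) {
  labels <- if (inherits(m, "expr_matrix")) m$class_labels else m
  if (is.numeric(labels) || is.logical(labels)) {
    labels <- as.integer(labels)
    if (!all(labels %in% c(0L, 1L))) stop("numeric labels must be 0/1")
    return(labels)
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case'/'control' or 0/1")
  as.integer(labels == "case")
}

#' Write an expression matrix and its sample labels as TSV
#'
#' The expression file has a header row of sample IDs after a leading
#' `probe_id` (or `gene_id`) column; each subsequent row is a feature.
#' The labels file has columns `sample_id`, `class`, `batch`.
#'
#' @param m An `expr_matrix`.
#' @param expr_path Path for the expression TSV.
#' @param labels_path Optional path for the labels TSV.
#' @return `expr_path`, invisibly.
#' @export
write_expression_tsv <- function(m, expr_path, labels_path = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  id_col <- if (m$level == "probe") "probe_id" else "gene_id"
  df <- data.frame(rownames(m$values), m$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c(id_col, colnames(m$values))
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(labels_path)) {
    lab <- data.frame(sample_id = colnames(m$values),
                      class = m$class_labels, batch = m$batch)
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(expr_path)
}

#' Read an expression matrix and sample labels from TSV
#'
#' @param expr_path Expression TSV as written by [write_expression_tsv()]:
#'   one header row of sample IDs, a leading feature-ID column.
#' @param labels_path Labels TSV with columns `sample_id`, `class`, `batch`
#'   (batch optional).
#' @param level Feature level of the rows; inferred from the ID column name
#'   (`probe_id`/`gene_id`) when `NULL`.
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(expr_path, labels_path, level = NULL) {
  df <- utils::read.delim(expr_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs a feature column and >= 1 sample")
  id_name <- names(df)[1]
  if (is.null(level)) {
    level <- if (identical(id_name, "gene_id")) "gene" else "probe"
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) stop("non-numeric entries in expression TSV")
  rownames(values) <- df[[1]]
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(lab)))
    stop("labels TSV must have columns sample_id and class")
  idx <- match(colnames(values), lab$sample_id)
  if (anyNA(idx)) stop("labels missing for some samples: ",
                       paste(colnames(values)[is.na(idx)], collapse = ", "))
  batch <- if ("batch" %in% names(lab)) lab$batch[idx] else NULL
  expr_matrix(values, lab$class[idx], batch = batch, level = level)
}

#' Read a probe-to-gene annotation table
#'
#' @param path TSV with columns `probe_id`, `gene_id`.
#' @return A data.frame with those two columns.
#' @export
read_annotation_tsv <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_id") %in% names(ann)))
    stop("annotation TSV must have columns probe_id and gene_id")
  ann[, c("probe_id", "gene_id")]
}
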