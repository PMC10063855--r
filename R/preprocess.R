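#' Quantile-normalize an expression matrix
#'
#' Forces every sample column to the same empirical distribution: the
#' row-wise mean of the sorted input columns. Ties within a column receive
#' the mean of the quantile values they span. This is the package's
#' distribution-matching normalization for matrices that arrive already on
#' the log2 scale; set `log2_transform = TRUE` for linear-scale input.
#'
#' @param m An `expr_matrix` with at least two samples.
#' @param log2_transform Apply `log2(x + 1)` before normalizing.
#' @return The normalized `expr_matrix`.
#' @export
quantile_normalize <- function(m, log2_transform = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (ncol(m$values) < 2) stop("quantile normalization needs >= 2 samples")
  v <- m$values
  if (log2_transform) v <- log2(v + 1)
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  m$values <- out
  m
}

#' Collapse probe-level rows to gene level by averaging
#'
#' Probes mapping to the same gene are averaged (arithmetic mean on the log2
#' scale). Probes without an annotation entry are dropped with a message.
#' A probe mapping to more than one gene is an error.
#'
#' @param m Probe-level `expr_matrix`.
#' @param annotation data.frame with columns `probe_id`, `gene_id`.
#' @return Gene-level `expr_matrix`, rows sorted by gene ID.
#' @export
collapse_probes <- function(m, annotation) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$level != "probe") stop("input must be probe-level")
  if (!all(c("probe_id", "gene_id") %in% names(annotation)))
    stop("annotation must have columns probe_id and gene_id")
  ann <- unique(annotation[, c("probe_id", "gene_id")])
  if (anyDuplicated(ann$probe_id))
    stop("annotation maps at least one probe to multiple genes")
  probes <- rownames(m$values)
  gene <- ann$gene_id[match(probes, ann$probe_id)]
  unmapped <- sum(is.na(gene))
  if (unmapped > 0)
    message(unmapped, " probe(s) without gene annotation dropped")
  keep <- !is.na(gene)
  if (!any(keep)) stop("no probe maps to a gene")
  sums <- rowsum(m$values[keep, , drop = FALSE], group = gene[keep])
  counts <- as.vector(table(gene[keep])[rownames(sums)])
  m$values <- sums / counts
  m$level <- "gene"
  m
}

#' Standardize each gene within each known batch
#'
#' Within every batch, each gene is centered to mean zero and scaled to unit
#' variance (sample SD). Genes with zero variance inside a batch are centered
#' only and reported in the `"constant_genes"` attribute, never dropped.
#' Removes additive batch offsets exactly; requires at least two samples per
#' batch.
#'
#' @param m Gene- or probe-level `expr_matrix` with batch labels.
#' @return The corrected `expr_matrix` (attribute `constant_genes` lists
#'   features flagged constant in at least one batch).
#' @export
batch_correct <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  tab <- table(m$batch)
  if (any(tab < 2))
    stop("batch with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  flagged <- character()
  for (b in names(tab)) {
    idx <- m$batch == b
    sub <- m$values[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, stats::sd)
    const <- sdv == 0
    flagged <- union(flagged, rownames(sub)[const])
    sdv[const] <- 1
    m$values[, idx] <- (sub - mu) / sdv
  }
  attr(m, "constant_genes") <- flagged
  m
}

#' Per-gene Welch differential-expression screen with BH correction
#'
#' Two-sided Welch (unequal-variance) t-test of case versus control for every
#' gene, with Benjamini-Hochberg step-up q-values over all tested genes.
#' Genes with zero variance in both classes get t = 0 and p = 1.
#'
#' @param m Gene-level `expr_matrix` with >= 2 samples per class.
#' @return A tibble with columns `gene_id`, `t`, `p`, `q`, `mean_diff`
#'   (case minus control), ordered by ascending p.
#' @export
differential_expression <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  y <- class_numeric(m)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 < 2 || n0 < 2) stop("each class needs >= 2 samples")
  x1 <- m$values[, y == 1, drop = FALSE]
  x0 <- m$values[, y == 0, drop = FALSE]
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  tt <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  degenerate <- se2 == 0
  tt[degenerate] <- 0
  p[degenerate] <- 1
  q <- stats::p.adjust(p, method = "BH")
  out <- tibble::tibble(gene_id = rownames(m$values), t = unname(tt),
                        p = unname(p), q = unname(q),
                        mean_diff = unname(m1 - m0))
  out[order(out$p, out$gene_id), ]
}
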