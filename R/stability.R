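#' Configuration for bootstrap stability selection
#'
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param score_threshold Stability-score threshold for the pass flag
#'   (default 0.6): a gene "passes" when it is selected in at least this
#'   fraction of iterations.
#' @param penalty_strength Inverse regularization strength of the L1
#'   logistic-regression selector (larger = weaker penalty); the per-sample
#'   lasso penalty used is `1 / (n * penalty_strength)`.
#' @param coef_epsilon A gene counts as selected in an iteration when its
#'   absolute coefficient exceeds this value.
#' @param stratified Draw bootstrap samples within each class, preserving
#'   the case/control mix (default TRUE).
#' @param max_skip_frac Abort if more than this fraction of iterations fails
#'   to converge (skipped iterations keep denominator `n_boot`).
#' @param seed RNG seed.
#' @return A list of class `stability_config`.
#' @export
stability_config <- function(n_boot = 100, score_threshold = 0.6,
                             penalty_strength = 1, coef_epsilon = 1e-8,
                             stratified = TRUE, max_skip_frac = 0.1,
                             seed = 1) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (score_threshold <= 0 || score_threshold > 1)
    stop("score_threshold must be in (0, 1]")
  if (penalty_strength <= 0) stop("penalty_strength must be positive")
  if (coef_epsilon <= 0) stop("coef_epsilon must be positive")
  structure(list(n_boot = as.integer(n_boot),
                 score_threshold = score_threshold,
                 penalty_strength = penalty_strength,
                 coef_epsilon = coef_epsilon, stratified = stratified,
                 max_skip_frac = max_skip_frac, seed = as.integer(seed)),
            class = "stability_config")
}

# deterministic per-iteration seed below 2^31
.iter_seed <- function(seed, iteration) {
  ((as.double(seed) %% 65011) * 32503 + as.double(iteration) * 7919) %%
    2147483629 + 1
}

#' Bootstrap sample indices for one stability-selection iteration
#'
#' Draws `length(labels)` indices with replacement. With `stratified = TRUE`
#' the draw keeps exactly the observed number of case and control slots.
#' The result is a deterministic function of `(seed, iteration)`.
#'
#' @param labels Class labels (`"case"`/`"control"` or an `expr_matrix`).
#' @param iteration Iteration number (1-based).
#' @param seed Base RNG seed of the run.
#' @param stratified Stratify by class.
#' @return Integer index vector of length `length(labels)`.
#' @export
bootstrap_indices <- function(labels, iteration, seed, stratified = TRUE) {
  y <- class_numeric(labels)
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present in labels")
  withr::with_seed(.iter_seed(seed, iteration), {
    if (stratified) {
      cases <- which(y == 1); controls <- which(y == 0)
      c(sample(cases, length(cases), replace = TRUE),
        sample(controls, length(controls), replace = TRUE))
    } else {
      sample(length(y), length(y), replace = TRUE)
    }
  })
}

#' Fit the L1-penalized logistic-regression selector on one bootstrap draw
#'
#' Features are standardized on the draw itself (no information from
#' out-of-draw samples); constant features get unit scale and therefore a
#' zero coefficient. The intercept is unpenalized. Non-convergence returns
#' `NULL` so the caller can skip the iteration.
#'
#' @param X Samples x genes numeric matrix (one bootstrap draw).
#' @param y 0/1 class vector (control = 0, case = 1).
#' @param penalty_strength Inverse regularization strength (see
#'   [stability_config()]).
#' @return Named numeric coefficient vector (no intercept), or `NULL` if the
#'   optimizer did not converge.
#' @export
fit_sparse_logistic <- function(X, y, penalty_strength = 1) {
  if (length(unique(y)) < 2) stop("both classes required in the draw")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  lambda <- 1 / (nrow(X) * penalty_strength)
  fit <- tryCatch(
    glmnet::glmnet(Xs, y, family = "binomial", alpha = 1, lambda = lambda,
                   standardize = FALSE, intercept = TRUE),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) return(NULL)
  coefs <- as.numeric(fit$beta)
  names(coefs) <- colnames(X)
  coefs
}

#' Bootstrap stability selection of class-informative genes
#'
#' Runs `n_boot` stratified bootstrap iterations; in each, an L1 logistic
#' regression is fit on the draw and genes with a non-negligible coefficient
#' count as selected. A gene's stability score is its selection frequency
#' over all `n_boot` iterations. Samples are put in canonical (sorted sample
#' ID) order before any draw, so results do not depend on input column order.
#'
#' @param m Gene-level, preprocessed `expr_matrix`.
#' @param cfg A [stability_config()].
#' @return A tibble of class `stability_result` with columns `gene_id`,
#'   `score`, `mean_abs_coef` (mean |coefficient| over iterations where
#'   selected, 0 if never), `rank` (1 = most stable) and `pass`
#'   (`score >= score_threshold`). Attributes: `n_boot`, `n_skipped`,
#'   `config`.
#' @export
stability_select <- function(m, cfg = stability_config()) {
  stopifnot(inherits(m, "expr_matrix"), inherits(cfg, "stability_config"))
  y_all <- class_numeric(m)
  if (sum(y_all == 1) < 2 || sum(y_all == 0) < 2)
    stop("each class needs >= 2 samples")
  ord <- order(colnames(m$values))
  X <- t(m$values[, ord, drop = FALSE])
  y <- y_all[ord]
  labels <- m$class_labels[ord]
  p <- ncol(X)
  sel_count <- numeric(p)
  coef_sum <- numeric(p)
  skipped <- 0L
  for (it in seq_len(cfg$n_boot)) {
    idx <- bootstrap_indices(labels, it, cfg$seed, cfg$stratified)
    coefs <- fit_sparse_logistic(X[idx, , drop = FALSE], y[idx],
                                 cfg$penalty_strength)
    if (is.null(coefs)) {
      skipped <- skipped + 1L
      next
    }
    sel <- abs(coefs) > cfg$coef_epsilon
    sel_count <- sel_count + sel
    coef_sum <- coef_sum + ifelse(sel, abs(coefs), 0)
  }
  if (skipped > cfg$max_skip_frac * cfg$n_boot)
    stop(sprintf("%d of %d iterations failed to converge", skipped, cfg$n_boot))
  if (skipped > 0)
    message(skipped, " non-convergent iteration(s) skipped")
  score <- unname(sel_count / cfg$n_boot)
  mean_abs_coef <- unname(ifelse(sel_count > 0, coef_sum / sel_count, 0))
  genes <- colnames(X)
  ord_rank <- order(-score, -mean_abs_coef, genes)
  rank <- integer(p)
  rank[ord_rank] <- seq_len(p)
  out <- tibble::tibble(gene_id = genes, score = score,
                        mean_abs_coef = mean_abs_coef, rank = rank,
                        pass = score >= cfg$score_threshold)
  out <- out[order(out$rank), ]
  attr(out, "n_boot") <- cfg$n_boot
  attr(out, "n_skipped") <- skipped
  attr(out, "config") <- cfg
  class(out) <- c("stability_result", class(out))
  out
}

#' Ordered gene list from a stability result
#'
#' Descending stability score; ties broken by descending mean absolute
#' coefficient, then lexicographically by gene ID.
#'
#' @param r A `stability_result` from [stability_select()].
#' @return Character vector of gene IDs, rank 1 first.
#' @export
rank_genes <- function(r) {
  stopifnot(all(c("gene_id", "score", "mean_abs_coef") %in% names(r)))
  r$gene_id[order(-r$score, -r$mean_abs_coef, r$gene_id)]
}
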