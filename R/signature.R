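#' Genes common to both cohorts' top-k ranked lists
#'
#' Intersects the top-`top_k` prefixes of two ranked gene lists. The common
#' genes are ordered by ascending rank sum across the two cohorts, ties by
#' ascending minimum rank, remaining ties lexicographically — a documented
#' convention, since any single joint order of two rankings is one.
#'
#' @param ranked_a,ranked_b Character vectors: full rankings (rank 1 first)
#'   of each cohort's genes.
#' @param top_k Prefix length to intersect (default 1500).
#' @return A tibble with columns `gene_id`, `rank_a`, `rank_b`, ordered by
#'   the combined key. Empty (with a warning) when the prefixes are disjoint.
#' @export
common_genes <- function(ranked_a, ranked_b, top_k = 1500) {
  if (anyDuplicated(ranked_a) || anyDuplicated(ranked_b))
    stop("rankings must not contain duplicate gene IDs")
  top_a <- utils::head(ranked_a, top_k)
  top_b <- utils::head(ranked_b, top_k)
  common <- intersect(top_a, top_b)
  if (length(common) == 0) {
    warning("no genes common to the two top-", top_k, " lists")
    return(tibble::tibble(gene_id = character(), rank_a = integer(),
                          rank_b = integer()))
  }
  rank_a <- match(common, ranked_a)
  rank_b <- match(common, ranked_b)
  ord <- order(rank_a + rank_b, pmin(rank_a, rank_b), common)
  tibble::tibble(gene_id = common[ord], rank_a = rank_a[ord],
                 rank_b = rank_b[ord])
}

#' Nested gene lists for incremental signature evaluation
#'
#' Default mode grows the signature in steps of `step` genes (the last set is
#' always the full common list); `explicit_sizes` instead evaluates the
#' prefixes at the given sizes.
#'
#' @param common A [common_genes()] tibble or a character vector of ordered
#'   gene IDs.
#' @param step Increment in genes (default 10).
#' @param explicit_sizes Optional integer vector of prefix sizes.
#' @return Named list of nested character vectors; names are the sizes.
#' @export
incremental_sets <- function(common, step = 10, explicit_sizes = NULL) {
  genes <- if (is.data.frame(common)) common$gene_id else as.character(common)
  n <- length(genes)
  if (n == 0) stop("common gene list is empty")
  if (is.null(explicit_sizes)) {
    sizes <- unique(c(seq_len(n %/% step) * step, n))
    if (step > n) sizes <- n
  } else {
    sizes <- as.integer(explicit_sizes)
    if (any(sizes < 1) || any(diff(sizes) <= 0))
      stop("explicit_sizes must be strictly increasing positive integers")
    if (max(sizes) > n)
      stop("requested size ", max(sizes), " exceeds the ", n,
           " available common genes")
  }
  stats::setNames(lapply(sizes, function(k) genes[seq_len(k)]), sizes)
}

#' Area under the ROC curve
#'
#' Rank-sum (Mann-Whitney) formulation: the probability that a randomly
#' chosen case outscores a randomly chosen control, ties counting one half.
#'
#' @param scores Numeric prediction scores (higher = more case-like).
#' @param labels Class labels (`"case"`/`"control"` or 0/1).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- class_numeric(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision without interpolation: walking thresholds
#' from the highest score down, AP = sum over thresholds of
#' (recall increment) x (precision at that threshold). Tied scores enter as
#' a single threshold, so a constant scorer yields exactly the prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  y <- class_numeric(labels)
  n1 <- sum(y == 1)
  if (n1 == 0) stop("at least one case required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  cum_tp <- cumsum(yy)
  cum_pos <- seq_along(yy)
  # threshold boundaries: last index of each tied block
  last <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cum_tp[last]
  precision <- tp / cum_pos[last]
  recall <- tp / n1
  sum(diff(c(0, recall)) * precision)
}

# standardize train, apply to test; constant features get unit scale
.standardize_pair <- function(train, test) {
  mu <- colMeans(train)
  sdv <- apply(train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  list(train = sweep(sweep(train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(test, 2, mu, check.margin = FALSE), 2, sdv, "/"))
}

# L2 logistic classifier used inside evaluation folds; p = 1 falls back to
# plain logistic regression because the elastic-net fit needs >= 2 columns
.fit_l2_score <- function(train_x, train_y, test_x, ridge_penalty = 1) {
  if (ncol(train_x) == 1) {
    df <- data.frame(y = train_y, x = train_x[, 1])
    fit <- suppressWarnings(stats::glm(y ~ x, data = df, family = stats::binomial()))
    as.numeric(suppressWarnings(
      stats::predict(fit, data.frame(x = test_x[, 1]), type = "response")))
  } else {
    lambda <- 1 / (nrow(train_x) * ridge_penalty)
    fit <- glmnet::glmnet(train_x, train_y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    as.numeric(stats::predict(fit, test_x, type = "response"))
  }
}

#' Leave-one-out cross-validated evaluation of a gene signature
#'
#' For each sample, an L2-penalized logistic regression on the remaining
#' samples (restricted to `gene_list`, standardized on the training fold)
#' scores the held-out sample. AUROC and AUPRC are computed once on the
#' pooled out-of-fold scores. Deterministic: no randomness is involved.
#'
#' @param m Gene-level `expr_matrix`.
#' @param gene_list Character vector of genes to use (must be rows of `m`).
#' @param ridge_penalty Inverse L2 regularization strength of the fold
#'   classifier.
#' @return A list with `scores` (named out-of-fold case probabilities),
#'   `labels`, `auroc`, `auprc`.
#' @export
loocv_evaluate <- function(m, gene_list, ridge_penalty = 1) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(gene_list) < 1) stop("gene_list must contain >= 1 gene")
  missing <- setdiff(gene_list, rownames(m$values))
  if (length(missing) > 0)
    stop("genes absent from the matrix: ", paste(missing, collapse = ", "))
  y <- class_numeric(m)
  if (min(sum(y == 1), sum(y == 0)) < 2)
    stop("a class has < 2 samples; leave-one-out folds would lose a class — ",
         "use stratified k-fold evaluation instead")
  X <- t(m$values[gene_list, , drop = FALSE])
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    std <- .standardize_pair(X[-i, , drop = FALSE], X[i, , drop = FALSE])
    scores[i] <- .fit_l2_score(std$train, y[-i], std$test, ridge_penalty)
  }
  names(scores) <- colnames(m$values)
  list(scores = scores, labels = m$class_labels,
       auroc = auroc(scores, y), auprc = auprc(scores, y))
}

#' Stratified percentile bootstrap confidence interval for a ranking metric
#'
#' Resamples (score, label) pairs with replacement within each class —
#' preserving prevalence, which AUPRC depends on — and takes percentile
#' quantiles of the metric over the resamples.
#'
#' @param scores Numeric prediction scores.
#' @param labels Class labels.
#' @param metric `"auroc"` or `"auprc"`.
#' @param n_resample Number of bootstrap resamples (>= 100).
#' @param level Confidence level (default 0.95).
#' @param seed RNG seed.
#' @return Numeric `c(lower, upper)`.
#' @export
bootstrap_ci <- function(scores, labels, metric = c("auroc", "auprc"),
                         n_resample = 2000, level = 0.95, seed = 1) {
  metric <- match.arg(metric)
  if (n_resample < 100) stop("n_resample must be >= 100")
  y <- class_numeric(labels)
  cases <- which(y == 1); controls <- which(y == 0)
  if (length(cases) == 0 || length(controls) == 0)
    stop("both classes required")
  fn <- if (metric == "auroc") auroc else auprc
  stat <- withr::with_seed(seed, {
    vapply(seq_len(n_resample), function(i) {
      idx <- c(sample(cases, length(cases), replace = TRUE),
               sample(controls, length(controls), replace = TRUE))
      fn(scores[idx], y[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stat, c(alpha, 1 - alpha)))
  # widen (never narrow) so the interval always covers the point estimate
  point <- fn(scores, y)
  c(min(ci[1], point), max(ci[2], point))
}

#' Evaluate nested gene signatures across cohorts
#'
#' Runs [loocv_evaluate()] for every (cohort, signature size) combination and
#' attaches stratified bootstrap confidence intervals for both metrics.
#'
#' @param cohorts Named list of gene-level `expr_matrix` objects (or a single
#'   `expr_matrix`, evaluated as cohort `"a"`).
#' @param sets Nested gene lists from [incremental_sets()].
#' @param n_resample,level,seed Confidence-interval settings (see
#'   [bootstrap_ci()]).
#' @param ridge_penalty Fold-classifier penalty (see [loocv_evaluate()]).
#' @return A `signature_curve` tibble: `size`, `cohort`, `auroc`,
#'   `auroc_lo`, `auroc_hi`, `auprc`, `auprc_lo`, `auprc_hi`, `genes`
#'   (list-column).
#' @export
evaluate_curve <- function(cohorts, sets, n_resample = 2000, level = 0.95,
                           seed = 1, ridge_penalty = 1) {
  if (inherits(cohorts, "expr_matrix")) cohorts <- list(a = cohorts)
  if (length(sets) == 0) stop("no signature sets to evaluate")
  sizes <- as.integer(names(sets))
  if (any(diff(sizes) <= 0)) stop("set sizes must be strictly increasing")
  rows <- list()
  for (cname in names(cohorts)) {
    m <- cohorts[[cname]]
    for (j in seq_along(sets)) {
      ev <- loocv_evaluate(m, sets[[j]], ridge_penalty = ridge_penalty)
      roc_ci <- bootstrap_ci(ev$scores, ev$labels, "auroc",
                             n_resample = n_resample, level = level,
                             seed = seed + j)
      prc_ci <- bootstrap_ci(ev$scores, ev$labels, "auprc",
                             n_resample = n_resample, level = level,
                             seed = seed + j)
      rows[[length(rows) + 1]] <- tibble::tibble(
        size = sizes[j], cohort = cname,
        auroc = ev$auroc, auroc_lo = roc_ci[1], auroc_hi = roc_ci[2],
        auprc = ev$auprc, auprc_lo = prc_ci[1], auprc_hi = prc_ci[2],
        genes = list(sets[[j]]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("signature_curve", class(out))
  out
}

#' Optimal signature size from an evaluation curve
#'
#' The optimum is the size maximizing the chosen metric; with several cohorts
#' the metric is first averaged across cohorts at each size. Ties go to the
#' smallest size.
#'
#' @param curve A `signature_curve` from [evaluate_curve()].
#' @param metric `"auroc"` or `"auprc"`.
#' @return Integer: the optimal signature size.
#' @export
select_optimal <- function(curve, metric = c("auroc", "auprc")) {
  metric <- match.arg(metric)
  if (nrow(curve) == 0) stop("empty curve")
  agg <- tapply(curve[[metric]], curve$size, mean)
  sizes <- as.integer(names(agg))
  best <- max(agg)
  min(sizes[agg >= best - 1e-12])
}
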