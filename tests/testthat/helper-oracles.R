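# Independent brute-force oracles used to check the package's primitives.
# These deliberately use naive loops / direct enumeration, never the
# implementation's code path.

# AUROC as explicit concordant-pair counting over all case-control pairs
bf_auroc <- function(scores, labels) {
  y <- as.integer(labels == "case" | labels == 1 | labels == TRUE)
  cases <- scores[y == 1]
  controls <- scores[y == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# AUPRC by direct step integration over distinct thresholds, computing
# precision and recall by counting at each threshold
bf_auprc <- function(scores, labels) {
  y <- as.integer(labels == "case" | labels == 1 | labels == TRUE)
  npos <- sum(y)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prev_recall <- 0
  for (t in thresholds) {
    called <- scores >= t
    tp <- sum(called & y == 1)
    precision <- tp / sum(called)
    recall <- tp / npos
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  ap
}

# Benjamini-Hochberg step-up: q_(i) = min over j >= i of p_(j) * n / j
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(1, min(p[ord][i:n] * n / (i:n)))
  }
  q <- numeric(n)
  q[ord] <- q_sorted
  q
}

# Upper-tail hypergeometric P(X >= x) by direct enumeration of the tail
bf_hyper_tail <- function(x, set_size, universe_size, n_hits) {
  upper <- min(set_size, n_hits)
  if (x > upper) return(0)
  sum(vapply(x:upper, function(i) {
    choose(set_size, i) * choose(universe_size - set_size, n_hits - i) /
      choose(universe_size, n_hits)
  }, numeric(1)))
}

# small deterministic gene-level expression fixture
tiny_gene_em <- function(n_case = 6, n_control = 6, n_genes = 10, seed = 42,
                         informative = integer(), effect = 3) {
  withr::with_seed(seed, {
    v <- matrix(rnorm(n_genes * (n_case + n_control)), n_genes)
    for (g in informative) v[g, seq_len(n_case)] <- v[g, seq_len(n_case)] + effect
    rownames(v) <- sprintf("g%02d", seq_len(n_genes))
    colnames(v) <- sprintf("s%02d", seq_len(ncol(v)))
    expr_matrix(v, rep(c("case", "control"), c(n_case, n_control)),
                level = "gene")
  })
}
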