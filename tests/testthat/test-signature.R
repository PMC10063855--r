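test_that("common genes intersect top-k prefixes with the documented order", {
  cg <- common_genes(c("g1", "g2", "g3", "g4"), c("g3", "g1", "g5", "g2"),
                     top_k = 3)
  expect_identical(cg$gene_id, c("g1", "g3"))  # rank sums 3 and 4
  expect_equal(cg$rank_a, c(1, 3))
  expect_equal(cg$rank_b, c(2, 1))

  ranked <- sprintf("g%04d", 1:2000)
  cg2 <- common_genes(ranked, ranked, top_k = 1500)
  expect_identical(cg2$gene_id, ranked[1:1500])

  expect_warning(cg3 <- common_genes(c("a", "b"), c("c", "d"), top_k = 2),
                 "no genes common")
  expect_equal(nrow(cg3), 0)
  expect_error(common_genes(c("a", "a"), c("b", "c")), "duplicate")
})

test_that("incremental sets are nested prefixes at the requested sizes", {
  genes <- sprintf("g%03d", 1:25)
  sets <- incremental_sets(genes, step = 10)
  expect_identical(names(sets), c("10", "20", "25"))
  expect_identical(sets[["20"]][1:10], sets[["10"]])

  sets2 <- incremental_sets(sprintf("g%03d", 1:185),
                            explicit_sizes = c(12, 21, 48, 69, 92, 185))
  expect_identical(names(sets2), c("12", "21", "48", "69", "92", "185"))
  for (i in 2:6) {
    k <- length(sets2[[i - 1]])
    expect_identical(sets2[[i]][seq_len(k)], sets2[[i - 1]])
  }

  expect_identical(incremental_sets(genes, step = 40), list("25" = genes))
  expect_error(incremental_sets(genes, explicit_sizes = c(10, 30)), "exceeds")
  expect_error(incremental_sets(character()), "empty")
})

test_that("AUROC matches brute-force concordant-pair counting", {
  expect_equal(auroc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(0.5, 6), rep(c(1, 0), 3)), 0.5)
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)), 0.75)
  withr::with_seed(7, {
    for (i in 1:300) {
      n <- sample(2:12, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- sample(seq(0, 1, 0.125), n, replace = TRUE)  # induces ties
      expect_equal(auroc(s, y), bf_auroc(s, y), tolerance = 1e-12)
    }
  })
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUPRC matches direct precision-recall step integration", {
  expect_equal(auprc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 0, 1, 0)),
               0.5 * 1 + 0.5 * (2 / 3), tolerance = 1e-12)
  # constant scorer returns the prevalence exactly
  expect_equal(auprc(rep(1, 10), rep(c(1, 0, 0, 0, 0), 2)), 0.2)
  withr::with_seed(8, {
    for (i in 1:300) {
      n <- sample(2:12, 1)
      y <- c(1, sample(0:1, n - 1, replace = TRUE))
      s <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      expect_equal(auprc(s, y), bf_auprc(s, y), tolerance = 1e-12)
    }
  })
  expect_error(auprc(1:3, c(0, 0, 0)), "case")
})

test_that("cross-check: AUROC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    for (i in 1:20) {
      y <- sample(0:1, 30, replace = TRUE)
      if (length(unique(y)) < 2) next
      s <- rnorm(30)
      ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
      expect_equal(auroc(s, y), ref, tolerance = 1e-12)
    }
  })
})

test_that("LOOCV pools out-of-fold scores deterministically", {
  em <- tiny_gene_em(10, 10, n_genes = 8, seed = 3, informative = 1,
                     effect = 8)
  ev <- loocv_evaluate(em, "g01")
  expect_equal(ev$auroc, 1.0)
  expect_length(ev$scores, 20)
  ev2 <- loocv_evaluate(em, "g01")
  expect_identical(ev$scores, ev2$scores)

  ev3 <- loocv_evaluate(em, rownames(em$values))
  expect_gte(ev3$auroc, 0.9)

  expect_error(loocv_evaluate(em, character()), ">= 1 gene")
  expect_error(loocv_evaluate(em, "nope"), "absent")
  em_bad <- tiny_gene_em(1, 8, n_genes = 5, seed = 2)
  expect_error(loocv_evaluate(em_bad, "g01"), "stratified k-fold")
})

test_that("LOOCV on permuted labels is near chance", {
  em <- tiny_gene_em(15, 15, n_genes = 12, seed = 19, informative = 1:3)
  aucs <- vapply(1:8, function(s) {
    perm <- withr::with_seed(s, sample(em$class_labels))
    em_perm <- expr_matrix(em$values, perm, level = "gene")
    loocv_evaluate(em_perm, rownames(em$values)[1:5])$auroc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.2)
})

test_that("bootstrap confidence intervals behave as percentiles", {
  y <- rep(c(1, 0), each = 15)
  perfect <- c(rnorm(15, 10), rnorm(15, -10))
  ci <- bootstrap_ci(perfect, y, "auroc", n_resample = 200, seed = 1)
  expect_equal(ci, c(1, 1))

  withr::with_seed(5, {
    s <- rnorm(30, mean = y)
    for (metric in c("auroc", "auprc")) {
      point <- if (metric == "auroc") auroc(s, y) else auprc(s, y)
      ci <- bootstrap_ci(s, y, metric, n_resample = 300, seed = 2)
      expect_lte(ci[1], point)
      expect_gte(ci[2], point)
      expect_true(all(ci >= 0 & ci <= 1))
    }
  })
  expect_error(bootstrap_ci(perfect, y, "auroc", n_resample = 50), "100")

  # interval width shrinks with sample size under the same generator
  width <- function(n, seed) {
    withr::with_seed(seed, {
      yy <- rep(c(1, 0), each = n / 2)
      ss <- rnorm(n, mean = 0.8 * yy)
      ci <- bootstrap_ci(ss, yy, "auroc", n_resample = 400, seed = 99)
      diff(ci)
    })
  }
  expect_lt(width(500, 4), width(50, 4))
})

test_that("curve evaluation and optimum selection follow the tie rule", {
  em <- tiny_gene_em(12, 12, n_genes = 20, seed = 37, informative = 1:4,
                     effect = 1.5)
  sets <- incremental_sets(rownames(em$values), step = 8)
  curve <- evaluate_curve(em, sets, n_resample = 150, seed = 6)
  expect_equal(nrow(curve), 3)
  expect_true(all(curve$auroc >= 0 & curve$auroc <= 1))
  expect_true(all(curve$auroc_lo <= curve$auroc & curve$auroc <= curve$auroc_hi))
  expect_true(all(curve$auprc_lo <= curve$auprc & curve$auprc <= curve$auprc_hi))

  fake <- curve
  fake$auroc <- c(0.9, 0.9, 0.8)
  expect_equal(select_optimal(fake, "auroc"), 8)  # tie -> smallest size
  single <- curve[2, ]
  expect_equal(select_optimal(single, "auroc"), single$size)
  expect_error(select_optimal(curve[0, ], "auroc"), "empty")
})
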