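test_that("generated cohorts have the specified shape and truth record", {
  spec <- cohort_spec(70, 26, n_genes = 300, n_informative = 25, seed = 3)
  co <- generate_cohort(spec)
  expect_equal(ncol(co$matrix$values), 96)
  expect_equal(sum(co$matrix$class_labels == "case") / 96, 70 / 96)
  expect_equal(nrow(co$matrix$values), nrow(co$annotation))
  expect_length(co$truth$informative_genes, 25)
  expect_true(all(co$truth$informative_genes %in% co$truth$gene_ids))
  # every probe maps to exactly one gene, multiplicity within 1..3
  mult <- table(co$annotation$gene_id)
  expect_equal(length(mult), 300)
  expect_true(all(mult >= 1 & mult <= 3))
  # every sample labeled exactly once, classes and batches disjoint domains
  expect_equal(sort(names(co$truth$class_labels)), sort(colnames(co$matrix$values)))
  expect_length(intersect(unique(co$matrix$class_labels),
                          unique(co$matrix$batch)), 0)
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(10, 5, n_genes = 20, n_informative = 30),
               "n_informative")
  expect_error(cohort_spec(0, 5), "positive")
  expect_error(cohort_spec(5, -1), "positive")
})

test_that("zero effect size yields symmetric classes", {
  spec <- cohort_spec(100, 100, n_genes = 150, n_informative = 20,
                      effect_size = 0, noise_sd = 1, n_batches = 1,
                      batch_shift_sd = 0, seed = 11)
  co <- generate_cohort(spec)
  y <- class_numeric(co$matrix)
  diff <- rowMeans(co$matrix$values[, y == 1]) -
    rowMeans(co$matrix$values[, y == 0])
  # per-probe SE of the mean difference ~ sqrt(2 * (1 + 0.0625) / 100)
  se <- sqrt(2 * (1 + 0.25^2) / 100)
  expect_true(all(abs(diff) < 4 * se))
})

test_that("planted effects are recovered from the emitted matrix", {
  spec <- cohort_spec(200, 200, n_genes = 120, n_informative = 15,
                      effect_size = 2, noise_sd = 0.5, n_batches = 1,
                      batch_shift_sd = 0, seed = 7,
                      probe_multiplicity = c("1" = 1))
  co <- generate_cohort(spec)
  y <- class_numeric(co$matrix)
  genes <- sub("_p1$", "", rownames(co$matrix$values))
  diff <- rowMeans(co$matrix$values[, y == 1]) -
    rowMeans(co$matrix$values[, y == 0])
  se <- sqrt(2 * (0.5^2 + (0.25 * 0.5)^2) / 200)
  for (g in co$truth$informative_genes) {
    expected <- co$truth$effect_sign[[g]] * 2
    expect_lt(abs(diff[genes == g] - expected), 3 * se)
  }
})

test_that("cohort generation is deterministic and file output byte-identical", {
  spec <- cohort_spec(10, 8, n_genes = 40, n_informative = 5, seed = 99)
  co1 <- generate_cohort(spec)
  co2 <- generate_cohort(spec)
  expect_identical(co1$matrix$values, co2$matrix$values)
  expect_identical(co1$truth, co2$truth)
  f1 <- tempfile(); f2 <- tempfile()
  write_expression_tsv(co1$matrix, f1)
  write_expression_tsv(co2$matrix, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("expression TSV and labels round-trip through files", {
  spec <- cohort_spec(6, 6, n_genes = 30, n_informative = 4, seed = 5)
  co <- generate_cohort(spec)
  ef <- tempfile(); lf <- tempfile()
  write_expression_tsv(co$matrix, ef, lf)
  back <- read_expression_tsv(ef, lf)
  expect_equal(back$values, co$matrix$values)
  expect_identical(back$class_labels, co$matrix$class_labels)
  expect_identical(back$batch, co$matrix$batch)
  expect_identical(back$level, "probe")
})

test_that("paired cohorts share exactly the requested informative genes", {
  base <- function(seed) cohort_spec(20, 15, n_genes = 200, n_informative = 50,
                                     seed = seed)
  for (shared in c(0L, 30L, 50L)) {
    pair <- generate_paired_cohorts(base(1), base(2), shared)
    overlap <- intersect(pair$a$truth$informative_genes,
                         pair$b$truth$informative_genes)
    expect_length(overlap, shared)
  }
  pair <- generate_paired_cohorts(base(1), base(2), 50)
  expect_identical(pair$a$truth$informative_genes,
                   pair$b$truth$informative_genes)
  expect_error(generate_paired_cohorts(base(1), base(2), 51), "shared")
  spec_other <- cohort_spec(20, 15, n_genes = 100, n_informative = 10, seed = 3)
  expect_error(generate_paired_cohorts(base(1), spec_other, 5), "incompatible")
})

test_that("gene-set generation plants the requested set", {
  universe <- sprintf("G%03d", 1:100)
  planted <- universe[1:20]
  gsc <- generate_gene_sets(universe, n_sets = 1, planted_set = planted,
                            seed = 2)
  expect_length(gsc$sets, 1)
  expect_setequal(gsc$sets$PLANTED_SET, planted)
  gsc2 <- generate_gene_sets(universe, n_sets = 10, planted_set = planted,
                             size_range = c(5, 30), seed = 2)
  expect_length(gsc2$sets, 10)
  expect_true(all(unlist(gsc2$sets) %in% universe))
  expect_error(generate_gene_sets(universe, 5, planted_set = character()),
               "non-empty")
  expect_error(generate_gene_sets(universe, 5, size_range = c(10, 200),
                                  planted_set = planted), "universe")
})

test_that("generated networks plant hubs in a simple graph", {
  universe <- sprintf("G%03d", 1:150)
  hubs <- c("G005", "G050", "G100")
  g <- generate_network(universe, planted_hubs = hubs, hub_degree = 12,
                        background_degree_mean = 1, seed = 8)
  expect_true(all(igraph::degree(g, hubs) >= 12))
  expect_true(igraph::is_simple(g))
  # with sparse background only the planted nodes reach the hub cutoff
  expect_setequal(find_hubs(g, 10), hubs)
  expect_error(generate_network(universe, hub_degree = 200), "universe")
})

test_that("emitted SIF re-parses to the same degree sequence", {
  universe <- sprintf("N%02d", 1:40)
  g <- generate_network(universe, planted_hubs = "N01", hub_degree = 10,
                        seed = 4)
  f <- tempfile(fileext = ".sif")
  write_sif(g, f)
  g2 <- read_sif(f)
  d1 <- igraph::degree(g)
  d1 <- d1[d1 > 0]  # isolated nodes cannot appear in an edge list
  d2 <- igraph::degree(g2)
  expect_setequal(names(d2), names(d1))
  expect_equal(d2[names(d1)], d1)
})
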