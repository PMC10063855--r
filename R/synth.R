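#' Specification of a synthetic cohort
#'
#' Describes one synthetic whole-blood expression cohort with a planted set
#' of class-informative genes. Defaults mirror the structure of the two
#' public pediatric acute hypoxemic respiratory failure cohorts the package
#' targets: unbalanced case/control mixes, a few thousand genes measured by
#' one to three probes each, and additive batch structure.
#'
#' @param n_cases Number of case samples (severe hypoxemia analog).
#' @param n_controls Number of control samples (mild).
#' @param n_genes Number of distinct genes.
#' @param n_informative Number of class-informative genes.
#' @param effect_size Mean log2-expression shift applied to cases for each
#'   informative gene. The shift sign is drawn per gene (+1/-1, equal
#'   probability) and recorded in the truth.
#' @param noise_sd Within-class standard deviation of the gene-level signal
#'   on the log2 scale. Probe-level noise is `0.25 * noise_sd` on top.
#' @param probe_multiplicity Named numeric vector of probabilities over
#'   probe counts per gene; names are the counts. Default: 70% of genes have
#'   one probe, 25% two, 5% three.
#' @param n_batches Number of processing batches samples are split over.
#' @param batch_shift_sd Standard deviation of the per-batch additive offset
#'   (constant across genes within a batch).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   expression (typical microarray log-intensities sit around 7).
#' @param seed RNG seed making the cohort fully reproducible.
#' @param prefix Sample/feature ID prefix (distinguishes paired cohorts).
#'
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_cases, n_controls, n_genes = 5000,
                        n_informative = 50, effect_size = 0.75, noise_sd = 1,
                        probe_multiplicity = c("1" = 0.70, "2" = 0.25, "3" = 0.05),
                        n_batches = 2, batch_shift_sd = 0.5,
                        baseline_mean = 7, baseline_sd = 1.5,
                        seed = 1, prefix = "S") {
  if (n_cases < 1 || n_controls < 1)
    stop("sample counts must be positive")
  if (n_informative > n_genes)
    stop("n_informative must not exceed n_genes")
  if (abs(sum(probe_multiplicity) - 1) > 1e-8 || any(probe_multiplicity < 0))
    stop("probe_multiplicity must be a probability vector")
  if (is.null(names(probe_multiplicity)))
    stop("probe_multiplicity must be named by probe count")
  if (n_batches < 1) stop("n_batches must be >= 1")
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         n_genes = as.integer(n_genes), n_informative = as.integer(n_informative),
         effect_size = effect_size, noise_sd = noise_sd,
         probe_multiplicity = probe_multiplicity,
         n_batches = as.integer(n_batches), batch_shift_sd = batch_shift_sd,
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         seed = as.integer(seed), prefix = prefix),
    class = "cohort_spec"
  )
}

.gene_ids <- function(n, width = max(5, nchar(n))) sprintf("G%0*d", width, seq_len(n))

#' Generate one synthetic cohort
#'
#' The generative model works on the log2 scale. Each gene g has a baseline
#' drawn once from Normal(baseline_mean, baseline_sd). For sample i the
#' gene-level signal is Normal(baseline_g + shift, noise_sd), where shift is
#' `sign_g * effect_size` for informative genes in cases and 0 otherwise.
#' Each probe of a gene observes the gene signal plus independent
#' Normal(0, 0.25 * noise_sd) probe noise. Each batch contributes one
#' additive offset drawn from Normal(0, batch_shift_sd), shared by all genes
#' of all samples in the batch. Samples are assigned to batches round-robin
#' within each class so batches stay class-balanced.
#'
#' @param spec A [cohort_spec()].
#' @param informative_genes Optional character vector forcing which gene IDs
#'   are informative (used by [generate_paired_cohorts()]); sampled when `NULL`.
#' @return A list with `matrix` (probe-level `expr_matrix`), `truth` (see
#'   below) and `annotation` (probe_id/gene_id data.frame). `truth` is a list
#'   with `informative_genes`, `effect_sign` (named +1/-1), `class_labels`,
#'   `batch` and `gene_ids`.
#' @export
generate_cohort <- function(spec, informative_genes = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, .generate_cohort_impl(spec, informative_genes))
}

.generate_cohort_impl <- function(spec, informative_genes) {
  n <- spec$n_cases + spec$n_controls
  genes <- .gene_ids(spec$n_genes)
  if (is.null(informative_genes)) {
    informative_genes <- sort(sample(genes, spec$n_informative))
  } else {
    if (!all(informative_genes %in% genes))
      stop("informative_genes outside the gene universe")
    if (length(informative_genes) != spec$n_informative)
      stop("length(informative_genes) must equal n_informative")
    informative_genes <- sort(informative_genes)
  }
  sign <- sample(c(-1, 1), length(informative_genes), replace = TRUE)
  names(sign) <- informative_genes

  class_labels <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
  sample_ids <- sprintf("%s%03d", spec$prefix, seq_len(n))
  # round-robin within class keeps batches class-balanced
  batch <- integer(n)
  batch[class_labels == "case"] <- (seq_len(spec$n_cases) - 1) %% spec$n_batches + 1
  batch[class_labels == "control"] <- (seq_len(spec$n_controls) - 1) %% spec$n_batches + 1
  batch <- sprintf("b%d", batch)

  baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
  shift <- numeric(spec$n_genes)
  names(baseline) <- genes
  inf_idx <- match(informative_genes, genes)
  shift[inf_idx] <- sign * spec$effect_size

  # gene-level signal: genes x samples
  signal <- matrix(stats::rnorm(spec$n_genes * n, sd = spec$noise_sd),
                   spec$n_genes, n) + baseline
  is_case <- class_labels == "case"
  signal[, is_case] <- signal[, is_case] + shift

  n_probes <- sample(as.integer(names(spec$probe_multiplicity)), spec$n_genes,
                     replace = TRUE, prob = spec$probe_multiplicity)
  probe_gene <- rep(seq_len(spec$n_genes), n_probes)
  probe_ids <- sprintf("%s_p%d", genes[probe_gene],
                       unlist(lapply(n_probes, seq_len), use.names = FALSE))
  values <- signal[probe_gene, , drop = FALSE] +
    matrix(stats::rnorm(length(probe_gene) * n, sd = 0.25 * spec$noise_sd),
           length(probe_gene), n)

  batch_offset <- stats::rnorm(spec$n_batches, 0, spec$batch_shift_sd)
  values <- values + rep(batch_offset[as.integer(sub("^b", "", batch))],
                         each = nrow(values))
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids

  m <- expr_matrix(values, class_labels, batch = batch, level = "probe")
  truth <- list(informative_genes = informative_genes, effect_sign = sign,
                class_labels = stats::setNames(class_labels, sample_ids),
                batch = stats::setNames(batch, sample_ids), gene_ids = genes)
  annotation <- data.frame(probe_id = probe_ids, gene_id = genes[probe_gene],
                           stringsAsFactors = FALSE)
  list(matrix = m, truth = truth, annotation = annotation)
}

#' Generate twin cohorts with a controlled overlap of informative genes
#'
#' Both cohorts share the same gene universe (the larger of the two
#' `n_genes`; specs must agree). Exactly `shared_informative` gene IDs are
#' informative in both cohorts; the remaining informative genes of each
#' cohort are disjoint between cohorts.
#'
#' @param spec_a,spec_b [cohort_spec()]s for the two cohorts.
#' @param shared_informative Number of informative genes common to both.
#' @return A list with elements `a` and `b`, each as returned by
#'   [generate_cohort()].
#' @export
generate_paired_cohorts <- function(spec_a, spec_b, shared_informative = 30) {
  stopifnot(inherits(spec_a, "cohort_spec"), inherits(spec_b, "cohort_spec"))
  if (spec_a$n_genes != spec_b$n_genes)
    stop("incompatible gene universes: specs must share n_genes")
  if (shared_informative > min(spec_a$n_informative, spec_b$n_informative))
    stop("shared_informative exceeds a cohort's n_informative")
  genes <- .gene_ids(spec_a$n_genes)
  picks <- withr::with_seed(spec_a$seed + spec_b$seed, {
    n_needed <- shared_informative +
      (spec_a$n_informative - shared_informative) +
      (spec_b$n_informative - shared_informative)
    pool <- sample(genes, n_needed)
    shared <- pool[seq_len(shared_informative)]
    rest <- setdiff(pool, shared)
    only_a <- rest[seq_len(spec_a$n_informative - shared_informative)]
    only_b <- setdiff(rest, only_a)
    list(a = sort(c(shared, only_a)), b = sort(c(shared, only_b)))
  })
  list(a = generate_cohort(spec_a, informative_genes = picks$a),
       b = generate_cohort(spec_b, informative_genes = picks$b))
}

#' Generate a gene-set collection containing one planted set
#'
#' @param universe Character vector of gene IDs.
#' @param n_sets Total number of sets, including the planted one.
#' @param size_range Length-2 integer range of background set sizes.
#' @param planted_set Gene IDs forming the planted set (must be non-empty and
#'   inside `universe`).
#' @param seed RNG seed.
#' @return A `gene_set_collection` (see [read_gmt()]); the planted set is
#'   named `"PLANTED_SET"`.
#' @export
generate_gene_sets <- function(universe, n_sets = 20, size_range = c(10, 50),
                               planted_set, seed = 1) {
  if (length(planted_set) == 0) stop("planted_set must be non-empty")
  if (!all(planted_set %in% universe)) stop("planted_set not inside universe")
  if (max(size_range) > length(universe))
    stop("size_range exceeds the universe size")
  if (n_sets < 1) stop("n_sets must be >= 1")
  sets <- withr::with_seed(seed, {
    bg <- list()
    if (n_sets > 1) {
      sizes <- sample(seq(size_range[1], size_range[2]), n_sets - 1,
                      replace = TRUE)
      bg <- lapply(sizes, function(k) sort(sample(universe, k)))
      names(bg) <- sprintf("RANDOM_SET_%03d", seq_along(bg))
    }
    c(list(PLANTED_SET = sort(unique(planted_set))), bg)
  })
  desc <- stats::setNames(
    c("planted informative gene set",
      rep("random background set", length(sets) - 1)), names(sets))
  gene_set_collection(sets, desc)
}

#' Generate an interaction network with planted hub nodes
#'
#' Background edges come from an Erdős–Rényi draw with per-node expected
#' degree `background_degree_mean`; each planted hub then receives extra
#' edges to randomly chosen other nodes until its degree reaches
#' `hub_degree`. The result is a simple undirected graph.
#'
#' @param universe Character vector of node (gene) IDs.
#' @param planted_hubs Node IDs to promote to hubs (subset of `universe`).
#' @param hub_degree Minimum degree each planted hub must reach (>= 1).
#' @param background_degree_mean Expected background degree per node.
#' @param seed RNG seed.
#' @return An [igraph::igraph] object with vertex names from `universe`.
#' @export
generate_network <- function(universe, planted_hubs = character(),
                             hub_degree = 10, background_degree_mean = 1,
                             seed = 1) {
  if (hub_degree < 1) stop("hub_degree must be >= 1")
  if (!all(planted_hubs %in% universe)) stop("planted_hubs not inside universe")
  n <- length(universe)
  if (hub_degree > n - 1) stop("hub_degree exceeds universe size - 1")
  withr::with_seed(seed, {
    p <- min(1, background_degree_mean / (n - 1))
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- universe
    for (hub in planted_hubs) {
      need <- hub_degree - igraph::degree(g, hub)
      if (need > 0) {
        candidates <- setdiff(universe,
                              c(hub, igraph::V(g)$name[
                                igraph::as_adj_list(g)[[hub]]]))
        new <- sample(candidates, need)
        g <- igraph::add_edges(g, as.vector(rbind(hub, new)))
      }
    }
    igraph::simplify(g)
  })
}

#' Write the synthetic truth record as JSON
#'
#' @param truth Truth list from [generate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(informative_genes = truth$informative_genes,
         effect_sign = as.list(truth$effect_sign),
         class_labels = as.list(truth$class_labels),
         batch = as.list(truth$batch)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
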