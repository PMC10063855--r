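# Stage seeds are derived deterministically from the single global seed so
# that every stage has an independent stream but the whole bundle is
# reproducible from one number.
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  ((as.double(seed) %% 65011) * 48271 + h * 131) %% 2147483629 + 1
}

# stable content hash (31-base polynomial, mod 2^31-1) of a string;
# avoids a digest dependency
.content_hash <- function(x) {
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.config_template <- list(
  seed = list(type = "integer", required = TRUE),
  shared_informative = list(type = "integer", default = 30L),
  cohorts = list(type = "block"),
  preprocess = list(type = "block", keys = list(
    quantile_normalize = list(type = "logical", default = TRUE),
    batch_correct = list(type = "logical", default = TRUE))),
  stability = list(type = "block", keys = list(
    n_boot = list(type = "integer", default = 100L),
    score_threshold = list(type = "numeric", default = 0.6),
    penalty_strength = list(type = "numeric", default = 1),
    coef_epsilon = list(type = "numeric", default = 1e-8),
    stratified = list(type = "logical", default = TRUE))),
  signature = list(type = "block", keys = list(
    top_k = list(type = "integer", default = 1500L),
    step = list(type = "integer", default = 10L),
    sizes = list(type = "integer_vector", default = NULL),
    metric = list(type = "character", default = "auroc"),
    ci_resamples = list(type = "integer", default = 2000L))),
  enrich = list(type = "block", keys = list(
    gmt = list(type = "character", default = NULL))),
  network = list(type = "block", keys = list(
    sif = list(type = "character", default = NULL),
    min_degree = list(type = "integer", default = 10L)))
)

.cohort_synth_keys <- c("n_cases", "n_controls", "n_genes", "n_informative",
                        "effect_size", "noise_sd", "n_batches",
                        "batch_shift_sd")
.cohort_path_keys <- c("expr", "labels", "annotation")

.check_scalar <- function(value, type, key, errors) {
  ok <- switch(type,
    integer = is.numeric(value) && length(value) == 1 &&
      abs(value - round(value)) < 1e-9,
    numeric = is.numeric(value) && length(value) == 1,
    logical = is.logical(value) && length(value) == 1,
    character = is.character(value) && length(value) == 1,
    integer_vector = is.numeric(value),
    FALSE)
  if (!ok) c(errors, sprintf("key '%s': expected %s", key, type)) else errors
}

#' Validate and normalize a pipeline run configuration
#'
#' Accepts a YAML file path or an already-parsed list. Unknown keys are
#' rejected; all type mismatches are reported together, not one at a time;
#' defaults (100 bootstrap iterations, 0.6 stability threshold, top-1500
#' intersection, 10-gene steps, hub degree 10) are filled in and echoed in
#' the returned object. A config validates only if it describes two cohorts,
#' each either synthetic (`n_cases`/`n_controls`/...) or file-backed
#' (`expr`/`labels` and optional `annotation`).
#'
#' @param config YAML path or list.
#' @return A normalized list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML mapping")
  errors <- character()
  unknown <- setdiff(names(config), names(.config_template))
  if (length(unknown) > 0)
    errors <- c(errors, paste0("unknown key '", unknown, "'"))
  if (is.null(config$seed)) {
    errors <- c(errors, "key 'seed' is mandatory")
  } else {
    errors <- .check_scalar(config$seed, "integer", "seed", errors)
  }
  out <- list(seed = if (is.numeric(config$seed)) as.integer(config$seed) else NA_integer_)
  sh <- config$shared_informative
  if (!is.null(sh)) errors <- .check_scalar(sh, "integer", "shared_informative", errors)
  out$shared_informative <- if (is.null(sh)) 30L else as.integer(sh)

  # block keys with defaults
  for (blk in c("preprocess", "stability", "signature", "enrich", "network")) {
    tmpl <- .config_template[[blk]]$keys
    given <- config[[blk]]
    if (!is.null(given) && !is.list(given)) {
      errors <- c(errors, sprintf("key '%s': expected a mapping", blk))
      given <- list()
    }
    unknown <- setdiff(names(given), names(tmpl))
    if (length(unknown) > 0)
      errors <- c(errors, paste0("unknown key '", blk, ".", unknown, "'"))
    blk_out <- list()
    for (key in names(tmpl)) {
      val <- given[[key]]
      if (is.null(val)) {
        blk_out[key] <- list(tmpl[[key]]$default)
      } else {
        errors <- .check_scalar(val, tmpl[[key]]$type,
                                paste0(blk, ".", key), errors)
        if (tmpl[[key]]$type %in% c("integer", "integer_vector") &&
            is.numeric(val)) val <- as.integer(val)
        blk_out[[key]] <- val
      }
    }
    out[[blk]] <- blk_out
  }

  # cohorts
  cohorts <- config$cohorts
  if (is.null(cohorts) || !is.list(cohorts)) {
    errors <- c(errors, "key 'cohorts': must define cohorts 'a' and 'b'")
  } else {
    missing <- setdiff(c("a", "b"), names(cohorts))
    if (length(missing) > 0)
      errors <- c(errors, paste0("key 'cohorts': cohort '", missing,
                                 "' is missing"))
    unknown <- setdiff(names(cohorts), c("a", "b"))
    if (length(unknown) > 0)
      errors <- c(errors, paste0("unknown key 'cohorts.", unknown, "'"))
    out$cohorts <- list()
    for (cn in intersect(c("a", "b"), names(cohorts))) {
      cc <- cohorts[[cn]]
      if (!is.list(cc)) {
        errors <- c(errors, sprintf("key 'cohorts.%s': expected a mapping", cn))
        next
      }
      unknown <- setdiff(names(cc),
                         c(.cohort_synth_keys, .cohort_path_keys, "mode"))
      if (length(unknown) > 0)
        errors <- c(errors, paste0("unknown key 'cohorts.", cn, ".", unknown, "'"))
      cc$mode <- NULL  # re-validating an already-normalized config
      is_path <- any(.cohort_path_keys %in% names(cc))
      if (is_path) {
        for (key in c("expr", "labels")) {
          if (is.null(cc[[key]])) {
            errors <- c(errors, sprintf("key 'cohorts.%s.%s' is required for file-backed cohorts", cn, key))
          } else if (!file.exists(cc[[key]])) {
            errors <- c(errors, sprintf("cohorts.%s.%s: file not found: %s", cn, key, cc[[key]]))
          }
        }
        if (!is.null(cc$annotation) && !file.exists(cc$annotation))
          errors <- c(errors, sprintf("cohorts.%s.annotation: file not found: %s", cn, cc$annotation))
        out$cohorts[[cn]] <- c(list(mode = "files"), cc)
      } else {
        for (key in c("n_cases", "n_controls")) {
          if (is.null(cc[[key]]))
            errors <- c(errors, sprintf("key 'cohorts.%s.%s' is required for synthetic cohorts", cn, key))
          else
            errors <- .check_scalar(cc[[key]], "integer",
                                    paste0("cohorts.", cn, ".", key), errors)
        }
        defaults <- list(n_genes = 5000L, n_informative = 50L,
                         effect_size = 0.75, noise_sd = 1, n_batches = 2L,
                         batch_shift_sd = 0.5)
        for (key in names(defaults))
          if (is.null(cc[[key]])) cc[[key]] <- defaults[[key]]
        out$cohorts[[cn]] <- c(list(mode = "synth"), cc)
      }
    }
  }
  if (!is.null(out$enrich$gmt) && !file.exists(out$enrich$gmt))
    errors <- c(errors, paste0("enrich.gmt: file not found: ", out$enrich$gmt))
  if (!is.null(out$network$sif) && !file.exists(out$network$sif))
    errors <- c(errors, paste0("network.sif: file not found: ", out$network$sif))
  if (length(errors) > 0)
    stop("invalid config:\n", paste0("  - ", errors, collapse = "\n"))
  class(out) <- c("run_config", "list")
  out
}

#' Write a normalized configuration back to YAML
#'
#' @param cfg A `run_config` from [validate_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  yaml::write_yaml(x, path)
  invisible(path)
}

.log_line <- function(con, stage, event, ...) {
  rec <- c(list(stage = stage, event = event), list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

.load_cohort <- function(cc, stage_seed, prefix) {
  if (cc$mode == "files") {
    m <- read_expression_tsv(cc$expr, cc$labels)
    ann <- if (!is.null(cc$annotation)) read_annotation_tsv(cc$annotation) else NULL
    list(matrix = m, truth = NULL, annotation = ann)
  } else {
    spec <- cohort_spec(n_cases = cc$n_cases, n_controls = cc$n_controls,
                        n_genes = cc$n_genes, n_informative = cc$n_informative,
                        effect_size = cc$effect_size, noise_sd = cc$noise_sd,
                        n_batches = cc$n_batches,
                        batch_shift_sd = cc$batch_shift_sd,
                        seed = stage_seed, prefix = prefix)
    generate_cohort(spec)
  }
}

#' Run the full signature-discovery pipeline
#'
#' Orchestrates every stage from one validated config and one global seed:
#' cohort generation (or loading), preprocessing (quantile normalization,
#' probe collapsing, per-batch standardization, the differential-expression
#' screen), bootstrap stability selection per cohort, top-k intersection and
#' incremental LOOCV evaluation, over-representation analysis of the optimal
#' signature, and network hub detection. All stage outputs land in
#' `out_dir`; `manifest.json` records the normalized config, its hash, seeds
#' and versions, and `timings.json` the per-stage wall times (kept separate
#' so all other outputs are byte-identical across re-runs with the same
#' config and seed).
#'
#' @param cfg A `run_config` (or YAML path / list, validated on entry).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the in-memory stage results: `cohorts`,
#'   `de`, `stability`, `common`, `curve`, `opt_size`, `signature`,
#'   `enrichment`, `hubs`, `manifest`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (!inherits(cfg, "run_config")) cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "pipeline.log.jsonl")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  seed <- cfg$seed

  # --- stage: cohorts -------------------------------------------------------
  .log_line(con, "cohorts", "start")
  cohorts <- tick("cohorts", {
    both_synth <- cfg$cohorts$a$mode == "synth" && cfg$cohorts$b$mode == "synth"
    if (both_synth) {
      sa <- cfg$cohorts$a; sb <- cfg$cohorts$b
      spec_a <- cohort_spec(sa$n_cases, sa$n_controls, sa$n_genes,
                            sa$n_informative, sa$effect_size, sa$noise_sd,
                            n_batches = sa$n_batches,
                            batch_shift_sd = sa$batch_shift_sd,
                            seed = .stage_seed(seed, "synth_a"), prefix = "A")
      spec_b <- cohort_spec(sb$n_cases, sb$n_controls, sb$n_genes,
                            sb$n_informative, sb$effect_size, sb$noise_sd,
                            n_batches = sb$n_batches,
                            batch_shift_sd = sb$batch_shift_sd,
                            seed = .stage_seed(seed, "synth_b"), prefix = "B")
      generate_paired_cohorts(spec_a, spec_b, cfg$shared_informative)
    } else {
      list(a = .load_cohort(cfg$cohorts$a, .stage_seed(seed, "synth_a"), "A"),
           b = .load_cohort(cfg$cohorts$b, .stage_seed(seed, "synth_b"), "B"))
    }
  })
  for (cn in c("a", "b")) {
    write_expression_tsv(cohorts[[cn]]$matrix,
                         file.path(out_dir, paste0("cohort_", cn, "_expr.tsv")),
                         file.path(out_dir, paste0("cohort_", cn, "_labels.tsv")))
    if (!is.null(cohorts[[cn]]$truth))
      write_truth_json(cohorts[[cn]]$truth,
                       file.path(out_dir, paste0("cohort_", cn, "_truth.json")))
  }

  # --- stage: preprocess ----------------------------------------------------
  .log_line(con, "preprocess", "start")
  de <- list()
  gene_level <- tick("preprocess", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(cn) {
      m <- cohorts[[cn]]$matrix
      if (cfg$preprocess$quantile_normalize) m <- quantile_normalize(m)
      if (m$level == "probe") {
        if (is.null(cohorts[[cn]]$annotation))
          stop("stage preprocess: probe-level cohort '", cn,
               "' has no probe annotation")
        m <- collapse_probes(m, cohorts[[cn]]$annotation)
      }
      if (cfg$preprocess$batch_correct) m <- batch_correct(m)
      m
    })
  })
  for (cn in c("a", "b")) {
    de[[cn]] <- differential_expression(gene_level[[cn]])
    utils::write.csv(de[[cn]],
                     file.path(out_dir, paste0("de_", cn, ".csv")),
                     row.names = FALSE, quote = FALSE)
    .log_line(con, "preprocess", "de_screen", cohort = cn,
              n_q_lt_0.05 = sum(de[[cn]]$q < 0.05))
  }

  # --- stage: stability -----------------------------------------------------
  .log_line(con, "stability", "start")
  stab <- tick("stability", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(cn) {
      scfg <- stability_config(
        n_boot = cfg$stability$n_boot,
        score_threshold = cfg$stability$score_threshold,
        penalty_strength = cfg$stability$penalty_strength,
        coef_epsilon = cfg$stability$coef_epsilon,
        stratified = cfg$stability$stratified,
        seed = .stage_seed(seed, paste0("stability_", cn)))
      stability_select(gene_level[[cn]], scfg)
    })
  })
  for (cn in c("a", "b")) {
    utils::write.csv(stab[[cn]],
                     file.path(out_dir, paste0("stability_", cn, ".csv")),
                     row.names = FALSE, quote = FALSE)
    .log_line(con, "stability", "done", cohort = cn,
              n_pass = sum(stab[[cn]]$pass),
              n_skipped = attr(stab[[cn]], "n_skipped"))
  }

  # --- stage: signature -----------------------------------------------------
  .log_line(con, "signature", "start")
  sig <- tick("signature", {
    common <- common_genes(rank_genes(stab$a), rank_genes(stab$b),
                           top_k = cfg$signature$top_k)
    if (nrow(common) == 0)
      stop("stage signature: no common genes in the top-k lists")
    sets <- incremental_sets(common, step = cfg$signature$step,
                             explicit_sizes = cfg$signature$sizes)
    curve <- evaluate_curve(
      list(a = gene_level$a, b = gene_level$b), sets,
      n_resample = cfg$signature$ci_resamples,
      seed = .stage_seed(seed, "signature_ci"))
    opt <- select_optimal(curve, metric = cfg$signature$metric)
    list(common = common, sets = sets, curve = curve, opt = opt)
  })
  utils::write.csv(sig$common, file.path(out_dir, "common_genes.csv"),
                   row.names = FALSE, quote = FALSE)
  curve_out <- sig$curve[, setdiff(names(sig$curve), "genes")]
  utils::write.csv(curve_out, file.path(out_dir, "signature_curve.csv"),
                   row.names = FALSE, quote = FALSE)
  for (nm in names(sig$sets))
    writeLines(sig$sets[[nm]],
               file.path(out_dir, sprintf("signature_size_%s.txt", nm)))
  signature <- sig$sets[[as.character(sig$opt)]]
  jsonlite::write_json(
    list(metric = cfg$signature$metric, optimal_size = sig$opt,
         genes = signature),
    file.path(out_dir, "optimum.json"), auto_unbox = TRUE, pretty = TRUE)
  .log_line(con, "signature", "done", n_common = nrow(sig$common),
            optimal_size = sig$opt)

  # --- stage: enrich --------------------------------------------------------
  .log_line(con, "enrich", "start")
  universe <- rownames(gene_level$a$values)
  enr <- tick("enrich", {
    gsc <- if (!is.null(cfg$enrich$gmt)) {
      read_gmt(cfg$enrich$gmt)
    } else if (!is.null(cohorts$a$truth)) {
      planted <- intersect(cohorts$a$truth$informative_genes,
                           cohorts$b$truth$informative_genes)
      generate_gene_sets(universe, n_sets = 20, planted_set = planted,
                         seed = .stage_seed(seed, "genesets"))
    } else {
      NULL
    }
    if (is.null(gsc)) {
      .log_line(con, "enrich", "skipped", reason = "no GMT given")
      NULL
    } else {
      list(gsc = gsc,
           table = ora(intersect(signature, universe), universe, gsc),
           counts = pathway_gene_counts(signature, gsc),
           overlap = set_overlap_edges(gsc))
    }
  })
  if (!is.null(enr)) {
    write_gmt(enr$gsc, file.path(out_dir, "gene_sets.gmt"))
    utils::write.csv(enr$table, file.path(out_dir, "enrichment.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(enr$counts, file.path(out_dir, "pathway_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(enr$overlap, file.path(out_dir, "set_overlap.csv"),
                     row.names = FALSE, quote = FALSE)
    .log_line(con, "enrich", "done", n_sets = length(enr$gsc$sets),
              top_set = enr$table$set[1])
  }

  # --- stage: network -------------------------------------------------------
  .log_line(con, "network", "start")
  net <- tick("network", {
    g <- if (!is.null(cfg$network$sif)) {
      read_sif(cfg$network$sif)
    } else if (!is.null(cohorts$a$truth)) {
      planted <- intersect(cohorts$a$truth$informative_genes,
                           cohorts$b$truth$informative_genes)
      hubs <- utils::head(sort(planted), 3)
      generate_network(universe, planted_hubs = hubs,
                       hub_degree = cfg$network$min_degree + 2,
                       seed = .stage_seed(seed, "network"))
    } else {
      NULL
    }
    if (is.null(g)) {
      .log_line(con, "network", "skipped", reason = "no SIF given")
      NULL
    } else {
      list(graph = g, nodes = node_table(g, cfg$network$min_degree),
           hubs = find_hubs(g, cfg$network$min_degree))
    }
  })
  if (!is.null(net)) {
    write_sif(net$graph, file.path(out_dir, "network.sif"))
    utils::write.csv(net$nodes, file.path(out_dir, "network_nodes.csv"),
                     row.names = FALSE, quote = FALSE)
    writeLines(net$hubs, file.path(out_dir, "hubs.txt"))
    .log_line(con, "network", "done", n_hubs = length(net$hubs))
  }

  # --- manifest -------------------------------------------------------------
  cfg_yaml <- yaml::as.yaml(unclass(cfg))
  manifest <- list(
    config = unclass(cfg),
    config_hash = .content_hash(cfg_yaml),
    global_seed = seed,
    stage_seeds = list(
      synth_a = .stage_seed(seed, "synth_a"),
      synth_b = .stage_seed(seed, "synth_b"),
      stability_a = .stage_seed(seed, "stability_a"),
      stability_b = .stage_seed(seed, "stability_b"),
      signature_ci = .stage_seed(seed, "signature_ci"),
      genesets = .stage_seed(seed, "genesets"),
      network = .stage_seed(seed, "network")),
    versions = list(
      package = as.character(utils::packageVersion("ahrfsig")),
      r = R.version.string))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohorts = cohorts, gene_level = gene_level, de = de,
                 stability = stab, common = sig$common, curve = sig$curve,
                 opt_size = sig$opt, signature = signature,
                 enrichment = if (is.null(enr)) NULL else enr$table,
                 hubs = if (is.null(net)) NULL else net$hubs,
                 manifest = manifest))
}
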