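#' Gene-set collection
#'
#' @param sets Named list of character vectors (set name -> member gene IDs).
#' @param descriptions Optional named character vector of set descriptions.
#' @return A list of class `gene_set_collection` with elements `sets` and
#'   `descriptions`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every set must be named")
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(lengths(sets) == 0)) stop("empty gene sets are not allowed")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = lapply(sets, as.character),
                 descriptions = descriptions[names(sets)]),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, sizes %d-%d\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then one or more member gene IDs, all
#' tab-separated. Duplicate genes within a set are deduplicated with a
#' message; duplicate set names are an error.
#'
#' @param path GMT file path.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop("malformed GMT line ", bad[1], ": expected >= 3 tab-separated fields")
  nm <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nm))
    stop("duplicate set name: ", nm[duplicated(nm)][1])
  desc <- stats::setNames(vapply(fields, `[`, character(1), 2), nm)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  ndup <- sum(vapply(sets, function(s) sum(duplicated(s)), integer(1)))
  if (ndup > 0) {
    message(ndup, " duplicate gene(s) within sets deduplicated")
    sets <- lapply(sets, unique)
  }
  gene_set_collection(sets, desc)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc A `gene_set_collection`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  lines <- vapply(names(gsc$sets), function(nm) {
    paste(c(nm, gsc$descriptions[[nm]], gsc$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Tests each gene set for over-representation of the hit list against the
#' gene universe: the one-sided upper-tail hypergeometric probability of
#' observing at least the number of hits found in the set, with BH FDR
#' across all tested sets. Sets are intersected with the universe first;
#' sets left empty by the intersection are dropped with a message.
#'
#' @param hits Character vector of hit gene IDs (e.g. a signature), a subset
#'   of `universe`.
#' @param universe Character vector: the testing universe (by convention all
#'   genes on the collapsed expression matrix).
#' @param gsc A `gene_set_collection`.
#' @return A tibble with columns `set`, `found`, `set_size`,
#'   `entities_ratio` (set size / universe size), `p`, `fdr`, sorted by
#'   ascending p then set name.
#' @export
ora <- function(hits, universe, gsc) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (length(hits) == 0) stop("empty hit list")
  if (length(universe) == 0) stop("empty universe")
  if (!all(hits %in% universe))
    stop("hits must be a subset of the universe")
  sets <- lapply(gsc$sets, intersect, universe)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    message(sum(empty), " set(s) empty after universe intersection dropped")
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no testable sets after universe intersection")
  N <- length(universe)
  k <- length(hits)
  found <- vapply(sets, function(s) length(intersect(s, hits)), integer(1))
  size <- lengths(sets)
  p <- stats::phyper(found - 1, size, N - size, k, lower.tail = FALSE)
  out <- tibble::tibble(set = names(sets), found = unname(found),
                        set_size = unname(size),
                        entities_ratio = unname(size) / N,
                        p = unname(p),
                        fdr = stats::p.adjust(unname(p), method = "BH"))
  out[order(out$p, out$set), ]
}

#' Per-set hit counts (bar-chart export)
#'
#' @inheritParams ora
#' @return A tibble `set`, `found`, sorted by descending count then name.
#' @export
pathway_gene_counts <- function(hits, gsc) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  hits <- unique(as.character(hits))
  found <- vapply(gsc$sets, function(s) length(intersect(s, hits)), integer(1))
  out <- tibble::tibble(set = names(gsc$sets), found = unname(found))
  out[order(-out$found, out$set), ]
}

#' Pairwise gene-set overlap edges (Jaccard)
#'
#' Flat export for external network visualization of related sets.
#'
#' @param gsc A `gene_set_collection`.
#' @param min_jaccard Minimum Jaccard similarity for an edge (default 0.25).
#' @return A tibble `set_a`, `set_b`, `jaccard`.
#' @export
set_overlap_edges <- function(gsc, min_jaccard = 0.25) {
  stopifnot(inherits(gsc, "gene_set_collection"))
  nms <- names(gsc$sets)
  rows <- list()
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) {
      for (j in seq(i + 1, length(nms))) {
        a <- gsc$sets[[i]]; b <- gsc$sets[[j]]
        jac <- length(intersect(a, b)) / length(union(a, b))
        if (jac >= min_jaccard)
          rows[[length(rows) + 1]] <- tibble::tibble(
            set_a = nms[i], set_b = nms[j], jaccard = jac)
      }
    }
  }
  if (length(rows) == 0)
    return(tibble::tibble(set_a = character(), set_b = character(),
                          jaccard = numeric()))
  do.call(rbind, rows)
}
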