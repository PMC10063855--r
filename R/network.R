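#' Read a SIF interaction network
#'
#' Simple interaction format: each line is
#' `nodeA <tab> relation <tab> nodeB [<tab> nodeC ...]`; a multi-target line
#' expands to one edge from nodeA to each target. The loaded graph is
#' undirected and simple: reversed duplicates collapse to one edge and
#' self-loops are dropped with a warning. Lines with fewer than three fields
#' are an error. Tab is the delimiter when present on a line, otherwise
#' whitespace.
#'
#' @param path SIF file path.
#' @return An undirected simple [igraph::igraph] with named vertices.
#' @export
read_sif <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(igraph::make_empty_graph(directed = FALSE))
  fields <- lapply(lines, function(l) {
    if (grepl("\t", l, fixed = TRUE)) strsplit(l, "\t", fixed = TRUE)[[1]]
    else strsplit(trimws(l), "[[:space:]]+")[[1]]
  })
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0)
    stop("SIF line ", bad[1], " has fewer than 3 fields")
  edges <- do.call(rbind, lapply(fields, function(f) {
    cbind(f[1], f[-(1:2)])
  }))
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

#' Write an interaction graph as SIF
#'
#' Edges are written one per line with relation `pp`, endpoints sorted within
#' each line and lines sorted, so output is canonical.
#'
#' @param g An [igraph::igraph] with named vertices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    lines <- sort(paste(el[, 1], "pp", el[, 2], sep = "\t"))
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Degree-based hub genes of an interaction network
#'
#' Hubs are nodes whose degree (number of distinct neighbors) is at least
#' `min_degree`; the conventional protein-interaction hub cutoff is 10.
#'
#' @param g An [igraph::igraph].
#' @param min_degree Minimum degree to call a hub (default 10).
#' @return Character vector of hub node names, sorted by descending degree
#'   then name.
#' @export
find_hubs <- function(g, min_degree = 10) {
  if (igraph::vcount(g) == 0) return(character())
  deg <- igraph::degree(g)
  hubs <- names(deg)[deg >= min_degree]
  hubs[order(-deg[hubs], hubs)]
}

#' Node table of an interaction network
#'
#' @param g An [igraph::igraph].
#' @param min_degree Hub cutoff (see [find_hubs()]).
#' @return A tibble `node`, `degree`, `is_hub`, sorted by descending degree
#'   then name.
#' @export
node_table <- function(g, min_degree = 10) {
  if (igraph::vcount(g) == 0)
    return(tibble::tibble(node = character(), degree = integer(),
                          is_hub = logical()))
  deg <- igraph::degree(g)
  out <- tibble::tibble(node = names(deg), degree = as.integer(deg),
                        is_hub = deg >= min_degree)
  out[order(-out$degree, out$node), ]
}
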