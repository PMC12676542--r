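#' Build a two-hemisphere cortical surrogate graph
#'
#' Constructs a small graph standing in for a cortical surface mesh: two
#' disconnected hemispheres (left then right), each a ring or a square
#' grid. Real cortical meshes have tens of thousands of vertices per
#' hemisphere; these surrogates keep every downstream algorithm
#' graph-generic while staying desk-scale.
#'
#' @param n_per_hemisphere Number of vertices in each hemisphere (>= 4).
#'   For `topology = "grid"` it should be a perfect square; otherwise the
#'   grid uses the largest square not exceeding it plus a chained remainder.
#' @param topology `"ring"` or `"grid"`.
#' @return A `cortical_graph` object: list with `n_vertices`, `edges`
#'   (two-column integer matrix, 1-based, each undirected edge once),
#'   `hemisphere` (factor `"L"`/`"R"` per vertex), `cortex_mask` (logical
#'   per vertex, `TRUE` = analyzable), and `neighbors` (per-vertex adjacency
#'   list, precomputed for the MRF machinery).
#' @examples
#' g <- build_cortical_graph(16, "grid")
#' table(g$hemisphere)
#' @export
build_cortical_graph <- function(n_per_hemisphere, topology = c("ring", "grid")) {
  topology <- match.arg(topology)
  if (!is_count(n_per_hemisphere, 1L) || n_per_hemisphere < 4L)
    stopf("n_per_hemisphere must be an integer >= 4, got %s", format(n_per_hemisphere))
  n <- as.integer(n_per_hemisphere)

  hemi_edges <- switch(topology,
    ring = cbind(seq_len(n), c(seq_len(n - 1L) + 1L, 1L)),
    grid = grid_edges(n)
  )
  edges <- rbind(hemi_edges, hemi_edges + n)
  # drop duplicate ring edge for n == 2 style degeneracies; not reachable at n >= 4
  structure(
    list(
      n_vertices = 2L * n,
      edges = edges,
      hemisphere = factor(rep(c("L", "R"), each = n), levels = c("L", "R")),
      cortex_mask = rep(TRUE, 2L * n),
      topology = topology,
      neighbors = adjacency_list(edges, 2L * n)
    ),
    class = "cortical_graph"
  )
}

# Edge list of a near-square grid on n vertices (row-major). If n is not a
# perfect square, the trailing remainder is chained onto the last row so the
# hemisphere stays connected.
grid_edges <- function(n) {
  side <- floor(sqrt(n))
  m <- side * side
  idx <- function(r, c) (r - 1L) * side + c
  e <- list()
  for (r in seq_len(side)) for (c in seq_len(side)) {
    if (c < side) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
    if (r < side) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
  }
  if (n > m) for (v in (m + 1L):n) e[[length(e) + 1L]] <- c(v - 1L, v)
  do.call(rbind, e)
}

adjacency_list <- function(edges, n_vertices) {
  nb <- vector("list", n_vertices)
  for (v in seq_len(n_vertices)) nb[[v]] <- integer(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  lapply(nb, function(x) sort(unique(x)))
}

#' @export
print.cortical_graph <- function(x, ...) {
  cat(sprintf(
    "cortical_graph: %d vertices (%d L / %d R), %d edges, topology=%s\n",
    x$n_vertices, sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
    nrow(x$edges), x$topology
  ))
  invisible(x)
}

# igraph view of a hemisphere-respecting graph; used for connectivity checks
# and component counts.
as_igraph <- function(graph) {
  igraph::graph_from_edgelist(graph$edges, directed = FALSE)
}

validate_cortical_graph <- function(graph) {
  e <- graph$edges
  if (any(e[, 1L] == e[, 2L])) stopf("graph has self-loops")
  hemi <- graph$hemisphere
  if (any(hemi[e[, 1L]] != hemi[e[, 2L]])) stopf("graph has cross-hemisphere edges")
  if (!all(c("L", "R") %in% hemi)) stopf("both hemispheres must be non-empty")
  invisible(TRUE)
}

# Number of connected same-label components over unmasked vertices.
label_components <- function(graph, labels) {
  keep <- which(graph$cortex_mask & labels > 0L)
  if (!length(keep)) return(0L)
  e <- graph$edges
  same <- labels[e[, 1L]] == labels[e[, 2L]] &
    e[, 1L] %in% keep & e[, 2L] %in% keep
  g <- igraph::graph_from_edgelist(e[same, , drop = FALSE], directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, graph$n_vertices - igraph::vcount(g)))
  comp <- igraph::components(g)
  memb <- comp$membership[keep]
  length(unique(memb))
}
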