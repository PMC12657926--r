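#' All-pairs shortest-path hop distances
#'
#' BFS hop distances between every vertex pair of a connected undirected
#' simple graph.
#'
#' @param g a connected igraph graph.
#' @return Integer matrix of hop distances.
#' @export
all_pairs_distances <- function(g) {
  check_simple_connected(g)
  d <- igraph::distances(g, algorithm = "unweighted")
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

check_simple_connected <- function(g) {
  if (!igraph::is_simple(g)) {
    stop("graph must be simple (no loops or multi-edges)", call. = FALSE)
  }
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; take largest_component() first", call. = FALSE)
  }
  invisible(g)
}

#' Edge partition: vertices strictly closer to each endpoint
#'
#' For an edge `rs`, `alpha_r` counts the vertices strictly closer to `r`
#' than to `s` (including `r` itself) and `alpha_s` the vertices strictly
#' closer to `s`; equidistant vertices fall in `tie_count` and belong to
#' neither side. Always `alpha_r + alpha_s + tie_count = v`.
#'
#' @param g a connected igraph graph.
#' @param e length-2 vector naming an edge by its endpoints (vertex ids or
#'   names).
#' @param dm optional precomputed distance matrix from
#'   [all_pairs_distances()].
#' @return List with `alpha_r`, `alpha_s`, `tie_count`.
#' @export
edge_partition <- function(g, e, dm = NULL) {
  if (is.null(dm)) dm <- all_pairs_distances(g)
  ids <- as.integer(igraph::V(g)[e])
  if (length(ids) != 2L || !igraph::are_adjacent(g, ids[1], ids[2])) {
    stop("e must be an edge of the graph", call. = FALSE)
  }
  cnt <- partition_counts_cpp(dm, matrix(ids, 1L))
  list(alpha_r = cnt[1, 1], alpha_s = cnt[1, 2], tie_count = cnt[1, 3])
}

# Partition counts for every edge; returns a data.frame with one row per
# edge (columns r, s, alpha_r, alpha_s, ties), vertex ids 1-based positions.
edge_partition_table <- function(g, dm = NULL) {
  if (is.null(dm)) dm <- all_pairs_distances(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  cnt <- partition_counts_cpp(dm, el)
  data.frame(r = el[, 1], s = el[, 2],
             alpha_r = cnt[, 1], alpha_s = cnt[, 2], ties = cnt[, 3])
}

index_from_partition <- function(part, dm) {
  ar <- part$alpha_r; as_ <- part$alpha_s
  c(Sz  = sum(ar * as_),
    ABC = sum(sqrt((ar + as_ - 2) / (ar * as_))),
    PI  = sum(ar + as_),
    MO  = sum(abs(ar - as_)),
    NGG = sum(1 / sqrt(ar * as_)),
    W   = sum(dm) / 2)
}

#' Distance-based topological indices
#'
#' Six edge- and pair-based graph invariants computed from the shortest-path
#' structure of a connected simple graph. With `alpha_r`, `alpha_s` the
#' per-edge counts of strictly closer vertices (see [edge_partition()]):
#'
#' * Szeged `Sz = sum alpha_r * alpha_s`
#' * Graovac-Ghorbani `ABC = sum sqrt((alpha_r + alpha_s - 2) /
#'   (alpha_r * alpha_s))`
#' * Padmakar-Ivan `PI = sum (alpha_r + alpha_s)`
#' * Mostar `MO = sum |alpha_r - alpha_s|`
#' * normalized Graovac-Ghorbani `NGG = sum 1 / sqrt(alpha_r * alpha_s)`
#' * Wiener `W = sum of hop distances over unordered vertex pairs`
#'
#' @param g a connected igraph graph with at least 2 vertices.
#' @param dm optional precomputed distance matrix.
#' @return A single numeric value, or for [compute_index_vector()] a named
#'   vector `(Sz, ABC, PI, MO, NGG, W)`.
#' @export
compute_index_vector <- function(g, dm = NULL) {
  if (igraph::vcount(g) < 2L) stop("graph needs at least 2 vertices", call. = FALSE)
  if (is.null(dm)) dm <- all_pairs_distances(g)
  index_from_partition(edge_partition_table(g, dm), dm)
}

#' @rdname compute_index_vector
#' @export
szeged <- function(g, dm = NULL) unname(compute_index_vector(g, dm)["Sz"])

#' @rdname compute_index_vector
#' @export
graovac_ghorbani <- function(g, dm = NULL) unname(compute_index_vector(g, dm)["ABC"])

#' @rdname compute_index_vector
#' @export
pi_index <- function(g, dm = NULL) unname(compute_index_vector(g, dm)["PI"])

#' @rdname compute_index_vector
#' @export
mostar <- function(g, dm = NULL) unname(compute_index_vector(g, dm)["MO"])

#' @rdname compute_index_vector
#' @export
ngg <- function(g, dm = NULL) unname(compute_index_vector(g, dm)["NGG"])

#' @rdname compute_index_vector
#' @export
wiener <- function(g, dm = NULL) {
  if (is.null(dm)) dm <- all_pairs_distances(g)
  sum(dm) / 2
}

#' Is a graph distance-balanced?
#'
#' A graph is distance-balanced when every edge has `alpha_r = alpha_s`,
#' equivalently when its Mostar index is 0. The unrewired Watts-Strogatz
#' ring lattice is a standard example.
#'
#' @inheritParams compute_index_vector
#' @return Logical scalar.
#' @export
is_distance_balanced <- function(g, dm = NULL) {
  part <- edge_partition_table(g, dm)
  all(part$alpha_r == part$alpha_s)
}

#' Small-world summary statistics
#'
#' Mean local clustering coefficient (vertices of degree < 2 contribute 0)
#' and average shortest-path length over unordered distinct vertex pairs,
#' the two quantities classically compared between an observed network and
#' a matched random/small-world reference.
#'
#' @param g a connected igraph graph with at least 3 vertices.
#' @return List with `C_cc`, `L_apl`, `v`, `mean_degree`.
#' @export
small_world_summary <- function(g) {
  check_simple_connected(g)
  if (igraph::vcount(g) < 3L) stop("graph needs at least 3 vertices", call. = FALSE)
  cc <- igraph::transitivity(g, type = "localundirected")
  cc[!is.finite(cc)] <- 0  # degree < 2
  list(C_cc = mean(cc),
       L_apl = igraph::mean_distance(g),
       v = igraph::vcount(g),
       mean_degree = 2 * igraph::ecount(g) / igraph::vcount(g))
}

#' Index vectors for a set of graphs as a CSV-ready table
#'
#' @param graphs named list of connected igraph graphs.
#' @return data.frame with columns `graph_id`, the six indices, `v`,
#'   `edges`, `C_cc`, `L_apl`.
#' @export
index_table <- function(graphs) {
  if (is.null(names(graphs))) names(graphs) <- seq_along(graphs)
  rows <- lapply(names(graphs), function(id) {
    g <- graphs[[id]]
    iv <- compute_index_vector(g)
    sw <- small_world_summary(g)
    data.frame(graph_id = id, Sz = iv["Sz"], ABC = iv["ABC"], PI = iv["PI"],
               MO = iv["MO"], NGG = iv["NGG"], W = iv["W"],
               v = sw$v, edges = igraph::ecount(g),
               C_cc = sw$C_cc, L_apl = sw$L_apl, row.names = NULL)
  })
  do.call(rbind, rows)
}
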