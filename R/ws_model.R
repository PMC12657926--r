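#' Ring lattice
#'
#' The Watts-Strogatz substrate: `v` vertices on a ring, each joined to its
#' `delta` nearest neighbours (`delta/2` on each side), giving a
#' `delta`-regular graph with `v * delta / 2` edges.
#'
#' @param v number of vertices.
#' @param delta even neighbour count, `2 <= delta <= v - 1`.
#' @return An igraph graph with graph attributes `v`, `delta`.
#' @export
ring_lattice <- function(v, delta) {
  check_ws_params(v, delta)
  el <- ws_rewire_cpp(as.integer(v), as.integer(delta), 0)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::graph_attr(g, "v") <- as.integer(v)
  igraph::graph_attr(g, "delta") <- as.integer(delta)
  g
}

check_ws_params <- function(v, delta) {
  if (delta %% 2 != 0) stop("delta must be even", call. = FALSE)
  if (delta < 2 || delta > v - 1) {
    stop("need 2 <= delta <= v - 1", call. = FALSE)
  }
  invisible(NULL)
}

#' Sequential Watts-Strogatz rewiring
#'
#' Rewires a ring lattice by the original sequential procedure: spans
#' `u = 1..delta/2` are scanned in order (nearest neighbours first), vertices
#' in ring order within each span, and each lattice edge `(i, i+u)` is,
#' independently with probability `p`, replaced by `(i, j)` with `j` drawn
#' uniformly from the vertices that are neither `i` nor currently adjacent
#' to `i` (no self-loops, no duplicate edges). The edge count `v * delta / 2`
#' is conserved; a saturated vertex keeps its edge. Randomness comes from R's
#' RNG, so `set.seed()` makes the result reproducible.
#'
#' @param g a ring lattice from [ring_lattice()].
#' @param p rewiring probability in `[0, 1]`.
#' @return The rewired igraph graph (attributes `v`, `delta`, `p`).
#' @export
ws_rewire <- function(g, p) {
  v <- igraph::graph_attr(g, "v"); delta <- igraph::graph_attr(g, "delta")
  if (is.null(v) || is.null(delta)) {
    stop("g must be a ring lattice built by ring_lattice()", call. = FALSE)
  }
  ws_graph(v, delta, p)
}

#' @rdname ws_rewire
#' @param v,delta ring-lattice parameters as in [ring_lattice()].
#' @export
ws_graph <- function(v, delta, p) {
  check_ws_params(v, delta)
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    stop("p must be a single probability in [0, 1]", call. = FALSE)
  }
  el <- ws_rewire_cpp(as.integer(v), as.integer(delta), p)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < v) g <- igraph::add_vertices(g, v - igraph::vcount(g))
  igraph::graph_attr(g, "v") <- as.integer(v)
  igraph::graph_attr(g, "delta") <- as.integer(delta)
  igraph::graph_attr(g, "p") <- p
  g
}

#' Closed-form neighbourhood count on the unrewired lattice
#'
#' For an edge of span `u` in the `delta`-regular ring lattice on `v`
#' vertices (rewiring probability 0), the closed form for the number of
#' vertices strictly closer to one endpoint, with `C = floor((v-1)/delta)`
#' and `gamma = (v-1) mod delta`, is
#' `u*(C-1) + gamma` when `gamma < u` and `u*C + 1` otherwise.
#' The value is returned exactly as printed; [theorem1_validate()] audits it
#' against the BFS oracle, which disagrees on at least one `gamma < u` case
#' (see the package vignette).
#'
#' @param v vertex count.
#' @param delta even neighbour count with `delta < v/2`.
#' @param u edge span, `1 <= u <= delta/2`.
#' @return Integer count.
#' @export
theorem1_alpha_closed <- function(v, delta, u) {
  check_theorem1_params(v, delta, u)
  C <- (v - 1) %/% delta
  gam <- (v - 1) %% delta
  if (gam < u) u * (C - 1) + gam else u * C + 1
}

check_theorem1_params <- function(v, delta, u) {
  if (delta %% 2 != 0) stop("delta must be even", call. = FALSE)
  if (!(delta < v / 2)) stop("closed form requires delta < v/2", call. = FALSE)
  if (u < 1 || u > delta / 2) stop("need 1 <= u <= delta/2", call. = FALSE)
  invisible(NULL)
}

#' BFS oracle for the lattice neighbourhood count
#'
#' Ground truth for [theorem1_alpha_closed()]: builds the ring lattice,
#' takes the edge `(0, u)`, and counts by BFS the vertices strictly closer
#' to `u` than to `0`. By the lattice's symmetry the two endpoint counts are
#' equal.
#'
#' @inheritParams theorem1_alpha_closed
#' @return Integer count.
#' @export
theorem1_alpha_oracle <- function(v, delta, u) {
  check_theorem1_params(v, delta, u)
  g <- ring_lattice(v, delta)
  d <- igraph::distances(g, v = c(1L, u + 1L), algorithm = "unweighted")
  sum(d[2, ] < d[1, ])
}

#' Audit the closed form against the BFS oracle over a parameter grid
#'
#' Evaluates every `(v, delta, u)` with `v` in `v_range`, even
#' `delta < v/2`, and `1 <= u <= delta/2`, and reports where the printed
#' closed form and the BFS oracle agree, split by branch (`gamma < u` vs
#' `gamma >= u`).
#'
#' @param v_range integer vector of vertex counts.
#' @param delta_values optional even `delta` values to restrict to.
#' @return data.frame with columns `v, delta, u, C, gamma, branch,
#'   alpha_closed, alpha_oracle, agree`; per-branch agreement counts are in
#'   attribute `summary`.
#' @export
theorem1_validate <- function(v_range = 8:60, delta_values = NULL) {
  rows <- list()
  for (v in v_range) {
    deltas <- seq(2L, v, by = 2L)
    deltas <- deltas[deltas < v / 2]
    if (!is.null(delta_values)) deltas <- intersect(deltas, delta_values)
    for (delta in deltas) {
      lat <- ring_lattice(v, delta)
      dm <- igraph::distances(lat, v = seq_len(delta / 2 + 1),
                              algorithm = "unweighted")
      for (u in seq_len(delta / 2)) {
        gam <- (v - 1) %% delta
        rows[[length(rows) + 1L]] <- data.frame(
          v = v, delta = delta, u = u,
          C = (v - 1) %/% delta, gamma = gam,
          branch = if (gam < u) "gamma<u" else "otherwise",
          alpha_closed = theorem1_alpha_closed(v, delta, u),
          alpha_oracle = sum(dm[u + 1, ] < dm[1, ]))
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(v = integer(), delta = integer(), u = integer(), C = integer(),
               gamma = integer(), branch = character(),
               alpha_closed = integer(), alpha_oracle = integer())
  out$agree <- out$alpha_closed == out$alpha_oracle
  attr(out, "summary") <- if (nrow(out)) {
    stats::aggregate(agree ~ branch, out, function(a) c(n = length(a), agree = sum(a)))
  } else NULL
  out
}

#' Replicate ensemble of Watts-Strogatz index statistics
#'
#' Generates `reps` independent WS graphs at fixed `(v, delta, p)`, computes
#' the six distance-based indices plus the clustering coefficient and
#' average path length of each (on the largest connected component if
#' rewiring disconnects the graph), and returns per-index means and standard
#' deviations. Seed the R RNG beforehand for reproducibility.
#'
#' @inheritParams ws_graph
#' @param reps number of replicates, at least 1.
#' @return An object of class `ws_ensemble`: list with `params`, `reps`,
#'   `mean`, `sd` (named over `Sz, ABC, PI, MO, NGG, W, C_cc, L_apl`), and
#'   `n_disconnected`.
#' @export
ensemble_indices <- function(v, delta, p, reps = 100) {
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  vals <- matrix(NA_real_, reps, 8,
                 dimnames = list(NULL, c("Sz", "ABC", "PI", "MO", "NGG", "W",
                                         "C_cc", "L_apl")))
  n_disc <- 0L
  for (r in seq_len(reps)) {
    g <- ws_graph(v, delta, p)
    if (!igraph::is_connected(g)) {
      n_disc <- n_disc + 1L
      g <- largest_component(g, quiet = TRUE)
    }
    dm <- all_pairs_distances(g)
    iv <- compute_index_vector(g, dm)
    sw <- small_world_summary(g)
    vals[r, ] <- c(iv, sw$C_cc, sw$L_apl)
  }
  structure(list(params = list(v = v, delta = delta, p = p),
                 reps = reps,
                 mean = colMeans(vals),
                 sd = apply(vals, 2, stats::sd),
                 n_disconnected = n_disc),
            class = "ws_ensemble")
}

#' @export
print.ws_ensemble <- function(x, ...) {
  cat(sprintf("<ws_ensemble v=%d delta=%d p=%.3f reps=%d (%d disconnected)>\n",
              x$params$v, x$params$delta, x$params$p, x$reps, x$n_disconnected))
  print(round(rbind(mean = x$mean, sd = x$sd), 4))
  invisible(x)
}

#' Rewiring-probability scan of ensemble-mean indices
#'
#' Sweeps a grid of rewiring probabilities, computes a replicate ensemble at
#' each grid point, and locates the global maximum and minimum of each mean
#' index curve (ties broken toward the smallest grid `p`).
#'
#' @inheritParams ensemble_indices
#' @param p_grid increasing vector of probabilities in `[0, 1]`.
#' @param seed optional seed applied once before the scan.
#' @return An object of class `ws_scan`: list with `p_grid`, `mean` and `sd`
#'   matrices (`length(p_grid) x 8`), and data.frame `argext` with the grid
#'   `p` of each index's global maximum and minimum.
#' @export
extremum_scan <- function(v, delta, p_grid = seq(0, 1, by = 0.05),
                          reps = 200, seed = NULL) {
  if (any(p_grid < 0 | p_grid > 1)) stop("p_grid must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(p_grid, function(p) ensemble_indices(v, delta, p, reps))
  means <- do.call(rbind, lapply(res, `[[`, "mean"))
  sds <- do.call(rbind, lapply(res, `[[`, "sd"))
  rownames(means) <- rownames(sds) <- format(p_grid)
  argext <- data.frame(
    index = colnames(means),
    p_max = p_grid[apply(means, 2, which.max)],  # which.max takes first = smallest p
    p_min = p_grid[apply(means, 2, which.min)],
    row.names = NULL)
  structure(list(v = v, delta = delta, p_grid = p_grid, reps = reps,
                 mean = means, sd = sds, argext = argext),
            class = "ws_scan")
}

#' @export
print.ws_scan <- function(x, ...) {
  cat(sprintf("<ws_scan v=%d delta=%d reps=%d over %d grid points>\n",
              x$v, x$delta, x$reps, length(x$p_grid)))
  print(x$argext)
  invisible(x)
}

#' Matched Watts-Strogatz reference ensemble for a graph
#'
#' Builds the WS ensemble used to normalize a graph's index vector: same
#' vertex count, `delta` the nearest even integer (at least 2, at most the
#' largest feasible value `v - 1` rounded down to even) to the graph's mean
#' degree, rewiring probability `p_ref`.
#'
#' @param g a connected igraph graph.
#' @param p_ref reference rewiring probability (default 0.25, the centre of
#'   the small-world sensitivity range).
#' @param reps ensemble replicates.
#' @param seed optional seed applied before generation.
#' @return A `ws_ensemble` (see [ensemble_indices()]).
#' @export
matched_ws_reference <- function(g, p_ref = 0.25, reps = 100, seed = NULL) {
  check_simple_connected(g)
  v <- igraph::vcount(g)
  md <- 2 * igraph::ecount(g) / v
  delta <- max(2, 2 * round(md / 2))
  delta_cap <- if ((v - 1) %% 2 == 0) v - 1 else v - 2
  delta <- min(delta, delta_cap)
  if (!is.null(seed)) set.seed(seed)
  ensemble_indices(v, delta, p_ref, reps)
}

#' Normalize an index vector against a WS reference ensemble
#'
#' Each component is divided by the corresponding ensemble mean, placing
#' graphs of different size and density on a consistent scale (the analogue
#' of C/C_rand-style small-world normalization). The Mostar component is
#' divided by `mean MO + 1`, since the reference mean is exactly 0 for the
#' distance-balanced unrewired lattice.
#'
#' @param raw named index vector from [compute_index_vector()].
#' @param ref a `ws_ensemble` reference.
#' @return Named numeric vector `(Sz, ABC, PI, MO, NGG, W)`.
#' @export
normalize_index_vector <- function(raw, ref) {
  stopifnot(inherits(ref, "ws_ensemble"))
  idx <- c("Sz", "ABC", "PI", "MO", "NGG", "W")
  m <- ref$mean[idx]
  denom <- ifelse(idx == "MO", m + 1, m)
  if (any(denom <= 0)) {
    stop("reference ensemble has a non-positive mean index: ",
         paste(idx[denom <= 0], collapse = ", "), call. = FALSE)
  }
  out <- raw[idx] / denom
  names(out) <- idx
  out
}
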