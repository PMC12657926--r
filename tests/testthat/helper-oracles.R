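# Independent brute-force oracles. Deliberately naive: adjacency lists and a
# hand-rolled BFS, with distances recomputed from scratch for every edge, so
# the main implementation (igraph distances + compiled partition counts) is
# checked against a fully separate code path.

oracle_adjlist <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- igraph::vcount(g)
  adj <- vector("list", n)
  for (i in seq_len(nrow(el))) {
    a <- el[i, 1]; b <- el[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

oracle_bfs <- function(adj, src) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    for (w in adj[[u]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[u] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# All six indices by per-edge fresh BFS
oracle_indices <- function(g) {
  adj <- oracle_adjlist(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  Sz <- 0; ABC <- 0; PI <- 0; MO <- 0; NGG <- 0
  for (i in seq_len(nrow(el))) {
    r <- el[i, 1]; s <- el[i, 2]
    dr <- oracle_bfs(adj, r)
    ds <- oracle_bfs(adj, s)
    ar <- sum(dr < ds); as_ <- sum(ds < dr)
    Sz <- Sz + ar * as_
    ABC <- ABC + sqrt((ar + as_ - 2) / (ar * as_))
    PI <- PI + ar + as_
    MO <- MO + abs(ar - as_)
    NGG <- NGG + 1 / sqrt(ar * as_)
  }
  W <- 0
  for (v in seq_along(adj)) W <- W + sum(oracle_bfs(adj, v))
  c(Sz = Sz, ABC = ABC, PI = PI, MO = MO, NGG = NGG, W = W / 2)
}

random_connected_graph <- function(n, p = 0.3) {
  make_graph("random_connected", size = n, edge_prob = p)
}

constant_image <- function(value = 100, n = 2, m = 2) {
  gray_image(matrix(value, n, m))
}

# tiny labelled dataset for classifier tests: 2D Gaussian blobs per class
blob_data <- function(n_per_class = 20, centers = rbind(c(0, 0), c(4, 4)),
                      sd = 0.5) {
  k <- nrow(centers)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(stats::rnorm(n_per_class, centers[i, 1], sd),
          stats::rnorm(n_per_class, centers[i, 2], sd))
  }))
  list(features = x, labels = factor(rep(seq_len(k) - 1, each = n_per_class)))
}
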