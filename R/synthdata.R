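#' Default class-conditional image specification
#'
#' One row per stage label 0-3 giving the texture parameters of the
#' synthetic grayscale images: Gaussian smoothing length `ell` (pixels),
#' contrast `contrast` (intensity sd of the smoothed field before clipping),
#' and additive pixel noise `noise_sd`. Both the smoothing length and the
#' contrast strictly decrease with the stage label: coarse, high-contrast
#' texture produces heavily clipped, plateau-rich intensity histograms
#' (akin to the dark background and bright tissue plateaus of structural
#' MRI), whose thresholded pixel graphs contain large clique-like blocks --
#' high clustering, long brightness-path structure -- while fine,
#' low-contrast texture gives near-Gaussian histograms and more uniform,
#' less clustered graphs. The result is a monotone structural covariate
#' across stages for the classifier to detect.
#'
#' @return data.frame with columns `label`, `ell`, `contrast`, `noise_sd`.
#' @export
default_image_spec <- function() {
  data.frame(label = 0:3,
             ell = c(12, 7, 4, 2),
             contrast = c(110, 80, 60, 45),
             noise_sd = 3)
}

# 1D Gaussian convolution matrix (rows renormalized at the borders)
gauss_conv <- function(n, ell) {
  idx <- seq_len(n)
  k <- outer(idx, idx, function(a, b) exp(-(a - b)^2 / (2 * ell^2)))
  k / rowSums(k)
}

#' Generate one synthetic grayscale image
#'
#' Smoothed-noise texture: a white-noise field is convolved with an
#' isotropic Gaussian kernel of length `ell`, standardized, scaled to sd
#' `contrast` around mid-gray, and perturbed with additive pixel noise.
#' Intensities are clipped to `[0, 255]`. Seed the RNG for reproducibility.
#'
#' @param label stage label 0-3 (only recorded; the texture comes from the
#'   remaining arguments).
#' @param size image side length in pixels (square image).
#' @param ell Gaussian smoothing length in pixels, `> 0`.
#' @param contrast intensity standard deviation of the smoothed field.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param quantize round intensities to whole 8-bit luminance levels
#'   (default `TRUE`, matching real image formats).
#' @return A [gray_image] with attribute `label`.
#' @export
make_image <- function(label = 0, size = 32, ell = 5, contrast = 45,
                       noise_sd = 5, quantize = TRUE) {
  if (ell <= 0) stop("ell must be positive", call. = FALSE)
  field <- matrix(stats::rnorm(size * size), size, size)
  k <- gauss_conv(size, ell)
  sm <- k %*% field %*% t(k)
  s <- stats::sd(as.vector(sm))
  if (s > 0) sm <- (sm - mean(sm)) / s
  img <- 128 + contrast * sm
  if (noise_sd > 0) img <- img + matrix(stats::rnorm(size * size, sd = noise_sd),
                                        size, size)
  img <- pmin(pmax(img, 0), 255)
  if (quantize) img <- round(img)
  out <- gray_image(img)
  attr(out, "label") <- label
  out
}

#' Generate a labeled synthetic image dataset
#'
#' `n_per_class` images per stage (optionally thinned per class by
#' `imbalance` to exercise SMOTE), drawn from the class-conditional spec.
#' All randomness flows from `seed`: the RNG is seeded once and images are
#' generated in label-major, replicate-minor order, so a fixed seed gives a
#' byte-identical dataset.
#'
#' @param n_per_class images per class before imbalance.
#' @param spec image spec table as from [default_image_spec()].
#' @param seed RNG seed.
#' @param imbalance length-4 multipliers in `(0, 1]` applied to class
#'   counts (`ceiling(n_per_class * imbalance)`).
#' @param size image side length.
#' @return List with `images` (list of [gray_image]) and `labels` (integer
#'   vector).
#' @export
make_dataset <- function(n_per_class = 50, spec = default_image_spec(),
                         seed = 1, imbalance = c(1, 1, 1, 1), size = 32) {
  stopifnot(n_per_class >= 1, length(imbalance) == 4)
  set.seed(seed)
  images <- list(); labels <- integer()
  for (r in seq_len(nrow(spec))) {
    n_cl <- max(1L, ceiling(n_per_class * imbalance[r]))
    for (i in seq_len(n_cl)) {
      images[[length(images) + 1L]] <-
        make_image(spec$label[r], size = size, ell = spec$ell[r],
                   contrast = spec$contrast[r], noise_sd = spec$noise_sd[r])
      labels <- c(labels, spec$label[r])
    }
  }
  list(images = images, labels = labels)
}

#' Write a synthetic dataset to disk as PNGs plus a labels CSV
#'
#' @param dataset result of [make_dataset()].
#' @param dir output directory (created if absent).
#' @return Path to the written `labels.csv`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(dataset$images))
  for (i in seq_along(dataset$images)) {
    files[i] <- sprintf("img_%04d.png", i)
    png::writePNG(dataset$images[[i]]$intensities / 255,
                  file.path(dir, files[i]))
  }
  lab <- data.frame(file = files, label = dataset$labels)
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(file.path(dir, "labels.csv"))
}

#' Graph fixtures for testing and oracles
#'
#' Small simple graphs from named families: `path`, `cycle`, `complete`,
#' `ring_lattice` (delegates to [ring_lattice()]), `random_tree` (uniform
#' labelled tree), and `random_connected` (Erdos-Renyi, resampled until
#' connected). Seed the RNG for reproducibility of the random families.
#'
#' @param family one of the families above.
#' @param size vertex count.
#' @param edge_prob edge probability for `random_connected`.
#' @param delta neighbour count for `ring_lattice`.
#' @param max_tries resampling bound for `random_connected`.
#' @return An igraph graph.
#' @export
make_graph <- function(family = c("path", "cycle", "complete", "ring_lattice",
                                  "random_tree", "random_connected"),
                       size = 5, edge_prob = 0.3, delta = 2, max_tries = 100) {
  family <- match.arg(family)
  switch(family,
    path = igraph::make_ring(size, circular = FALSE),
    cycle = igraph::make_ring(size, circular = TRUE),
    complete = igraph::make_full_graph(size),
    ring_lattice = ring_lattice(size, delta),
    random_tree = igraph::sample_tree(size),
    random_connected = {
      for (i in seq_len(max_tries)) {
        g <- igraph::sample_gnp(size, edge_prob)
        if (igraph::is_connected(g)) return(g)
      }
      stop("could not sample a connected graph in ", max_tries,
           " tries; raise edge_prob", call. = FALSE)
    })
}
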