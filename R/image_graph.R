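#' Grayscale image container
#'
#' Light S3 wrapper around a numeric intensity matrix. Rows are image rows
#' (height `n`), columns are image columns (width `m`); intensities are
#' luminance values on the 0--255 scale. Pixels are indexed row-major and
#' 0-based: pixel `(i, j)` (row `i`, column `j`, both 0-based) has index
#' `i * m + j`.
#'
#' @param intensities numeric matrix, `n x m`, values in `[0, 255]`.
#' @return An object of class `gray_image`.
#' @export
gray_image <- function(intensities) {
  intensities <- as.matrix(intensities)
  if (nrow(intensities) < 2L || ncol(intensities) < 2L) {
    stop("gray_image requires at least 2x2 pixels", call. = FALSE)
  }
  if (!all(is.finite(intensities))) {
    stop("gray_image intensities must be finite", call. = FALSE)
  }
  if (min(intensities) < 0 || max(intensities) > 255) {
    stop("gray_image intensities must lie in [0, 255]", call. = FALSE)
  }
  structure(list(intensities = unname(intensities)), class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<gray_image %d x %d (height x width), range [%.1f, %.1f]>\n",
              d[1], d[2], min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Image width (columns) and height (rows)
#' @param img a `gray_image`.
#' @return Integer scalar.
#' @export
image_width <- function(img) ncol(img$intensities)

#' @rdname image_width
#' @export
image_height <- function(img) nrow(img$intensities)

#' Row-major pixel indexing
#'
#' Converts between 0-based `(row, col)` coordinates and the 0-based
#' row-major pixel index used for BDM rows/columns and graph vertex names.
#'
#' @param i,j 0-based row and column.
#' @param m image width in pixels (number of columns).
#' @param idx 0-based row-major pixel index.
#' @return `pixel_index` returns the index; `pixel_coord` a two-column matrix
#'   of `(row, col)` pairs.
#' @export
pixel_index <- function(i, j, m) i * m + j

#' @rdname pixel_index
#' @export
pixel_coord <- function(idx, m) cbind(row = idx %/% m, col = idx %% m)

#' Load an image file as a grayscale intensity grid
#'
#' Reads a PNG (natively) or JPEG (through EBImage, when installed) and
#' reduces colour channels by a weighted luma combination. Intensities are
#' rescaled to the 0--255 range.
#'
#' @param path path to a PNG or JPEG file.
#' @param luma_weights length-3 weights for the R, G, B channels; must sum
#'   to 1. The default is the ITU-R BT.601 luma transform.
#' @return A [gray_image].
#' @export
load_grayscale <- function(path, luma_weights = c(0.299, 0.587, 0.114)) {
  if (!file.exists(path)) stop("cannot read image file: ", path, call. = FALSE)
  if (length(luma_weights) != 3L || abs(sum(luma_weights) - 1) > 1e-8) {
    stop("luma_weights must be 3 values summing to 1", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG input requires the EBImage package; convert to PNG instead",
           call. = FALSE)
    }
    arr <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x (width) as the first dimension; transpose to rows x cols
    arr <- if (length(dim(arr)) == 2L) t(arr) else aperm(arr, c(2L, 1L, 3L))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(arr) == 0L) stop("zero-size image: ", path, call. = FALSE)
  gray <- if (length(dim(arr)) == 2L) {
    arr
  } else {
    nch <- dim(arr)[3]
    if (nch >= 3L) {
      luma_weights[1] * arr[, , 1] + luma_weights[2] * arr[, , 2] +
        luma_weights[3] * arr[, , 3]
    } else {
      arr[, , 1]
    }
  }
  gray_image(gray * 255)
}

#' Downsample an image by area averaging
#'
#' Each output pixel is the overlap-weighted mean of the source pixels it
#' covers, so the operation is exact block averaging when the size ratio is
#' an integer and a proper area average otherwise. A no-op when the target
#' size equals the source size.
#'
#' @param img a [gray_image].
#' @param target_m,target_n target width and height in pixels, each at
#'   least 2 and no larger than the source dimensions.
#' @return A [gray_image] of size `target_n x target_m`.
#' @export
downsample <- function(img, target_m, target_n) {
  stopifnot(inherits(img, "gray_image"))
  m <- image_width(img); n <- image_height(img)
  if (target_m < 2 || target_n < 2) {
    stop("target dimensions must be at least 2", call. = FALSE)
  }
  if (target_m > m || target_n > n) {
    stop("target dimensions exceed source image size", call. = FALSE)
  }
  if (target_m == m && target_n == n) return(img)
  out <- area_weights(target_n, n) %*% img$intensities %*% t(area_weights(target_m, m))
  gray_image(pmin(pmax(out, 0), 255))
}

# Overlap-weight matrix mapping `src` cells onto `dst` equal-width cells;
# rows sum to 1.
area_weights <- function(dst, src) {
  w <- matrix(0, dst, src)
  scale <- src / dst
  for (k in seq_len(dst)) {
    lo <- (k - 1) * scale
    hi <- k * scale
    cells <- floor(lo):min(ceiling(hi) - 1, src - 1)
    w[k, cells + 1] <- pmin(hi, cells + 1) - pmax(lo, cells)
  }
  w / rowSums(w)
}

#' Brightness distance matrix (BDM)
#'
#' Pairwise absolute luminance differences `L(p, q) = |Lum(p) - Lum(q)|`
#' between all pixels of an image, in row-major pixel order. The result is a
#' symmetric `mn x mn` matrix with zero diagonal.
#'
#' @param img a [gray_image].
#' @return Numeric matrix of pairwise brightness distances.
#' @export
compute_bdm <- function(img) {
  stopifnot(inherits(img, "gray_image"))
  lum <- as.vector(t(img$intensities))  # row-major traversal
  abs(outer(lum, lum, "-"))
}

#' Min-max normalization of a BDM
#'
#' Rescales entries to `[0, 1]` via `(L - min L) / (max L - min L)`. For a
#' constant image the range is degenerate and all entries are defined as 0
#' (with a warning), so that thresholding yields the complete graph.
#'
#' @param bdm a brightness distance matrix from [compute_bdm()].
#' @return Matrix of the same dimension with entries in `[0, 1]`.
#' @export
normalize_bdm <- function(bdm) {
  bdm <- as.matrix(bdm)
  rng <- range(bdm)
  if (rng[2] == rng[1]) {
    warning("degenerate BDM (constant image): normalized entries set to 0",
            call. = FALSE)
    return(matrix(0, nrow(bdm), ncol(bdm)))
  }
  (bdm - rng[1]) / (rng[2] - rng[1])
}

#' Threshold a normalized BDM into a pixel graph
#'
#' Builds the undirected simple graph whose edge `pq` exists iff
#' `1 - L_n(p, q) >= tau` and `p != q`: pixels with sufficiently similar
#' brightness are joined. Higher `tau` gives a sparser graph. Vertices are
#' named by their 0-based row-major pixel index; isolated pixels are kept.
#'
#' @param nbdm normalized BDM from [normalize_bdm()].
#' @param tau similarity threshold in `[0, 1]`.
#' @return An igraph graph with graph attribute `tau`.
#' @export
threshold_adjacency <- function(nbdm, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0 || tau > 1) {
    stop("tau must be a single value in [0, 1]", call. = FALSE)
  }
  nbdm <- as.matrix(nbdm)
  a <- (1 - nbdm >= tau)
  diag(a) <- FALSE  # self-loops removed
  el <- which(a & upper.tri(a), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = nrow(nbdm), directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::V(g)$name <- as.character(seq_len(nrow(nbdm)) - 1L)
  g <- igraph::set_graph_attr(g, "tau", tau)
  g
}

#' Largest connected component
#'
#' Induced subgraph on the largest connected component. Size ties are broken
#' toward the component containing the smallest vertex index (first vertex in
#' graph order).
#'
#' @param g an igraph graph.
#' @param quiet suppress the message reporting the component count.
#' @return The induced subgraph; the input itself when already connected.
#' @export
largest_component <- function(g, quiet = FALSE) {
  if (igraph::vcount(g) == 0L) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  if (comp$no == 1L) return(g)
  if (!quiet) {
    message(sprintf("graph has %d components; keeping the largest (%d of %d vertices)",
                    comp$no, max(comp$csize), igraph::vcount(g)))
  }
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    # tie: component whose earliest vertex comes first in graph order
    first_vertex <- vapply(best, function(k) min(which(comp$membership == k)), 0L)
    best <- best[which.min(first_vertex)]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Build a pixel graph from an image in one call
#'
#' Convenience wrapper chaining [compute_bdm()], [normalize_bdm()] and
#' [threshold_adjacency()], optionally restricted to the largest connected
#' component.
#'
#' @param img a [gray_image].
#' @param tau similarity threshold in `[0, 1]`.
#' @param keep_all_components keep the full (possibly disconnected) graph.
#' @param quiet passed to [largest_component()].
#' @return An igraph pixel graph.
#' @export
image_to_graph <- function(img, tau = 0.95, keep_all_components = FALSE,
                           quiet = TRUE) {
  g <- threshold_adjacency(normalize_bdm(suppressWarnings(compute_bdm(img))), tau)
  if (!keep_all_components) g <- largest_component(g, quiet = quiet)
  g
}

#' Read and write plain-text edge lists
#'
#' Graphs are exchanged as whitespace-delimited edge lists, one `u v` pair
#' per line with 0-based vertex labels (vertex names when present, else
#' position minus one).
#'
#' @param g an igraph graph.
#' @param path output (input) file path.
#' @return `write_edgelist_txt` returns `path` invisibly; `read_edgelist_txt`
#'   returns an igraph graph with 0-based character vertex names.
#' @export
write_edgelist_txt <- function(g, path) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  if (!is.null(igraph::V(g)$name)) {
    nm <- igraph::V(g)$name
    el <- cbind(nm[el[, 1] + 1L], nm[el[, 2] + 1L])
  }
  utils::write.table(el, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_edgelist_txt
#' @export
read_edgelist_txt <- function(path) {
  el <- as.matrix(utils::read.table(path, header = FALSE,
                                    colClasses = "character"))
  igraph::graph_from_edgelist(el, directed = FALSE)
}
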