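test_that("grayscale loading reduces colour by the luma weights", {
  tmp <- tempfile(fileext = ".png")
  # grayscale identity
  png::writePNG(matrix(100 / 255, 2, 2), tmp)
  img <- load_grayscale(tmp)
  expect_equal(as.vector(img$intensities), rep(100, 4))
  # colour: white and pure red under BT.601 weights
  arr <- array(0, c(2, 2, 3))
  arr[1, 1, ] <- 1                 # white pixel
  arr[1, 2, 1] <- 1                # pure red pixel
  png::writePNG(arr, tmp)
  img <- load_grayscale(tmp, luma_weights = c(0.299, 0.587, 0.114))
  expect_equal(img$intensities[1, 1], 255)
  expect_equal(img$intensities[1, 2], 0.299 * 255, tolerance = 1e-6)
  expect_error(load_grayscale(tempfile(fileext = ".png")), "cannot read")
  expect_error(load_grayscale(tmp, luma_weights = c(1, 1, 1)), "summing to 1")
})

test_that("downsampling area-averages and validates target size", {
  expect_equal(downsample(constant_image(50, 4, 4), 2, 2)$intensities,
               matrix(50, 2, 2))
  img <- gray_image(matrix(c(0, 0, 255, 255), 2, 2))
  # full-image mean via the internal weight matrices
  expect_equal(sum(area_weights(1, 2) %*% img$intensities %*% t(area_weights(1, 2))),
               127.5)
  big <- gray_image(matrix(runif(176 * 208, 0, 255), 176, 208))
  small <- downsample(big, 32, 32)
  expect_equal(dim(small$intensities), c(32L, 32L))
  expect_identical(downsample(img, 2, 2), img)
  expect_error(downsample(img, 4, 4), "exceed")
})

test_that("BDM holds absolute luminance differences in row-major order", {
  img <- gray_image(matrix(c(0, 128, 255, 10), 2, 2, byrow = TRUE))
  bdm <- compute_bdm(img)
  # row-major pixel order: (0,128,255,10)
  expect_equal(bdm[1, ], c(0, 128, 255, 10))
  expect_equal(bdm[2, 3], 127)
  expect_true(isSymmetric(bdm))
  expect_equal(diag(bdm), rep(0, 4))
  expect_equal(compute_bdm(constant_image()), matrix(0, 4, 4))
})

test_that("BDM normalization min-max rescales, with a degenerate-image rule", {
  img <- gray_image(matrix(c(0, 128, 255, 10), 2, 2, byrow = TRUE))
  nb <- normalize_bdm(compute_bdm(img))
  expect_equal(nb[1, 2], 128 / 255)
  expect_equal(max(nb), 1)
  expect_equal(min(nb), 0)
  expect_warning(nb0 <- normalize_bdm(compute_bdm(constant_image())),
                 "degenerate")
  expect_equal(nb0, matrix(0, 4, 4))
})

test_that("thresholding follows the similarity rule and removes self-loops", {
  img <- gray_image(matrix(c(0, 128, 255, 128), 2, 2, byrow = TRUE))
  nb <- normalize_bdm(compute_bdm(img))
  g <- threshold_adjacency(nb, 0.5)
  el <- igraph::as_edgelist(g)
  # pixels 1 (=128) and 2 (=255): 1 - 127/255 = 0.502 >= 0.5 -> edge;
  # pixels 1 and 3 are identical -> edge; 0-128 and 0-255 fail at tau=0.5
  expect_true(all(apply(el, 1, function(e) !"0" %in% e)))
  expect_true(igraph::are_adjacent(g, "1", "3"))
  expect_true(igraph::are_adjacent(g, "1", "2"))
  g0 <- threshold_adjacency(nb, 0)
  expect_equal(igraph::ecount(g0), choose(4, 2))  # complete graph
  expect_equal(sum(igraph::which_loop(g0)), 0)
  suppressWarnings(gc1 <- threshold_adjacency(normalize_bdm(compute_bdm(constant_image())), 1))
  expect_equal(igraph::ecount(gc1), choose(4, 2))
  expect_error(threshold_adjacency(nb, 1.5), "tau")
})

test_that("edge count decreases monotonically in tau over random images", {
  set.seed(42)
  taus <- seq(0, 1, by = 0.1)
  for (rep in 1:5) {
    img <- gray_image(matrix(runif(36, 0, 255), 6, 6))
    nb <- normalize_bdm(compute_bdm(img))
    ec <- vapply(taus, function(t) igraph::ecount(threshold_adjacency(nb, t)), 0)
    expect_true(all(diff(ec) <= 0))
  }
})

test_that("BDM invariants hold for random images", {
  set.seed(7)
  for (rep in 1:10) {
    img <- gray_image(matrix(runif(25, 0, 255), 5, 5))
    bdm <- compute_bdm(img)
    expect_true(isSymmetric(bdm))
    expect_equal(diag(bdm), rep(0, 25))
    expect_true(all(bdm >= 0))
    nb <- normalize_bdm(bdm)
    expect_true(all(nb >= 0 & nb <= 1))
    expect_equal(max(nb), 1)
  }
})

test_that("largest_component keeps the biggest piece with first-vertex ties", {
  g <- igraph::make_ring(5)
  expect_identical(largest_component(g), g)
  h <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_ring(3))
  expect_message(lc <- largest_component(h), "2 components")
  expect_equal(igraph::vcount(lc), 5)
  # two components of size 4: keep the one containing the first vertex
  t2 <- igraph::disjoint_union(igraph::make_ring(4), igraph::make_full_graph(4))
  lc2 <- largest_component(t2, quiet = TRUE)
  expect_equal(igraph::vcount(lc2), 4)
  expect_equal(igraph::ecount(lc2), 4)  # the ring, containing vertex 1
  expect_error(largest_component(igraph::make_empty_graph(0)), "empty")
})

test_that("row-major pixel indexing round-trips", {
  m <- 7
  for (idx in c(0L, 3L, 13L, 27L)) {
    rc <- pixel_coord(idx, m)
    expect_equal(pixel_index(rc[, "row"], rc[, "col"], m), idx,
                 ignore_attr = TRUE)
  }
})

test_that("edge lists round-trip through plain text files", {
  g <- image_to_graph(gray_image(matrix(c(0, 4, 8, 250), 2, 2, byrow = TRUE)),
                      tau = 0.97, keep_all_components = TRUE)
  tmp <- tempfile(fileext = ".txt")
  write_edgelist_txt(g, tmp)
  g2 <- read_edgelist_txt(tmp)
  expect_equal(igraph::ecount(g2), igraph::ecount(g))
  lines <- readLines(tmp)
  expect_true(all(grepl("^\\d+ \\d+$", lines)))
})
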