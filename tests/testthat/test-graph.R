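hex_coords <- function(rows = 7, cols = 7, spacing = 1) {
  make_lattice(sim_config(rows = rows, cols = cols, spacing = spacing))
}

center_spot <- function(coords) {
  mid <- colMeans(coords)
  which.min(rowSums(sweep(coords, 2L, mid)^2))
}

test_that("radius rule links strictly inside the radius and never at distance 0", {
  expect_equal(nrow(build_sng_radius(rbind(c(0, 0), c(2, 0)), 1)$edges), 0)
  # 3x3 unit grid, radius 1.1: center spot has its 4 rook neighbors
  g33 <- expand.grid(x = 0:2, y = 0:2)
  g <- build_sng_radius(as.matrix(g33), 1.1)
  expect_equal(sng_degree(g)[5], 4)
  # coincident points are not linked (strict d > 0)
  dup <- build_sng_radius(rbind(c(0, 0), c(0, 0), c(0.5, 0)), 1)
  expect_false(any(dup$edges[, 1] == 1 & dup$edges[, 2] == 2))
  expect_error(build_sng_radius(rbind(c(0, 0), c(NA, 0)), 1), "non-finite")
})

test_that("covering-radius KNN captures the hex 6-ring and handles ties", {
  co <- hex_coords(9, 9)
  g <- build_sng_knn(co, 6)
  expect_equal(sng_degree(g)[center_spot(co)], 6)
  # two points, k = 1: a single edge
  expect_equal(nrow(build_sng_knn(rbind(c(0, 0), c(1, 0)), 1)$edges), 1)
  # collinear equally spaced points, k = 2: middle point linked both sides
  g5 <- build_sng_knn(cbind(1:5, 0), 2)
  nb3 <- sort(c(g5$edges[g5$edges[, 1] == 3, 2], g5$edges[g5$edges[, 2] == 3, 1]))
  expect_true(all(c(2, 4) %in% nb3))
  expect_error(build_sng_knn(cbind(1:3, 0), 3), "k must satisfy")
  # every spot covers at least k neighbors (ties may add more)
  expect_true(all(sng_degree(g) >= 6))
})

test_that("adjacency is symmetric and binary with no self-loops for all builders", {
  co <- hex_coords(5, 5)
  for (g in list(build_sng_knn(co, 6), build_sng_radius(co, 1.2))) {
    A <- adjacency(g)
    expect_equal(max(abs(A - Matrix::t(A))), 0)
    expect_true(all(A@x == 1))
    expect_equal(sum(Matrix::diag(A)), 0)
  }
})

slice_of <- function(coords, shift = c(0, 0)) {
  co <- sweep(coords, 2L, -shift)
  spatial_dataset(matrix(1, nrow(co), 2), co)
}

test_that("two-slice graph is the KNN over the union point set", {
  co <- hex_coords(5, 5)
  near <- slice_of(co)
  far <- slice_of(co, shift = c(1e4, 0))
  # far-apart slices: no cross edges, graph is the union of per-slice graphs
  g <- build_2dsng(list(near, far))
  per <- build_sng_knn(co, 6)
  expect_equal(nrow(g$edges), 2 * nrow(per$edges))
  n1 <- nrow(co)
  expect_false(any(g$edges[, 1] <= n1 & g$edges[, 2] > n1))
  # identical overlapping slices: cross-slice edges exist
  g2 <- build_2dsng(list(near, slice_of(co)))
  expect_true(any(g2$edges[, 1] <= n1 & g2$edges[, 2] > n1))
  expect_error(build_2dsng(list(near)), "exactly 2")
  expect_error(build_2dsng(list(near, near, near)), "build_3dsng")
})

test_that("vertical stack links only adjacent slices within the 13/20 caps", {
  co <- hex_coords(9, 9)
  slices <- lapply(1:4, function(s) slice_of(co))
  g <- build_3dsng(slices)
  n1 <- nrow(co)
  deg <- sng_degree(g)
  slice_id <- rep(1:4, each = n1)
  ctr <- center_spot(co)
  # outer-slice interior spot: at most 6 + 7 neighbors; middle: 6 + 7 + 7
  expect_lte(deg[ctr], 13)
  expect_equal(deg[ctr], 13)              # perfect stack attains the cap
  expect_equal(deg[n1 + ctr], 20)
  # no edge ever skips a slice
  es <- cbind(slice_id[g$edges[, 1]], slice_id[g$edges[, 2]])
  expect_true(all(abs(es[, 1] - es[, 2]) <= 1))
  expect_error(build_3dsng(slices[1:2]), "build_2dsng")
})

test_that("stack graph restricted to one slice equals the per-slice KNN graph", {
  co <- hex_coords(6, 6)
  slices <- lapply(1:3, function(s) slice_of(co))
  g <- build_3dsng(slices)
  n1 <- nrow(co)
  within2 <- g$edges[g$edges[, 1] > n1 & g$edges[, 1] <= 2 * n1 &
                     g$edges[, 2] > n1 & g$edges[, 2] <= 2 * n1, ] - n1
  per <- build_sng_knn(co, 6)$edges
  expect_equal(within2[order(within2[, 1], within2[, 2]), , drop = FALSE],
               per, ignore_attr = TRUE)
})

test_that("build_graph dispatches on slice count and exports edges", {
  d <- sim_standard_small(seed = 5)
  g <- build_graph(d)
  expect_identical(g$mode, "knn")
  path <- file.path(withr::local_tempdir(), "edges.tsv")
  export_edges(g, spot_ids = d$spot_ids, path = path)
  df <- read.delim(path)
  expect_equal(nrow(df), nrow(g$edges))
  expect_true(all(df$src %in% d$spot_ids))
})
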