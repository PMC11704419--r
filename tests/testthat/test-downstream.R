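test_that("agreement indices satisfy their identities and match pair counting", {
  truth <- c(1, 1, 2, 2, 3, 3)
  expect_equal(ari(truth, truth), 1)
  expect_equal(nmi(truth, truth), 1)
  expect_equal(fms(truth, truth), 1)
  # a single constant prediction carries no information after chance correction
  expect_equal(ari(rep(1, 6), truth), 0)
  # arbitrary partitions: cross-check against the brute-force pair loop
  set.seed(6)
  for (rep in 1:4) {
    a <- sample(1:3, 12, replace = TRUE)
    b <- sample(1:3, 12, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-12)
    expect_equal(fms(a, b), oracle_fms(a, b), tolerance = 1e-12)
    expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-10)
    # symmetry and invariance to relabeling
    expect_equal(ari(a, b), ari(b, a))
    expect_equal(ari(a, b), ari(4 - a, b))
  }
  expect_error(ari(1:3, 1:4), "length")
})

test_that("mixture clustering recovers well-separated blobs deterministically", {
  set.seed(7)
  H <- rbind(matrix(rnorm(60, 0, 0.1), 30, 2),
             matrix(rnorm(60, 8, 0.1), 30, 2))
  lab <- rep(1:2, each = 30)
  cl <- cluster_domains(H, k = 2, seed = 1)
  expect_equal(ari(cl$labels, lab), 1)
  expect_equal(cl$k, 2)
  expect_match(cl$model_kind, "mclust")
  expect_identical(cluster_domains(H, k = 2, seed = 1)$labels, cl$labels)
  expect_error(cluster_domains(H, k = 1), "k must")
  expect_error(cluster_domains(matrix(1, 10, 3), k = 2), "degenerate")
  # works straight off a fitted model too
  expect_s3_class(cl, "cluster_result")
})

test_that("iLISI reaches its analytic extremes", {
  set.seed(8)
  # two identically distributed, fully interleaved batches: ~2
  H <- matrix(rnorm(400), 200, 2)
  b <- rep(1:2, 100)
  expect_gt(median(ilisi(H, b)), 1.8)
  # fully separated batches: ~1
  Hs <- rbind(matrix(rnorm(200, 0, 0.1), 100, 2),
              matrix(rnorm(200, 50, 0.1), 100, 2))
  expect_lt(median(ilisi(Hs, rep(1:2, each = 100))), 1.05)
  # three equal mixed batches: ~3; always within [1, n_batches]
  H3 <- matrix(rnorm(600), 300, 2)
  v3 <- ilisi(H3, rep(1:3, 100))
  expect_gt(median(v3), 2.6)
  expect_true(all(v3 >= 1 - 1e-9 & v3 <= 3 + 1e-9))
  expect_warning(one <- ilisi(H, rep(1, 200)), "single batch")
  expect_true(all(one == 1))
})

test_that("internal cluster-quality indices behave on synthetic geometries", {
  set.seed(9)
  far <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2),
               matrix(rnorm(100, 20, 0.05), 50, 2))
  lab <- rep(1:2, each = 50)
  expect_gt(calinski_harabasz(far, lab), 1e4)
  expect_lt(davies_bouldin(far, lab), 0.01)
  # point clusters: zero within-scatter, DB exactly 0
  pts <- rbind(matrix(1, 5, 2), matrix(5, 5, 2))
  expect_equal(davies_bouldin(pts, rep(1:2, each = 5)), 0)
  # random labels on a single blob: CH concentrates near 1
  blob <- matrix(rnorm(1000), 500, 2)
  expect_lt(abs(calinski_harabasz(blob, sample(1:2, 500, TRUE)) - 1), 1)
  expect_error(calinski_harabasz(far, rep(1, 100)), "2 clusters")
})

test_that("attention export carries positions, weights and self-loop flags", {
  tp <- tiny_problem(n = 9, d_in = 6, dims = c(5, 3), seed = 101, k = 2)
  d <- spatial_dataset(tp$X, tp$coords)
  f <- stgmae(d, graph = tp$graph, dims = c(5, 3), epochs = 2, seed = 1)
  df <- attention_edges(f, layer = 1)
  ecache <- stgmae:::.edge_cache(tp$graph)
  expect_equal(nrow(df), length(ecache$src))  # all directed pairs incl self
  sums <- tapply(df$weight, df$src, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  expect_identical(df$self_loop, df$src == df$dst)
  expect_equal(df$x_src, tp$coords[df$src, 1])
  expect_error(attention_edges(f, layer = 2), "valid layers")
  path <- file.path(withr::local_tempdir(), "att.tsv")
  attention_edges(f, layer = 1, path = path)
  expect_true(file.exists(path))
})

test_that("metrics report aggregates external, internal and mixing metrics", {
  set.seed(11)
  H <- rbind(matrix(rnorm(80, 0, 0.2), 40, 2),
             matrix(rnorm(80, 6, 0.2), 40, 2))
  lab <- rep(1:2, each = 40)
  mr <- metrics_report(H, lab, truth = lab, batch = rep(1:2, 40))
  expect_equal(mr$ari, 1)
  expect_equal(mr$nmi, 1)
  expect_equal(mr$fms, 1)
  expect_true(mr$calinski_harabasz > 0 && mr$davies_bouldin >= 0)
  expect_true(mr$ilisi_median >= 1)
})
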