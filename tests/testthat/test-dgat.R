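two_node_graph <- function() build_sng_knn(rbind(c(0, 0), c(1, 0)), 1)

test_that("attention matches the closed-form two-node worked example", {
  # x = (1, 2), W0 = W1 = [1], v = [1]:
  # e_aa = sigmoid(1 + 1), e_ab = sigmoid(1 + 2), att = softmax(e_a.)
  rec <- attention_scores(matrix(c(1, 2), 2, 1), two_node_graph(),
                          W0 = matrix(1), W1 = matrix(1), v = 1)
  e_aa <- 1 / (1 + exp(-2))
  e_ab <- 1 / (1 + exp(-3))
  att_aa <- exp(e_aa) / (exp(e_aa) + exp(e_ab))
  i <- which(rec$src == 1 & rec$dst == 1)
  j <- which(rec$src == 1 & rec$dst == 2)
  expect_equal(rec$score[i], e_aa, tolerance = 1e-12)
  expect_equal(rec$weight[i], att_aa, tolerance = 1e-12)
  expect_equal(rec$weight[j], 1 - att_aa, tolerance = 1e-12)
  # the spot embedding the weights imply: ELU(att_aa*1 + att_ab*2) > 1
  h_a <- att_aa * 1 + (1 - att_aa) * 2
  expect_equal(h_a, 1.5179, tolerance = 1e-4)
})

test_that("zero scoring vector gives uniform attention; isolated nodes attend to themselves", {
  set.seed(10)
  co <- cbind(runif(6), runif(6))
  g <- build_sng_knn(co, 3)
  H <- matrix(rnorm(12), 6, 2)
  rec <- attention_scores(H, g, W0 = matrix(rnorm(4), 2, 2),
                          W1 = matrix(rnorm(4), 2, 2), v = c(0, 0))
  for (i in 1:6) {
    w <- rec$weight[rec$src == i]
    expect_equal(w, rep(1 / length(w), length(w)), tolerance = 1e-12)
  }
  # two far-apart points with a radius graph: both isolated, att_ii = 1
  giso <- build_sng_radius(rbind(c(0, 0), c(100, 0)), 1)
  r2 <- attention_scores(matrix(1:2, 2, 1), giso, matrix(1), matrix(1), 1)
  expect_identical(r2$src, r2$dst)
  expect_equal(r2$weight, c(1, 1))
})

test_that("attention rows sum to one within 1e-6 with entries in [0, 1]", {
  tp <- tiny_problem(n = 12, d_in = 6, dims = c(5, 3), seed = 21, k = 3)
  inf <- encode(tp$graph, tp$X, tp$params)
  for (rec in inf$attention) {
    sums <- rowsum(rec$weight, rec$src)[, 1]
    expect_true(all(abs(sums - 1) < 1e-6))
    expect_true(all(rec$weight >= 0 & rec$weight <= 1))
  }
})

test_that("encode and decode match the dense per-node oracle to 1e-10", {
  for (seed in c(31, 32)) {
    tp <- tiny_problem(n = 5, d_in = 4, dims = c(3, 2), seed = seed, k = 2)
    inf <- encode(tp$graph, tp$X, tp$params)
    orc <- oracle_encode(tp$X, tp$graph, tp$params)
    expect_lt(max(abs(inf$H - orc$H)), 1e-10)
    # attention records agree with the dense oracle matrices
    P <- as.matrix(attention_matrix(inf$attention[[1]]))
    expect_lt(max(abs(P - orc$att[[1]])), 1e-10)
    # decoder: transposed weights, reused attention
    Hr <- apply_remask(inf$H, draw_remask_plan(5, 0.4, rng_seed = seed),
                       tp$params$h_mask)
    Z <- decode(tp$graph, Hr, tp$params, inf$attention)
    expect_lt(max(abs(Z - oracle_decode(Hr, tp$graph, tp$params, orc$att))),
              1e-10)
  }
  # degenerate single-layer stack: plain unweighted aggregation both ways
  tp1 <- tiny_problem(n = 3, d_in = 3, dims = 2, seed = 33, k = 1)
  inf1 <- encode(tp1$graph, tp1$X, tp1$params)
  orc1 <- oracle_encode(tp1$X, tp1$graph, tp1$params)
  expect_lt(max(abs(inf1$H - orc1$H)), 1e-10)
  Z1 <- decode(tp1$graph, inf1$H, tp1$params, list())
  expect_lt(max(abs(Z1 - oracle_decode(inf1$H, tp1$graph, tp1$params,
                                       list()))), 1e-10)
})

test_that("the decoder owns no weights: all parameters are encoder-side", {
  params <- dgat_params(10, dims = c(6, 3), seed = 1)
  expected <- (6 * 10 + 6 * 10 + 6) +  # layer 1: W0, W1, v
    3 * 6 +                            # layer 2: W0 only (no attention)
    10 + 3                             # the two mask tokens
  expect_equal(stgmae:::.n_params(params), expected)
  expect_null(params$layers[[2]]$W1)
  expect_false(params$layers[[2]]$has_attention)
})

test_that("consistent spot permutation permutes embeddings and reconstructions", {
  tp <- tiny_problem(n = 8, d_in = 5, dims = c(4, 2), seed = 41, k = 2)
  inf <- encode(tp$graph, tp$X, tp$params)
  Z <- decode(tp$graph, inf$H, tp$params, inf$attention)
  perm <- sample(8)
  inv <- order(perm)
  pg <- stgmae:::.new_sng(8, cbind(inv[tp$graph$edges[, 1]],
                                   inv[tp$graph$edges[, 2]]),
                          "knn", tp$graph$params)
  infp <- encode(pg, tp$X[perm, ], tp$params)
  expect_equal(infp$H, inf$H[perm, ], tolerance = 1e-8)
  Zp <- decode(pg, infp$H, tp$params, infp$attention)
  expect_equal(Zp, Z[perm, ], tolerance = 1e-8)
})

test_that("dual-view pass has the stated shapes and degenerates correctly", {
  tp <- tiny_problem(n = 20, d_in = 40, dims = c(512, 30), seed = 51, k = 3)
  set.seed(1)
  out <- forward_dual(tp$graph, tp$X, tp$params, mask_ratio = 0,
                      replace_ratio = 0, remask_ratio = 0)
  # no corruption anywhere: the two views are the same computation
  expect_identical(out$Z0, out$Z1)
  expect_identical(out$X_tilde, tp$X)
  expect_equal(dim(out$H), c(20, 30))
  expect_equal(dim(out$Z0), c(20, 40))
  # at the stated ratios the two remask draws differ essentially always
  set.seed(2)
  co <- cbind(runif(1000), runif(1000))
  big <- forward_dual(build_sng_knn(co, 3),
                      matrix(abs(rnorm(3000)), 1000, 3),
                      dgat_params(3, dims = c(4, 2), seed = 3))
  expect_false(identical(big$plans$remask0$remask_set,
                         big$plans$remask1$remask_set))
  expect_length(big$plans$mask$masked_set, 500)
})

test_that("encoder input validation and all-zero propagation", {
  tp <- tiny_problem(seed = 61)
  expect_error(encode(tp$graph, tp$X[, 1:2], tp$params), "expects")
  H0 <- encode(tp$graph, matrix(0, 6, 5), tp$params)$H
  expect_true(all(H0 == 0))  # ELU(0) = 0 through every layer
})
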