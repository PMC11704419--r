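test_that("scaled cosine error satisfies its analytic identities", {
  x <- matrix(c(1, 0), 1, 2)
  for (g in c(1, 2, 3)) expect_equal(sce(x, x, g), 0)
  expect_equal(sce(x, matrix(c(0, 1), 1, 2), gamma = 2), 1)   # orthogonal
  expect_equal(sce(x, -x, gamma = 2), 4)                      # antiparallel
  # scale invariance per row and permutation invariance over rows
  set.seed(1)
  X <- matrix(rnorm(12), 4, 3)
  Z <- matrix(rnorm(12), 4, 3)
  expect_equal(sce(X, 3.7 * X), 0)
  p <- sample(4)
  expect_equal(sce(X, Z), sce(X[p, ], Z[p, ]))
  expect_warning(sce(matrix(0, 1, 3), matrix(1, 1, 3)), "zero-norm")
})

test_that("total loss splits views by mask partition and reduces to the L2 term", {
  set.seed(2)
  X <- matrix(abs(rnorm(12)) + 0.5, 4, 3)
  plan <- draw_mask_plan(4, 0.5, 0, rng_seed = 3)
  params <- dgat_params(3, dims = c(3, 2), seed = 4)
  # exact reconstructions on the scored rows: only weight decay remains
  lb <- total_loss(X, X, X, plan, params, gamma = 2, weight_decay = 1e-3)
  expect_equal(lb$sce0, 0)
  expect_equal(lb$sce1, 0)
  expect_equal(lb$total, lb$wd)
  wd_direct <- 1e-3 * (sum(params$layers[[1]]$W0^2) +
                       sum(params$layers[[1]]$W1^2) +
                       sum(params$layers[[2]]$W0^2))
  expect_equal(lb$wd, wd_direct)
  # zero weights: no decay penalty
  p0 <- params
  for (k in 1:2) {
    p0$layers[[k]]$W0[] <- 0
    if (!is.null(p0$layers[[k]]$W1)) p0$layers[[k]]$W1[] <- 0
  }
  expect_equal(total_loss(X, X, X, plan, p0)$wd, 0)
  # hand-evaluated breakdown on arbitrary reconstructions
  Z0 <- matrix(rnorm(12), 4, 3)
  Z1 <- matrix(rnorm(12), 4, 3)
  lb2 <- total_loss(X, Z0, Z1, plan, params, gamma = 2, weight_decay = 0)
  byrow <- function(rows, Z) mean(sapply(rows, function(i) {
    cc <- sum(X[i, ] * Z[i, ]) / (sqrt(sum(X[i, ]^2)) * sqrt(sum(Z[i, ]^2)))
    (1 - cc)^2
  }))
  expect_equal(lb2$sce0, byrow(plan$masked_set, Z0))
  expect_equal(lb2$sce1, byrow(plan$keep_set, Z1))
  expect_equal(lb2$total, lb2$sce0 + lb2$sce1)
})

test_that("analytic gradients match central finite differences", {
  tp <- tiny_problem(n = 8, d_in = 5, dims = c(4, 3), seed = 71, k = 2)
  ec <- stgmae:::.edge_cache(tp$graph)
  plans <- list(mask = draw_mask_plan(8, 0.5, 0.25, rng_seed = 72),
                remask0 = draw_remask_plan(8, 0.5, rng_seed = 73),
                remask1 = draw_remask_plan(8, 0.5, rng_seed = 74))
  st <- stgmae:::.train_step(tp$X, tp$params, ec, plans, gamma = 2,
                             weight_decay = 1e-3)
  lossf <- function(pp)
    stgmae:::.train_step(tp$X, pp, ec, plans, 2, 1e-3)$loss$total
  h <- 1e-6
  check <- function(get, set, ana) {
    arr <- get(tp$params)
    set.seed(75)
    for (i in sample(length(arr), min(8, length(arr)))) {
      pp <- tp$params
      pp <- set(pp, i, arr[i] + h); up <- lossf(pp)
      pp <- set(pp, i, arr[i] - h); dn <- lossf(pp)
      num <- (up - dn) / (2 * h)
      expect_equal(ana[i], num, tolerance = 1e-4)
    }
  }
  for (k in 1:2) for (nm in c("W0", "W1", "v")) {
    if (is.null(tp$params$layers[[k]][[nm]])) next
    check(function(p) p$layers[[k]][[nm]],
          function(p, i, val) { p$layers[[k]][[nm]][i] <- val; p },
          st$grads$layers[[k]][[nm]])
  }
  for (nm in c("x_mask", "h_mask"))
    check(function(p) p[[nm]],
          function(p, i, val) { p[[nm]][i] <- val; p },
          st$grads[[nm]])
})

test_that("gradient flows to both mask tokens", {
  tp <- tiny_problem(n = 10, d_in = 5, dims = c(4, 3), seed = 81, k = 2)
  ec <- stgmae:::.edge_cache(tp$graph)
  plans <- list(mask = draw_mask_plan(10, 0.5, 0, rng_seed = 82),
                remask0 = draw_remask_plan(10, 0.5, rng_seed = 83),
                remask1 = draw_remask_plan(10, 0.5, rng_seed = 84))
  st <- stgmae:::.train_step(tp$X, tp$params, ec, plans, 2, 1e-3)
  expect_gt(sqrt(sum(st$grads$x_mask^2)), 0)
  expect_gt(sqrt(sum(st$grads$h_mask^2)), 0)
})

small_fit_data <- function(seed = 91) {
  d <- simulate_dataset(sim_config(rows = 6, cols = 6, n_genes = 30,
                                   n_domains = 2, seed = seed))
  preprocess(d, min_cells = 1)
}

test_that("fitting is reproducible under a seed and runs at epochs = 1", {
  p <- small_fit_data()
  f1 <- stgmae(p, dims = c(8, 4), epochs = 1, seed = 5)
  expect_true(is.finite(f1$loss$total[1]))
  f2 <- stgmae(p, dims = c(8, 4), epochs = 3, seed = 5)
  f3 <- stgmae(p, dims = c(8, 4), epochs = 3, seed = 5)
  expect_identical(f2$loss, f3$loss)
  expect_identical(f2$latent, f3$latent)
  expect_equal(f1$loss$total[1], f2$loss$total[1])
})

test_that("degenerate masking configurations are rejected or handled", {
  p <- small_fit_data()
  expect_error(stgmae(p, dims = c(8, 4), epochs = 1, mask_ratio = 0),
               "keep_only_loss")
  expect_error(stgmae(p, dims = c(8, 4), epochs = 1, mask_ratio = 1),
               "kept")
  # heterogeneity-style run: keep-only loss with no masking allowed
  f <- stgmae(p, dims = c(8, 4), epochs = 2, mask_ratio = 0,
              replace_ratio = 0, seed = 1, keep_only_loss = TRUE)
  expect_true(is.finite(f$loss$total[2]))
  expect_warning(stgmae(p, dims = c(8, 4), epochs = 1, gamma = 5, seed = 1),
                 "outside")
})

test_that("inference is deterministic with the documented output ranges", {
  p <- small_fit_data()
  f <- stgmae(p, dims = c(8, 4), epochs = 5, seed = 2)
  expect_equal(ncol(f$latent), 4)
  expect_identical(predict(f), predict(f))
  Z <- predict(f, type = "denoised")
  expect_identical(Z, get_denoised(f))
  expect_true(all(Z >= -1))            # ELU range
  expect_identical(get_latent(f), f$latent)
  expect_equal(dim(residuals(f)), dim(p$expr))
  expect_equal(p$expr - fitted(f), residuals(f), ignore_attr = TRUE)
})

test_that("model object methods expose the fit", {
  p <- small_fit_data()
  f <- stgmae(p, dims = c(8, 4), epochs = 2, seed = 3)
  expect_output(print(f), "autoencoder")
  expect_output(print(summary(f)), "weight-tied")
  cf <- coef(f)
  expect_true(all(c("W0_1", "W1_1", "v_1", "W0_2", "x_mask", "h_mask") %in%
                  names(cf)))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
})
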