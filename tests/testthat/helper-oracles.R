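# Independent oracles used across tests: literal per-node loop evaluations of
# the model equations (no shared code with the vectorized implementation) and
# brute-force pair-counting for the clustering indices.

oracle_sigmoid <- function(x) 1 / (1 + exp(-x))
oracle_elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

# encoder evaluated node by node from the printed equations, dense attention
oracle_encode <- function(X, graph, params) {
  n <- nrow(X)
  A <- as.matrix(adjacency(graph, self_loops = TRUE))
  h <- X
  att_list <- list()
  for (k in seq_along(params$layers)) {
    lay <- params$layers[[k]]
    W0 <- lay$W0
    newh <- matrix(0, n, nrow(W0))
    if (lay$has_attention) {
      att <- matrix(0, n, n)
      for (i in seq_len(n)) {
        Ni <- which(A[i, ] > 0)
        e <- vapply(Ni, function(j)
          sum(lay$v * oracle_sigmoid(as.numeric(W0 %*% h[i, ]) +
                                     as.numeric(lay$W1 %*% h[j, ]))),
          numeric(1))
        w <- exp(e - max(e))
        w <- w / sum(w)
        att[i, Ni] <- w
        agg <- rep(0, nrow(W0))
        for (m in seq_along(Ni))
          agg <- agg + w[m] * as.numeric(W0 %*% h[Ni[m], ])
        newh[i, ] <- oracle_elu(agg)
      }
      att_list[[k]] <- att
    } else {
      for (i in seq_len(n)) {
        Ni <- which(A[i, ] > 0)
        agg <- rep(0, nrow(W0))
        for (j in Ni) agg <- agg + as.numeric(W0 %*% h[j, ])
        newh[i, ] <- oracle_elu(agg)
      }
    }
    h <- newh
  }
  list(H = h, att = att_list)
}

# decoder with explicitly transposed weights and reused dense attention
oracle_decode <- function(Hhat, graph, params, att_list) {
  n <- nrow(Hhat)
  A <- as.matrix(adjacency(graph, self_loops = TRUE))
  cur <- Hhat
  for (k in rev(seq_along(params$layers))) {
    W0hat <- t(params$layers[[k]]$W0)
    newh <- matrix(0, n, nrow(W0hat))
    for (i in seq_len(n)) {
      Ni <- which(A[i, ] > 0)
      agg <- rep(0, nrow(W0hat))
      for (j in Ni) {
        w <- if (k > 1L) att_list[[k - 1L]][i, j] else 1
        agg <- agg + w * as.numeric(W0hat %*% cur[j, ])
      }
      newh[i, ] <- oracle_elu(agg)
    }
    cur <- newh
  }
  cur
}

# pairwise-agreement counts by explicit double loop
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) tp <- tp + 1
    else if (sa && !sb) fp <- fp + 1
    else if (!sa && sb) fn <- fn + 1
    else tn <- tn + 1
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_ari <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  tp <- pc["tp"]; fp <- pc["fp"]; fn <- pc["fn"]; tn <- pc["tn"]
  num <- 2 * (tp * tn - fp * fn)
  den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
  unname(num / den)
}

oracle_fms <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  unname(pc["tp"] / sqrt((pc["tp"] + pc["fp"]) * (pc["tp"] + pc["fn"])))
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  ct <- table(a, b) / n
  px <- rowSums(ct); py <- colSums(ct)
  hx <- -sum(ifelse(px > 0, px * log(px), 0))
  hy <- -sum(ifelse(py > 0, py * log(py), 0))
  mi <- sum(ifelse(ct > 0, ct * log(ct / (px %o% py)), 0))
  mi / ((hx + hy) / 2)
}

# small random test model + graph used by several dgat/training tests
tiny_problem <- function(n = 6, d_in = 5, dims = c(4, 3), seed = 11,
                         k = 2) {
  set.seed(seed)
  X <- matrix(abs(rnorm(n * d_in)) + 0.1, n, d_in)
  coords <- cbind(runif(n), runif(n))
  graph <- build_sng_knn(coords, k = k)
  params <- dgat_params(d_in, dims = dims, seed = seed + 1)
  # perturb tokens away from zero so their gradients are generic
  params$x_mask <- rnorm(d_in, sd = 0.1)
  params$h_mask <- rnorm(dims[length(dims)], sd = 0.1)
  list(X = X, coords = coords, graph = graph, params = params)
}
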