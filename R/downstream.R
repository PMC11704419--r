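#' Model-based clustering of latent embeddings
#'
#' Fits a Gaussian mixture with shared ellipsoidal covariance ("EEE") to the
#' embedding matrix via \pkg{mclust}, with the cluster count fixed to the
#' requested number of spatial domains (matching the convention of setting
#' `k` to the annotation count).
#'
#' @param H N-by-d embedding matrix, or a fitted `stgmae` (its latent
#'   embedding is used).
#' @param k number of clusters, `2 <= k <= N`.
#' @param seed RNG seed controlling the k-means restarts; the EM refinement
#'   is deterministic given the initialization.
#' @param model mclust covariance model string (default `"EEE"`).
#' @param nstart k-means restarts for the initialization (default 10).
#' @return A `cluster_result`: list with integer `labels` in `1..k`, `k`,
#'   `seed` and `model_kind`.
#' @export
cluster_domains <- function(H, k, seed = 1, model = "EEE", nstart = 10) {
  if (inherits(H, "stgmae")) H <- H$latent
  H <- as.matrix(H)
  if (k < 2 || k > nrow(H)) stop("k must satisfy 2 <= k <= N")
  keep <- apply(H, 2L, stats::sd) > 0
  if (!any(keep))
    stop("degenerate embedding: every dimension has zero variance")
  H <- H[, keep, drop = FALSE]
  set.seed(as.integer(seed))
  km <- stats::kmeans(scale(H), centers = k, nstart = nstart,
                      iter.max = 100)
  # EM refinement of the k-means partition under the requested model;
  # mclust's me() resolves me<MODEL> in the caller frame
  fn <- paste0("me", model)
  assign(fn, getExportedValue("mclust", fn))
  em <- try(mclust::me(data = H, modelName = model,
                       z = mclust::unmap(km$cluster, groups = seq_len(k))),
            silent = TRUE)
  if (!inherits(em, "try-error") && !is.null(em$z) && !anyNA(em$z)) {
    labels <- as.integer(mclust::map(em$z))
    kind <- paste0(model, " (mclust, k-means init)")
  } else {
    labels <- as.integer(km$cluster)
    kind <- "k-means (EM refinement unavailable)"
  }
  structure(list(labels = labels, k = as.integer(k),
                 seed = as.integer(seed), model_kind = kind),
            class = "cluster_result")
}

#' @method print cluster_result
#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", x$k, "clusters over", length(x$labels),
      "spots [", x$model_kind, "]\n")
  print(table(cluster = x$labels))
  invisible(x)
}

.check_labels <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("label vectors differ in length (", length(pred), " vs ",
         length(truth), ")")
  if (anyNA(pred) || anyNA(truth)) stop("labels contain missing values")
  list(p = as.integer(factor(pred)), t = as.integer(factor(truth)))
}

#' Adjusted Rand index
#' @param pred,truth two partitions of the same spots (any label coding).
#' @return ARI in `[-1, 1]`; 1 iff the partitions agree up to relabeling.
#' @export
ari <- function(pred, truth) {
  l <- .check_labels(pred, truth)
  mclust::adjustedRandIndex(l$p, l$t)
}

#' Normalized mutual information
#' @inheritParams ari
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(pred, truth) {
  l <- .check_labels(pred, truth)
  igraph::compare(l$p, l$t, method = "nmi")
}

#' Fowlkes-Mallows score
#'
#' Geometric mean of pairwise precision and recall, from the pair-counting
#' contingency table.
#'
#' @inheritParams ari
#' @return FMS in `[0, 1]`.
#' @export
fms <- function(pred, truth) {
  l <- .check_labels(pred, truth)
  ct <- table(l$p, l$t)
  tp <- sum(choose(ct, 2))
  pa <- sum(choose(rowSums(ct), 2))
  pb <- sum(choose(colSums(ct), 2))
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

#' Integration local inverse Simpson's index
#'
#' Per-spot effective number of batches in an embedding neighborhood:
#' Gaussian-kernel weights over the nearest neighbors are tuned to a fixed
#' perplexity, batch proportions are computed under those weights, and the
#' inverse Simpson concentration `1 / sum(p_b^2)` is returned. Values lie in
#' `[1, n_batches]`: 1 means pure (unmixed) neighborhoods, `n_batches` means
#' perfect mixing.
#'
#' @param H N-by-d embedding (or expression) matrix.
#' @param batch batch/slice label per spot.
#' @param perplexity kernel perplexity (default 30); the neighborhood is the
#'   `3 * perplexity` nearest spots.
#' @return Numeric vector of per-spot iLISI values (summarize with
#'   `median`).
#' @export
ilisi <- function(H, batch, perplexity = 30) {
  H <- as.matrix(H)
  n <- nrow(H)
  batch <- as.integer(factor(batch))
  if (length(batch) != n) stop("batch length does not match rows of H")
  n_b <- max(batch)
  if (n_b < 2L) {
    warning("single batch: iLISI is identically 1")
    return(rep(1, n))
  }
  k <- min(3L * perplexity, n - 1L)
  d2 <- .pairwise_dist(H)^2
  target <- log(min(perplexity, k))
  out <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    nb <- order(di)[seq_len(k)]
    dn <- di[nb]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-beta * dn)
      sw <- sum(w)
      if (sw <= 0) { entropy <- 0 } else {
        p <- w / sw
        entropy <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(entropy - target) < 1e-5) break
      if (entropy > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    w <- exp(-beta * dn)
    p <- w / sum(w)
    bl <- batch[-i][nb]
    props <- vapply(seq_len(n_b), function(b) sum(p[bl == b]), numeric(1))
    out[i] <- 1 / sum(props^2)
  }
  out
}

#' Calinski-Harabasz index
#'
#' Ratio of between-cluster to within-cluster dispersion,
#' `(B/(k-1)) / (W/(n-k))`; larger values indicate tighter, better-separated
#' clusters.
#'
#' @param H N-by-d embedding matrix.
#' @param labels cluster assignment per row (>= 2 nonempty clusters).
#' @return A nonnegative scalar.
#' @export
calinski_harabasz <- function(H, labels) {
  H <- as.matrix(H)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  n <- nrow(H)
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("empty cluster")
  gm <- colMeans(H)
  W <- 0; B <- 0
  for (c in seq_len(k)) {
    Hc <- H[labels == c, , drop = FALSE]
    cm <- colMeans(Hc)
    W <- W + sum(sweep(Hc, 2L, cm)^2)
    B <- B + nrow(Hc) * sum((cm - gm)^2)
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity
#' `(s_i + s_j) / d(c_i, c_j)` with `s` the mean within-cluster distance to
#' the centroid; smaller is better, 0 for point clusters.
#'
#' @inheritParams calinski_harabasz
#' @return A nonnegative scalar.
#' @export
davies_bouldin <- function(H, labels) {
  H <- as.matrix(H)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2) stop("need at least 2 clusters")
  if (any(tabulate(labels, k) == 0)) stop("empty cluster")
  cents <- t(vapply(seq_len(k), function(c)
    colMeans(H[labels == c, , drop = FALSE]), numeric(ncol(H))))
  s <- vapply(seq_len(k), function(c) {
    Hc <- H[labels == c, , drop = FALSE]
    mean(sqrt(rowSums(sweep(Hc, 2L, cents[c, ])^2)))
  }, numeric(1))
  dc <- .pairwise_dist(cents)
  db <- vapply(seq_len(k), function(i) {
    r <- (s[i] + s[-i]) / dc[i, -i]
    max(r)
  }, numeric(1))
  mean(db)
}

#' Export attention edges for microenvironment inspection
#'
#' Tabulates the trained attention weights of one layer together with the
#' spatial positions of both endpoints, so edges can be drawn at their
#' tissue locations and colored by weight. Self-loop rows are flagged.
#'
#' @param object a fitted `stgmae`, or a list of `attention_record`s.
#' @param layer which attention layer (default 1).
#' @param coords N-by-2 coordinates (taken from the fit when available).
#' @param path optional TSV output path.
#' @return Data frame `(src, dst, x_src, y_src, x_dst, y_dst, weight,
#'   self_loop)`.
#' @export
attention_edges <- function(object, layer = 1, coords = NULL, path = NULL) {
  if (inherits(object, "stgmae")) {
    att <- object$attention
    if (is.null(coords)) coords <- object$coords
  } else att <- object
  if (layer < 1 || layer > length(att))
    stop("layer ", layer, " has no attention; valid layers: ",
         if (length(att)) paste(seq_along(att), collapse = ", ")
         else "none")
  rec <- att[[layer]]
  stopifnot(inherits(rec, "attention_record"))
  if (is.null(coords)) stop("coordinates required")
  coords <- as.matrix(coords)
  df <- data.frame(src = rec$src, dst = rec$dst,
                   x_src = coords[rec$src, 1L], y_src = coords[rec$src, 2L],
                   x_dst = coords[rec$dst, 1L], y_dst = coords[rec$dst, 2L],
                   weight = rec$weight, layer = layer,
                   self_loop = rec$src == rec$dst)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}

#' Full evaluation report for a clustering
#'
#' @param H embedding matrix used for the internal indices.
#' @param pred predicted cluster labels.
#' @param truth optional ground-truth labels (external indices reported
#'   when present).
#' @param batch optional batch labels (median iLISI reported when present).
#' @return Named list of metric values.
#' @export
metrics_report <- function(H, pred, truth = NULL, batch = NULL) {
  out <- list(calinski_harabasz = calinski_harabasz(H, pred),
              davies_bouldin = davies_bouldin(H, pred))
  if (!is.null(truth)) {
    out$ari <- ari(pred, truth)
    out$nmi <- nmi(pred, truth)
    out$fms <- fms(pred, truth)
  }
  if (!is.null(batch))
    out$ilisi_median <- stats::median(ilisi(H, batch))
  out
}
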