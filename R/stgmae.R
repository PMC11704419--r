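#' Fit a dual-remask graph attention autoencoder
#'
#' Trains the self-supervised model on a spatial expression matrix: every
#' epoch a fresh masking plan corrupts the input (learnable mask token plus
#' a small random-replacement fraction), the dynamic-attention encoder maps
#' the corrupted features to a low-dimensional embedding, two independent
#' remaskings of that embedding are decoded through the weight-tied decoder,
#' and the scaled cosine error is minimized with Adam — one decoding view
#' scored on the masked spots (noise correction), the other on the kept
#' spots (detail recovery), plus an explicit L2 penalty on the weight
#' matrices. After training a clean (uncorrupted) inference pass provides
#' the latent embedding and attention record stored on the object.
#'
#' @param x a [spatial_dataset] (preprocessed: normalized, log-transformed),
#'   or a numeric spot-by-gene matrix.
#' @param coords N-by-2 coordinates; required when `x` is a bare matrix and
#'   no `graph` is given.
#' @param graph an `sng`; built with [build_graph()] (covering-radius KNN,
#'   or the multi-slice rules when `x` carries several slices) when omitted.
#' @param dims encoder layer widths, latent last (default `c(512, 30)`).
#' @param epochs training epochs (default 500).
#' @param gamma scaled-cosine exponent; values outside `[1, 3]` trigger a
#'   warning (default 2; larger values suit tissues with complex domain
#'   structure).
#' @param lr Adam learning rate (default 0.001).
#' @param weight_decay coefficient of the explicit L2 loss term (default
#'   0.001); the optimizer applies no additional internal decay.
#' @param mask_ratio fraction of spots masked per epoch (default 0.5).
#' @param replace_ratio fraction of masked spots replaced by random spots'
#'   features (default 0.05; set 0 for microenvironment-heterogeneity runs).
#' @param remask_ratio fraction of embeddings remasked per decoding view
#'   (default 0.5).
#' @param k covering-neighbor count for the default graph (default 6).
#' @param seed integer seed controlling initialization and all per-epoch
#'   plan draws; identical seeds give identical fits on CPU.
#' @param keep_only_loss score only the kept spots (required when
#'   `mask_ratio` rounds to zero masked spots).
#' @param verbose print the loss every 50 epochs.
#' @return An object of class `stgmae` with components `params`, `latent`
#'   (N-by-d_latent embedding from the clean pass), `attention`, `loss`
#'   (per-epoch breakdown), `graph`, `config`, and the training matrix.
#' @examples
#' \donttest{
#' d <- simulate_dataset(sim_config(rows = 8, cols = 8, n_genes = 40,
#'                                  n_domains = 2, seed = 1))
#' d <- preprocess(d, min_cells = 1)
#' fit <- stgmae(d, dims = c(32, 8), epochs = 20, seed = 1)
#' fit
#' }
#' @export
stgmae <- function(x, coords = NULL, graph = NULL, dims = c(512, 30),
                   epochs = 500, gamma = 2, lr = 0.001,
                   weight_decay = 0.001, mask_ratio = 0.5,
                   replace_ratio = 0.05, remask_ratio = 0.5, k = 6,
                   seed = 1, keep_only_loss = FALSE, verbose = FALSE) {
  cl <- match.call()
  if (inherits(x, "spatial_dataset")) {
    X <- x$expr
    coords <- x$coords
    if (is.null(graph)) graph <- build_graph(x, k = k)
  } else {
    X <- as.matrix(x)
    if (is.null(graph)) {
      if (is.null(coords))
        stop("supply coords or a prebuilt graph with a matrix input")
      graph <- build_sng_knn(coords, k = k)
    }
  }
  n <- nrow(X)
  if (graph$n != n) stop("graph size (", graph$n,
                         ") does not match spot count (", n, ")")
  stopifnot(epochs >= 1, lr > 0, weight_decay >= 0)
  if (gamma < 1 || gamma > 3)
    warning("gamma = ", gamma, " is outside the conventional [1, 3] range")
  if (floor(mask_ratio * n) == 0 && !keep_only_loss)
    stop("mask_ratio leaves no masked spots, so the masked-view loss is ",
         "undefined; raise mask_ratio or set keep_only_loss = TRUE")
  if (floor(mask_ratio * n) >= n)
    stop("mask_ratio leaves no kept spots")

  set.seed(as.integer(seed))
  params <- dgat_params(ncol(X), dims = dims)
  ec <- .edge_cache(graph)
  state <- .adam_init(params)
  log_df <- data.frame(epoch = integer(epochs), sce0 = numeric(epochs),
                       sce1 = numeric(epochs), wd = numeric(epochs),
                       total = numeric(epochs))
  for (ep in seq_len(epochs)) {
    plans <- list(mask = draw_mask_plan(n, mask_ratio, replace_ratio),
                  remask0 = draw_remask_plan(n, remask_ratio),
                  remask1 = draw_remask_plan(n, remask_ratio))
    step <- .train_step(X, params, ec, plans, gamma, weight_decay,
                        keep_only = keep_only_loss)
    if (!is.finite(step$loss$total))
      stop("non-finite loss at epoch ", ep)
    upd <- .adam_update(params, step$grads, state, lr = lr)
    params <- upd$params
    state <- upd$state
    log_df[ep, ] <- c(ep, step$loss$sce0, step$loss$sce1, step$loss$wd,
                      step$loss$total)
    if (verbose && (ep == 1L || ep %% 50L == 0L))
      message(sprintf("epoch %4d  loss %.5f (sce0 %.5f, sce1 %.5f, wd %.5f)",
                      ep, step$loss$total, step$loss$sce0, step$loss$sce1,
                      step$loss$wd))
  }
  inf <- encode(graph, X, params)
  structure(list(params = params, latent = inf$H, attention = inf$attention,
                 loss = log_df, graph = graph, X = X, coords = coords,
                 dims = dims,
                 config = list(epochs = epochs, gamma = gamma, lr = lr,
                               weight_decay = weight_decay,
                               mask_ratio = mask_ratio,
                               replace_ratio = replace_ratio,
                               remask_ratio = remask_ratio, seed = seed,
                               keep_only_loss = keep_only_loss),
                 call = cl), class = "stgmae")
}

#' @method print stgmae
#' @export
print.stgmae <- function(x, ...) {
  cat("Dual-remask graph attention autoencoder\n\nCall:\n  ",
      deparse(x$call), "\n\n", sep = "")
  cat("Spots: ", nrow(x$X), "   genes: ", ncol(x$X),
      "   layers: ", paste(x$params$dims, collapse = " -> "), "\n", sep = "")
  cat("Epochs: ", x$config$epochs, "   final loss: ",
      format(utils::tail(x$loss$total, 1), digits = 5), "\n", sep = "")
  invisible(x)
}

#' @method summary stgmae
#' @export
summary.stgmae <- function(object, ...) {
  out <- list(call = object$call, dims = object$params$dims,
              n_spots = nrow(object$X), n_genes = ncol(object$X),
              n_params = .n_params(object$params),
              config = object$config,
              loss_first = object$loss[1L, ],
              loss_last = object$loss[nrow(object$loss), ],
              graph = object$graph)
  class(out) <- "summary.stgmae"
  out
}

#' @method print summary.stgmae
#' @export
print.summary.stgmae <- function(x, ...) {
  cat("Dual-remask graph attention autoencoder\n\nCall:\n  ",
      deparse(x$call), "\n\n", sep = "")
  cat("Data:   ", x$n_spots, " spots x ", x$n_genes, " genes\n", sep = "")
  cat("Model:  ", paste(x$dims, collapse = " -> "), " (",
      x$n_params, " trainable values, weight-tied decoder)\n", sep = "")
  cat("Graph:  ", x$graph$mode, ", mean degree ",
      round(2 * nrow(x$graph$edges) / x$graph$n, 2), "\n", sep = "")
  cat("Mask:   ", x$config$mask_ratio * 100, "% masked, ",
      x$config$replace_ratio * 100, "% of those replaced, ",
      x$config$remask_ratio * 100, "% remasked per view\n", sep = "")
  cat(sprintf("Loss:   epoch 1: %.5f  ->  epoch %d: %.5f\n",
              x$loss_first$total, x$loss_last$epoch, x$loss_last$total))
  invisible(x)
}

#' @export
coef.stgmae <- function(object, ...) {
  p <- object$params
  out <- list()
  for (k in seq_along(p$layers)) {
    out[[paste0("W0_", k)]] <- p$layers[[k]]$W0
    if (!is.null(p$layers[[k]]$W1)) {
      out[[paste0("W1_", k)]] <- p$layers[[k]]$W1
      out[[paste0("v_", k)]] <- p$layers[[k]]$v
    }
  }
  out$x_mask <- p$x_mask
  out$h_mask <- p$h_mask
  out
}

#' Predict latent embeddings or denoised expression
#'
#' Inference uses the uncorrupted input (no masking or remasking), so
#' repeated calls are identical: `type = "latent"` returns the encoder
#' embedding, `type = "denoised"` a single decode of that embedding through
#' the tied decoder.
#'
#' @param object a fitted `stgmae`.
#' @param newdata optional [spatial_dataset] or matrix with the same gene
#'   panel; defaults to the training data.
#' @param graph graph for `newdata` (built from its coordinates when
#'   omitted).
#' @param type `"latent"` (default) or `"denoised"`.
#' @param ... unused.
#' @return N-by-d_latent or N-by-d_in matrix.
#' @export
predict.stgmae <- function(object, newdata = NULL, graph = NULL,
                           type = c("latent", "denoised"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X
    graph <- object$graph
  } else if (inherits(newdata, "spatial_dataset")) {
    X <- newdata$expr
    if (is.null(graph)) graph <- build_graph(newdata)
  } else {
    X <- as.matrix(newdata)
    if (is.null(graph)) stop("supply a graph with a matrix newdata")
  }
  inf <- encode(graph, X, object$params)
  if (type == "latent") return(inf$H)
  decode(graph, inf$H, object$params, inf$attention)
}

#' @export
fitted.stgmae <- function(object, ...) {
  predict(object, type = "denoised")
}

#' @export
residuals.stgmae <- function(object, ...) {
  object$X - fitted(object)
}

#' @export
plot.stgmae <- function(x, ...) {
  graphics::plot(x$loss$epoch, x$loss$total, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  graphics::lines(x$loss$epoch, x$loss$sce0, col = "steelblue", lty = 2)
  graphics::lines(x$loss$epoch, x$loss$sce1, col = "firebrick", lty = 2)
  graphics::legend("topright", c("total", "masked view", "kept view"),
                   col = c("black", "steelblue", "firebrick"),
                   lty = c(1, 2, 2), bty = "n")
  invisible(x)
}

#' Latent embedding of a fitted model
#' @param object a fitted `stgmae`.
#' @return The stored N-by-d_latent matrix from the clean inference pass.
#' @export
get_latent <- function(object) {
  stopifnot(inherits(object, "stgmae"))
  object$latent
}

#' Denoised expression from a fitted model
#' @param object a fitted `stgmae`.
#' @return N-by-d_in reconstruction of the (uncorrupted) input.
#' @export
get_denoised <- function(object) {
  stopifnot(inherits(object, "stgmae"))
  predict(object, type = "denoised")
}
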