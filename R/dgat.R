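#' @title Dynamic graph attention autoencoder internals
#' @description The encoder/decoder stack: attention layers score each
#'   directed neighbor pair with `v' sigmoid(W0 h_i + W1 h_j)` (activation
#'   first, then the scoring projection, so neighbor ranking can vary per
#'   query node), normalize scores with a per-node softmax, and aggregate
#'   `W0`-transformed neighbor features; the final encoder layer and the
#'   final decoder step aggregate without attention. The decoder reuses the
#'   transposed encoder weights and the encoder's attention, so it holds no
#'   parameters of its own beyond the shared latent mask token.
#' @name dgat
NULL

.elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}

# derivative of ELU wrt pre-activation, given the pre-activation
.elu_grad <- function(pre) {
  g <- array(1, dim(pre))
  neg <- pre < 0
  g[neg] <- exp(pre[neg])
  g
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Initialize the trainable state of the autoencoder
#'
#' Creates the full parameter set: per layer a `W0` weight matrix, and for
#' attention layers additionally the attention-only matrix `W1` and scoring
#' vector `v`; plus the input-space mask token and the latent-space remask
#' token. Layers `1..L-1` carry attention; the final layer does not. The
#' decoder is weight-tied (transposes of the encoder `W0`s) and owns no
#' entries here.
#'
#' @param d_in input feature dimension (number of genes).
#' @param dims encoder layer widths, last entry is the latent dimension
#'   (default `c(512, 30)`).
#' @param seed optional seed for the weight initialization.
#' @return A `dgat_params` object.
#' @export
dgat_params <- function(d_in, dims = c(512, 30), seed = NULL) {
  stopifnot(d_in >= 1, length(dims) >= 1, all(dims >= 1))
  if (!is.null(seed)) set.seed(seed)
  full <- c(d_in, dims)
  L <- length(dims)
  glorot <- function(dout, din) {
    lim <- sqrt(6 / (din + dout))
    matrix(stats::runif(dout * din, -lim, lim), dout, din)
  }
  layers <- lapply(seq_len(L), function(k) {
    att <- k < L
    list(W0 = glorot(full[k + 1L], full[k]),
         W1 = if (att) glorot(full[k + 1L], full[k]) else NULL,
         v = if (att) stats::runif(full[k + 1L], -1, 1) / sqrt(full[k + 1L])
             else NULL,
         has_attention = att)
  })
  structure(list(dims = full, layers = layers,
                 x_mask = numeric(d_in), h_mask = numeric(dims[L])),
            class = "dgat_params")
}

#' @method print dgat_params
#' @export
print.dgat_params <- function(x, ...) {
  cat("dgat_params: dims", paste(x$dims, collapse = " -> "),
      "|", .n_params(x), "trainable values\n")
  invisible(x)
}

.n_params <- function(params) {
  sum(vapply(params$layers, function(l)
    length(l$W0) + length(l$W1) + length(l$v), 1)) +
    length(params$x_mask) + length(params$h_mask)
}

# directed edge index including self-loops, grouped by source node; built
# once per graph and reused across epochs
.edge_cache <- function(graph) {
  n <- graph$n
  src <- c(graph$edges[, 1L], graph$edges[, 2L], seq_len(n))
  dst <- c(graph$edges[, 2L], graph$edges[, 1L], seq_len(n))
  o <- order(src, dst)
  src <- src[o]; dst <- dst[o]
  list(n = n, src = src, dst = dst,
       grp = split(seq_along(src), src),
       Aself = adjacency(graph, self_loops = TRUE))
}

# per-source softmax with a per-group max-subtraction stabilizer
.edge_softmax <- function(escore, ec) {
  mx <- vapply(ec$grp, function(ix) max(escore[ix]), numeric(1))
  ex <- exp(escore - mx[ec$src])
  denom <- rowsum(ex, ec$src)[, 1L]
  unname(ex / denom[ec$src])
}

# attention weights of one layer given the layer input; returns the edge
# probabilities p (aligned with ec$src/ec$dst) and the intermediates needed
# for backprop
.attention_forward <- function(Hprev, layer, ec) {
  S <- Hprev %*% t(layer$W0)
  Tm <- Hprev %*% t(layer$W1)
  U <- .sigmoid(S[ec$src, , drop = FALSE] + Tm[ec$dst, , drop = FALSE])
  escore <- drop(U %*% layer$v)
  p <- .edge_softmax(escore, ec)
  list(S = S, Tm = Tm, U = U, p = p,
       P = Matrix::sparseMatrix(i = ec$src, j = ec$dst, x = p,
                                dims = c(ec$n, ec$n)))
}

#' Attention weights of one layer
#'
#' Computes the dynamic attention record for a layer: scores
#' `e_ij = v' sigmoid(W0 h_i + W1 h_j)` over every directed pair with
#' `j` in the neighborhood of `i` (stored neighbors plus `i` itself),
#' normalized per node by a numerically stabilized softmax. An isolated node
#' attends only to itself with weight 1.
#'
#' @param H_prev N-by-d layer input matrix.
#' @param graph an `sng` over the same N spots.
#' @param W0,W1 d_out-by-d weight matrices.
#' @param v length-d_out scoring vector.
#' @return An `attention_record`: list with `src`, `dst`, `score`, `weight`
#'   and `n`; weights over each source's neighborhood sum to 1.
#' @export
attention_scores <- function(H_prev, graph, W0, W1, v) {
  stopifnot(inherits(graph, "sng"), nrow(H_prev) == graph$n)
  ec <- .edge_cache(graph)
  layer <- list(W0 = W0, W1 = W1, v = v)
  af <- .attention_forward(as.matrix(H_prev), layer, ec)
  escore <- drop(af$U %*% v)
  structure(list(src = ec$src, dst = ec$dst, score = escore,
                 weight = af$p, n = ec$n), class = "attention_record")
}

#' Sparse matrix view of an attention record
#' @param record an `attention_record`.
#' @return A `dgCMatrix` with `att[i, j]` the weight of neighbor `j` for
#'   node `i`; each row sums to 1 over the node's neighborhood.
#' @export
attention_matrix <- function(record) {
  stopifnot(inherits(record, "attention_record"))
  Matrix::sparseMatrix(i = record$src, j = record$dst, x = record$weight,
                       dims = c(record$n, record$n))
}

# full encoder pass with caches for backprop
.encode_cache <- function(Xin, params, ec) {
  L <- length(params$layers)
  H <- Xin
  att <- vector("list", L)
  cache <- vector("list", L)
  for (k in seq_len(L)) {
    layer <- params$layers[[k]]
    if (layer$has_attention) {
      af <- .attention_forward(H, layer, ec)
      C <- as.matrix(af$P %*% af$S)
      cache[[k]] <- list(af = af, Hin = H, C = C)
      att[[k]] <- af
    } else {
      B <- as.matrix(ec$Aself %*% H)
      C <- B %*% t(layer$W0)
      cache[[k]] <- list(B = B, Hin = H, C = C)
    }
    H <- .elu(C)
    if (any(!is.finite(H)))
      stop("non-finite values in encoder layer ", k)
    cache[[k]]$H <- H
  }
  list(H = H, att = att, layers = cache)
}

# full decoder pass (tied weights, reused attention) with caches
.decode_cache <- function(Hhat, params, ec, att) {
  L <- length(params$layers)
  cache <- vector("list", L)
  cur <- Hhat
  for (k in rev(seq_len(L))) {
    G <- cur %*% params$layers[[k]]$W0     # (W0^(k))' applied row-wise
    pre <- if (k > 1L) as.matrix(att[[k - 1L]]$P %*% G)
           else as.matrix(ec$Aself %*% G)
    out <- .elu(pre)
    cache[[k]] <- list(Hin = cur, G = G, pre = pre)
    cur <- out
  }
  list(Z = cur, layers = cache)
}

#' Encode spot features into latent embeddings
#'
#' Runs the encoder stack: attention-weighted aggregation plus ELU for
#' layers `1..L-1`, unweighted neighbor-sum aggregation plus ELU for the
#' final layer. Neighborhoods always include the spot itself.
#'
#' @param graph an `sng`.
#' @param X N-by-d_in feature matrix (column count must match the first
#'   layer).
#' @param params a `dgat_params`.
#' @return List with `H` (N-by-d_latent embedding) and `attention` (list of
#'   `attention_record`s, one per attention layer).
#' @export
encode <- function(graph, X, params) {
  stopifnot(inherits(graph, "sng"), inherits(params, "dgat_params"))
  X <- as.matrix(X)
  if (ncol(X) != params$dims[1L])
    stop("X has ", ncol(X), " columns but the model expects ",
         params$dims[1L])
  if (nrow(X) != graph$n) stop("X rows do not match graph size")
  ec <- .edge_cache(graph)
  enc <- .encode_cache(X, params, ec)
  att <- lapply(which(!vapply(enc$att, is.null, TRUE)), function(k) {
    af <- enc$att[[k]]
    structure(list(src = ec$src, dst = ec$dst,
                   score = drop(af$U %*% params$layers[[k]]$v),
                   weight = af$p, n = ec$n), class = "attention_record")
  })
  list(H = enc$H, attention = att)
}

#' Decode latent embeddings into reconstructed expression
#'
#' Applies the weight-tied decoder in reverse layer order: each attention
#' step reuses the encoder's attention weights exactly (never recomputing
#' them on the remasked input), and the final step is the unweighted
#' aggregation through the transposed first-layer weights.
#'
#' @param graph an `sng`.
#' @param H_remasked N-by-d_latent matrix (typically a remasked embedding).
#' @param params a `dgat_params`.
#' @param att list of `attention_record`s from the matching [encode()] call.
#' @return N-by-d_in reconstruction matrix.
#' @export
decode <- function(graph, H_remasked, params, att) {
  stopifnot(inherits(graph, "sng"), inherits(params, "dgat_params"))
  H_remasked <- as.matrix(H_remasked)
  L <- length(params$layers)
  n_att <- sum(vapply(params$layers, `[[`, TRUE, "has_attention"))
  if (length(att) != n_att)
    stop("expected ", n_att, " attention record(s), got ", length(att))
  if (ncol(H_remasked) != params$dims[length(params$dims)])
    stop("latent dimension mismatch")
  ec <- .edge_cache(graph)
  att_p <- lapply(att, function(a) {
    stopifnot(inherits(a, "attention_record"))
    if (a$n != graph$n) stop("attention record size mismatch")
    list(P = attention_matrix(a))
  })
  dec <- .decode_cache(H_remasked, params, ec, att_p)
  dec$Z
}

#' One dual-view corrupted forward pass
#'
#' Draws a masking plan, encodes the corrupted features, draws two
#' independent remasking plans, and decodes both remasked embeddings through
#' the shared tied decoder with the encoder's attention. Plans are drawn from
#' the current RNG stream (seed upstream for reproducibility).
#'
#' @param graph an `sng`.
#' @param X N-by-d_in feature matrix.
#' @param params a `dgat_params`.
#' @param mask_ratio,replace_ratio,remask_ratio corruption ratios (defaults
#'   0.5 / 0.05 / 0.5).
#' @return List with `X_tilde`, `H`, `H0`, `H1`, `Z0`, `Z1`, `plans`
#'   (`mask`, `remask0`, `remask1`) and `attention`.
#' @export
forward_dual <- function(graph, X, params, mask_ratio = 0.5,
                         replace_ratio = 0.05, remask_ratio = 0.5) {
  X <- as.matrix(X)
  n <- nrow(X)
  plan <- draw_mask_plan(n, mask_ratio, replace_ratio)
  r0 <- draw_remask_plan(n, remask_ratio)
  r1 <- draw_remask_plan(n, remask_ratio)
  Xt <- apply_mask(X, plan, params$x_mask)
  enc <- encode(graph, Xt, params)
  H0 <- apply_remask(enc$H, r0, params$h_mask)
  H1 <- apply_remask(enc$H, r1, params$h_mask)
  Z0 <- decode(graph, H0, params, enc$attention)
  Z1 <- decode(graph, H1, params, enc$attention)
  list(X_tilde = Xt, H = enc$H, H0 = H0, H1 = H1, Z0 = Z0, Z1 = Z1,
       plans = list(mask = plan, remask0 = r0, remask1 = r1),
       attention = enc$attention)
}
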