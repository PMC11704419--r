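#' Scaled cosine error
#'
#' Mean over paired rows of `(1 - cos(x_i, z_i))^gamma`. The exponent
#' `gamma` controls how quickly easy (already well-reconstructed) rows stop
#' contributing. Rows whose norm falls below `1e-12` are guarded: their
#' cosine is treated as 0 and a warning is emitted.
#'
#' @param x_rows,z_rows m-by-d matrices of paired rows (targets and
#'   reconstructions).
#' @param gamma scaling exponent, conventionally in `[1, 3]` (default 2).
#' @return A scalar in `[0, 2^gamma]`.
#' @export
sce <- function(x_rows, z_rows, gamma = 2) {
  .sce_with_grad(as.matrix(x_rows), as.matrix(z_rows), gamma,
                 want_grad = FALSE)$value
}

.sce_with_grad <- function(Xr, Zr, gamma, want_grad = TRUE) {
  stopifnot(nrow(Xr) >= 1, all(dim(Xr) == dim(Zr)))
  eps <- 1e-12
  m <- nrow(Xr)
  s <- rowSums(Xr * Zr)
  nx <- sqrt(rowSums(Xr^2))
  nz <- sqrt(rowSums(Zr^2))
  bad <- nx < eps | nz < eps
  if (any(bad))
    warning(sum(bad), " zero-norm row(s); cosine treated as 0")
  cosv <- ifelse(bad, 0, s / (nx * nz))
  value <- mean((1 - cosv)^gamma)
  if (!want_grad) return(list(value = value))
  coef <- -(gamma / m) * (1 - cosv)^(gamma - 1)
  coef[bad] <- 0
  inv <- ifelse(bad, 0, 1 / (nx * nz))
  dZ <- coef * (Xr * inv - (s * inv / pmax(nz^2, eps)) * Zr)
  list(value = value, dZ = dZ)
}

.wd_penalty <- function(params, weight_decay) {
  weight_decay * sum(vapply(params$layers, function(l)
    sum(l$W0^2) + if (is.null(l$W1)) 0 else sum(l$W1^2), 1))
}

#' Total training loss
#'
#' `L_sce0` scores the dual-view reconstruction `Z0` on the masked rows
#' only (noise correction), `L_sce1` scores `Z1` on the kept rows only
#' (detail recovery), and the L2 term penalizes all `W0`/`W1` weight
#' matrices across layers. The total is their plain sum.
#'
#' @param X clean N-by-d target matrix.
#' @param Z0,Z1 the two dual-view reconstructions.
#' @param plan the `mask_plan` that partitioned the spots.
#' @param params the `dgat_params` (for the L2 term).
#' @param gamma scaled-cosine exponent (default 2).
#' @param weight_decay L2 coefficient (default 0.001).
#' @return List with `sce0`, `sce1`, `wd`, `total`.
#' @export
total_loss <- function(X, Z0, Z1, plan, params, gamma = 2,
                       weight_decay = 0.001) {
  stopifnot(inherits(plan, "mask_plan"))
  if (length(plan$masked_set) == 0L && plan$mask_ratio > 0)
    stop("mask plan has an empty masked set despite mask_ratio > 0")
  sce0 <- if (length(plan$masked_set))
    sce(X[plan$masked_set, , drop = FALSE],
        Z0[plan$masked_set, , drop = FALSE], gamma) else 0
  sce1 <- if (length(plan$keep_set))
    sce(X[plan$keep_set, , drop = FALSE],
        Z1[plan$keep_set, , drop = FALSE], gamma) else 0
  wd <- .wd_penalty(params, weight_decay)
  list(sce0 = sce0, sce1 = sce1, wd = wd, total = sce0 + sce1 + wd)
}

.zero_grads <- function(params) {
  list(layers = lapply(params$layers, function(l)
    list(W0 = array(0, dim(l$W0)),
         W1 = if (is.null(l$W1)) NULL else array(0, dim(l$W1)),
         v = if (is.null(l$v)) NULL else numeric(length(l$v)))),
    x_mask = numeric(length(params$x_mask)),
    h_mask = numeric(length(params$h_mask)))
}

# One full forward + analytic backward pass at fixed corruption plans.
# Deterministic given (X, params, plans); the training loop draws fresh
# plans per epoch, and the finite-difference tests call this directly.
.train_step <- function(X, params, ec, plans, gamma, weight_decay,
                        keep_only = FALSE) {
  L <- length(params$layers)
  plan <- plans$mask
  rows0 <- plan$masked_set
  rows1 <- plan$keep_set
  if (length(rows0) == 0L && !keep_only)
    stop("empty masked set: use keep_only mode or raise mask_ratio")
  if (length(rows1) == 0L)
    stop("empty keep set: mask_ratio must leave unmasked spots")

  Xt <- apply_mask(X, plan, params$x_mask)
  enc <- .encode_cache(Xt, params, ec)
  views <- list(list(r = plans$remask0, rows = rows0),
                list(r = plans$remask1, rows = rows1))
  grads <- .zero_grads(params)
  gP <- vector("list", L)
  for (k in seq_len(L))
    if (params$layers[[k]]$has_attention) gP[[k]] <- numeric(length(ec$src))
  dH <- array(0, dim(enc$H))
  sce_vals <- c(0, 0)

  for (vi in 1:2) {
    vw <- views[[vi]]
    if (length(vw$rows) == 0L) next
    Hhat <- apply_remask(enc$H, vw$r, params$h_mask)
    dec <- .decode_cache(Hhat, params, ec, lapply(enc$att, function(a)
      if (is.null(a)) NULL else list(P = a$P)))
    lg <- .sce_with_grad(X[vw$rows, , drop = FALSE],
                         dec$Z[vw$rows, , drop = FALSE], gamma)
    sce_vals[vi] <- lg$value
    d_cur <- array(0, dim(dec$Z))
    d_cur[vw$rows, ] <- lg$dZ
    for (k in seq_len(L)) {
      ck <- dec$layers[[k]]
      dpre <- d_cur * .elu_grad(ck$pre)
      if (k == 1L) {
        dG <- as.matrix(ec$Aself %*% dpre)
      } else {
        af <- enc$layers[[k - 1L]]$af
        dG <- as.matrix(Matrix::crossprod(af$P, dpre))
        gP[[k - 1L]] <- gP[[k - 1L]] +
          rowSums(dpre[ec$src, , drop = FALSE] * ck$G[ec$dst, , drop = FALSE])
      }
      grads$layers[[k]]$W0 <- grads$layers[[k]]$W0 + crossprod(ck$Hin, dG)
      d_cur <- dG %*% t(params$layers[[k]]$W0)
    }
    if (length(vw$r$remask_set)) {
      grads$h_mask <- grads$h_mask +
        colSums(d_cur[vw$r$remask_set, , drop = FALSE])
      d_cur[vw$r$remask_set, ] <- 0
    }
    dH <- dH + d_cur
  }

  d_cur <- dH
  for (k in rev(seq_len(L))) {
    lay <- enc$layers[[k]]
    pl <- params$layers[[k]]
    dC <- d_cur * .elu_grad(lay$C)
    if (!pl$has_attention) {
      grads$layers[[k]]$W0 <- grads$layers[[k]]$W0 + crossprod(dC, lay$B)
      d_cur <- as.matrix(ec$Aself %*% (dC %*% pl$W0))
    } else {
      af <- lay$af
      dS <- as.matrix(Matrix::crossprod(af$P, dC))
      gP[[k]] <- gP[[k]] +
        rowSums(dC[ec$src, , drop = FALSE] * af$S[ec$dst, , drop = FALSE])
      dot <- rowsum(af$p * gP[[k]], ec$src)[, 1L]
      de <- af$p * (gP[[k]] - dot[ec$src])
      grads$layers[[k]]$v <- grads$layers[[k]]$v + drop(crossprod(af$U, de))
      dUpre <- tcrossprod(de, pl$v) * (af$U * (1 - af$U))
      dS <- dS + rowsum(dUpre, ec$src)
      dT <- rowsum(dUpre, ec$dst)
      grads$layers[[k]]$W0 <- grads$layers[[k]]$W0 + crossprod(dS, lay$Hin)
      grads$layers[[k]]$W1 <- grads$layers[[k]]$W1 + crossprod(dT, lay$Hin)
      d_cur <- dS %*% pl$W0 + dT %*% pl$W1
    }
  }
  tok <- .token_rows(plan)
  if (length(tok))
    grads$x_mask <- grads$x_mask + colSums(d_cur[tok, , drop = FALSE])

  wd <- .wd_penalty(params, weight_decay)
  for (k in seq_len(L)) {
    grads$layers[[k]]$W0 <- grads$layers[[k]]$W0 +
      2 * weight_decay * params$layers[[k]]$W0
    if (!is.null(params$layers[[k]]$W1))
      grads$layers[[k]]$W1 <- grads$layers[[k]]$W1 +
        2 * weight_decay * params$layers[[k]]$W1
  }
  list(loss = list(sce0 = sce_vals[1L], sce1 = sce_vals[2L], wd = wd,
                   total = sce_vals[1L] + sce_vals[2L] + wd),
       grads = grads)
}

# Adam optimizer state and update; the explicit L2 term lives in the loss,
# so the optimizer itself applies no additional decay.
.adam_init <- function(params) {
  list(m = .zero_grads(params), v = .zero_grads(params), t = 0L)
}

.adam_update <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (k in seq_along(params$layers)) {
    for (nm in c("W0", "W1", "v")) {
      if (is.null(params$layers[[k]][[nm]])) next
      u <- upd(params$layers[[k]][[nm]], grads$layers[[k]][[nm]],
               state$m$layers[[k]][[nm]], state$v$layers[[k]][[nm]])
      params$layers[[k]][[nm]] <- u$p
      state$m$layers[[k]][[nm]] <- u$m
      state$v$layers[[k]][[nm]] <- u$v
    }
  }
  for (nm in c("x_mask", "h_mask")) {
    u <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- u$p
    state$m[[nm]] <- u$m
    state$v[[nm]] <- u$v
  }
  list(params = params, state = state)
}
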