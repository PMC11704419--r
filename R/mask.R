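#' Draw a masking plan
#'
#' Samples the corruption plan applied to the input features before encoding:
#' `floor(mask_ratio * n)` spots are masked (uniformly, without replacement);
#' of those, `floor(replace_ratio * n_masked)` are designated replacement
#' targets that receive the original features of a uniformly drawn global
#' spot instead of the learnable mask token. The remaining spots form the
#' keep set and are never modified.
#'
#' @param n number of spots.
#' @param mask_ratio fraction of spots to mask in `[0, 1]` (default 0.5).
#' @param replace_ratio fraction of *masked* spots whose token is swapped for
#'   a random spot's features (default 0.05; use 0 for
#'   microenvironment-heterogeneity runs).
#' @param rng_seed optional integer; when supplied the draw is made
#'   reproducible with `set.seed`, otherwise the current RNG stream is used
#'   (as inside the training loop, where plans are redrawn every epoch).
#' @return A `mask_plan`: list with `masked_set`, `keep_set`,
#'   `replace_pairs` (two-column matrix `target`, `source`), and the ratios.
#' @export
draw_mask_plan <- function(n, mask_ratio = 0.5, replace_ratio = 0.05,
                           rng_seed = NULL) {
  stopifnot(n >= 1, mask_ratio >= 0, mask_ratio <= 1,
            replace_ratio >= 0, replace_ratio <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_mask <- floor(mask_ratio * n)
  masked <- if (n_mask > 0) sort(sample.int(n, n_mask)) else integer(0)
  keep <- setdiff(seq_len(n), masked)
  n_rep <- floor(replace_ratio * n_mask)
  replace_pairs <- if (n_rep > 0)
    cbind(target = sample(masked, n_rep),
          source = sample.int(n, n_rep, replace = TRUE))
  else cbind(target = integer(0), source = integer(0))
  structure(list(n = as.integer(n), masked_set = masked, keep_set = keep,
                 replace_pairs = replace_pairs, mask_ratio = mask_ratio,
                 replace_ratio = replace_ratio),
            class = "mask_plan")
}

#' Apply a masking plan to a feature matrix
#'
#' Keep-set rows are returned untouched; replacement targets receive the
#' original row of their source spot; all other masked rows are overwritten
#' with the mask token.
#'
#' @param X N-by-d feature matrix.
#' @param plan a `mask_plan` from [draw_mask_plan()].
#' @param token length-d mask token (the learnable input-space vector).
#' @return The corrupted matrix, same shape as `X`.
#' @export
apply_mask <- function(X, plan, token) {
  stopifnot(inherits(plan, "mask_plan"), nrow(X) == plan$n,
            length(token) == ncol(X))
  if (length(plan$masked_set) &&
      (min(plan$masked_set) < 1L || max(plan$masked_set) > nrow(X)))
    stop("mask index out of range")
  out <- X
  token_rows <- setdiff(plan$masked_set, plan$replace_pairs[, "target"])
  if (length(token_rows))
    out[token_rows, ] <- rep(token, each = length(token_rows))
  if (nrow(plan$replace_pairs))
    out[plan$replace_pairs[, "target"], ] <-
      X[plan$replace_pairs[, "source"], , drop = FALSE]
  out
}

# rows that received the mask token (gradient flows to the token there)
.token_rows <- function(plan) {
  setdiff(plan$masked_set, plan$replace_pairs[, "target"])
}

#' Draw a remasking plan
#'
#' Samples the subset of spots whose latent embeddings are overwritten with
#' the shared latent mask token before decoding. The draw is uniform and
#' independent of any input [draw_mask_plan()]: spots are equally likely to
#' be remasked whether or not they were masked before. No random replacement
#' occurs in remasking.
#'
#' @param n number of spots.
#' @param ratio fraction to remask in `[0, 1]` (default 0.5).
#' @param rng_seed optional integer seed (see [draw_mask_plan()]).
#' @return A `remask_plan`: list with `remask_set` and `ratio`.
#' @export
draw_remask_plan <- function(n, ratio = 0.5, rng_seed = NULL) {
  stopifnot(n >= 1, ratio >= 0, ratio <= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  n_mask <- floor(ratio * n)
  remask <- if (n_mask > 0) sort(sample.int(n, n_mask)) else integer(0)
  structure(list(n = as.integer(n), remask_set = remask, ratio = ratio),
            class = "remask_plan")
}

#' Apply a remasking plan to a latent matrix
#'
#' @param H N-by-d latent matrix.
#' @param plan a `remask_plan`.
#' @param token_h length-d latent mask token.
#' @return `H` with remasked rows replaced by `token_h`.
#' @export
apply_remask <- function(H, plan, token_h) {
  stopifnot(inherits(plan, "remask_plan"), nrow(H) == plan$n)
  if (length(token_h) != ncol(H))
    stop("remask token dimension (", length(token_h),
         ") does not match latent dimension (", ncol(H), ")")
  out <- H
  if (length(plan$remask_set))
    out[plan$remask_set, ] <- rep(token_h, each = length(plan$remask_set))
  out
}
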