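#' Drop genes detected in too few spots
#'
#' Retains exactly the genes with nonzero expression in at least `min_cells`
#' spots. Retained values are untouched; only columns are dropped.
#'
#' @param dataset a [spatial_dataset] with nonnegative expression.
#' @param min_cells minimum number of spots a gene must be detected in
#'   (default 3).
#' @return A [spatial_dataset] with the qualifying genes.
#' @export
filter_genes <- function(dataset, min_cells = 3) {
  stopifnot(inherits(dataset, "spatial_dataset"), min_cells >= 0)
  prevalence <- colSums(dataset$expr > 0)
  keep <- prevalence >= min_cells
  if (!any(keep)) {
    h <- table(prevalence)
    stop("no gene is detected in >= ", min_cells,
         " spots; prevalence histogram: ",
         paste(sprintf("%s spots: %d genes", names(h), as.integer(h)),
               collapse = "; "))
  }
  .keep_genes(dataset, which(keep))
}

#' Drop excluded genes by list or symbol prefix
#'
#' Removes user-listed genes (e.g. exogenous control RNAs) and, by default,
#' mitochondrial genes recognized by the `MT-`/`mt-` symbol prefix.
#'
#' @param dataset a [spatial_dataset].
#' @param exclude character vector of gene ids to drop (exact match).
#' @param prefixes symbol prefixes to drop (default `c("MT-", "mt-")`);
#'   use `character(0)` to disable.
#' @return A [spatial_dataset] without the excluded genes.
#' @export
filter_excluded <- function(dataset, exclude = NULL,
                            prefixes = c("MT-", "mt-")) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  drop <- dataset$gene_ids %in% exclude
  for (p in prefixes) drop <- drop | startsWith(dataset$gene_ids, p)
  if (all(drop)) stop("exclusion rules would remove every gene")
  if (!any(drop)) return(dataset)
  .keep_genes(dataset, which(!drop))
}

#' Library-size normalization and log transform
#'
#' Scales each spot to a common total (the median spot total by default),
#' then applies `log1p`. Spots with zero total are left as zeros with a
#' warning.
#'
#' @param dataset a [spatial_dataset] with nonnegative expression.
#' @param target positive scaling target, or `"median"` for the median
#'   spot total over nonzero spots (default).
#' @param log_transform apply `log1p` after scaling (default `TRUE`).
#' @return A [spatial_dataset] with normalized (and log-transformed)
#'   expression.
#' @export
normalize_log <- function(dataset, target = "median", log_transform = TRUE) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  x <- dataset$expr
  if (any(x < 0)) stop("normalization expects nonnegative expression")
  totals <- rowSums(x)
  nz <- totals > 0
  if (!any(nz)) stop("every spot has zero total expression")
  if (identical(target, "median")) target <- stats::median(totals[nz])
  target <- as.numeric(target)
  if (!is.finite(target) || target <= 0) stop("target must be a positive real")
  if (any(!nz))
    warning(sum(!nz), " spot(s) with zero total left as zeros")
  fac <- ifelse(nz, target / totals, 0)
  x <- x * fac
  if (log_transform) x <- log1p(x)
  .with_expr(dataset, x)
}

#' Select highly variable genes
#'
#' Ranks genes by binned normalized dispersion: per-gene mean and
#' dispersion (variance/mean) are computed on the de-logged values, genes are
#' grouped into 20 mean bins, dispersions are z-scored within each bin, and
#' the `n_hvg` genes with the highest normalized dispersion are kept.
#' Identity when the dataset already has `n_hvg` genes or fewer.
#'
#' @param dataset a [spatial_dataset], normalized and log-transformed.
#' @param n_hvg number of genes to keep (default 3000).
#' @param n_bins number of mean bins for dispersion normalization.
#' @return A [spatial_dataset] restricted to the selected genes (original
#'   column order preserved).
#' @export
select_hvg <- function(dataset, n_hvg = 3000, n_bins = 20) {
  stopifnot(inherits(dataset, "spatial_dataset"), n_hvg >= 1)
  g <- ncol(dataset$expr)
  if (g <= n_hvg) return(dataset)
  x <- expm1(dataset$expr)
  mu <- colMeans(x)
  v <- colSums((x - rep(mu, each = nrow(x)))^2) / max(1, nrow(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1, min(n_bins, floor(g / 2)))  # every bin holds >= 2 genes
  bins <- if (n_bins == 1) rep(1L, g)
          else cut(rank(mu, ties.method = "first"),
                   breaks = n_bins, labels = FALSE)
  z <- disp
  for (b in unique(bins)) {
    i <- bins == b
    m <- mean(disp[i]); s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - m) / s
  }
  keep <- sort(order(z, decreasing = TRUE)[seq_len(n_hvg)])
  .keep_genes(dataset, keep)
}

#' Standard preprocessing pipeline
#'
#' Runs the canonical stage order: exclusion filter, prevalence filter,
#' library-size normalization, log transform, and highly-variable-gene
#' selection. HVG selection is skipped for denoising runs
#' (`skip_hvg = TRUE`), where the full gene panel must be reconstructed.
#'
#' @param dataset a raw-count [spatial_dataset].
#' @param min_cells prevalence threshold for [filter_genes()] (default 3).
#' @param n_hvg number of variable genes for [select_hvg()] (default 3000).
#' @param normalize_target per-spot total target, or `"median"`.
#' @param log_transform apply `log1p` (default `TRUE`).
#' @param skip_hvg skip variable-gene selection (default `FALSE`).
#' @param exclude,prefixes passed to [filter_excluded()].
#' @return The preprocessed [spatial_dataset].
#' @export
preprocess <- function(dataset, min_cells = 3, n_hvg = 3000,
                       normalize_target = "median", log_transform = TRUE,
                       skip_hvg = FALSE, exclude = NULL,
                       prefixes = c("MT-", "mt-")) {
  d <- filter_excluded(dataset, exclude = exclude, prefixes = prefixes)
  d <- filter_genes(d, min_cells = min_cells)
  d <- normalize_log(d, target = normalize_target,
                     log_transform = log_transform)
  if (!skip_hvg) d <- select_hvg(d, n_hvg = n_hvg)
  d
}
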