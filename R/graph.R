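#' @title Spatial neighbor graphs
#' @description Builders for the binary symmetric adjacency over spots:
#'   fixed-radius graphs for single-cell-resolution platforms, covering-radius
#'   KNN graphs for lattice platforms, merged two-slice graphs, and
#'   adjacent-slice-only graphs for vertical stacks. The stored graph never
#'   contains self-loops; the model adds the self edge at aggregation time.
#' @name sng
NULL

.new_sng <- function(n, edges, mode, params) {
  if (length(edges) == 0L) edges <- matrix(integer(0), 0L, 2L)
  edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                 pmax(edges[, 1L], edges[, 2L]))
  edges <- unique(edges[edges[, 1L] != edges[, 2L], , drop = FALSE])
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n))
    stop("edge endpoint outside 1..n")
  structure(list(n = as.integer(n), edges = edges, mode = mode,
                 params = params), class = "sng")
}

#' @method print sng
#' @export
print.sng <- function(x, ...) {
  cat("spatial neighbor graph (", x$mode, "): ", x$n, " spots, ",
      nrow(x$edges), " undirected edges, mean degree ",
      round(2 * nrow(x$edges) / x$n, 2), "\n", sep = "")
  invisible(x)
}

#' Sparse adjacency matrix of a spatial neighbor graph
#'
#' @param graph an `sng` object.
#' @param self_loops add the diagonal (the neighborhood used by the model
#'   includes each spot itself); default `FALSE`, matching the stored graph.
#' @return A symmetric binary `dgCMatrix`.
#' @export
adjacency <- function(graph, self_loops = FALSE) {
  stopifnot(inherits(graph, "sng"))
  i <- c(graph$edges[, 1L], graph$edges[, 2L])
  j <- c(graph$edges[, 2L], graph$edges[, 1L])
  if (self_loops) { i <- c(i, seq_len(graph$n)); j <- c(j, seq_len(graph$n)) }
  Matrix::sparseMatrix(i = i, j = j, x = 1, dims = c(graph$n, graph$n))
}

#' Spot degrees of a spatial neighbor graph
#' @param graph an `sng` object.
#' @return Integer vector of degrees (self-loops excluded).
#' @export
sng_degree <- function(graph) {
  stopifnot(inherits(graph, "sng"))
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n)
}

.check_coords <- function(coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 2L) stop("coords must be N x 2")
  if (any(!is.finite(coords))) stop("non-finite coordinates")
  coords
}

.pairwise_dist <- function(a, b = a) {
  # plain Euclidean cross-distances; sizes here are small enough for dense
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fixed-radius spatial neighbor graph
#'
#' Links spots `i`, `j` iff `0 < ||coords_i - coords_j|| < radius` (strict on
#' both sides, so coincident spots are never linked by the radius rule).
#'
#' @param coords N-by-2 coordinate matrix.
#' @param radius positive distance threshold.
#' @return An `sng` object.
#' @export
build_sng_radius <- function(coords, radius) {
  coords <- .check_coords(coords)
  stopifnot(is.numeric(radius), radius > 0)
  d <- .pairwise_dist(coords)
  hit <- which(d > 0 & d < radius, arr.ind = TRUE)
  hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
  .new_sng(nrow(coords), hit, "radius", list(radius = radius))
}

# per-spot covering-radius neighbor lists: for each row of `a`, all rows of
# `b` within the distance to its k-th nearest (ties at that distance kept).
# `exclude_self` drops the zero-distance self match when a and b coincide.
.covering_neighbors <- function(a, b, k, exclude_self = FALSE) {
  d <- .pairwise_dist(a, b)
  if (exclude_self) diag(d) <- Inf
  k <- min(k, ncol(d) - exclude_self)
  lapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    r <- sort(di, partial = k)[k]
    # relative slack so lattice distance ties survive floating-point noise
    which(di <= r * (1 + 1e-9) + 1e-12)
  })
}

#' Covering-radius KNN spatial neighbor graph
#'
#' For each spot, finds the minimal radius covering its `k` nearest
#' neighbors and links it to every spot within that radius (distance ties at
#' the covering radius are all included, so the rule is deterministic and
#' order-independent). The edge set is symmetrized by union. On a regular
#' hexagonal lattice with `k = 6`, interior spots get exactly their 6-ring.
#'
#' @param coords N-by-2 coordinate matrix.
#' @param k number of neighbors to cover, `1 <= k < N` (default 6, the
#'   hexagonal-lattice neighbor count).
#' @return An `sng` object.
#' @export
build_sng_knn <- function(coords, k = 6) {
  coords <- .check_coords(coords)
  n <- nrow(coords)
  if (k < 1 || k >= n) stop("k must satisfy 1 <= k < N (k=", k, ", N=", n, ")")
  nb <- .covering_neighbors(coords, coords, k, exclude_self = TRUE)
  edges <- cbind(rep(seq_len(n), lengths(nb)), unlist(nb))
  .new_sng(n, edges, "knn", list(k = k))
}

#' Merge multi-slice datasets into one
#'
#' Concatenates pre-aligned slices into a single [spatial_dataset] with
#' `slice_idx` recording slice membership. All slices must share the same
#' gene panel.
#'
#' @param slices list of [spatial_dataset] objects (one slice each).
#' @return A single [spatial_dataset].
#' @export
concat_slices <- function(slices) {
  stopifnot(length(slices) >= 1,
            all(vapply(slices, inherits, TRUE, "spatial_dataset")))
  gene_ids <- slices[[1L]]$gene_ids
  for (s in slices) if (!identical(s$gene_ids, gene_ids))
    stop("slices must share an identical gene panel")
  expr <- do.call(rbind, lapply(slices, `[[`, "expr"))
  coords <- do.call(rbind, lapply(slices, `[[`, "coords"))
  ids <- unlist(lapply(seq_along(slices), function(i)
    paste0("s", i, "_", slices[[i]]$spot_ids)))
  slice_idx <- rep(seq_along(slices),
                   vapply(slices, function(s) nrow(s$expr), 1L))
  labels <- if (all(!vapply(slices, function(s) is.null(s$labels), TRUE)))
    factor(unlist(lapply(slices, function(s) as.character(s$labels))))
  else NULL
  spatial_dataset(expr, coords, spot_ids = ids, gene_ids = gene_ids,
                  slice_idx = slice_idx, labels = labels)
}

#' Two-slice merged spatial neighbor graph
#'
#' Treats two co-registered slices as one point set and applies the
#' covering-radius KNN rule over the union, so neighborhoods may span both
#' slices.
#'
#' @param slices list of exactly 2 aligned [spatial_dataset] slices.
#' @param k covering-neighbor count (default 6).
#' @return An `sng` over the concatenated spots (slice 1 first).
#' @export
build_2dsng <- function(slices, k = 6) {
  if (length(slices) < 2L) stop("build_2dsng needs exactly 2 slices")
  if (length(slices) > 2L)
    stop("more than 2 slices: use build_3dsng for vertical stacks")
  coords <- rbind(.check_coords(slices[[1L]]$coords),
                  .check_coords(slices[[2L]]$coords))
  g <- build_sng_knn(coords, k = k)
  .new_sng(g$n, g$edges, "sng2d", list(k = k))
}

#' Vertical-stack spatial neighbor graph
#'
#' For an ordered stack of three or more pre-aligned slices: within each
#' slice the covering-radius KNN rule with `k_intra` neighbors is applied;
#' across slices each spot is linked only into its immediately adjacent
#' slice(s), to the spots within the minimal in-plane radius covering
#' `k_cross` of them. Consecutive slice pairs are scanned in both directions
#' so no adjacency is missed; non-adjacent slices are never linked. On a
#' perfectly stacked hexagonal lattice this yields at most `6 + 7` neighbors
#' for spots on the outer slices and `6 + 7 + 7` for middle-slice spots.
#'
#' @param slices ordered list of >= 3 [spatial_dataset] slices (order is the
#'   vertical stacking order).
#' @param k_intra within-slice covering-neighbor count (default 6).
#' @param k_cross per-adjacent-slice covering-neighbor count (default 7: the
#'   directly facing spot plus its 6-ring on a perfect stack).
#' @return An `sng` over the concatenated spots (slices in order).
#' @export
build_3dsng <- function(slices, k_intra = 6, k_cross = 7) {
  if (length(slices) < 3L)
    stop("fewer than 3 slices: use build_2dsng for a slice pair")
  coords <- lapply(slices, function(s) .check_coords(s$coords))
  sizes <- vapply(coords, nrow, 1L)
  offset <- c(0L, cumsum(sizes))
  edges <- vector("list", 0L)
  for (s in seq_along(slices)) {
    g <- build_sng_knn(coords[[s]], k = min(k_intra, sizes[s] - 1L))
    edges[[length(edges) + 1L]] <- g$edges + offset[s]
  }
  for (s in seq_len(length(slices) - 1L)) {
    a <- coords[[s]]; b <- coords[[s + 1L]]
    nb_ab <- .covering_neighbors(a, b, k_cross)
    edges[[length(edges) + 1L]] <-
      cbind(rep(seq_len(sizes[s]), lengths(nb_ab)) + offset[s],
            unlist(nb_ab) + offset[s + 1L])
    nb_ba <- .covering_neighbors(b, a, k_cross)
    edges[[length(edges) + 1L]] <-
      cbind(rep(seq_len(sizes[s + 1L]), lengths(nb_ba)) + offset[s + 1L],
            unlist(nb_ba) + offset[s])
  }
  .new_sng(sum(sizes), do.call(rbind, edges), "sng3d",
           list(k_intra = k_intra, k_cross = k_cross))
}

#' Build the neighbor graph for a (possibly multi-slice) dataset
#'
#' Dispatches on the number of slices: single slice -> covering-radius KNN;
#' two slices -> merged pair graph; three or more -> adjacent-slice stack
#' graph.
#'
#' @param dataset a [spatial_dataset] (slice membership in `slice_idx`).
#' @param k,k_cross covering-neighbor counts (within-slice and cross-slice).
#' @param mode override: one of "auto", "knn", "radius"; `radius` requires
#'   `radius`.
#' @param radius threshold for `mode = "radius"`.
#' @return An `sng` matching the dataset's spot order.
#' @export
build_graph <- function(dataset, k = 6, k_cross = 7, mode = "auto",
                        radius = NULL) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  if (mode == "radius") {
    if (is.null(radius)) stop("mode 'radius' requires a radius")
    return(build_sng_radius(dataset$coords, radius))
  }
  n_slices <- max(dataset$slice_idx)
  if (mode == "knn" || n_slices == 1L)
    return(build_sng_knn(dataset$coords, k = k))
  slices <- lapply(seq_len(n_slices), function(s) {
    i <- dataset$slice_idx == s
    spatial_dataset(dataset$expr[i, , drop = FALSE],
                    dataset$coords[i, , drop = FALSE],
                    spot_ids = dataset$spot_ids[i],
                    gene_ids = dataset$gene_ids)
  })
  if (n_slices == 2L) build_2dsng(slices, k = k)
  else build_3dsng(slices, k_intra = k, k_cross = k_cross)
}

#' Export the edge list of a graph
#' @param graph an `sng`.
#' @param spot_ids optional spot identifiers for labeling.
#' @param path optional TSV output path.
#' @return A data frame `(src, dst)` (invisibly if written to `path`).
#' @export
export_edges <- function(graph, spot_ids = NULL, path = NULL) {
  stopifnot(inherits(graph, "sng"))
  df <- data.frame(src = graph$edges[, 1L], dst = graph$edges[, 2L])
  if (!is.null(spot_ids)) {
    df$src <- spot_ids[df$src]
    df$dst <- spot_ids[df$dst]
  }
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
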