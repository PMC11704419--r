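#' Construct a spatial expression dataset
#'
#' Bundles a spot-by-gene expression matrix with planar spot coordinates,
#' an optional slice index for vertically stacked multi-slice data, and
#' optional ground-truth domain labels. Spots are rows and genes are columns
#' throughout the package; the vertical axis of a stack is carried only by
#' `slice_idx`, never by a third coordinate.
#'
#' @param expr numeric spot-by-gene matrix (raw counts or normalized values);
#'   no `NA`/`Inf` entries, all values finite.
#' @param coords numeric N-by-2 matrix of planar spot positions.
#' @param spot_ids character vector of unique spot identifiers. Defaults to
#'   `rownames(expr)` or `spot_1..spot_N`.
#' @param gene_ids character vector of unique gene identifiers. Defaults to
#'   `colnames(expr)` or `gene_1..gene_G`.
#' @param slice_idx integer slice membership per spot, values contiguous from
#'   1. Defaults to all 1 (single slice).
#' @param labels optional per-spot domain annotations (factor or character),
#'   used for evaluation only.
#' @return An object of class `spatial_dataset`: a list with elements `expr`,
#'   `coords`, `spot_ids`, `gene_ids`, `slice_idx`, `labels`.
#' @examples
#' d <- spatial_dataset(matrix(rpois(12, 2), 4, 3), cbind(1:4, 0))
#' d
#' @export
spatial_dataset <- function(expr, coords, spot_ids = NULL, gene_ids = NULL,
                            slice_idx = NULL, labels = NULL) {
  expr <- as.matrix(expr)
  storage.mode(expr) <- "double"
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- nrow(expr); g <- ncol(expr)
  if (n < 1L || g < 1L)
    stop("dataset must have at least one spot and one gene (got ", n,
         " spots, ", g, " genes)")
  if (any(!is.finite(expr)))
    stop("expression matrix contains NA/NaN/Inf values")
  if (!is.matrix(coords) || ncol(coords) != 2L || nrow(coords) != n)
    stop("coords must be an N x 2 matrix matching the expression rows (",
         n, " spots vs ", nrow(coords), " coordinate rows)")
  if (any(!is.finite(coords)))
    stop("coordinates contain NA/NaN/Inf values")
  if (is.null(spot_ids)) spot_ids <- rownames(expr)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(g))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (length(spot_ids) != n) stop("spot_ids length does not match spot count")
  if (length(gene_ids) != g) stop("gene_ids length does not match gene count")
  if (anyDuplicated(spot_ids))
    stop("duplicate spot_id: ", paste(unique(spot_ids[duplicated(spot_ids)]),
                                      collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_id: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                      collapse = ", "))
  if (is.null(slice_idx)) slice_idx <- rep(1L, n)
  slice_idx <- as.integer(slice_idx)
  if (length(slice_idx) != n) stop("slice_idx length does not match spot count")
  u <- sort(unique(slice_idx))
  if (!identical(u, seq_along(u)))
    stop("slice_idx values must be contiguous integers starting at 1 (got ",
         paste(u, collapse = ","), ")")
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels length does not match spot count")
    labels <- as.factor(labels)
  }
  rownames(expr) <- spot_ids
  colnames(expr) <- gene_ids
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  structure(list(expr = expr, coords = coords, spot_ids = spot_ids,
                 gene_ids = gene_ids, slice_idx = slice_idx, labels = labels),
            class = "spatial_dataset")
}

#' @method print spatial_dataset
#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", nrow(x$expr), "spots x", ncol(x$expr), "genes,",
      max(x$slice_idx), "slice(s)")
  if (!is.null(x$labels))
    cat(",", nlevels(x$labels), "annotated domains")
  cat("\n")
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$expr)

# Matrix Market coordinate writer with full double precision. The disk
# orientation is genes x spots (the common single-cell dialect); the reader
# transposes at load.
.write_mtx <- function(expr, path) {
  m <- t(expr)                       # genes x spots on disk
  idx <- which(m != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
  vals <- m[idx]
  integral <- length(vals) == 0L || all(vals == round(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%%%%MatrixMarket matrix coordinate %s general",
                     if (integral) "integer" else "real"), con)
  writeLines(sprintf("%d %d %d", nrow(m), ncol(m), length(vals)), con)
  if (length(vals)) {
    lines <- if (integral)
      sprintf("%d %d %d", idx[, 1L], idx[, 2L], as.integer(vals))
    else sprintf("%d %d %.17g", idx[, 1L], idx[, 2L], vals)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a spatial expression bundle
#'
#' Reads a Matrix Market expression matrix (genes x spots on disk, transposed
#' at load so that spots are rows in memory) together with TSV sidecars for
#' coordinates and gene identifiers, and optionally a label sidecar.
#'
#' @param matrix_path path to the `.mtx` expression matrix (genes x spots).
#' @param coords_path path to a TSV with columns `spot_id`, `x`, `y` and
#'   optionally `slice`; row order defines spot order.
#' @param genes_path path to a TSV with column `gene_id` (one row per gene).
#' @param labels_path optional TSV with columns `spot_id`, `label`.
#' @return A validated [spatial_dataset]. Spot order follows the coordinate
#'   file and matches the matrix columns on disk.
#' @seealso [write_bundle()]
#' @export
read_bundle <- function(matrix_path, coords_path, genes_path,
                        labels_path = NULL) {
  m <- Matrix::readMM(matrix_path)
  coords_df <- utils::read.delim(coords_path, stringsAsFactors = FALSE)
  if (!all(c("spot_id", "x", "y") %in% names(coords_df)))
    stop("coords file must have columns spot_id, x, y")
  genes_df <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  if (!"gene_id" %in% names(genes_df))
    stop("genes file must have a gene_id column")
  n_mat <- ncol(m)                    # spots are columns on disk
  n_coord <- nrow(coords_df)
  if (n_mat != n_coord)
    stop("dimension mismatch: matrix has ", n_mat,
         " spots (columns) but coordinate file has ", n_coord, " rows")
  if (nrow(genes_df) != nrow(m))
    stop("dimension mismatch: matrix has ", nrow(m),
         " genes (rows) but gene file has ", nrow(genes_df), " rows")
  if (anyDuplicated(coords_df$spot_id))
    stop("duplicate spot_id in coordinate file: ",
         paste(unique(coords_df$spot_id[duplicated(coords_df$spot_id)]),
               collapse = ", "))
  expr <- t(as.matrix(m))
  slice_idx <- if ("slice" %in% names(coords_df))
    as.integer(coords_df$slice) else NULL
  labels <- NULL
  if (!is.null(labels_path)) {
    lab_df <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    if (!all(c("spot_id", "label") %in% names(lab_df)))
      stop("labels file must have columns spot_id, label")
    labels <- lab_df$label[match(coords_df$spot_id, lab_df$spot_id)]
    if (anyNA(labels)) stop("labels file is missing some spot_ids")
  } else if ("label" %in% names(coords_df)) {
    labels <- coords_df$label
  }
  spatial_dataset(expr, cbind(coords_df$x, coords_df$y),
                  spot_ids = coords_df$spot_id, gene_ids = genes_df$gene_id,
                  slice_idx = slice_idx, labels = labels)
}

#' Write a spatial expression bundle
#'
#' Emits `matrix.mtx` (genes x spots, Matrix Market coordinate format with
#' full double precision), `coords.tsv`, `genes.tsv`, optionally `labels.tsv`,
#' and a `manifest.json` recording MD5 checksums, dimensions and the disk
#' orientation convention.
#'
#' @param dataset a [spatial_dataset].
#' @param out_dir output directory, created if absent.
#' @return Invisibly, the manifest as a list.
#' @export
write_bundle <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "spatial_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- c(matrix = file.path(out_dir, "matrix.mtx"),
             coords = file.path(out_dir, "coords.tsv"),
             genes = file.path(out_dir, "genes.tsv"))
  .write_mtx(dataset$expr, paths[["matrix"]])
  coords_df <- data.frame(spot_id = dataset$spot_ids,
                          x = dataset$coords[, 1L], y = dataset$coords[, 2L],
                          slice = dataset$slice_idx)
  utils::write.table(coords_df, paths[["coords"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_id = dataset$gene_ids), paths[["genes"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$labels)) {
    paths <- c(paths, labels = file.path(out_dir, "labels.tsv"))
    utils::write.table(data.frame(spot_id = dataset$spot_ids,
                                  label = as.character(dataset$labels)),
                       paths[["labels"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    orientation = "matrix.mtx is genes x spots; in-memory matrices are spots x genes (transposed at load)",
    n_spots = nrow(dataset$expr), n_genes = ncol(dataset$expr),
    n_slices = max(dataset$slice_idx),
    files = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                    basename(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# subset helper used by the preprocessing stages: keep genes (columns) by index
.keep_genes <- function(dataset, keep) {
  spatial_dataset(dataset$expr[, keep, drop = FALSE], dataset$coords,
                  spot_ids = dataset$spot_ids,
                  gene_ids = dataset$gene_ids[keep],
                  slice_idx = dataset$slice_idx, labels = dataset$labels)
}

# replace the expression matrix, keeping all metadata
.with_expr <- function(dataset, expr) {
  spatial_dataset(expr, dataset$coords, spot_ids = dataset$spot_ids,
                  gene_ids = dataset$gene_ids, slice_idx = dataset$slice_idx,
                  labels = dataset$labels)
}
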