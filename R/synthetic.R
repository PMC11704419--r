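#' Simulation configuration
#'
#' Parameters of the spatially structured expression simulator. Defaults
#' describe the "standard-small" fixture used throughout the package's
#' tests: a 20 x 20 hexagonal lattice (400 spots, Visium-like geometry),
#' 200 genes of which 30% are domain-informative with a 4-fold mean shift,
#' negative-binomial counts with moderate overdispersion, and 30% random
#' dropout.
#'
#' @param rows,cols lattice dimensions (both >= 2).
#' @param spacing lattice spacing in arbitrary planar units (default 1).
#' @param layout `"hex"` (offset rows, interior degree 6) or `"grid"`.
#' @param n_domains number of spatial domains (default 4).
#' @param domain_pattern `"bands"` (contiguous horizontal strata, mimicking
#'   cortical layers) or `"blobs"` (nearest-seed Voronoi regions).
#' @param n_genes gene count (default 200).
#' @param de_frac fraction of genes that are domain-informative (default
#'   0.3).
#' @param nb_mean_base baseline negative-binomial mean (default 2).
#' @param nb_mean_fold mean fold-change of an informative gene inside its
#'   domain (default 4).
#' @param nb_dispersion negative-binomial size parameter (default 2;
#'   smaller = more overdispersed).
#' @param dropout_rate independent zeroing probability applied after the
#'   count draw, emulating technical dropouts (default 0.3).
#' @param n_slices number of slices for multi-slice stacks (default 1).
#' @param batch_log_fc_sd standard deviation of the per-slice per-gene
#'   log-normal batch factor (default 0; used by [make_multislice()]).
#' @param seed RNG seed; identical config + seed gives identical data.
#' @return A `sim_config` list.
#' @export
sim_config <- function(rows = 20, cols = 20, spacing = 1, layout = "hex",
                       n_domains = 4, domain_pattern = "bands",
                       n_genes = 200, de_frac = 0.3, nb_mean_base = 2,
                       nb_mean_fold = 4, nb_dispersion = 2,
                       dropout_rate = 0.3, n_slices = 1,
                       batch_log_fc_sd = 0, seed = 7) {
  stopifnot(rows >= 2, cols >= 2, spacing > 0, n_genes >= 1,
            n_domains >= 1, de_frac >= 0, de_frac <= 1,
            nb_mean_base > 0, nb_mean_fold > 0, nb_dispersion > 0,
            dropout_rate >= 0, dropout_rate < 1, n_slices >= 1,
            batch_log_fc_sd >= 0)
  layout <- match.arg(layout, c("hex", "grid"))
  domain_pattern <- match.arg(domain_pattern, c("bands", "blobs"))
  structure(as.list(environment()), class = "sim_config")
}

#' Spot lattice coordinates
#'
#' `hex`: offset rows at a vertical pitch of `spacing * sqrt(3)/2`, odd rows
#' shifted by half a spacing, so interior spots have exactly 6 equidistant
#' nearest neighbors. `grid`: a square lattice.
#'
#' @param cfg a [sim_config] (fields `rows`, `cols`, `spacing`, `layout`).
#' @return N-by-2 coordinate matrix, `N = rows * cols`, row-major order.
#' @export
make_lattice <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  r <- rep(seq_len(cfg$rows), each = cfg$cols)
  c_ <- rep(seq_len(cfg$cols), times = cfg$rows)
  if (cfg$layout == "hex") {
    x <- (c_ - 1 + ifelse(r %% 2 == 0, 0.5, 0)) * cfg$spacing
    y <- (r - 1) * cfg$spacing * sqrt(3) / 2
  } else {
    x <- (c_ - 1) * cfg$spacing
    y <- (r - 1) * cfg$spacing
  }
  cbind(x = x, y = y)
}

#' Assign spatial domains to lattice spots
#'
#' `bands`: contiguous horizontal strata (rows split as evenly as possible
#' into `n_domains` groups). `blobs`: nearest-seed Voronoi regions around
#' uniformly drawn seed spots; reseeded internally (up to 10 times) if a
#' domain comes out empty.
#'
#' @param coords N-by-2 coordinates from [make_lattice()].
#' @param cfg a [sim_config].
#' @return Integer domain label per spot, every domain nonempty.
#' @export
assign_domains <- function(coords, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(coords)
  if (cfg$domain_pattern == "bands") {
    if (cfg$n_domains > cfg$rows)
      stop("bands require n_domains <= rows")
    ys <- sort(unique(coords[, 2L]))
    band_of_row <- as.integer(cut(seq_along(ys), cfg$n_domains,
                                  labels = FALSE))
    return(band_of_row[match(coords[, 2L], ys)])
  }
  for (attempt in 1:10) {
    seeds <- coords[sample.int(n, cfg$n_domains), , drop = FALSE]
    d <- .pairwise_dist(coords, seeds)
    lab <- max.col(-d, ties.method = "first")
    if (all(tabulate(lab, cfg$n_domains) > 0)) return(lab)
  }
  stop("failed to draw nonempty blob domains after 10 attempts")
}

#' Simulate domain-programmed counts with dropout
#'
#' Each informative gene is assigned to one domain and gets mean
#' `nb_mean_base * nb_mean_fold` there and `nb_mean_base` elsewhere; counts
#' are negative binomial with size `nb_dispersion`, then independently
#' zeroed with probability `dropout_rate`.
#'
#' @param labels integer domain label per spot.
#' @param cfg a [sim_config].
#' @return List with `counts` (spot-by-gene integer matrix) and `truth`
#'   (data frame `gene`, `domain` (`NA` for background genes), `fold`).
#' @export
simulate_expression <- function(labels, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- length(labels)
  g <- cfg$n_genes
  n_de <- floor(cfg$de_frac * g)
  gene_domain <- rep(NA_integer_, g)
  if (n_de > 0)
    gene_domain[seq_len(n_de)] <-
      rep_len(seq_len(cfg$n_domains), n_de)   # round-robin assignment
  mu <- matrix(cfg$nb_mean_base, n, g)
  for (j in which(!is.na(gene_domain)))
    mu[labels == gene_domain[j], j] <- cfg$nb_mean_base * cfg$nb_mean_fold
  counts <- matrix(stats::rnbinom(n * g, size = cfg$nb_dispersion, mu = mu),
                   n, g)
  if (cfg$dropout_rate > 0) {
    drop <- matrix(stats::runif(n * g) < cfg$dropout_rate, n, g)
    counts[drop] <- 0L
  }
  truth <- data.frame(gene = paste0("gene_", seq_len(g)),
                      domain = gene_domain,
                      fold = ifelse(is.na(gene_domain), 1, cfg$nb_mean_fold))
  list(counts = counts, truth = truth)
}

#' Simulate a single-slice spatial dataset
#'
#' Convenience wrapper: lattice + domain labels + domain-programmed counts,
#' returned as a labeled [spatial_dataset]. Fully deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [sim_config].
#' @return A [spatial_dataset] with `labels` set to the generating domains
#'   and the gene truth table attached as attribute `"truth"`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  coords <- make_lattice(cfg)
  labels <- assign_domains(coords, cfg)
  sim <- simulate_expression(labels, cfg)
  d <- spatial_dataset(sim$counts, coords, labels = labels)
  attr(d, "truth") <- sim$truth
  d
}

#' Simulate a vertically aligned multi-slice stack
#'
#' Every slice shares the same lattice and domain geometry (so truth labels
#' are identical across slices); each slice applies an independent per-gene
#' multiplicative batch factor `exp(N(0, batch_log_fc_sd))` to the
#' negative-binomial means before drawing counts, emulating slice-level
#' batch effects.
#'
#' @param cfg a [sim_config]; `cfg$n_slices` (or `n_slices`) must be >= 2.
#' @param n_slices override of `cfg$n_slices`.
#' @param batch_log_fc_sd override of `cfg$batch_log_fc_sd`.
#' @return List of per-slice [spatial_dataset]s; combine with
#'   [concat_slices()].
#' @export
make_multislice <- function(cfg = sim_config(), n_slices = NULL,
                            batch_log_fc_sd = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(n_slices)) cfg$n_slices <- n_slices
  if (!is.null(batch_log_fc_sd)) cfg$batch_log_fc_sd <- batch_log_fc_sd
  if (cfg$n_slices < 2) stop("multi-slice stacks need n_slices >= 2")
  set.seed(cfg$seed)
  coords <- make_lattice(cfg)
  labels <- assign_domains(coords, cfg)
  n <- nrow(coords); g <- cfg$n_genes
  n_de <- floor(cfg$de_frac * g)
  gene_domain <- rep(NA_integer_, g)
  if (n_de > 0)
    gene_domain[seq_len(n_de)] <- rep_len(seq_len(cfg$n_domains), n_de)
  mu0 <- matrix(cfg$nb_mean_base, n, g)
  for (j in which(!is.na(gene_domain)))
    mu0[labels == gene_domain[j], j] <- cfg$nb_mean_base * cfg$nb_mean_fold
  lapply(seq_len(cfg$n_slices), function(s) {
    fac <- exp(stats::rnorm(g, 0, cfg$batch_log_fc_sd))
    mu <- sweep(mu0, 2L, fac, "*")
    counts <- matrix(stats::rnbinom(n * g, size = cfg$nb_dispersion,
                                    mu = mu), n, g)
    if (cfg$dropout_rate > 0) {
      drop <- matrix(stats::runif(n * g) < cfg$dropout_rate, n, g)
      counts[drop] <- 0L
    }
    spatial_dataset(counts, coords,
                    spot_ids = paste0("spot_", seq_len(n)),
                    labels = labels)
  })
}

#' The standard-small test fixture
#'
#' The versioned fixture used by the package's acceptance checks: hex
#' 20 x 20 lattice (400 spots), 200 genes, 4 horizontal band domains,
#' `de_frac` 0.3, dropout 0.3, seed 7.
#'
#' @param seed fixture seed (default 7).
#' @return A labeled [spatial_dataset].
#' @export
sim_standard_small <- function(seed = 7) {
  simulate_dataset(sim_config(seed = seed))
}
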