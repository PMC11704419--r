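.config_schema <- c(
  "run_id", "outdir", "seed", "stages", "log_level",
  "simulate.rows", "simulate.cols", "simulate.spacing", "simulate.layout",
  "simulate.n_domains", "simulate.domain_pattern", "simulate.n_genes",
  "simulate.de_frac", "simulate.nb_mean_base", "simulate.nb_mean_fold",
  "simulate.nb_dispersion", "simulate.dropout_rate", "simulate.n_slices",
  "simulate.batch_log_fc_sd",
  "input.matrix", "input.coords", "input.genes", "input.labels",
  "preprocess.min_cells", "preprocess.n_hvg", "preprocess.target",
  "preprocess.skip_hvg",
  "graph.mode", "graph.k", "graph.k_cross", "graph.radius",
  "train.dims", "train.epochs", "train.gamma", "train.lr",
  "train.weight_decay", "train.mask_ratio", "train.replace_ratio",
  "train.remask_ratio",
  "cluster.k")

.num_keys <- c("seed", "simulate.rows", "simulate.cols", "simulate.spacing",
               "simulate.n_domains", "simulate.n_genes", "simulate.de_frac",
               "simulate.nb_mean_base", "simulate.nb_mean_fold",
               "simulate.nb_dispersion", "simulate.dropout_rate",
               "simulate.n_slices", "simulate.batch_log_fc_sd",
               "preprocess.min_cells", "preprocess.n_hvg",
               "graph.k", "graph.k_cross", "graph.radius",
               "train.epochs", "train.gamma", "train.lr",
               "train.weight_decay", "train.mask_ratio",
               "train.replace_ratio", "train.remask_ratio", "cluster.k")

#' Read a pipeline configuration file
#'
#' Plain-text `key = value` configuration (one pair per line, `#` comments).
#' Every key is validated against the pipeline schema; unknown keys are
#' rejected with the offending key named. Numeric keys are coerced.
#'
#' @param path configuration file path.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% .config_schema)
      stop("unknown config key: ", key)
    if (key %in% .num_keys) {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("config key ", key, " needs a number, got: ", val)
      val <- num
    }
    cfg[[key]] <- val
  }
  cfg
}

.cfg_get <- function(cfg, key, default) {
  if (is.null(cfg[[key]])) default else cfg[[key]]
}

.pipeline_log <- function(level, quiet, ...) {
  if (!quiet) message(format(Sys.time(), "%H:%M:%S"), " [", level, "] ", ...)
}

# per-stage resume bookkeeping: a stage is skipped when its recorded
# fingerprint (config hash + seed) matches and all of its outputs exist
.state_path <- function(outdir) file.path(outdir, "pipeline_state.json")

.read_state <- function(outdir) {
  p <- .state_path(outdir)
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

.stage_done <- function(state, stage, fingerprint, outputs) {
  !is.null(state[[stage]]) &&
    identical(state[[stage]]$fingerprint, fingerprint) &&
    all(file.exists(outputs))
}

.mark_stage <- function(outdir, state, stage, fingerprint, outputs) {
  state[[stage]] <- list(fingerprint = fingerprint,
                         outputs = as.list(outputs),
                         checksums = as.list(stats::setNames(
                           unname(tools::md5sum(outputs)),
                           basename(outputs))))
  jsonlite::write_json(state, .state_path(outdir), auto_unbox = TRUE,
                       pretty = TRUE)
  state
}

#' Run the full analysis pipeline from a configuration file
#'
#' Executes the requested stages in order (`simulate` or external `input`,
#' `preprocess`, `graph`, `train`, `cluster`, `denoise`, `attention`,
#' `metrics`), writing every artifact under the output directory:
#' `bundle/` and `preprocessed/` expression bundles, `edges.tsv`,
#' `embeddings.tsv`, `training_log.csv`, `clusters.tsv`, `denoised.mtx`,
#' `attention_edges.tsv`, and `metrics.json`. Each stage logs its seed and
#' records output checksums; rerunning with an unchanged configuration
#' skips stages whose fingerprint and outputs are intact.
#'
#' @param config_path path to a `key = value` configuration file (see
#'   [read_run_config()]).
#' @param seed optional override of the configured seed.
#' @param outdir optional override of the configured output directory.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the artifact paths and key results.
#' @export
run_pipeline <- function(config_path, seed = NULL, outdir = NULL,
                         quiet = FALSE) {
  cfg <- read_run_config(config_path)
  if (is.null(seed)) seed <- as.integer(.cfg_get(cfg, "seed", 1))
  seed <- as.integer(seed)
  if (is.null(outdir)) outdir <- .cfg_get(cfg, "outdir", "stgmae_run")
  if (identical(.cfg_get(cfg, "log_level", "info"), "quiet")) quiet <- TRUE
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- strsplit(.cfg_get(
    cfg, "stages", "simulate,preprocess,graph,train,cluster,metrics"),
    ",")[[1L]]
  stages <- trimws(stages)
  known <- c("simulate", "input", "preprocess", "graph", "train", "cluster",
             "denoise", "attention", "metrics")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  fp_all <- paste(seed, paste(names(cfg), unlist(lapply(cfg, paste,
                  collapse = ",")), sep = "=", collapse = ";"))
  state <- .read_state(outdir)
  res <- list(outdir = outdir)
  dataset <- NULL; prep <- NULL; graph <- NULL; fit <- NULL

  run_stage <- function(stage, outputs, fun) {
    fp <- paste(stage, fp_all)
    if (.stage_done(state, stage, fp, outputs)) {
      .pipeline_log("info", quiet, "stage ", stage,
                    ": unchanged, skipping (checksum match)")
      return(FALSE)
    }
    .pipeline_log("info", quiet, "stage ", stage, ": running (seed ", seed,
                  ")")
    ok <- try(fun(), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop("stage '", stage, "' failed: ", attr(ok, "condition")$message)
    state <<- .mark_stage(outdir, state, stage, fp, outputs)
    TRUE
  }

  bundle_dir <- file.path(outdir, "bundle")
  if ("simulate" %in% stages) {
    outs <- file.path(bundle_dir, c("matrix.mtx", "coords.tsv", "genes.tsv",
                                    "labels.tsv"))
    run_stage("simulate", c(outs, file.path(outdir, "truth.tsv")), function() {
      sc <- sim_config(
        rows = .cfg_get(cfg, "simulate.rows", 20),
        cols = .cfg_get(cfg, "simulate.cols", 20),
        spacing = .cfg_get(cfg, "simulate.spacing", 1),
        layout = .cfg_get(cfg, "simulate.layout", "hex"),
        n_domains = .cfg_get(cfg, "simulate.n_domains", 4),
        domain_pattern = .cfg_get(cfg, "simulate.domain_pattern", "bands"),
        n_genes = .cfg_get(cfg, "simulate.n_genes", 200),
        de_frac = .cfg_get(cfg, "simulate.de_frac", 0.3),
        nb_mean_base = .cfg_get(cfg, "simulate.nb_mean_base", 2),
        nb_mean_fold = .cfg_get(cfg, "simulate.nb_mean_fold", 4),
        nb_dispersion = .cfg_get(cfg, "simulate.nb_dispersion", 2),
        dropout_rate = .cfg_get(cfg, "simulate.dropout_rate", 0.3),
        n_slices = .cfg_get(cfg, "simulate.n_slices", 1),
        batch_log_fc_sd = .cfg_get(cfg, "simulate.batch_log_fc_sd", 0),
        seed = seed)
      d <- if (sc$n_slices >= 2) concat_slices(make_multislice(sc))
           else simulate_dataset(sc)
      write_bundle(d, bundle_dir)
      tr <- attr(d, "truth")
      if (is.null(tr)) tr <- data.frame(gene = d$gene_ids)
      utils::write.table(tr, file.path(outdir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
    dataset <- read_bundle(file.path(bundle_dir, "matrix.mtx"),
                           file.path(bundle_dir, "coords.tsv"),
                           file.path(bundle_dir, "genes.tsv"),
                           file.path(bundle_dir, "labels.tsv"))
  } else if (!is.null(cfg[["input.matrix"]])) {
    dataset <- read_bundle(cfg[["input.matrix"]], cfg[["input.coords"]],
                           cfg[["input.genes"]], cfg[["input.labels"]])
  } else if (any(c("preprocess", "graph", "train") %in% stages)) {
    stop("no input: include the simulate stage or set input.* paths")
  }

  prep_dir <- file.path(outdir, "preprocessed")
  if ("preprocess" %in% stages) {
    outs <- file.path(prep_dir, c("matrix.mtx", "coords.tsv", "genes.tsv"))
    run_stage("preprocess", outs, function() {
      p <- preprocess(
        dataset,
        min_cells = .cfg_get(cfg, "preprocess.min_cells", 3),
        n_hvg = .cfg_get(cfg, "preprocess.n_hvg", 3000),
        normalize_target = .cfg_get(cfg, "preprocess.target", "median"),
        skip_hvg = identical(.cfg_get(cfg, "preprocess.skip_hvg", "false"),
                             "true"))
      write_bundle(p, prep_dir)
    })
    prep <- read_bundle(file.path(prep_dir, "matrix.mtx"),
                        file.path(prep_dir, "coords.tsv"),
                        file.path(prep_dir, "genes.tsv"),
                        if (file.exists(file.path(prep_dir, "labels.tsv")))
                          file.path(prep_dir, "labels.tsv"))
  } else prep <- dataset

  if ("graph" %in% stages || "train" %in% stages) {
    edges_path <- file.path(outdir, "edges.tsv")
    run_stage("graph", edges_path, function() {
      g <- build_graph(prep,
                       k = .cfg_get(cfg, "graph.k", 6),
                       k_cross = .cfg_get(cfg, "graph.k_cross", 7),
                       mode = .cfg_get(cfg, "graph.mode", "auto"),
                       radius = cfg[["graph.radius"]])
      export_edges(g, path = edges_path)
    })
    graph <- build_graph(prep, k = .cfg_get(cfg, "graph.k", 6),
                         k_cross = .cfg_get(cfg, "graph.k_cross", 7),
                         mode = .cfg_get(cfg, "graph.mode", "auto"),
                         radius = cfg[["graph.radius"]])
  }

  model_path <- file.path(outdir, "model.rds")
  if ("train" %in% stages) {
    outs <- c(file.path(outdir, "embeddings.tsv"),
              file.path(outdir, "training_log.csv"), model_path)
    dims <- as.numeric(strsplit(
      .cfg_get(cfg, "train.dims", "512,30"), ",")[[1L]])
    run_stage("train", outs, function() {
      f <- stgmae(prep, graph = graph, dims = dims,
                  epochs = .cfg_get(cfg, "train.epochs", 500),
                  gamma = .cfg_get(cfg, "train.gamma", 2),
                  lr = .cfg_get(cfg, "train.lr", 0.001),
                  weight_decay = .cfg_get(cfg, "train.weight_decay", 0.001),
                  mask_ratio = .cfg_get(cfg, "train.mask_ratio", 0.5),
                  replace_ratio = .cfg_get(cfg, "train.replace_ratio", 0.05),
                  remask_ratio = .cfg_get(cfg, "train.remask_ratio", 0.5),
                  seed = seed, verbose = !quiet)
      emb <- data.frame(spot_id = prep$spot_ids, f$latent)
      utils::write.table(emb, file.path(outdir, "embeddings.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.csv(f$loss, file.path(outdir, "training_log.csv"),
                       row.names = FALSE)
      saveRDS(f, model_path)
    })
    fit <- readRDS(model_path)
    res$fit <- fit
  }

  if ("cluster" %in% stages) {
    stopifnot(!is.null(fit))
    kk <- .cfg_get(cfg, "cluster.k",
                   if (!is.null(prep$labels)) nlevels(prep$labels) else
                     stop("cluster.k not set and no labels to infer it from"))
    clusters_path <- file.path(outdir, "clusters.tsv")
    run_stage("cluster", clusters_path, function() {
      cl <- cluster_domains(fit$latent, k = kk, seed = seed)
      utils::write.table(data.frame(spot_id = prep$spot_ids,
                                    cluster = cl$labels),
                         clusters_path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
    res$clusters <- utils::read.delim(clusters_path)
  }

  if ("denoise" %in% stages) {
    stopifnot(!is.null(fit))
    run_stage("denoise", file.path(outdir, "denoised.mtx"), function() {
      Z <- predict(fit, type = "denoised")
      rownames(Z) <- prep$spot_ids
      colnames(Z) <- prep$gene_ids
      .write_mtx(Z, file.path(outdir, "denoised.mtx"))
    })
  }

  if ("attention" %in% stages) {
    stopifnot(!is.null(fit))
    run_stage("attention", file.path(outdir, "attention_edges.tsv"),
              function() {
      attention_edges(fit, layer = 1,
                      path = file.path(outdir, "attention_edges.tsv"))
    })
  }

  if ("metrics" %in% stages) {
    stopifnot(!is.null(fit))
    metrics_path <- file.path(outdir, "metrics.json")
    run_stage("metrics", metrics_path, function() {
      pred <- if (!is.null(res$clusters)) res$clusters$cluster else
        stop("metrics stage needs the cluster stage")
      truth <- if (!is.null(prep$labels)) as.integer(prep$labels)
      batch <- if (max(prep$slice_idx) > 1L) prep$slice_idx
      mr <- metrics_report(fit$latent, pred, truth = truth, batch = batch)
      jsonlite::write_json(mr, metrics_path, auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
    })
    res$metrics <- jsonlite::read_json(metrics_path)
  }

  .pipeline_log("info", quiet, "pipeline complete: ", outdir)
  invisible(res)
}
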