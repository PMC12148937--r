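# pipeline orchestration: config validation, seed derivation, stage chaining

.STAGE_KEYS <- list(
  simulate = c("counts", "traces", "scene"),
  qc = c("thresholds", "doublet", "refine", "input"),
  cluster = c("method", "n_hvg", "n_pcs", "k_neighbors", "resolution", "input"),
  lr = c("trim", "min_frac_expressing", "n_permutations", "kh"),
  transfer = c("ref", "ref_labels", "mask", "k", "n_pcs"),
  calcium = c("traces", "z_threshold", "min_separation_s", "smooth_s"),
  proximity = c("scene"))

.check_keys <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown key '%s' in %s", extra[1], where), call. = FALSE)
  invisible(TRUE)
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list: global keys `seed`, `out_dir`,
#' `log_level`, plus one block per stage to run (`simulate`, `qc`,
#' `cluster`, `lr`, `transfer`, `calcium`, `proximity`). Unknown keys at
#' any level are rejected by name. Every stochastic stage receives a
#' sub-seed derived from the global seed.
#'
#' @param config named list, or path to a YAML file.
#' @return the validated config (class `run_config`).
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  .check_keys(config, c("seed", "out_dir", "log_level", names(.STAGE_KEYS)),
              "run config")
  if (is.null(config$out_dir)) stop("out_dir is required", call. = FALSE)
  config$seed <- as.integer(config$seed %||% 1L)
  for (st in intersect(names(config), names(.STAGE_KEYS)))
    .check_keys(config[[st]], .STAGE_KEYS[[st]], sprintf("stage '%s'", st))
  structure(config, class = "run_config")
}

.log_msg <- function(level, cfg, ...) {
  if (identical(cfg$log_level %||% "info", "quiet")) return(invisible())
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the configured pipeline stages
#'
#' Executes the stage blocks present in the configuration in canonical
#' order (simulate, qc, cluster, lr, transfer, calcium, proximity),
#' chaining each stage's output directory into the next. Writes per-stage
#' outputs under `out_dir` and a JSON manifest recording versions, seeds
#' and cell counts; reruns with the same config and seed produce an
#' identical manifest.
#'
#' @param config a [run_config()] (or list/YAML path accepted by it).
#' @return the manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  cfg <- run_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "enskit",
                   version = as.character(utils::packageVersion("enskit")),
                   r_version = paste(R.version$major, R.version$minor, sep = "."),
                   seed = cfg$seed, stages = list())
  add_stage <- function(name, info) {
    manifest$stages[[name]] <<- c(list(seed = .derive_seed(cfg$seed,
                                                           length(manifest$stages) + 1L)),
                                  info)
  }
  counts_dir <- NULL; traces_path <- NULL; scene_path <- NULL
  labels_path <- NULL

  if (!is.null(cfg$simulate)) {
    s <- cfg$simulate
    info <- list()
    if (!is.null(s$counts)) {
      sc <- do.call(sim_counts_config,
                    c(s$counts, list(seed = .derive_seed(cfg$seed, 11))))
      sim <- gen_counts(sc)
      counts_dir <- file.path(out, "simulated_counts")
      write_counts_10x(sim$counts, counts_dir)
      utils::write.table(data.frame(cell = names(sim$truth$class_of_cell),
                                    class = sim$truth$class_of_cell,
                                    sex = sim$truth$sex_of_cell),
                         file.path(out, "counts_truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      info$n_cells <- ncol(sim$counts); info$n_genes <- nrow(sim$counts)
    }
    if (!is.null(s$traces)) {
      tc <- do.call(sim_trace_config,
                    c(s$traces, list(seed = .derive_seed(cfg$seed, 12))))
      tr <- gen_traces(tc)
      traces_path <- file.path(out, "simulated_traces.csv")
      write_traces_csv(tr$traces, traces_path)
      info$n_rois <- tc$n_cells
    }
    if (!is.null(s$scene)) {
      gc_ <- do.call(sim_scene_config,
                     c(s$scene, list(seed = .derive_seed(cfg$seed, 13))))
      sce <- gen_scene(gc_)
      scene_path <- file.path(out, "simulated_scene.json")
      write_scene_json(sce$scene, scene_path)
      info$n_scene_cells <- gc_$n_cells
    }
    add_stage("simulate", info)
    .log_msg("info", cfg, "simulate: done")
  }

  if (!is.null(cfg$qc)) {
    src <- cfg$qc$input %||% counts_dir
    if (is.null(src)) stop("stage 'qc': no input counts (missing simulate output or qc$input)",
                           call. = FALSE)
    counts <- read_counts_10x(src)
    th <- do.call(qc_thresholds, cfg$qc$thresholds %||% list())
    gf <- global_filter(counts, th)
    filtered <- gf$counts
    if (!is.null(cfg$qc$doublet)) {
      dp <- do.call(doublet_params, cfg$qc$doublet)
      sc <- doublet_scores(filtered, dp, seed = .derive_seed(cfg$seed, 21))
      filtered <- filtered[, sc <= attr(sc, "threshold"), drop = FALSE]
    }
    counts_dir <- file.path(out, "qc_counts")
    write_counts_10x(filtered, counts_dir)
    jsonlite::write_json(gf$report$steps, file.path(out, "qc_report.json"),
                         dataframe = "rows")
    add_stage("qc", list(n_in = ncol(counts), n_out = ncol(filtered)))
    .log_msg("info", cfg, "qc: ", ncol(filtered), " cells retained")
  }

  if (!is.null(cfg$cluster)) {
    if (is.null(counts_dir)) stop("stage 'cluster': no input counts (missing qc output)",
                                  call. = FALSE)
    counts <- read_counts_10x(counts_dir)
    nh <- normalize_hvg(counts,
                        normalize_config(method = cfg$cluster$method %||% "log_cpm",
                                         n_hvg = cfg$cluster$n_hvg %||% 1000))
    emb <- pca_embed(nh$normalized, cfg$cluster$n_pcs %||% 15, genes = nh$hvg)
    gcfg <- graph_cluster_config(n_pcs = cfg$cluster$n_pcs %||% 15,
                                 k_neighbors = cfg$cluster$k_neighbors %||% 20,
                                 resolution = cfg$cluster$resolution %||% 1.0,
                                 seed = .derive_seed(cfg$seed, 31))
    lab <- snn_louvain(emb$embedding, gcfg)
    labels_path <- file.path(out, "clusters.tsv")
    utils::write.table(data.frame(cell = names(lab), cluster = lab),
                       labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
    mk <- de_markers(nh$normalized, lab)
    utils::write.table(mk, file.path(out, "markers.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_stage("cluster", list(n_cells = ncol(counts),
                              n_clusters = length(unique(lab))))
    .log_msg("info", cfg, "cluster: ", length(unique(lab)), " communities")
  }

  if (!is.null(cfg$lr)) {
    if (is.null(counts_dir) || is.null(labels_path))
      stop("stage 'lr': missing upstream output of stage 'cluster'", call. = FALSE)
    counts <- read_counts_10x(counts_dir)
    lab <- utils::read.table(labels_path, header = TRUE, sep = "\t")
    nh <- normalize_hvg(counts, normalize_config(method = "log_cpm"))
    pars <- lr_params(trim = cfg$lr$trim %||% 0.2,
                      min_frac_expressing = cfg$lr$min_frac_expressing %||% 0,
                      n_permutations = cfg$lr$n_permutations %||% 99,
                      kh = cfg$lr$kh %||% 0.5,
                      seed = .derive_seed(cfg$seed, 41))
    res <- permutation_test(nh$normalized, lab$cluster, lr_database(), pars)
    utils::write.table(res, file.path(out, "lr_interactions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_stage("lr", list(n_interactions = nrow(res)))
  }

  if (!is.null(cfg$transfer)) {
    t <- cfg$transfer
    if (is.null(t$ref) || is.null(t$ref_labels) || is.null(counts_dir))
      stop("stage 'transfer': needs ref, ref_labels and upstream counts", call. = FALSE)
    ref <- read_counts_10x(t$ref)
    query <- read_counts_10x(counts_dir)
    rl <- utils::read.table(t$ref_labels, header = TRUE, sep = "\t")
    je <- joint_embed(ref, query, n_pcs = t$n_pcs %||% 50)
    tr <- transfer_labels(je$ref, je$query, rl[[2]],
                          mask = t$mask %||% character(0), k = t$k %||% 30)
    utils::write.table(
      data.frame(cell = names(tr$predicted), predicted.id = tr$predicted,
                 tr$scores, check.names = FALSE),
      file.path(out, "transfer.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("transfer", list(n_query = length(tr$predicted)))
  }

  if (!is.null(cfg$calcium)) {
    src <- cfg$calcium$traces %||% traces_path
    if (is.null(src)) stop("stage 'calcium': no traces (missing simulate output or calcium$traces)",
                           call. = FALSE)
    traces <- read_traces_csv(src)
    sp <- spike_params(z_threshold = cfg$calcium$z_threshold %||% 3.5,
                       min_separation_s = cfg$calcium$min_separation_s %||% 0.5,
                       smooth_s = cfg$calcium$smooth_s %||% 0.3)
    an <- analyze_traces(traces, stimulus_protocol(), sp)
    utils::write.table(an$epochs, file.path(out, "epoch_results.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(cell = names(an$categories),
                                  category = an$categories),
                       file.path(out, "cell_categories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    add_stage("calcium", list(n_rois = length(an$categories)))
  }

  if (!is.null(cfg$proximity)) {
    src <- cfg$proximity$scene %||% scene_path
    if (is.null(src)) stop("stage 'proximity': no scene (missing simulate output or proximity$scene)",
                           call. = FALSE)
    scene <- read_scene_json(src)
    dd <- distance_distribution(scene)
    utils::write.table(dd$distances, file.path(out, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    add_stage("proximity", list(n_cells = nrow(scene$cells)))
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
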