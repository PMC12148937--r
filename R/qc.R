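#' Global QC thresholds
#'
#' Thresholds for droplet-level quality filtering. Defaults match the
#' juvenile dataset conventions (mito fraction <= 0.2, 500-6,500 genes,
#' <= 40,000 UMIs); postnatal data used 0.1 for the mito cutoff. Gene-range
#' boundaries are inclusive. Pre-filters (cells under 200 UMIs, genes seen
#' in fewer than 3 cells) run before the thresholds.
#'
#' @param max_mito_fraction cells above this mitochondrial count fraction
#'   are removed.
#' @param min_genes,max_genes inclusive bounds on detected genes per cell.
#' @param max_umis cells above this UMI total are removed.
#' @param min_cell_umis pre-filter: minimum UMIs per cell (set to 0 to
#'   disable).
#' @param min_cells_per_gene pre-filter: genes detected in fewer cells are
#'   dropped (0 disables).
#' @param trim_percentiles (low, high) percentiles for the per-cluster UMI
#'   trim ([cluster_percentile_trim()]).
#' @return object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_mito_fraction = 0.2, min_genes = 500,
                          max_genes = 6500, max_umis = 40000,
                          min_cell_umis = 200, min_cells_per_gene = 3,
                          trim_percentiles = c(1, 99)) {
  if (!(min_genes < max_genes)) stop("min_genes must be < max_genes", call. = FALSE)
  if (length(trim_percentiles) != 2L ||
      any(trim_percentiles <= 0) || any(trim_percentiles >= 100) ||
      trim_percentiles[1] >= trim_percentiles[2])
    stop("trim_percentiles must satisfy 0 < low < high < 100", call. = FALSE)
  structure(list(max_mito_fraction = max_mito_fraction,
                 min_genes = min_genes, max_genes = max_genes,
                 max_umis = max_umis, min_cell_umis = min_cell_umis,
                 min_cells_per_gene = min_cells_per_gene,
                 trim_percentiles = as.numeric(trim_percentiles)),
            class = "qc_thresholds")
}

#' Per-cell QC statistics
#'
#' @param counts genes x cells count matrix; mitochondrial genes are
#'   recognized by the `mt-` prefix (case-insensitive).
#' @return data.frame: cell, n_umis, n_genes, mito_fraction.
#' @export
cell_qc_stats <- function(counts) {
  umis <- Matrix::colSums(counts)
  ngen <- Matrix::colSums(counts > 0)
  mito <- grepl("^mt-", rownames(counts), ignore.case = TRUE)
  mfrac <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) / pmax(umis, 1)
           else rep(NA_real_, ncol(counts))
  data.frame(cell = colnames(counts), n_umis = umis, n_genes = ngen,
             mito_fraction = mfrac, row.names = NULL)
}

#' Global droplet-level filtering
#'
#' Applies, in order: the gene pre-filter (genes detected in fewer than
#' `min_cells_per_gene` cells), the cell UMI pre-filter, then the three
#' global thresholds — mitochondrial fraction, detected-gene range
#' (inclusive), UMI ceiling. Per-cell statistics are computed once, after
#' the gene pre-filter; each removed cell is tagged with the first
#' criterion it violates.
#'
#' @param counts genes x cells count matrix.
#' @param th a [qc_thresholds()].
#' @return list: `counts` (filtered matrix), `report` — a list with
#'   `steps` (data.frame: step, n_removed, n_retained) and `removed_cells`
#'   (named character, cell -> reason code).
#' @export
global_filter <- function(counts, th = qc_thresholds()) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  steps <- list(); removed <- character(0)
  log_step <- function(step, n_removed, n_retained)
    steps[[length(steps) + 1L]] <<- data.frame(step = step,
                                               n_removed = n_removed,
                                               n_retained = n_retained)

  if (th$min_cells_per_gene > 0) {
    keep_g <- Matrix::rowSums(counts > 0) >= th$min_cells_per_gene
    counts <- counts[keep_g, , drop = FALSE]
    log_step("gene_min_cells", sum(!keep_g), ncol(counts))
  }
  stats <- cell_qc_stats(counts)
  no_mito <- all(is.na(stats$mito_fraction))
  if (no_mito) warning("no 'mt-' genes found; mitochondrial criterion skipped")

  reason <- rep(NA_character_, ncol(counts))
  flag <- function(cond, code) {
    cond[is.na(cond)] <- FALSE
    ifelse(is.na(reason) & cond, code, reason)
  }
  reason <- flag(stats$n_umis < th$min_cell_umis, "low_umi_prefilter")
  if (!no_mito)
    reason <- flag(stats$mito_fraction > th$max_mito_fraction, "high_mito")
  reason <- flag(stats$n_genes < th$min_genes, "low_genes")
  reason <- flag(stats$n_genes > th$max_genes, "high_genes")
  reason <- flag(stats$n_umis > th$max_umis, "high_umi")

  for (code in c("low_umi_prefilter", "high_mito", "low_genes",
                 "high_genes", "high_umi")) {
    n_rm <- sum(reason == code, na.rm = TRUE)
    log_step(code, n_rm, sum(is.na(reason)))
  }
  keep <- is.na(reason)
  removed <- stats::setNames(reason[!keep], stats$cell[!keep])
  list(counts = counts[, keep, drop = FALSE],
       report = list(steps = do.call(rbind, steps), removed_cells = removed))
}

#' Per-cluster UMI percentile trimming
#'
#' Within each cluster independently, removes cells whose UMI total is
#' strictly below the low-percentile value or strictly above the
#' high-percentile value of the cluster's UMI distribution. Percentiles use
#' linear interpolation between order statistics ([stats::quantile()] type
#' 7). Clusters with fewer than 3 cells are left untrimmed.
#'
#' @param umis_per_cell named numeric vector of per-cell UMI totals.
#' @param labels cluster labels, same length/order (or named).
#' @param trim (low, high) percentiles in (0, 100).
#' @return character vector of retained cell names, with attribute
#'   `skipped_clusters` listing untrimmed small clusters.
#' @export
cluster_percentile_trim <- function(umis_per_cell, labels, trim = c(1, 99)) {
  stopifnot(length(umis_per_cell) == length(labels),
            !is.null(names(umis_per_cell)))
  keep <- rep(TRUE, length(umis_per_cell))
  skipped <- character(0)
  for (cl in unique(labels)) {
    i <- which(labels == cl)
    if (length(i) < 3) { skipped <- c(skipped, as.character(cl)); next }
    q <- stats::quantile(umis_per_cell[i], trim / 100, type = 7, names = FALSE)
    keep[i] <- umis_per_cell[i] >= q[1] & umis_per_cell[i] <= q[2]
  }
  out <- names(umis_per_cell)[keep]
  attr(out, "skipped_clusters") <- skipped
  out
}

#' Artificial-doublet scoring parameters
#'
#' @param artificial_fraction fraction of the merged (real + artificial)
#'   dataset made of artificial doublets (pN-style; default 0.25).
#' @param k_neighbors neighborhood size for the pANN score.
#' @param n_pcs PCs for the embedding.
#' @param n_hvg variable genes for the embedding.
#' @param score_threshold `"auto"` (the `1 - expected_rate` score quantile)
#'   or a numeric cutoff.
#' @param expected_rate expected doublet rate used by the auto threshold.
#' @return object of class `doublet_params`.
#' @export
doublet_params <- function(artificial_fraction = 0.25, k_neighbors = 30,
                           n_pcs = 10, n_hvg = 1000,
                           score_threshold = "auto", expected_rate = 0.05) {
  .assert_scalar_num(artificial_fraction, "artificial_fraction", lo = 1e-9, hi = 0.9)
  .assert_scalar_num(k_neighbors, "k_neighbors", lo = 1, integer = TRUE)
  .assert_scalar_num(n_pcs, "n_pcs", lo = 2, integer = TRUE)
  structure(list(artificial_fraction = artificial_fraction,
                 k_neighbors = as.integer(k_neighbors),
                 n_pcs = as.integer(n_pcs), n_hvg = as.integer(n_hvg),
                 score_threshold = score_threshold,
                 expected_rate = expected_rate),
            class = "doublet_params")
}

#' pANN doublet scores
#'
#' Artificial doublets are formed by summing the raw counts of random
#' pairs of real cells; the merged dataset is log-CPM normalized, reduced
#' by PCA, and each real cell scored by the fraction of its k nearest
#' neighbors (proportion of artificial nearest neighbors, pANN) that are
#' artificial. Scores lie in [0, 1]; real doublets sit near artificial
#' doublets in the embedding and score high.
#'
#' @param counts genes x cells count matrix.
#' @param params a [doublet_params()].
#' @param seed integer seed for the artificial-doublet sampling.
#' @return named numeric score vector (one per real cell) with attribute
#'   `threshold` (the resolved score cutoff).
#' @export
doublet_scores <- function(counts, params = doublet_params(), seed = 1L) {
  stopifnot(inherits(params, "doublet_params"))
  n_real <- ncol(counts)
  if (params$k_neighbors >= n_real)
    stop("k_neighbors must be smaller than the number of cells", call. = FALSE)
  set.seed(seed)
  pN <- params$artificial_fraction
  n_art <- round(pN / (1 - pN) * n_real)
  p1 <- sample(n_real, n_art, replace = TRUE)
  p2 <- sample(n_real, n_art, replace = TRUE)
  x <- .as_dense(counts)
  art <- x[, p1, drop = FALSE] + x[, p2, drop = FALSE]
  colnames(art) <- sprintf("artificial%05d", seq_len(n_art))
  merged <- cbind(x, art)
  nh <- normalize_hvg(merged, normalize_config(method = "log_cpm",
                                               n_hvg = params$n_hvg))
  emb <- pca_embed(nh$normalized, params$n_pcs, genes = nh$hvg)$embedding
  d <- as.matrix(stats::dist(emb))
  k <- params$k_neighbors
  is_art <- c(rep(FALSE, n_real), rep(TRUE, n_art))
  score <- vapply(seq_len(n_real), function(i) {
    nn <- order(d[i, ])[2:(k + 1L)]       # nearest, excluding self
    mean(is_art[nn])
  }, numeric(1))
  names(score) <- colnames(counts)
  thr <- if (identical(params$score_threshold, "auto"))
    unname(stats::quantile(score, 1 - params$expected_rate, type = 7))
  else params$score_threshold
  attr(score, "threshold") <- thr
  score
}

#' Iterative marker-driven contaminant exclusion
#'
#' Each round: normalize and embed the current cells, cluster at the
#' round's resolutions, score every cluster against each exclusion
#' signature, drop clusters whose score exceeds the threshold, then
#' (optionally) percentile-trim UMIs within the surviving clusters and
#' continue with the remaining cells. The signature score of a cluster is
#' the mean over its cells of the cell-level signature expression
#' (mean normalized expression of the signature's genes), z-scored across
#' all cells; a cluster is dropped when that mean exceeds `z_threshold`
#' for any signature. (Scoring across cells rather than across cluster
#' means keeps the default threshold attainable when only a handful of
#' clusters exist.)
#'
#' @param counts genes x cells count matrix.
#' @param rounds_config list of rounds; each a list with `resolutions`
#'   (numeric vector) and optional `trim` (logical, default TRUE).
#' @param exclusion_signatures named list contaminant -> marker genes
#'   (e.g. epithelial Muc13, glial Sox10, myocyte Myh11).
#' @param seed integer seed.
#' @param z_threshold exclusion cutoff on the mean cell-level z score.
#' @param trim_percentiles (low, high) percentiles for the UMI trim.
#' @param n_hvg,n_pcs,k_neighbors embedding/graph parameters per round.
#' @return list: `counts` (refined matrix), `report` (data.frame per round
#'   and resolution: clusters found, cells excluded by signature, cells
#'   trimmed, cells remaining).
#' @export
iterative_refine <- function(counts, rounds_config, exclusion_signatures,
                             seed = 1L, z_threshold = 2,
                             trim_percentiles = c(1, 99), n_hvg = 1000,
                             n_pcs = 15, k_neighbors = 20) {
  stopifnot(is.list(rounds_config))
  report <- list()
  cur <- counts
  for (r in seq_along(rounds_config)) {
    rc <- rounds_config[[r]]
    res_v <- rc$resolutions %||% 1.0
    do_trim <- rc$trim %||% TRUE
    nh <- normalize_hvg(cur, normalize_config(method = "log_cpm", n_hvg = n_hvg))
    emb <- pca_embed(nh$normalized, n_pcs, genes = nh$hvg)$embedding

    # cell-level z score per signature
    sig_z <- lapply(exclusion_signatures, function(gs) {
      gs <- intersect(gs, rownames(nh$normalized))
      if (!length(gs)) return(rep(0, ncol(cur)))
      s <- colMeans(nh$normalized[gs, , drop = FALSE])
      if (stats::sd(s) == 0) rep(0, ncol(cur)) else (s - mean(s)) / stats::sd(s)
    })

    labels_last <- NULL
    excluded <- rep(FALSE, ncol(cur))
    n_clusters <- integer(0)
    for (j in seq_along(res_v)) {
      cfg <- graph_cluster_config(n_pcs = n_pcs, k_neighbors = k_neighbors,
                                  resolution = res_v[j],
                                  seed = .derive_seed(seed, r * 100 + j))
      lab <- snn_louvain(emb, cfg)
      labels_last <- lab
      n_clusters <- c(n_clusters, length(unique(lab)))
      for (z in sig_z) {
        cl_mean <- tapply(z, lab, mean)
        bad <- names(cl_mean)[cl_mean > z_threshold]
        excluded <- excluded | (as.character(lab) %in% bad)
      }
    }
    n_excl <- sum(excluded)
    keep <- !excluded
    if (!any(keep)) stop("iterative_refine removed all cells", call. = FALSE)

    n_trim <- 0L
    if (do_trim) {
      umis <- Matrix::colSums(cur[, keep, drop = FALSE])
      names(umis) <- colnames(cur)[keep]
      kept_names <- cluster_percentile_trim(umis, labels_last[keep],
                                            trim_percentiles)
      n_trim <- sum(keep) - length(kept_names)
      keep <- colnames(cur) %in% kept_names
    }
    if (!any(keep)) stop("iterative_refine removed all cells", call. = FALSE)
    cur <- cur[, keep, drop = FALSE]
    report[[r]] <- data.frame(round = r,
                              resolutions = paste(res_v, collapse = ","),
                              n_clusters = paste(n_clusters, collapse = ","),
                              n_excluded = n_excl, n_trimmed = n_trim,
                              n_remaining = ncol(cur))
  }
  list(counts = cur, report = do.call(rbind, report))
}
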