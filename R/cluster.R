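#' Default sex-linked genes excluded from variable-gene selection
#'
#' Xist/Tsix and the Y-linked genes drive sex-correlated structure in the
#' embedding; they are removed from the variable-gene set before PCA but
#' retained in the matrix for downstream analyses.
#' @export
SEX_GENES <- c("Xist", "Gm13305", "Tsix", "Gm8730", "Eif2s3y",
               "Ddx3y", "Uty", "Kdm5d")

#' Immediate-early genes optionally excluded from variable genes
#' @export
IEG_GENES <- c("Fos", "Jun", "Junb", "Egr1")

#' Normalization / variable-gene configuration
#'
#' @param method `"log_cpm"` (log1p of counts per 10k) or
#'   `"pearson_residual"` (analytic Pearson residuals of a negative
#'   binomial with fixed dispersion `theta`, clipped at `sqrt(n_cells)` —
#'   a closed-form variance-stabilization in the spirit of regularized NB
#'   regression).
#' @param n_hvg number of highly variable genes to keep.
#' @param exclude_genes genes barred from the HVG set (kept in the matrix);
#'   defaults to the sex-linked set.
#' @param theta fixed NB dispersion for Pearson residuals.
#' @return object of class `normalize_config`.
#' @export
normalize_config <- function(method = c("log_cpm", "pearson_residual"),
                             n_hvg = 3000, exclude_genes = SEX_GENES,
                             theta = 100) {
  method <- match.arg(method)
  .assert_scalar_num(n_hvg, "n_hvg", lo = 1, integer = TRUE)
  .assert_scalar_num(theta, "theta", lo = 1e-9)
  structure(list(method = method, n_hvg = as.integer(n_hvg),
                 exclude_genes = as.character(exclude_genes), theta = theta),
            class = "normalize_config")
}

#' Normalize counts and select highly variable genes
#'
#' `log_cpm`: \eqn{\log(1 + 10^4 x / \mathrm{libsize})}. `pearson_residual`:
#' \eqn{(x - \hat\mu)/\sqrt{\hat\mu + \hat\mu^2/\theta}} with
#' \eqn{\hat\mu_{gc} = \mathrm{libsize}_c \cdot \pi_g} (gene fraction of
#' total counts), clipped to \eqn{\pm\sqrt{n_\mathrm{cells}}}. HVGs are the
#' `n_hvg` genes of largest normalized variance, after removing
#' `exclude_genes` (the HVG count is preserved when enough genes remain).
#'
#' @param counts genes x cells count matrix (sparse or dense).
#' @param cfg a [normalize_config()].
#' @return list: `normalized` (dense genes x cells matrix), `hvg`
#'   (character vector), `libsize`.
#' @export
normalize_hvg <- function(counts, cfg = normalize_config()) {
  stopifnot(inherits(cfg, "normalize_config"))
  x <- .as_dense(counts)
  if (is.null(rownames(x))) stop("counts must have gene rownames", call. = FALSE)
  libsize <- colSums(x)
  if (any(libsize == 0)) stop("zero-libsize cell; run QC filtering first", call. = FALSE)
  norm <- if (cfg$method == "log_cpm") {
    log1p(sweep(x, 2, libsize, "/") * 1e4)
  } else {
    pi_g <- rowSums(x) / sum(x)
    mu <- outer(pi_g, libsize)
    r <- (x - mu) / sqrt(mu + mu^2 / cfg$theta)
    r[is.nan(r)] <- 0                        # genes with zero total counts
    clip <- sqrt(ncol(x))
    pmin(pmax(r, -clip), clip)
  }
  v <- apply(norm, 1L, stats::var)
  ord <- rownames(x)[order(v, decreasing = TRUE)]
  ord <- ord[v[order(v, decreasing = TRUE)] > 0]
  ord <- setdiff(ord, cfg$exclude_genes)
  if (!length(ord))   # fully degenerate input (e.g. identical cells)
    ord <- setdiff(rownames(x), cfg$exclude_genes)
  list(normalized = norm, hvg = utils::head(ord, cfg$n_hvg), libsize = libsize)
}

#' PCA embedding of cells
#'
#' Gene-centered PCA of the normalized expression of the given genes;
#' component columns are ordered by decreasing explained variance.
#'
#' @param normalized genes x cells matrix.
#' @param n_pcs number of components.
#' @param genes genes to use (e.g. the HVG list); default all rows.
#' @return list: `embedding` (cells x n_pcs), `loadings`
#'   (genes x n_pcs, orthonormal columns), `sdev`.
#' @export
pca_embed <- function(normalized, n_pcs = 30, genes = NULL) {
  .assert_scalar_num(n_pcs, "n_pcs", lo = 2, integer = TRUE)
  if (!is.null(genes)) normalized <- normalized[intersect(genes, rownames(normalized)), , drop = FALSE]
  X <- t(normalized)                               # cells x genes
  n_pcs <- min(n_pcs, ncol(X), nrow(X) - 1L)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_pcs)
  emb <- pc$x
  rownames(emb) <- colnames(normalized)
  list(embedding = emb, loadings = pc$rotation, sdev = pc$sdev[seq_len(n_pcs)])
}

#' Graph-clustering configuration
#'
#' @param n_pcs PCs used upstream (recorded for provenance).
#' @param k_neighbors neighbors for the kNN graph.
#' @param resolution Louvain resolution parameter.
#' @param seed integer seed fixing the Louvain traversal.
#' @param prune SNN edges with Jaccard weight below this are dropped.
#' @return object of class `graph_cluster_config`.
#' @export
graph_cluster_config <- function(n_pcs = 30, k_neighbors = 20,
                                 resolution = 1.0, seed = 1L, prune = 1 / 15) {
  .assert_scalar_num(k_neighbors, "k_neighbors", lo = 1, integer = TRUE)
  if (!(resolution > 0)) stop("resolution must be > 0", call. = FALSE)
  .assert_scalar_num(seed, "seed", integer = TRUE)
  structure(list(n_pcs = as.integer(n_pcs),
                 k_neighbors = as.integer(k_neighbors),
                 resolution = resolution, seed = as.integer(seed),
                 prune = prune),
            class = "graph_cluster_config")
}

#' SNN-graph Louvain clustering
#'
#' Builds a k-nearest-neighbor graph on Euclidean distance in PC space,
#' re-weights edges by the Jaccard overlap of the two cells' neighbor sets
#' (shared nearest neighbors; each set includes the cell itself), prunes
#' weak edges, and partitions with the Louvain algorithm at the requested
#' resolution. Community labels are 0..C-1 in decreasing community size.
#'
#' @param embedding cells x PCs matrix (rownames = cell ids).
#' @param cfg a [graph_cluster_config()].
#' @return named integer vector of cluster labels, with attributes
#'   `resolution` and `modularity`.
#' @export
snn_louvain <- function(embedding, cfg = graph_cluster_config()) {
  stopifnot(inherits(cfg, "graph_cluster_config"), is.matrix(embedding))
  n <- nrow(embedding); k <- cfg$k_neighbors
  if (k >= n) stop("k_neighbors must be smaller than the number of cells", call. = FALSE)
  d <- as.matrix(stats::dist(embedding))
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k + 1L)]))  # includes self
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k + 1L),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)                 # |N(i) ∩ N(j)|
  jac <- shared
  jac@x <- jac@x / (2 * (k + 1L) - jac@x)         # Jaccard with |sets| = k+1
  jac <- jac * (jac >= cfg$prune)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(Matrix::forceSymmetric(jac, uplo = "U"))
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE)
  set.seed(cfg$seed)
  comm <- igraph::cluster_louvain(g, resolution = cfg$resolution)
  memb <- igraph::membership(comm)
  sizes <- table(memb)
  new_id <- stats::setNames(seq_along(sizes) - 1L,
                            names(sort(sizes, decreasing = TRUE)))
  lab <- as.integer(new_id[as.character(memb)])
  names(lab) <- rownames(embedding)
  attr(lab, "resolution") <- cfg$resolution
  attr(lab, "modularity") <- max(igraph::modularity(comm))
  lab
}

#' One-vs-rest Wilcoxon marker table
#'
#' For each cluster, every gene is tested cluster-vs-rest with a two-sided
#' Wilcoxon rank-sum test on the normalized expression; p-values are
#' BH-adjusted across genes within the cluster, and genes ranked by
#' adjusted p then decreasing logFC, so p-ties break toward overexpressed
#' genes (the marker direction). logFC is the normalized-scale group mean
#' difference divided by log(2).
#'
#' @param normalized genes x cells matrix.
#' @param clusters named cluster labels covering the columns.
#' @param min_cells clusters smaller than this are skipped with a warning.
#' @return data.frame: cluster, gene, logFC, pct.in, pct.out, p, p_adj,
#'   rank (unique within cluster).
#' @export
de_markers <- function(normalized, clusters, min_cells = 2L) {
  stopifnot(ncol(normalized) == length(clusters))
  out <- list()
  for (cl in sort(unique(clusters))) {
    in_cl <- clusters == cl
    if (sum(in_cl) < min_cells) {
      warning(sprintf("cluster %s has < %d cells; skipped", cl, min_cells))
      next
    }
    xin <- normalized[, in_cl, drop = FALSE]
    xout <- normalized[, !in_cl, drop = FALSE]
    p <- vapply(seq_len(nrow(normalized)), function(g) {
      a <- xin[g, ]; b <- xout[g, ]
      if (all(a == a[1]) && all(b == a[1])) return(1)
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value
    }, numeric(1))
    lfc <- (rowMeans(xin) - rowMeans(xout)) / log(2)
    df <- data.frame(cluster = cl, gene = rownames(normalized),
                     logFC = lfc,
                     pct.in = rowMeans(xin > 0), pct.out = rowMeans(xout > 0),
                     p = p, p_adj = .bh_adjust(p), row.names = NULL)
    df$rank <- order(order(df$p_adj, -df$logFC))
    out[[as.character(cl)]] <- df[order(df$rank), ]
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Bundled marker-signature database
#'
#' Class -> marker-gene sets for the submucosal neuron classes and the
#' generic lineage states used for cluster annotation.
#' @return named list of character vectors.
#' @export
signature_db <- function() {
  list(smENC1 = c("Nmu", "Adgrg6"),
       smENC2 = c("Sst"),
       smENC3 = c("Vip", "Npy"),
       glia = c("Sox10", "Plp1"),
       SCP = c("Dhh", "Col14a1", "Gfra3"),
       neuroblast = c("Ascl1"),
       neuron = c("Elavl4"))
}

#' Annotate clusters against a signature database
#'
#' Signature score of a cluster = mean (over its cells and the signature's
#' genes) of gene-wise z-scaled normalized expression. A cluster is
#' assigned the top-scoring class when its score exceeds the runner-up by
#' at least `margin`; otherwise `"unassigned"`.
#'
#' @param normalized genes x cells matrix.
#' @param clusters named cluster labels over the columns.
#' @param db named list class -> marker genes (e.g. [signature_db()]).
#' @param margin minimum lead over the runner-up score.
#' @return data.frame: cluster, class, score, runner_up, runner_up_score.
#' @export
annotate_classes <- function(normalized, clusters, db = signature_db(),
                             margin = 0.1) {
  stopifnot(is.list(db), length(db) > 0)
  db_present <- lapply(db, intersect, rownames(normalized))
  if (all(lengths(db_present) == 0)) {
    warning("no signature genes present in the matrix; all clusters unassigned")
    cl <- sort(unique(clusters))
    return(data.frame(cluster = cl, class = "unassigned", score = NA_real_,
                      runner_up = NA_character_, runner_up_score = NA_real_))
  }
  z <- t(scale(t(normalized)))                    # z per gene across cells
  z[is.nan(z)] <- 0
  out <- list()
  for (cl in sort(unique(clusters))) {
    cells <- clusters == cl
    sc <- vapply(db_present, function(gs)
      if (!length(gs)) -Inf else mean(z[gs, cells, drop = FALSE]), numeric(1))
    ord <- order(sc, decreasing = TRUE)
    top <- names(sc)[ord[1]]; second <- names(sc)[ord[2]] %||% NA_character_
    assigned <- if (is.finite(sc[ord[1]]) &&
                    (length(sc) == 1 || sc[ord[1]] - sc[ord[2]] > margin))
      top else "unassigned"
    out[[as.character(cl)]] <-
      data.frame(cluster = cl, class = assigned, score = sc[ord[1]],
                 runner_up = second, runner_up_score = sc[ord[2]] %||% NA_real_,
                 row.names = NULL)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
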