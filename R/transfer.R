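#' Rule-based sex inference from Xist and Y-linked counts
#'
#' A cell is called female when it expresses Xist but no Y-linked gene,
#' male in the reverse case, `NA` when both evidence counts are zero, and
#' `ambiguous` when both are positive.
#'
#' @param counts genes x cells count matrix.
#' @param xist_gene name of the Xist gene row.
#' @param y_genes names of the Y-chromosome gene rows (absent names are
#'   ignored).
#' @return data.frame: cell, xist, y_sum, sex (`"F"`, `"M"`, `NA`,
#'   `"ambiguous"`).
#' @export
infer_sex <- function(counts, xist_gene = "Xist", y_genes = .Y_GENES) {
  if (!xist_gene %in% rownames(counts))
    stop(sprintf("gene '%s' not in matrix", xist_gene), call. = FALSE)
  y_genes <- intersect(y_genes, rownames(counts))
  xist <- as.numeric(counts[xist_gene, ])
  ysum <- if (length(y_genes))
    as.numeric(Matrix::colSums(counts[y_genes, , drop = FALSE]))
  else rep(0, ncol(counts))
  sex <- ifelse(xist > 0 & ysum == 0, "F",
         ifelse(xist == 0 & ysum > 0, "M",
         ifelse(xist == 0 & ysum == 0, NA_character_, "ambiguous")))
  data.frame(cell = colnames(counts), xist = xist, y_sum = ysum, sex = sex,
             row.names = NULL)
}

#' Joint PCA embedding of a reference and a query dataset
#'
#' Variable genes are selected per dataset, unioned, and intersected with
#' the genes shared by both matrices; PCA is fit on the concatenated
#' normalized data over that gene set. Optional batch alignment translates
#' the query so the two dataset centroids coincide in PC space (iterated
#' to convergence, at most `max_align_iter` passes) — the minimal defined
#' integration for datasets whose class structure is shared.
#'
#' @param ref_counts,query_counts genes x cells count matrices.
#' @param n_pcs number of components (e.g. 50).
#' @param norm_cfg a [normalize_config()] applied to both datasets.
#' @param align logical: perform centroid alignment.
#' @param max_align_iter cap on alignment passes.
#' @return list: `ref` and `query` (cell x PC matrices), `genes` (shared
#'   variable genes used), `loadings`.
#' @export
joint_embed <- function(ref_counts, query_counts, n_pcs = 50,
                        norm_cfg = normalize_config(), align = TRUE,
                        max_align_iter = 10L) {
  shared <- intersect(rownames(ref_counts), rownames(query_counts))
  if (length(shared) < 50)
    stop("fewer than 50 shared genes between reference and query", call. = FALSE)
  nr <- normalize_hvg(ref_counts, norm_cfg)
  nq <- normalize_hvg(query_counts, norm_cfg)
  genes <- intersect(union(nr$hvg, nq$hvg), shared)
  if (length(genes) < 2) stop("no shared variable genes", call. = FALSE)
  combined <- cbind(nr$normalized[genes, , drop = FALSE],
                    nq$normalized[genes, , drop = FALSE])
  pc <- pca_embed(combined, n_pcs, genes = genes)
  n_ref <- ncol(ref_counts)
  emb_r <- pc$embedding[seq_len(n_ref), , drop = FALSE]
  emb_q <- pc$embedding[-seq_len(n_ref), , drop = FALSE]
  if (align) {
    for (it in seq_len(max_align_iter)) {
      shift <- colMeans(emb_r) - colMeans(emb_q)
      emb_q <- sweep(emb_q, 2, shift, "+")
      if (sqrt(sum(shift^2)) < 1e-10) break
    }
  }
  list(ref = emb_r, query = emb_q, genes = genes, loadings = pc$loadings)
}

#' Masked label transfer by distance-weighted kNN
#'
#' Reference cells carrying a masked label are removed before the neighbor
#' search, so masked labels can never be predicted (the mechanism used to
#' keep transcriptionally similar reference classes out of competition).
#' Each query cell's label scores are the Gaussian-distance-weighted
#' fractions of its k reference neighbors per label (bandwidth = the
#' cell's median neighbor distance); the prediction is the argmax.
#'
#' @param ref_embedding,query_embedding cell x PC matrices on a shared
#'   basis (see [joint_embed()]).
#' @param ref_labels character labels for the reference cells.
#' @param mask labels to remove from the reference (must be a subset of
#'   the reference label set).
#' @param k neighbors (default 30).
#' @return list: `predicted` (named character per query cell), `scores`
#'   (query x label matrix; rows sum to 1, masked labels absent), `mask`.
#' @export
transfer_labels <- function(ref_embedding, query_embedding, ref_labels,
                            mask = character(0), k = 30) {
  stopifnot(nrow(ref_embedding) == length(ref_labels))
  ref_labels <- as.character(ref_labels)
  if (length(mask) && !all(mask %in% ref_labels))
    stop("mask contains labels absent from the reference", call. = FALSE)
  keep <- !(ref_labels %in% mask)
  if (!any(keep)) stop("mask removes all reference cells", call. = FALSE)
  ref_embedding <- ref_embedding[keep, , drop = FALSE]
  ref_labels <- ref_labels[keep]
  k <- min(k, nrow(ref_embedding))
  labs <- sort(unique(ref_labels))
  nq <- nrow(query_embedding)
  scores <- matrix(0, nq, length(labs), dimnames = list(rownames(query_embedding), labs))
  for (i in seq_len(nq)) {
    d <- sqrt(colSums((t(ref_embedding) - query_embedding[i, ])^2))
    nn <- order(d)[seq_len(k)]
    dn <- d[nn]
    h <- stats::median(dn)
    w <- if (h > 0) exp(-(dn / h)^2 / 2) else as.numeric(dn == 0)
    if (sum(w) == 0) w <- rep(1, k)
    for (j in seq_len(k))
      scores[i, ref_labels[nn[j]]] <- scores[i, ref_labels[nn[j]]] + w[j]
    scores[i, ] <- scores[i, ] / sum(scores[i, ])
  }
  predicted <- labs[max.col(scores, ties.method = "first")]
  names(predicted) <- rownames(query_embedding)
  list(predicted = predicted, scores = scores, mask = mask)
}
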