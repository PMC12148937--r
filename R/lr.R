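#' Truncated mean
#'
#' Drops `floor(n * trim)` values from each tail of the sorted vector and
#' averages the rest (per-tail trimming, the statistical convention).
#'
#' @param x numeric vector.
#' @param trim per-tail fraction in [0, 0.5).
#' @return the truncated mean.
#' @export
truncated_mean <- function(x, trim = 0.2) {
  if (!is.numeric(trim) || length(trim) != 1L || trim < 0 || trim >= 0.5)
    stop("trim must be in [0, 0.5)", call. = FALSE)
  x <- sort(as.numeric(x))
  k <- floor(length(x) * trim)
  if (2 * k >= length(x)) return(stats::median(x))
  mean(x[(k + 1):(length(x) - k)])
}

#' Bundled toy ligand-receptor database
#'
#' Ligand -> receptor(-subunit) records covering interactions relevant to
#' submucosal neuron classes and their epithelial targets (CGRP, somatostatin,
#' VIP, neurturin, FGF, neuromedin U, endothelin, substance P). Subunit
#' genes are semicolon-joined and aggregated by geometric mean when
#' scoring; the cofactor column is carried but not scored.
#'
#' @return data.frame: pathway, ligand, receptor, cofactor.
#' @export
lr_database <- function() {
  data.frame(
    pathway  = c("CALC", "SST", "VIP", "VIP", "NRTN", "FGF", "FGF",
                 "NMU", "EDN", "TAC"),
    ligand   = c("Calcb", "Sst", "Vip", "Vip", "Nrtn", "Fgf1", "Fgf1",
                 "Nmu", "Edn1", "Tac1"),
    receptor = c("Calcrl", "Sstr1", "Vipr2", "Vipr1", "Gfra2", "Fgfr2",
                 "Fgfr3", "Nmur1", "Ednrb", "Tacr1"),
    cofactor = "", stringsAsFactors = FALSE)
}

#' Ligand-receptor scoring parameters
#'
#' @param trim per-tail truncation fraction for group means (0.20 for
#'   neuron-neuron comparisons; 0.10 for neuron-epithelium, where small
#'   heterogeneous epithelial clusters would otherwise lose real signal).
#' @param min_frac_expressing minimum fraction of expressing cells for a
#'   ligand/receptor gene in its group; below it the gene's mean is set
#'   to 0 (0 disables).
#' @param n_permutations label permutations for the null (>= 1).
#' @param kh Hill constant of the saturating probability, on the
#'   normalized-expression scale.
#' @param seed integer seed for the permutations.
#' @return object of class `lr_params`.
#' @export
lr_params <- function(trim = 0.2, min_frac_expressing = 0,
                      n_permutations = 99, kh = 0.5, seed = 1L) {
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)", call. = FALSE)
  .assert_scalar_num(n_permutations, "n_permutations", lo = 1, integer = TRUE)
  .assert_scalar_num(kh, "kh", lo = 1e-12)
  structure(list(trim = trim, min_frac_expressing = min_frac_expressing,
                 n_permutations = as.integer(n_permutations), kh = kh,
                 seed = as.integer(seed)),
            class = "lr_params")
}

#' Overexpressed genes per group
#'
#' One-sided Wilcoxon (group vs rest, alternative greater) per gene with
#' BH adjustment across genes within the group; keeps genes with adjusted
#' p below `alpha` and positive normalized-scale fold change.
#'
#' @param normalized genes x cells non-negative expression matrix.
#' @param groups group labels over the columns.
#' @param alpha BH-adjusted significance cutoff.
#' @return named list group -> character vector of overexpressed genes.
#' @export
overexpressed_genes <- function(normalized, groups, alpha = 0.05) {
  groups <- as.character(groups)
  out <- list()
  for (g in sort(unique(groups))) {
    in_g <- groups == g
    if (!sum(in_g) || all(in_g)) stop("each group needs cells in and out of it",
                                      call. = FALSE)
    p <- vapply(seq_len(nrow(normalized)), function(i) {
      a <- normalized[i, in_g]; b <- normalized[i, !in_g]
      if (all(c(a, b) == a[1])) return(1)
      stats::wilcox.test(a, b, alternative = "greater", exact = FALSE,
                         correct = FALSE)$p.value
    }, numeric(1))
    lfc <- rowMeans(normalized[, in_g, drop = FALSE]) -
      rowMeans(normalized[, !in_g, drop = FALSE])
    out[[g]] <- rownames(normalized)[.bh_adjust(p) < alpha & lfc > 0]
  }
  out
}

# truncated means of the needed genes within each group; genes x groups
.group_trunc_means <- function(normalized, groups, genes, trim, min_frac) {
  glev <- sort(unique(groups))
  m <- matrix(0, length(genes), length(glev), dimnames = list(genes, glev))
  for (g in glev) {
    sub <- normalized[genes, groups == g, drop = FALSE]
    tm <- apply(sub, 1L, truncated_mean, trim = trim)
    if (min_frac > 0) tm[rowMeans(sub > 0) < min_frac] <- 0
    m[, g] <- tm
  }
  m
}

# assemble Hill probabilities for every sender x receiver x record from a
# genes x groups truncated-mean matrix
.assemble_probs <- function(tm, db, kh) {
  glev <- colnames(tm)
  geo <- function(genes, grp) exp(mean(log(tm[genes, grp])))
  rows <- list()
  for (r in seq_len(nrow(db))) {
    lg <- strsplit(db$ligand[r], ";")[[1]]
    rg <- strsplit(db$receptor[r], ";")[[1]]
    for (s in glev) for (v in glev) {
      L <- geo(lg, s); R <- geo(rg, v)
      lr <- L * R
      rows[[length(rows) + 1L]] <- data.frame(
        sender = s, receiver = v, pathway = db$pathway[r],
        ligand = db$ligand[r], receptor = db$receptor[r],
        prob = lr / (kh + lr))
    }
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Communication probability between cell groups
#'
#' For every ligand-receptor record and every ordered (sender, receiver)
#' group pair: L = geometric mean of the ligand genes' truncated means in
#' the sender, R = geometric mean of the receptor-subunit genes' truncated
#' means in the receiver, and probability = L*R / (kh + L*R) (Hill
#' saturation). The probability is 0 whenever the ligand or receptor
#' truncated mean is 0. Records referencing genes absent from the matrix
#' are skipped and listed in the `skipped` attribute.
#'
#' @param normalized genes x cells non-negative expression matrix (e.g.
#'   log-CPM); negative values are rejected.
#' @param groups group labels over columns.
#' @param db ligand-receptor records ([lr_database()] format).
#' @param params an [lr_params()].
#' @return data.frame: sender, receiver, pathway, ligand, receptor, prob.
#' @export
comm_probability <- function(normalized, groups, db = lr_database(),
                             params = lr_params()) {
  stopifnot(inherits(params, "lr_params"))
  if (any(normalized < 0))
    stop("normalized expression must be non-negative for LR scoring", call. = FALSE)
  need <- lapply(seq_len(nrow(db)), function(r)
    c(strsplit(db$ligand[r], ";")[[1]], strsplit(db$receptor[r], ";")[[1]]))
  ok <- vapply(need, function(g) all(g %in% rownames(normalized)), logical(1))
  skipped <- db[!ok, , drop = FALSE]
  db <- db[ok, , drop = FALSE]
  if (!nrow(db)) stop("no ligand-receptor record matches the matrix genes", call. = FALSE)
  genes <- unique(unlist(need[ok]))
  tm <- .group_trunc_means(normalized, as.character(groups), genes,
                           params$trim, params$min_frac_expressing)
  out <- .assemble_probs(tm, db, params$kh)
  attr(out, "skipped") <- skipped
  out
}

#' Permutation test for communication probabilities
#'
#' The null distribution reassigns group labels at random
#' `n_permutations` times and recomputes every probability;
#' p = (1 + #\{null >= observed\}) / (1 + n_permutations) (add-one
#' estimator, so p is never exactly zero). BH adjustment is applied within
#' each (sender, receiver) pair across records.
#'
#' @inheritParams comm_probability
#' @return the [comm_probability()] table with columns `p` and `p_adj`
#'   appended.
#' @export
permutation_test <- function(normalized, groups, db = lr_database(),
                             params = lr_params()) {
  groups <- as.character(groups)
  obs <- comm_probability(normalized, groups, db, params)
  db_used <- unique(obs[, c("pathway", "ligand", "receptor")])
  db_used$cofactor <- ""
  genes <- unique(unlist(strsplit(c(obs$ligand, obs$receptor), ";")))
  set.seed(params$seed)
  exceed <- numeric(nrow(obs))
  for (b in seq_len(params$n_permutations)) {
    gp <- sample(groups)
    tm <- .group_trunc_means(normalized, gp, genes, params$trim,
                             params$min_frac_expressing)
    null <- .assemble_probs(tm, db_used, params$kh)
    # .assemble_probs emits rows in a fixed record x sender x receiver
    # order; align to the observed table by key
    key <- function(d) paste(d$sender, d$receiver, d$pathway, d$ligand, d$receptor)
    null <- null[match(key(obs), key(null)), ]
    exceed <- exceed + (null$prob >= obs$prob)
  }
  obs$p <- (1 + exceed) / (1 + params$n_permutations)
  pair <- paste(obs$sender, obs$receiver)
  obs$p_adj <- NA_real_
  for (pr in unique(pair)) {
    i <- pair == pr
    obs$p_adj[i] <- .bh_adjust(obs$p[i])
  }
  obs
}
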