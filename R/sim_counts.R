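#' Configuration for the synthetic count-matrix generator
#'
#' Builds a validated configuration for [gen_counts()]. The generator emulates
#' a droplet scRNA-seq experiment on dissociated enteric-plexus cells:
#' negative-binomial counts with planted neuron classes and marker genes,
#' doublets formed by summing two parent cells, contaminating cells from a
#' distinct expression profile, per-cell mitochondrial fractions, and
#' sex-linked genes (Xist and four Y-chromosome genes) consistent with a
#' planted sex label.
#'
#' @param n_cells number of cells (columns).
#' @param n_genes number of genes (rows); must leave room for the reserved
#'   mitochondrial, sex and marker genes.
#' @param n_classes number of planted cell classes (>= 1).
#' @param markers_per_class number of marker genes elevated in each class.
#' @param marker_log2fc log2 fold elevation of marker genes in their class.
#' @param doublet_fraction fraction of cells that are doublets, in [0, 1].
#' @param contaminant_fraction fraction of cells drawn from the contaminant
#'   profile, in [0, 1].
#' @param mito_fraction_dist length-2 numeric (mean, sd) of the per-cell
#'   mitochondrial count fraction (clipped to [0, 0.8]).
#' @param libsize_lognormal length-2 numeric (mu, sigma) of the log-normal
#'   per-cell library size.
#' @param nb_dispersion negative-binomial dispersion phi (> 0), so that
#'   Var = mu + phi * mu^2.
#' @param sex_ratio fraction of cells labelled female, in [0, 1].
#' @param seed integer seed; identical configurations give identical output.
#' @param class_marker_names optional list (length `n_classes`) of character
#'   vectors renaming the first markers of each class (e.g. real marker
#'   symbols such as Nmu or Vip so annotation against a signature database
#'   can be exercised).
#'
#' @return an object of class `sim_counts_config`.
#' @export
sim_counts_config <- function(n_cells = 1000, n_genes = 2000, n_classes = 3,
                              markers_per_class = 10, marker_log2fc = 2,
                              doublet_fraction = 0, contaminant_fraction = 0,
                              mito_fraction_dist = c(0.05, 0.02),
                              libsize_lognormal = c(log(5000), 0.3),
                              nb_dispersion = 0.1, sex_ratio = 0.5,
                              seed = 1L, class_marker_names = NULL) {
  .assert_scalar_num(n_cells, "n_cells", lo = 2, integer = TRUE)
  .assert_scalar_num(n_genes, "n_genes", lo = 50, integer = TRUE)
  .assert_scalar_num(n_classes, "n_classes", lo = 1, integer = TRUE)
  .assert_scalar_num(markers_per_class, "markers_per_class", lo = 1, integer = TRUE)
  .assert_scalar_num(marker_log2fc, "marker_log2fc", lo = 0)
  .assert_scalar_num(doublet_fraction, "doublet_fraction", lo = 0, hi = 1)
  .assert_scalar_num(contaminant_fraction, "contaminant_fraction", lo = 0, hi = 1)
  if (doublet_fraction + contaminant_fraction >= 1)
    stop("doublet_fraction + contaminant_fraction must be < 1", call. = FALSE)
  if (length(mito_fraction_dist) != 2L || any(!is.finite(mito_fraction_dist)))
    stop("mito_fraction_dist must be finite (mean, sd)", call. = FALSE)
  if (length(libsize_lognormal) != 2L || any(!is.finite(libsize_lognormal)))
    stop("libsize_lognormal must be finite (mu, sigma)", call. = FALSE)
  .assert_scalar_num(nb_dispersion, "nb_dispersion", lo = 1e-8)
  .assert_scalar_num(sex_ratio, "sex_ratio", lo = 0, hi = 1)
  .assert_scalar_num(seed, "seed", integer = TRUE)
  n_reserved <- 10L + 5L + n_classes * markers_per_class + markers_per_class
  if (n_genes < n_reserved + 10L)
    stop(sprintf("n_genes too small: need at least %d for reserved genes", n_reserved + 10L),
         call. = FALSE)
  if (!is.null(class_marker_names)) {
    stopifnot(is.list(class_marker_names), length(class_marker_names) == n_classes)
    if (any(lengths(class_marker_names) > markers_per_class))
      stop("class_marker_names entries longer than markers_per_class", call. = FALSE)
  }
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_classes = as.integer(n_classes),
                 markers_per_class = as.integer(markers_per_class),
                 marker_log2fc = marker_log2fc,
                 doublet_fraction = doublet_fraction,
                 contaminant_fraction = contaminant_fraction,
                 mito_fraction_dist = as.numeric(mito_fraction_dist),
                 libsize_lognormal = as.numeric(libsize_lognormal),
                 nb_dispersion = nb_dispersion, sex_ratio = sex_ratio,
                 seed = as.integer(seed),
                 class_marker_names = class_marker_names),
            class = "sim_counts_config")
}

.MITO_GENES <- paste0("mt-", c("Nd1", "Nd2", "Co1", "Co2", "Co3",
                               "Atp6", "Cytb", "Nd4", "Nd5", "Rnr1"))
.Y_GENES <- c("Ddx3y", "Uty", "Kdm5d", "Eif2s3y")

#' Generate a synthetic count matrix with ground truth
#'
#' Draws a genes x cells negative-binomial count matrix in which each singlet
#' cell belongs to one of `n_classes` planted classes whose marker genes are
#' elevated `2^marker_log2fc`-fold; doublets are the summed counts of two
#' random singlet parents down-sampled to 0.8x the summed library (doublets
#' have elevated but not doubled depth); contaminants come from an unrelated
#' expression profile carrying their own markers. Mitochondrial genes carry
#' an `mt-` prefix and are rescaled to a drawn per-cell mitochondrial
#' fraction. Females express Xist and no Y-linked genes; males the reverse.
#'
#' @param config a [sim_counts_config()].
#' @return list with elements `counts` (a `dgCMatrix`, genes x cells) and
#'   `truth`, itself a list: `class_of_cell` (named character; class labels,
#'   `"doublet"` or `"contaminant"`), `sex_of_cell` (named, `"F"`/`"M"`),
#'   and `marker_genes` (class -> character vector, including an entry for
#'   the contaminant profile).
#' @export
#' @examples
#' sim <- gen_counts(sim_counts_config(n_cells = 100, n_genes = 300, seed = 7))
#' dim(sim$counts)
#' table(sim$truth$class_of_cell)
gen_counts <- function(config) {
  stopifnot(inherits(config, "sim_counts_config"))
  set.seed(config$seed)
  ng <- config$n_genes; nc <- config$n_cells; K <- config$n_classes
  m <- config$markers_per_class

  # gene namespace: mito + sex + class markers + contaminant markers + filler
  marker_names <- lapply(seq_len(K), function(k)
    sprintf("MarkerC%d.%d", k, seq_len(m)))
  if (!is.null(config$class_marker_names)) {
    for (k in seq_len(K)) {
      nm <- config$class_marker_names[[k]]
      if (length(nm)) marker_names[[k]][seq_along(nm)] <- nm
    }
  }
  contam_markers <- sprintf("ContamMarker.%d", seq_len(m))
  special <- c(.MITO_GENES, "Xist", .Y_GENES, unlist(marker_names), contam_markers)
  filler <- sprintf("Gene%05d", seq_len(ng - length(special)))
  genes <- c(special, filler)
  stopifnot(length(genes) == ng, !anyDuplicated(genes))

  # per-cell truth labels
  n_doub <- round(config$doublet_fraction * nc)
  n_cont <- round(config$contaminant_fraction * nc)
  n_sing <- nc - n_doub - n_cont
  if (n_sing < 2) stop("too few singlet cells under the requested fractions", call. = FALSE)
  slots <- sample(rep(c("singlet", "doublet", "contaminant"),
                      c(n_sing, n_doub, n_cont)))
  class_lab <- character(nc)
  class_lab[slots == "singlet"] <- paste0("class", sample(K, n_sing, replace = TRUE))
  class_lab[slots == "doublet"] <- "doublet"
  class_lab[slots == "contaminant"] <- "contaminant"

  sex <- ifelse(stats::runif(nc) < config$sex_ratio, "F", "M")
  libsize <- stats::rlnorm(nc, config$libsize_lognormal[1], config$libsize_lognormal[2])

  # baseline relative abundances; contaminants use a shuffled, re-marked profile
  base_p <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)
  names(base_p) <- genes
  base_p[.Y_GENES] <- 0; base_p["Xist"] <- 0   # sex genes imposed afterwards
  base_p[contam_markers] <- base_p[contam_markers] * 0.02  # near-silent outside contaminants
  fold <- 2^config$marker_log2fc
  class_p <- vapply(seq_len(K), function(k) {
    p <- base_p
    p[marker_names[[k]]] <- p[marker_names[[k]]] * fold
    p / sum(p)
  }, numeric(ng))
  cont_p <- base_p[sample(ng)]
  names(cont_p) <- genes
  cont_p[c("Xist", .Y_GENES)] <- 0
  cont_p[unlist(marker_names)] <- cont_p[unlist(marker_names)] * 0.02
  cont_p[contam_markers] <- mean(base_p) * fold
  cont_p <- cont_p / sum(cont_p)

  size <- 1 / config$nb_dispersion
  draw_cell <- function(p, ls) stats::rnbinom(ng, mu = ls * p, size = size)

  counts <- matrix(0L, nrow = ng, ncol = nc, dimnames = list(genes, NULL))
  sing_idx <- which(slots == "singlet")
  for (i in sing_idx) {
    k <- as.integer(sub("class", "", class_lab[i]))
    counts[, i] <- draw_cell(class_p[, k], libsize[i])
  }
  for (i in which(slots == "contaminant"))
    counts[, i] <- draw_cell(cont_p, libsize[i])

  # doublets: sum of two singlet parents, thinned to 0.8x the summed library
  for (i in which(slots == "doublet")) {
    par <- sample(sing_idx, 2L)
    summed <- counts[, par[1]] + counts[, par[2]]
    counts[, i] <- stats::rbinom(ng, size = summed, prob = 0.8)
    sex[i] <- sex[par[1]]
  }

  # impose the drawn mitochondrial fraction by rescaling mt- genes
  mito_idx <- match(.MITO_GENES, genes)
  mito_w <- base_p[.MITO_GENES] / sum(base_p[.MITO_GENES])
  f <- pmin(pmax(stats::rnorm(nc, config$mito_fraction_dist[1],
                              config$mito_fraction_dist[2]), 0), 0.8)
  for (i in seq_len(nc)) {
    non_mito <- sum(counts[, i]) - sum(counts[mito_idx, i])
    target <- round(f[i] * non_mito / (1 - f[i]))
    counts[mito_idx, i] <- as.integer(stats::rmultinom(1, target, mito_w))
  }

  # sex-linked counts consistent with the planted label
  is_f <- sex == "F"
  counts["Xist", ] <- ifelse(is_f, stats::rpois(nc, 5), 0L)
  for (g in .Y_GENES)
    counts[g, ] <- ifelse(is_f, 0L, stats::rpois(nc, 1.5))

  cells <- sprintf("cell%05d", seq_len(nc))
  colnames(counts) <- cells
  names(class_lab) <- names(sex) <- cells
  markers <- stats::setNames(marker_names, paste0("class", seq_len(K)))
  markers$contaminant <- contam_markers

  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
       truth = list(class_of_cell = class_lab, sex_of_cell = sex,
                    marker_genes = markers))
}
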