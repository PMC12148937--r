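# normalization/HVG selection, PCA, SNN-Louvain, marker ranking, annotation

test_that("log-CPM normalization follows the closed form", {
  m <- matrix(0L, 3, 2, dimnames = list(c("a", "b", "c"), c("x", "y")))
  m[, 1] <- c(1L, 4999L, 5000L)   # libsize 10^4
  m[, 2] <- c(10L, 100L, 890L)    # libsize 10^3
  nh <- normalize_hvg(m, normalize_config(method = "log_cpm", n_hvg = 3))
  expect_equal(nh$normalized["a", "x"], log1p(1), tolerance = 1e-12)
  expect_equal(nh$normalized["a", "y"], log1p(100), tolerance = 1e-12)
  expect_error(normalize_hvg(cbind(m, z = c(0L, 0L, 0L)),
                             normalize_config(method = "log_cpm")),
               "libsize")
})

test_that("HVG selection honors exclusion lists and keeps the requested count", {
  sim <- small_sim(seed = 3)
  nh0 <- normalize_hvg(sim$counts, normalize_config(method = "log_cpm",
                                                    n_hvg = 100,
                                                    exclude_genes = character(0)))
  top_gene <- nh0$hvg[1]
  nh1 <- normalize_hvg(sim$counts,
                       normalize_config(method = "log_cpm", n_hvg = 100,
                                        exclude_genes = top_gene))
  expect_false(top_gene %in% nh1$hvg)
  expect_length(nh1$hvg, 100L)
  # excluded genes stay in the normalized matrix
  expect_true(top_gene %in% rownames(nh1$normalized))
})

test_that("Pearson residuals are clipped, zero for constant-fraction genes", {
  sim <- small_sim(seed = 4, n_cells = 100)
  nh <- normalize_hvg(sim$counts, normalize_config(method = "pearson_residual",
                                                   n_hvg = 50))
  expect_true(all(abs(nh$normalized) <= sqrt(100) + 1e-9))
  # a gene with zero counts everywhere has residual variance 0, never an HVG
  m <- as.matrix(sim$counts)
  m["Gene00001", ] <- 0L
  nh2 <- normalize_hvg(m, normalize_config(method = "pearson_residual",
                                           n_hvg = nrow(m)))
  expect_false("Gene00001" %in% nh2$hvg)
})

test_that("PCA embedding matches a direct eigendecomposition", {
  set.seed(8)
  m <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("c", 1:10)))
  pc <- pca_embed(m, n_pcs = 5)
  # orthonormal loadings
  expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # captured variance cannot exceed total variance
  X <- scale(t(m), center = TRUE, scale = FALSE)
  expect_lte(sum(pc$sdev^2), sum(apply(X, 2, var)) + 1e-10)
  # eigendecomposition oracle: same component variances, same subspace
  ev <- eigen(cov(X))
  expect_equal(pc$sdev^2, ev$values[1:5], tolerance = 1e-10)
  for (j in 1:5)
    expect_equal(abs(sum(pc$loadings[, j] * ev$vectors[, j])), 1,
                 tolerance = 1e-8)
})

test_that("SNN-Louvain separates well-separated blobs and respects limits", {
  set.seed(10)
  emb <- rbind(matrix(rnorm(200 * 5), 200, 5),
               matrix(rnorm(200 * 5, mean = 10), 200, 5))
  rownames(emb) <- sprintf("c%03d", 1:400)
  truth <- rep(1:2, each = 200)
  for (s in 1:3) {
    lab <- snn_louvain(emb, graph_cluster_config(k_neighbors = 15,
                                                 resolution = 0.5, seed = s))
    expect_equal(length(unique(lab)), 2L)
    expect_equal(ari(lab, truth), 1)
  }
  # a single cloud at vanishing resolution is one community
  one <- emb[1:200, ]
  lab1 <- snn_louvain(one, graph_cluster_config(k_neighbors = 15,
                                                resolution = 1e-4, seed = 1))
  expect_equal(length(unique(lab1)), 1L)
  expect_error(snn_louvain(one[1:10, ], graph_cluster_config(k_neighbors = 15)),
               "k_neighbors")
})

test_that("cluster labels are invariant to cell order at fixed seed", {
  sim <- small_sim(seed = 15, n_cells = 200)
  nh <- normalize_hvg(sim$counts, normalize_config(method = "log_cpm", n_hvg = 200))
  emb <- pca_embed(nh$normalized, 10, genes = nh$hvg)$embedding
  cfg <- graph_cluster_config(k_neighbors = 15, resolution = 0.3, seed = 4)
  lab <- snn_louvain(emb, cfg)
  perm <- sample(nrow(emb))
  lab_p <- snn_louvain(emb[perm, ], cfg)
  expect_equal(ari(lab[rownames(emb)[perm]], lab_p), 1)
})

test_that("community count grows weakly with resolution", {
  sim <- small_sim(seed = 16, n_cells = 300)
  nh <- normalize_hvg(sim$counts, normalize_config(method = "log_cpm", n_hvg = 200))
  emb <- pca_embed(nh$normalized, 10, genes = nh$hvg)$embedding
  n_lo <- length(unique(snn_louvain(emb, graph_cluster_config(
    k_neighbors = 15, resolution = 0.04, seed = 2))))
  n_hi <- length(unique(snn_louvain(emb, graph_cluster_config(
    k_neighbors = 15, resolution = 0.4, seed = 2))))
  expect_lte(n_lo, n_hi)
})

test_that("marker tables rank planted markers first and match the rank-sum oracle", {
  sim <- gen_counts(sim_counts_config(n_cells = 200, n_genes = 300,
                                      n_classes = 2, markers_per_class = 5,
                                      marker_log2fc = 3, seed = 19))
  nh <- normalize_hvg(sim$counts, normalize_config(method = "log_cpm", n_hvg = 300))
  cls <- sim$truth$class_of_cell
  mk <- de_markers(nh$normalized, cls)
  top1 <- mk$gene[mk$cluster == "class1" & mk$rank == 1]
  expect_true(top1 %in% sim$truth$marker_genes$class1)
  expect_true(all(mk$p_adj >= mk$p))
  expect_false(any(duplicated(mk[mk$cluster == "class1", "rank"])))
  # oracle: pair-counting U statistic + tie-corrected normal approximation
  g <- sim$truth$marker_genes$class1[1]
  a <- nh$normalized[g, cls == "class1"][1:25]
  b <- nh$normalized[g, cls == "class2"][1:25]
  mk_small <- de_markers(nh$normalized[, c(names(a), names(b))],
                         rep(c("A", "B"), c(25, 25)))
  ours <- mk_small$p[mk_small$cluster == "A" & mk_small$gene == g]
  expect_equal(ours, oracle_wilcox_p(a, b), tolerance = 1e-10)
})

test_that("marker test keeps its size under the null", {
  set.seed(77)
  n_rej <- replicate(40, {
    m <- matrix(rpois(50 * 40, 5), 50, 40,
                dimnames = list(paste0("g", 1:50), paste0("c", 1:40)))
    cl <- rep(c("a", "b"), each = 20)
    mk <- de_markers(log1p(m), cl)
    mean(mk$p_adj[mk$cluster == "a"] < 0.05)
  })
  expect_lte(mean(n_rej), 0.06)
})

test_that("tiny clusters are skipped with a warning", {
  m <- matrix(rpois(30 * 10, 5), 30, 10,
              dimnames = list(paste0("g", 1:30), paste0("c", 1:10)))
  expect_warning(mk <- de_markers(log1p(m), c(rep("a", 9), "b")), "skipped")
  expect_false("b" %in% mk$cluster)
})

test_that("signature annotation maps planted classes to their names", {
  sim <- gen_counts(sim_counts_config(
    n_cells = 300, n_genes = 400, n_classes = 3, markers_per_class = 4,
    marker_log2fc = 3, seed = 25,
    class_marker_names = list(c("Nmu", "Adgrg6"), c("Sst"), c("Vip", "Npy"))))
  nh <- normalize_hvg(sim$counts, normalize_config(method = "log_cpm", n_hvg = 300))
  cls <- sim$truth$class_of_cell
  db <- signature_db()[c("smENC1", "smENC2", "smENC3")]
  ann <- annotate_classes(nh$normalized, cls, db)
  expect_equal(ann$class[ann$cluster == "class1"], "smENC1")
  expect_equal(ann$class[ann$cluster == "class2"], "smENC2")
  expect_equal(ann$class[ann$cluster == "class3"], "smENC3")
  # no overlap between signatures and genes: unassigned with a warning
  expect_warning(
    ann0 <- annotate_classes(nh$normalized, cls,
                             list(x = "NotAGene", y = "AlsoMissing")),
    "no signature genes")
  expect_true(all(ann0$class == "unassigned"))
  # exact tie between duplicated signatures: unassigned
  ann_tie <- annotate_classes(nh$normalized, cls,
                              list(s1 = c("Nmu", "Adgrg6"),
                                   s2 = c("Nmu", "Adgrg6")))
  expect_true(all(ann_tie$class == "unassigned"))
})
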