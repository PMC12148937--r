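# global thresholds, per-cluster percentile trimming, doublet scoring,
# iterative contaminant exclusion

# toy matrix: one cell per violated criterion + two clean cells
make_toy_qc <- function() {
  ng <- 8000
  genes <- c(paste0("mt-", 1:10), sprintf("g%04d", seq_len(ng - 10)))
  m <- matrix(0L, ng, 6, dimnames = list(genes, paste0("c", 1:6)))
  fill <- function(n_genes_on, umis, mito_frac = 0.01) {
    x <- integer(ng)
    on <- sample(11:ng, n_genes_on - 10)
    mito_umis <- round(umis * mito_frac)
    x[on] <- as.integer(stats::rmultinom(1, umis - mito_umis,
                                         rep(1, length(on))))
    x[1:10] <- as.integer(stats::rmultinom(1, mito_umis, rep(1, 10)))
    x
  }
  set.seed(99)
  m[, 1] <- fill(2000, 8000, mito_frac = 0.30)  # high mito
  m[, 2] <- fill(400, 8000)                      # too few genes
  m[, 3] <- fill(7000, 30000)                    # too many genes
  m[, 4] <- fill(3000, 45000)                    # too many UMIs
  m[, 5] <- fill(2000, 8000)                     # clean
  m[, 6] <- fill(2500, 9000)                     # clean
  m
}

test_that("global_filter removes exactly the cells violating each criterion", {
  m <- make_toy_qc()
  th <- qc_thresholds(max_mito_fraction = 0.2, min_genes = 500,
                      max_genes = 6500, max_umis = 40000,
                      min_cell_umis = 0, min_cells_per_gene = 0)
  gf <- global_filter(m, th)
  expect_equal(colnames(gf$counts), c("c5", "c6"))
  expect_equal(length(gf$report$removed_cells), 4L)
  expect_equal(unname(gf$report$removed_cells[c("c1", "c2", "c3", "c4")]),
               c("high_mito", "low_genes", "high_genes", "high_umi"))
  # retained + removed equals input at every step
  expect_true(all(gf$report$steps$n_removed + gf$report$steps$n_retained <= 6))
})

test_that("permissive thresholds are the identity and filtering is idempotent", {
  sim <- small_sim(seed = 7)
  th_id <- qc_thresholds(max_mito_fraction = 1, min_genes = 0, max_genes = 1e9,
                         max_umis = Inf, min_cell_umis = 0, min_cells_per_gene = 0)
  gf <- global_filter(sim$counts, th_id)
  expect_identical(dim(gf$counts), dim(sim$counts))
  # idempotence at the defaults used downstream
  th <- qc_thresholds(max_mito_fraction = 0.2, min_genes = 50, max_genes = 6500,
                      max_umis = 40000)
  once <- global_filter(sim$counts, th)
  twice <- global_filter(once$counts, th)
  expect_identical(dim(twice$counts), dim(once$counts))
  expect_length(twice$report$removed_cells, 0L)
})

test_that("missing mitochondrial genes skip the criterion with a warning", {
  m <- matrix(rpois(200 * 20, 5), 200, 20,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%02d", 1:20)))
  expect_warning(gf <- global_filter(m, qc_thresholds(min_genes = 0,
                                                      min_cell_umis = 0,
                                                      min_cells_per_gene = 0)),
                 "mitochondrial")
  expect_equal(ncol(gf$counts), 20L)
})

test_that("percentile trim matches the interpolated-percentile convention", {
  u <- stats::setNames(as.numeric(1:100), paste0("c", 1:100))
  kept <- cluster_percentile_trim(u, rep(1, 100), trim = c(1, 99))
  # type-7 percentiles of 1..100 at (1, 99)% are 1.99 and 99.01
  expect_setequal(setdiff(names(u), kept), c("c1", "c100"))
  # all-equal UMIs: nothing trimmed
  u2 <- stats::setNames(rep(500, 50), paste0("d", 1:50))
  expect_length(cluster_percentile_trim(u2, rep(1, 50)), 50L)
})

test_that("trimming acts within clusters independently and matches brute force", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(50:300, 1)
    u <- stats::setNames(round(stats::rlnorm(n, 8, 0.6)), sprintf("c%04d", 1:n))
    lab <- sample(1:4, n, replace = TRUE)
    kept <- cluster_percentile_trim(u, lab, trim = c(1, 99))
    # brute-force oracle: per-cluster sort + interpolated cutoffs
    oracle <- unlist(lapply(unique(lab), function(cl) {
      x <- u[lab == cl]
      if (length(x) < 3) return(names(x))
      s <- sort(x)
      interp <- function(p) {
        h <- (length(s) - 1) * p + 1
        lo <- floor(h)
        s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
      }
      names(x)[x >= interp(0.01) & x <= interp(0.99)]
    }))
    expect_setequal(kept, oracle)
  }
  # disjoint clusters never affect each other
  u <- stats::setNames(c(1:20, 1001:1020), paste0("c", 1:40))
  lab <- rep(1:2, each = 20)
  kept <- cluster_percentile_trim(u, lab)
  expect_true(all(paste0("c", c(2:19, 22:39)) %in% kept))
})

test_that("doublet scores are bounded, symmetric for identical cells, and ordered by truth", {
  sim <- small_sim(seed = 13, n_cells = 400, doublet_fraction = 0.1)
  sc <- doublet_scores(sim$counts, doublet_params(k_neighbors = 20, n_pcs = 10),
                       seed = 2)
  expect_true(all(sc >= 0 & sc <= 1))
  is_doub <- sim$truth$class_of_cell[names(sc)] == "doublet"
  expect_gt(auroc(sc, is_doub), 0.85)
  # identical cells: every score identical
  m <- matrix(5L, 100, 60, dimnames = list(sprintf("g%03d", 1:100),
                                           sprintf("c%02d", 1:60)))
  sc2 <- doublet_scores(m, doublet_params(k_neighbors = 10, n_pcs = 2,
                                          n_hvg = 50), seed = 1)
  expect_equal(length(unique(sc2)), 1L)
  expect_error(doublet_scores(m[, 1:5], doublet_params(k_neighbors = 30)),
               "k_neighbors")
})

test_that("doublet scoring is invariant to gene and cell order", {
  sim <- small_sim(seed = 17, n_cells = 150, doublet_fraction = 0.1)
  sc <- doublet_scores(sim$counts, doublet_params(k_neighbors = 10), seed = 5)
  g_perm <- sample(nrow(sim$counts))
  sc_g <- doublet_scores(sim$counts[g_perm, ], doublet_params(k_neighbors = 10),
                         seed = 5)
  expect_equal(sc, sc_g)
})

test_that("iterative_refine with no signatures and no trimming is the identity", {
  sim <- small_sim(seed = 23, n_cells = 200)
  out <- iterative_refine(sim$counts,
                          rounds_config = list(list(resolutions = 0.5,
                                                    trim = FALSE)),
                          exclusion_signatures = list(), seed = 1)
  expect_identical(dim(out$counts), dim(sim$counts))
  expect_equal(nrow(out$report), 1L)
})

test_that("iterative_refine removes planted contaminants and keeps true cells", {
  sim <- small_sim(seed = 29, n_cells = 600, n_genes = 600,
                   contaminant_fraction = 0.15)
  out <- iterative_refine(
    sim$counts,
    rounds_config = list(list(resolutions = c(0.6, 1.8), trim = FALSE),
                         list(resolutions = c(0.6, 1.8), trim = FALSE)),
    exclusion_signatures = list(contaminant = sim$truth$marker_genes$contaminant),
    seed = 3)
  cls <- sim$truth$class_of_cell
  cont <- names(cls)[cls == "contaminant"]
  true_cells <- names(cls)[cls != "contaminant"]
  removed_cont <- mean(!(cont %in% colnames(out$counts)))
  lost_true <- mean(!(true_cells %in% colnames(out$counts)))
  expect_gte(removed_cont, 0.95)
  expect_lte(lost_true, 0.02)
  expect_equal(nrow(out$report), 2L)
  expect_error(iterative_refine(sim$counts,
                                list(list(resolutions = 0.5)),
                                exclusion_signatures =
                                  list(x = rownames(sim$counts)[20]),
                                z_threshold = -10, seed = 1),
               "all cells")
})
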