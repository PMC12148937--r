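# shared fixtures and independent oracles for the test suite

# AUROC via the rank-sum identity: P(score_pos > score_neg) + 0.5 P(tie)
auroc <- function(score, is_pos) {
  stopifnot(length(score) == length(is_pos))
  r <- rank(score)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# adjusted Rand index from the pair-counting closed form
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# small default simulation reused across tests
small_sim <- function(seed = 42, n_cells = 300, n_genes = 400, ...) {
  gen_counts(sim_counts_config(n_cells = n_cells, n_genes = n_genes,
                               n_classes = 3, markers_per_class = 10,
                               marker_log2fc = 2, seed = seed, ...))
}

# two-group expression matrix carrying ligand-receptor genes, for LR tests:
# group A overexpresses the ligands, group B the receptors
lr_fixture <- function(n_per_group = 30, seed = 1) {
  set.seed(seed)
  db <- lr_database()
  genes <- unique(unlist(strsplit(c(db$ligand, db$receptor), ";")))
  filler <- sprintf("Filler%02d", 1:20)
  all_genes <- c(genes, filler)
  n <- 2 * n_per_group
  m <- matrix(stats::rlnorm(length(all_genes) * n, 0, 0.3),
              nrow = length(all_genes), dimnames = list(all_genes, NULL))
  groups <- rep(c("A", "B"), each = n_per_group)
  lig <- unique(unlist(strsplit(db$ligand, ";")))
  rec <- unique(unlist(strsplit(db$receptor, ";")))
  m[lig, groups == "A"] <- m[lig, groups == "A"] + 3
  m[rec, groups == "B"] <- m[rec, groups == "B"] + 3
  colnames(m) <- sprintf("c%03d", seq_len(n))
  list(normalized = m, groups = groups, db = db)
}

# independent two-sided Wilcoxon rank-sum: U by explicit pair counting,
# normal approximation with tie correction, no continuity correction
oracle_wilcox_p <- function(a, b) {
  U <- 0
  for (x in a) U <- U + sum(x > b) + 0.5 * sum(x == b)
  m <- length(a); n <- length(b); N <- m + n
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / ((N) * (N - 1))
  v <- m * n / 12 * ((N + 1) - tie_term)
  if (v == 0) return(1)
  z <- (U - m * n / 2) / sqrt(v)
  2 * stats::pnorm(-abs(z))
}

# step-up BH closed form, independent of stats::p.adjust
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- prev
  }
  adj
}
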