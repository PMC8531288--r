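test_that("rank-sum test matches enumeration on canonical small cases", {
  m <- as_counts(matrix(c(1, 2, 3, 4), 1, 4), genes = "g",
                 cells = c("a1", "a2", "b1", "b2"))
  de <- wilcoxon_de(m, c("a1", "a2"), c("b1", "b2"))
  expect_equal(de$p_value, 1 / 3)      # 2 of 6 assignments as extreme

  same <- as_counts(matrix(2, 1, 4), genes = "g", cells = c("a1", "a2", "b1", "b2"))
  expect_equal(wilcoxon_de(same, c("a1", "a2"), c("b1", "b2"))$p_value, 1)
})

test_that("rank-sum exact p equals the exhaustive permutation oracle under ties", {
  set.seed(21)
  for (sizes in list(c(3, 5), c(4, 4), c(5, 8), c(8, 8))) {
    na <- sizes[1]; nb <- sizes[2]
    vals <- matrix(sample(0:4, 10 * (na + nb), replace = TRUE), nrow = 10)
    m <- as_counts(vals, cells = sprintf("c%02d", seq_len(na + nb)))
    de <- wilcoxon_de(m, colnames(m)[1:na], colnames(m)[(na + 1):(na + nb)])
    oracle <- vapply(seq_len(10), function(i) {
      oracle_ranksum_p(vals[i, 1:na], vals[i, (na + 1):(na + nb)])
    }, numeric(1))
    expect_equal(de$p_value, oracle, tolerance = 1e-12)
  }
})

test_that("rank-sum normal approximation tracks base wilcox.test", {
  set.seed(22)
  vals <- matrix(rnorm(5 * 40), nrow = 5)
  m <- as_counts(vals, cells = sprintf("c%02d", 1:40))
  de <- wilcoxon_de(m, colnames(m)[1:20], colnames(m)[21:40])
  ref <- vapply(1:5, function(i) {
    stats::wilcox.test(vals[i, 1:20], vals[i, 21:40], exact = FALSE,
                       correct = TRUE)$p.value
  }, numeric(1))
  expect_equal(de$p_value, ref, tolerance = 1e-10)
})

test_that("rank-sum contract violations error", {
  m <- as_counts(matrix(1:8, 2, 4))
  expect_error(wilcoxon_de(m, c("c001", "c002"), c("c002", "c003")), "overlap")
  expect_error(wilcoxon_de(m, character(), "c001"), "non-empty")
})

test_that("TMM factors satisfy the depth and normalization identities", {
  set.seed(30)
  base <- matrix(rpois(600, 40) + 1, nrow = 200)
  identical4 <- as_counts(cbind(base[, 1], base[, 1], base[, 1], base[, 1]))
  expect_equal(unname(tmm_factors(identical4)), rep(1, 4))

  depth <- as_counts(cbind(base[, 1], base[, 1] * 2))
  expect_equal(unname(tmm_factors(depth)), c(1, 1))

  random <- as_counts(base)
  expect_equal(prod(tmm_factors(random)), 1, tolerance = 1e-9)
  expect_error(tmm_factors(as_counts(cbind(base[, 1], 0 * base[, 1]))), "all-zero")
})

test_that("TMM factors agree with the reference edgeR implementation", {
  set.seed(31)
  counts <- matrix(rnbinom(200 * 6, mu = 100 * exp(rnorm(200)), size = 5),
                   nrow = 200)
  counts[1:20, 4:6] <- counts[1:20, 4:6] * 5  # composition shift
  m <- as_counts(counts)
  ours <- tmm_factors(m)
  theirs <- edgeR::calcNormFactors(as.matrix(m), method = "TMM")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("bulk DE recovers planted genes at the published gates", {
  cfg <- sim_config(n_genes = 200, cells_per_stage = c(W07 = 10, W09 = 10, W11 = 10, W17 = 10),
                    n_markers = 5, n_mito = 5, n_sig_up = 20, n_sig_down = 10,
                    crosstalk_genes = list(), seed = 13)
  bk <- simulate_bulk(cfg, n_per_group = 3, fold_change = 4, dispersion = 0.05)
  de <- bulk_de(bk$counts, bk$groups, treatment = "tumor")
  sig <- build_signature(de, de_gates(), "cancer")
  sens <- mean(bk$truth$up %in% sig$up_genes)
  fdp <- if (length(sig$up_genes)) mean(!sig$up_genes %in% bk$truth$up) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdp, 0.2)
})

test_that("bulk DE degenerate and antisymmetry contracts hold", {
  set.seed(32)
  # pure depth differences: every gene has identical normalized values
  base <- rpois(50, 60) + 1
  counts <- cbind(base, 2 * base, base, 2 * base, base, base)
  m <- as_counts(counts)
  groups <- rep(c("normal", "tumor"), each = 3)
  de <- bulk_de(m, groups, treatment = "tumor")
  expect_true(all(de$p_value == 1))
  expect_true(all(de$statistic == 0))

  noisy <- as_counts(matrix(rpois(50 * 6, 60), nrow = 50))
  a <- bulk_de(noisy, groups, treatment = "tumor")
  swapped <- bulk_de(noisy, groups, treatment = "normal")
  expect_equal(a$log2_fc, -swapped$log2_fc, tolerance = 1e-12)
  expect_equal(a$p_value, swapped$p_value, tolerance = 1e-12)

  expect_error(bulk_de(m, rep("x", 6)), "two groups")
  expect_error(bulk_de(m, c("a", rep("b", 5))), "replicates")
})

test_that("signature gates are strict at every boundary", {
  de <- data.frame(
    gene = c("up_ok", "fc_at_gate", "fdr_at_gate", "down_ok", "down_at_gate", "null"),
    fold_change = c(1.6, 1.5, 3.0, 0.5, 0.67, 1.0),
    fdr = c(0.04, 0.04, 0.05, 0.04, 0.04, 0.9),
    stringsAsFactors = FALSE)
  sig <- build_signature(de, de_gates(), "gated")
  expect_identical(sig$up_genes, "up_ok")
  expect_identical(sig$down_genes, "down_ok")

  empty <- de_gates()
  expect_warning(build_signature(de[de$gene == "null", ], empty, "none"), "empty")
})

test_that("signature gating is invariant to gene order", {
  set.seed(33)
  de <- data.frame(gene = sprintf("g%02d", 1:40),
                   fold_change = exp(rnorm(40)),
                   fdr = runif(40), stringsAsFactors = FALSE)
  a <- build_signature(de, de_gates(), "s")
  b <- build_signature(de[sample(40), ], de_gates(), "s")
  expect_setequal(a$up_genes, b$up_genes)
  expect_setequal(a$down_genes, b$down_genes)
})

test_that("curated markers are merged by union with conflict resolution", {
  sig <- gene_signature("er_high", c("Foxa1"), c("Elf5"))
  grown <- augment_signature(sig, "Esr1")
  expect_setequal(grown$up_genes, c("Foxa1", "Esr1"))

  expect_identical(augment_signature(grown, "Esr1")$up_genes, grown$up_genes)

  expect_warning(moved <- augment_signature(sig, "Elf5"), "down to up")
  expect_true("Elf5" %in% moved$up_genes)
  expect_false("Elf5" %in% moved$down_genes)

  expect_warning(screened <- augment_signature(sig, c("Esr1", "NotAGene"),
                                               universe = c("Foxa1", "Elf5", "Esr1")),
                 "not in universe")
  expect_false("NotAGene" %in% screened$up_genes)
})

test_that("ER lineage calls follow the fraction-expressing rule", {
  m <- matrix(0, 2, 10, dimnames = list(c("Esr1", "g1"), sprintf("c%02d", 1:10)))
  m[2, ] <- 5
  clusters <- setNames(rep(c("A", "B"), each = 5), colnames(m))

  norm0 <- lognormalize(as_counts(m, genes = rownames(m), cells = colnames(m)))
  res0 <- classify_er_lineage(norm0, clusters)
  expect_true(all(res0$cluster_calls$call == "ERlow"))   # Esr1 silent everywhere

  m[1, 1:5] <- c(3, 4, 5, 6, 0)  # cluster A: 80% positive
  norm <- lognormalize(as_counts(m, genes = rownames(m), cells = colnames(m)))
  res <- classify_er_lineage(norm, clusters, expr_threshold = 0.5)
  calls <- setNames(res$cluster_calls$call, res$cluster_calls$cluster)
  expect_identical(unname(calls["A"]), "ERhigh")
  expect_identical(unname(calls["B"]), "ERlow")
  expect_identical(res$cell_calls$call[res$cell_calls$cluster == "A"], rep("ERhigh", 5))

  expect_warning(classify_er_lineage(norm, clusters, expr_threshold = 0), "threshold 0")
  expect_error(classify_er_lineage(norm, clusters, er_gene = "ESR1"), "not in matrix")
})

test_that("BH adjustment preserves the order of raw p-values", {
  set.seed(34)
  m <- as_counts(matrix(rpois(50 * 12, 5), nrow = 50), cells = sprintf("c%02d", 1:12))
  norm <- lognormalize(m, allow_zero_cells = TRUE)
  de <- wilcoxon_de(norm, colnames(m)[1:6], colnames(m)[7:12])
  ord <- order(de$p_value)
  expect_true(!is.unsorted(de$fdr[ord]))
  expect_true(all(de$fdr >= de$p_value - 1e-12))
})
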