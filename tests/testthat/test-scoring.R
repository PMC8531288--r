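test_that("mean-difference score is the up-mean minus down-mean", {
  vals <- matrix(c(2, 4, 1, 0,
                   0, 0, 0, 0), ncol = 2,
                 dimnames = list(c("u1", "u2", "d1", "other"), c("a", "zero")))
  norm <- structure(Matrix::Matrix(vals, sparse = TRUE))
  sig <- gene_signature("s", c("u1", "u2"), "d1")
  sc <- score_mean_diff(norm, sig)
  expect_equal(sc$score[sc$cell_id == "a"], 3 - 1)
  expect_equal(sc$score[sc$cell_id == "zero"], 0)

  up_only <- gene_signature("s2", c("u1", "u2"))
  expect_equal(score_mean_diff(norm, up_only)$score, c(3, 0))

  expect_warning(score_mean_diff(norm, gene_signature("s3", c("u1", "absent"))),
                 "absent")
  expect_error(score_mean_diff(norm, gene_signature("s4", "missing")), "no signature gene")
})

test_that("mean-difference score is linear in the expression of one cell", {
  set.seed(41)
  vals <- matrix(runif(30), nrow = 6,
                 dimnames = list(sprintf("g%d", 1:6), sprintf("c%d", 1:5)))
  sig <- gene_signature("s", c("g1", "g2", "g3"))
  base <- score_mean_diff(Matrix::Matrix(vals, sparse = TRUE), sig)
  vals2 <- vals; vals2[c("g1", "g2", "g3"), "c2"] <- vals2[c("g1", "g2", "g3"), "c2"] + 0.7
  shifted <- score_mean_diff(Matrix::Matrix(vals2, sparse = TRUE), sig)
  expect_equal(shifted$score[2] - base$score[2], 0.7, tolerance = 1e-12)
  expect_equal(shifted$score[-2], base$score[-2])
})

test_that("rank enrichment score matches the direct walk oracle", {
  set.seed(42)
  genes <- sprintf("g%02d", 1:30)
  x <- stats::setNames(sample(1:100, 30), genes)
  m <- Matrix::Matrix(matrix(x, ncol = 1, dimnames = list(genes, "cell")), sparse = TRUE)

  # set occupying exactly the top ranks
  top_set <- genes[order(-x)][1:6]
  es_top <- score_rank_es(m, top_set)$score
  expect_gt(es_top, 0)
  expect_equal(es_top, oracle_walk_score(x, genes, top_set), tolerance = 1e-12)

  # arbitrary sets agree with the oracle, with and without weighting
  for (tau in c(0, 1)) {
    for (k in c(3, 10)) {
      set <- sample(genes, k)
      expect_equal(score_rank_es(m, set, weight_exponent = tau)$score,
                   oracle_walk_score(x, genes, set, tau), tolerance = 1e-12)
    }
  }
})

test_that("a uniformly interleaved set scores near zero at weight zero", {
  n <- 40
  genes <- sprintf("g%02d", 1:n)
  x <- stats::setNames(n:1, genes)       # distinct, ordered
  set <- genes[seq(1, n, by = 4)]        # every 4th rank
  m <- Matrix::Matrix(matrix(x, ncol = 1, dimnames = list(genes, "cell")), sparse = TRUE)
  es <- score_rank_es(m, set, weight_exponent = 0)$score
  expect_lte(abs(es), 2 / (n - length(set)) * length(set))
})

test_that("rank enrichment score only depends on ranks", {
  set.seed(43)
  genes <- sprintf("g%02d", 1:25)
  x <- matrix(rexp(25), ncol = 1, dimnames = list(genes, "cell"))
  set <- sample(genes, 7)
  a <- score_rank_es(Matrix::Matrix(x, sparse = TRUE), set)$score
  b <- score_rank_es(Matrix::Matrix(log1p(x * 100), sparse = TRUE), set)$score
  expect_equal(a, b, tolerance = 1e-12)

  expect_error(score_rank_es(Matrix::Matrix(x, sparse = TRUE), genes), "equals the gene universe")
  expect_error(score_rank_es(Matrix::Matrix(x, sparse = TRUE), "nope"), "does not intersect")
})

test_that("median split assigns boundary cells to normal", {
  sc <- stats::setNames(c(0.1, 0.5, 0.9), c("a", "b", "c"))
  cls <- classify_by_median(sc)
  expect_identical(stats::setNames(cls$label, cls$cell_id),
                   c(a = "normal", b = "normal", c = "cancer"))
  expect_equal(cls$threshold, rep(0.5, 3))

  expect_warning(flat <- classify_by_median(stats::setNames(rep(1, 4), letters[1:4])),
                 "identical")
  expect_true(all(flat$label == "normal"))

  # even n with distinct scores: exactly half labelled cancer
  sc2 <- stats::setNames(1:10, letters[1:10])
  expect_equal(sum(classify_by_median(sc2)$label == "cancer"), 5)
  expect_error(classify_by_median(stats::setNames(1, "a")), ">= 2")
})

test_that("median-split recovery and stem-cluster identification on planted data", {
  cfg <- sim_config(n_genes = 1000,
                    cells_per_stage = c(W07 = 90, W09 = 90, W11 = 90, W17 = 90),
                    cancer_scope = "epithelial",
                    cancer_fraction_by_stage = c(W07 = .5, W09 = .5, W11 = .5, W17 = .5),
                    signature_effect = 8, n_markers = 10,
                    crosstalk_genes = list(), seed = 17)
  sim <- simulate_single_cell(cfg)
  truth <- sim$truth$cells
  epi <- truth$cell_id[truth$compartment == "epithelial"]
  norm <- lognormalize(sim$counts[, epi], allow_zero_cells = TRUE)

  scores <- score_mean_diff(norm, sim$truth$signature)
  # cancer cells score far above normal cells
  s <- stats::setNames(scores$score, scores$cell_id)
  can <- s[truth$cell_id[truth$cancer]]
  nor <- s[setdiff(epi, truth$cell_id[truth$cancer])]
  pooled_se <- sqrt(stats::var(can) / length(can) + stats::var(nor) / length(nor))
  expect_gt(mean(can) - mean(nor), 4 * pooled_se)

  cls <- classify_by_median(scores)
  acc <- mean((cls$label == "cancer") ==
              truth$cancer[match(cls$cell_id, truth$cell_id)])
  expect_gte(acc, 0.9)

  # the cluster holding the planted stem cells tops the stemness ranking
  stem_scores <- score_rank_es(norm, sim$truth$markers$stem)
  clusters <- stats::setNames(truth$cell_type[match(epi, truth$cell_id)], epi)
  res <- identify_stem_cluster(stem_scores, clusters)
  expect_identical(res$top, "stem")
  expect_gt(res$margin, 0)

  # mean-difference and rank scores order cells concordantly (same signature)
  es_cancer <- score_rank_es(norm, sim$truth$signature$up_genes)
  rho <- stats::cor(scores$score, es_cancer$score, method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("stem-cluster ranking reports margins and ties", {
  sc <- stats::setNames(c(0.9, 0.9, 0.1, 0.1), c("a1", "a2", "b1", "b2"))
  cl <- stats::setNames(c("A", "A", "B", "B"), names(sc))
  res <- identify_stem_cluster(sc, cl)
  expect_identical(res$top, "A")
  expect_equal(res$margin, 0.8)

  tied <- stats::setNames(c(0.5, 0.5), c("x", "y"))
  cl2 <- stats::setNames(c("A", "B"), c("x", "y"))
  expect_warning(res2 <- identify_stem_cluster(tied, cl2), "tie")
  expect_identical(res2$top, "A")

  single <- identify_stem_cluster(stats::setNames(c(1, 2), c("x", "y")),
                                  stats::setNames(c("A", "A"), c("x", "y")))
  expect_true(single$single_cluster)
  expect_equal(single$margin, 0)
})

test_that("proportion dynamics uses the denominator convention", {
  labels <- stats::setNames(c("bcsc", "bcsc", "other", "other"), c("a", "b", "c", "d"))
  stages <- stats::setNames(factor(c("W07", "W07", "W07", "W07"),
                                   levels = c("W07", "W09")), names(labels))
  out <- proportion_dynamics(labels, stages, denominator = names(labels), target = "bcsc")
  expect_equal(out$proportion[out$stage == "W07"], 0.5)
  expect_true(is.na(out$proportion[out$stage == "W09"]))  # empty denominator

  # complementary labels sum to one per non-empty stage
  comp <- proportion_dynamics(labels, stages, target = "other")
  expect_equal(out$proportion[1] + comp$proportion[1], 1)
})
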