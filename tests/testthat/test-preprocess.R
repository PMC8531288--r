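test_that("lognormalize matches its closed form and invariances", {
  m <- as_counts(matrix(c(0, 7, 0, 0, 3, 9), nrow = 3),
                 genes = c("g1", "g2", "g3"), cells = c("a", "b"))
  norm <- lognormalize(m)
  expect_equal(norm["g1", "a"], 0)                       # zero stays zero
  expect_equal(norm["g2", "a"], log(1 + 10000))          # single expressed gene
  # doubling all counts of a cell leaves it unchanged
  m2 <- m; m2[, "b"] <- m2[, "b"] * 2
  expect_equal(as.matrix(lognormalize(m2))[, "b"], as.matrix(norm)[, "b"])

  zero <- as_counts(matrix(c(1, 0), nrow = 1), genes = "g", cells = c("a", "b"))
  expect_error(lognormalize(zero), "zero total")
  expect_silent(lognormalize(zero, allow_zero_cells = TRUE))
})

test_that("HVG selection ranks by variance with deterministic ties", {
  norm <- Matrix::Matrix(rbind(const = c(5, 5, 5, 5),
                               vary = c(0, 10, 0, 10),
                               slight = c(1, 1, 1, 2)), sparse = TRUE)
  colnames(norm) <- sprintf("c%d", 1:4)
  expect_identical(select_hvgs(norm, 10), c("vary", "slight", "const"))  # n >= genes: all
  expect_identical(select_hvgs(norm, 1), "vary")
  # a constant gene never precedes a non-constant one
  expect_false("const" %in% select_hvgs(norm, 2))
  # equal-variance ties break lexicographically by gene id
  tied <- Matrix::Matrix(rbind(b = c(0, 1), a = c(1, 0), z = c(0, 1)), sparse = TRUE)
  colnames(tied) <- c("c1", "c2")
  expect_identical(select_hvgs(tied, 2), c("a", "b"))
  expect_error(select_hvgs(norm, 0), "n must be")
  # ranking is invariant to cell order
  expect_identical(select_hvgs(norm[, c(3, 1, 4, 2)], 3), select_hvgs(norm, 3))
})

test_that("HVG selection recovers planted high-variance marker genes", {
  # balanced cell types with strong identity programs: the 50 planted
  # markers are the genuinely high-variance genes of this universe
  cfg <- sim_config(n_genes = 2000, cells_per_stage = c(W07 = 75, W09 = 75, W11 = 75, W17 = 75),
                    n_markers = 10, marker_fold = 10, stem_fraction = 0.3,
                    epithelial_fraction = c(W07 = .5, W09 = .5, W11 = .5, W17 = .5),
                    cancer_fraction_by_stage = c(W07 = 0, W09 = 0, W11 = 0, W17 = 0),
                    crosstalk_genes = list(), seed = 4)
  sim <- simulate_single_cell(cfg)
  norm <- lognormalize(sim$counts, allow_zero_cells = TRUE)
  planted <- unlist(sim$truth$markers, use.names = FALSE)  # 50 marker genes
  hv <- select_hvgs(norm, length(planted))
  expect_gte(length(intersect(hv, planted)), 45)
})

test_that("scaling centers, standardizes and clips", {
  norm <- Matrix::Matrix(rbind(g1 = c(2, 2, 2), g2 = c(1, 5, 9), g3 = c(0, 0, 7)),
                         sparse = TRUE)
  colnames(norm) <- sprintf("c%d", 1:3)
  sc <- scale_genes(norm, clip = 10)
  expect_true(all(sc["g1", ] == 0))                      # constant gene -> zeros
  expect_lt(abs(mean(sc["g2", ])), 1e-9)
  expect_lt(abs(stats::sd(sc["g2", ]) - 1), 1e-9)
  sc2 <- scale_genes(norm, clip = 0.5)
  expect_true(all(abs(sc2) <= 0.5))
  expect_error(scale_genes(norm, genes = "nope"), "not in matrix")
})

test_that("PCA agrees with a dense eigendecomposition oracle", {
  set.seed(8)
  x <- matrix(rnorm(20 * 12), nrow = 12, dimnames = list(sprintf("g%02d", 1:12),
                                                         sprintf("c%02d", 1:20)))
  x <- t(scale(t(x)))
  emb <- run_pca(x, n_components = 5)
  # oracle: eigenvalues of the covariance of the cells x genes matrix
  ev <- eigen(stats::cov(t(x)), symmetric = TRUE)$values[1:5]
  expect_equal(emb$component_variances, ev, tolerance = 1e-8)
  expect_false(is.unsorted(rev(emb$component_variances)))
  # total embedded variance cannot exceed total variance
  expect_lte(sum(emb$component_variances), sum(apply(t(x), 2, stats::var)) + 1e-8)
})

test_that("PCA collapses rank-one data onto one component", {
  u <- rnorm(30); v <- rnorm(10)
  x <- outer(v, u)  # 10 genes x 30 cells, rank 1
  dimnames(x) <- list(sprintf("g%02d", 1:10), sprintf("c%02d", 1:30))
  emb <- run_pca(x, n_components = 4)
  expect_true(all(emb$component_variances[-1] <= 1e-9 * emb$component_variances[1]))
})

test_that("clustering recovers well-separated blobs and respects the seed", {
  set.seed(3)
  blob1 <- matrix(rnorm(100 * 2), ncol = 2)
  blob2 <- matrix(rnorm(100 * 2, mean = 20), ncol = 2)
  coords <- rbind(blob1, blob2)
  rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
  truth <- rep(c("a", "b"), each = 100)

  # coarse resolution for two coarse planted groups (at 0.4 both this
  # implementation and the reference SNN-Louvain toolkit subdivide blobs
  # of this size)
  cl <- cluster_cells(coords, resolution = 0.2, k_neighbors = 20, seed = 1)
  expect_equal(nlevels(cl), 2)
  expect_equal(ari(cl, truth), 1)

  # one isotropic blob at low resolution stays one cluster
  one <- cluster_cells(blob1 * 1, resolution = 0.05, k_neighbors = 20, seed = 1)
  expect_equal(nlevels(droplevels(one)), 1)

  cl2 <- cluster_cells(coords, resolution = 0.2, k_neighbors = 20, seed = 1)
  expect_identical(cl, cl2)

  expect_error(cluster_cells(coords[1:10, ], k_neighbors = 20), "k_neighbors")
})

test_that("kmeans fallback is available and labelled by size", {
  set.seed(3)
  coords <- rbind(matrix(rnorm(120 * 2), ncol = 2),
                  matrix(rnorm(60 * 2, mean = 15), ncol = 2))
  rownames(coords) <- sprintf("c%03d", seq_len(nrow(coords)))
  cl <- cluster_cells(coords, method = "kmeans", k_clusters = 2, seed = 2)
  expect_equal(nlevels(cl), 2)
  expect_gte(sum(cl == "1"), sum(cl == "2"))  # labels ordered by size
})
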