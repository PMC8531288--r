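# Normalization, variable-gene selection, scaling, PCA and graph clustering.

#' Log-normalize a count matrix
#'
#' Per-cell depth normalization to a fixed scale factor followed by
#' log(1 + x) with the natural log:
#' `value(g,c) = ln(1 + count(g,c) * scale_factor / total(c))`.
#' Zeros stay exactly zero, and the result is invariant to rescaling any
#' cell's depth.
#'
#' @param counts Gene-by-cell count matrix.
#' @param scale_factor Target per-cell total (default 10,000).
#' @param allow_zero_cells Keep all-zero cells (as all-zero columns) instead
#'   of erroring. QC is expected to have removed them upstream.
#' @return A sparse matrix of log-normalized values with attribute
#'   `scale_factor`.
#' @export
lognormalize <- function(counts, scale_factor = 10000, allow_zero_cells = FALSE) {
  validate_count_matrix(counts)
  if (scale_factor <= 0) stopf("scale_factor must be > 0")
  tot <- Matrix::colSums(counts)
  if (any(tot == 0) && !allow_zero_cells) {
    stopf("%d cell(s) have zero total counts; filter them or set allow_zero_cells = TRUE",
          sum(tot == 0))
  }
  m <- as_dgc(counts)
  scale <- ifelse(tot == 0, 0, scale_factor / tot)
  # scale the nonzero entries column-wise, then log1p
  cols <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(m@x * scale[cols])
  attr(m, "scale_factor") <- scale_factor
  sd_log("lognormalize: %d genes x %d cells, scale factor %g", nrow(m), ncol(m), scale_factor)
  m
}

#' Select highly variable genes
#'
#' Ranks genes by the variance of their log-normalized expression and
#' returns the top `n`. Ties are broken by lexicographic gene id; if `n`
#' exceeds the gene count, all genes are returned. The ranking is invariant
#' to cell order.
#'
#' @param norm Log-normalized matrix from [lognormalize()].
#' @param n Number of genes to select (default 3000).
#' @return Character vector of gene ids, highest variance first.
#' @export
select_hvgs <- function(norm, n = 3000) {
  if (n <= 0) stopf("select_hvgs: n must be > 0")
  if (nrow(norm) < 1) stopf("select_hvgs: no genes")
  nc <- ncol(norm)
  mu <- Matrix::rowMeans(norm)
  ex2 <- Matrix::rowMeans(norm^2)
  v <- (ex2 - mu^2) * nc / max(nc - 1, 1)
  v <- pmax(v, 0)
  ord <- order(-v, rownames(norm))
  n <- min(n, nrow(norm))
  rownames(norm)[ord[seq_len(n)]]
}

#' Center, scale and clip gene expression
#'
#' Per gene (row): subtract the mean across cells, divide by the standard
#' deviation, and clip to `[-clip, clip]`. Constant genes map to all-zero
#' rows.
#'
#' @param norm Log-normalized matrix.
#' @param genes Genes to scale (e.g. HVGs); default all.
#' @param clip Absolute value cap (default 10).
#' @return A dense genes-by-cells matrix of scaled values.
#' @export
scale_genes <- function(norm, genes = NULL, clip = 10) {
  if (is.null(genes)) genes <- rownames(norm)
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) stopf("scale_genes: %d gene(s) not in matrix", length(missing))
  m <- as.matrix(norm[genes, , drop = FALSE])
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  m <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  m[sdv == 0, ] <- 0
  m[m > clip] <- clip
  m[m < -clip] <- -clip
  m
}

#' Principal-component embedding of scaled expression
#'
#' Projects cells onto the top right-singular directions of the
#' cells-by-genes scaled matrix. The sign of each component is fixed so that
#' its largest-magnitude gene loading is positive, making the embedding
#' deterministic.
#'
#' @param scaled Genes-by-cells matrix from [scale_genes()].
#' @param n_components Number of components (<= min(cells, genes)).
#' @param seed Unused (the decomposition is deterministic); accepted for
#'   interface uniformity.
#' @return A list of class `sd_embedding`: `coordinates` (cells x
#'   components), `component_variances` (non-increasing), `n_components`,
#'   and `rotation` (gene loadings).
#' @export
run_pca <- function(scaled, n_components = 50, seed = NULL) {
  n_components <- min(n_components, nrow(scaled), ncol(scaled))
  if (n_components < 1) stopf("run_pca: n_components must be >= 1")
  pc <- stats::prcomp(t(scaled), center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  rownames(pc$x) <- colnames(scaled)
  structure(list(coordinates = pc$x[, seq_len(n_components), drop = FALSE],
                 component_variances = pc$sdev[seq_len(n_components)]^2,
                 n_components = n_components,
                 rotation = pc$rotation[, seq_len(n_components), drop = FALSE]),
            class = "sd_embedding")
}

#' @export
print.sd_embedding <- function(x, ...) {
  cat(sprintf("<sd_embedding> %d cells x %d components\n",
              nrow(x$coordinates), x$n_components))
  invisible(x)
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' Builds a k-nearest-neighbor graph in embedding space, weights edges by
#' the Jaccard overlap of neighbor sets (pruned below `prune`), and
#' partitions it by seeded greedy modularity optimization with a resolution
#' parameter. Labels are contiguous integers ordered by decreasing cluster
#' size. A deterministic k-means fallback (`method = "kmeans"`) is provided
#' for settings where a fixed cluster count is preferred.
#'
#' @param embedding An `sd_embedding` from [run_pca()], or a cells-by-dims
#'   coordinate matrix with rownames.
#' @param resolution Modularity resolution (default 0.4; larger tends to
#'   yield more clusters).
#' @param k_neighbors Neighbors per cell for the graph (default 20).
#' @param seed Seed for the community search.
#' @param method `"snn_louvain"` (default) or `"kmeans"`.
#' @param k_clusters Cluster count for the k-means fallback.
#' @param prune Jaccard cutoff below which SNN edges are dropped.
#' @return A factor of cluster labels ("1", "2", ...) named by cell id.
#' @export
cluster_cells <- function(embedding, resolution = 0.4, k_neighbors = 20,
                          seed = 1, method = c("snn_louvain", "kmeans"),
                          k_clusters = NULL, prune = 1 / 15) {
  method <- match.arg(method)
  coords <- if (inherits(embedding, "sd_embedding")) embedding$coordinates else embedding
  n <- nrow(coords)
  if (method == "kmeans") {
    if (is.null(k_clusters)) stopf("cluster_cells: k_clusters required for kmeans")
    set.seed(seed)
    km <- stats::kmeans(coords, centers = k_clusters, nstart = 10, iter.max = 100)
    return(relabel_by_size(km$cluster, rownames(coords)))
  }
  if (n < k_neighbors + 1) {
    stopf("cluster_cells: need at least k_neighbors + 1 = %d cells, got %d",
          k_neighbors + 1, n)
  }
  d <- as.matrix(stats::dist(coords))
  # k nearest neighbors including self, ties broken by index for determinism
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(k_neighbors)]))
  B <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(B)
  jac <- shared
  jac@x <- jac@x / (2 * k_neighbors - jac@x)
  jac@x[jac@x < prune] <- 0
  jac <- Matrix::drop0(jac)
  Matrix::diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  relabel_by_size(igraph::membership(comm), rownames(coords))
}

# Relabel cluster ids as "1","2",... by decreasing size (ties by old label).
#' @keywords internal
#' @noRd
relabel_by_size <- function(membership, cell_ids) {
  tab <- table(membership)
  new_order <- names(sort(tab, decreasing = TRUE))
  labels <- factor(match(as.character(membership), new_order),
                   levels = seq_along(new_order))
  labels <- factor(as.character(labels), levels = as.character(seq_along(new_order)))
  names(labels) <- cell_ids
  sd_log("clustering: %d cells -> %d clusters", length(labels), nlevels(labels))
  labels
}
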