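# Per-cell signature scoring, median-split classification, stem-cluster
# identification, and stage-wise proportion dynamics.

#' Mean-difference signature score
#'
#' Per cell: mean log-normalized expression over the signature's up-genes
#' minus the mean over its down-genes (0 when the down set is empty).
#' Signature genes absent from the matrix are dropped with a warning; it is
#' an error if none are present.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param sig A [gene_signature()].
#' @return A data.frame: `cell_id`, `score`, with attribute `method`
#'   (`"mean_diff"`).
#' @export
score_mean_diff <- function(norm, sig) {
  up <- intersect(sig$up_genes, rownames(norm))
  dn <- intersect(sig$down_genes, rownames(norm))
  if (!length(up) && !length(dn)) {
    stopf("score_mean_diff: no signature gene present in matrix")
  }
  n_missing <- (length(sig$up_genes) - length(up)) +
               (length(sig$down_genes) - length(dn))
  if (n_missing > 0) {
    warnf("score_mean_diff: %d signature gene(s) absent from matrix", n_missing)
  }
  up_mean <- if (length(up)) Matrix::colMeans(norm[up, , drop = FALSE]) else 0
  dn_mean <- if (length(dn)) Matrix::colMeans(norm[dn, , drop = FALSE]) else 0
  out <- data.frame(cell_id = colnames(norm),
                    score = as.numeric(up_mean - dn_mean),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "mean_diff"
  attr(out, "signature") <- sig$name
  out
}

#' Single-sample rank-based enrichment score
#'
#' A weighted Kolmogorov-Smirnov random-walk statistic on within-cell
#' expression ranks, in the spirit of single-sample gene-set enrichment.
#' Genes are ordered by decreasing expression (midranks for ties; ties in
#' the walk order broken by gene id). Walking down the ordering, an in-set
#' gene steps up by its rank weight `(N - midrank + 1)^weight_exponent`
#' normalized over the set; an out-of-set gene steps down by `1/(N - n)`.
#' The score is the maximum positive deviation plus the minimum negative
#' deviation of the walk ("maxdiff" convention) and lies in [-1, 1]. Being
#' rank-based, it is invariant to any strictly increasing transform of a
#' cell's expression values.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param gene_set Character vector of gene ids; must intersect the gene
#'   universe and be a strict subset of it.
#' @param weight_exponent Exponent on the rank weight (0 = unweighted KS;
#'   default 1).
#' @return A data.frame: `cell_id`, `score`, with attribute `method`
#'   (`"rank_es"`).
#' @export
score_rank_es <- function(norm, gene_set, weight_exponent = 1) {
  genes <- rownames(norm)
  set <- intersect(unique(gene_set), genes)
  if (!length(set)) stopf("score_rank_es: gene_set does not intersect the gene universe")
  if (length(set) == length(genes)) {
    stopf("score_rank_es: gene_set equals the gene universe; the walk is undefined")
  }
  n_gene <- length(genes)
  in_set <- genes %in% set
  m <- as.matrix(norm)
  scores <- vapply(seq_len(ncol(m)), function(ci) {
    x <- m[, ci]
    midrank <- rank(-x, ties.method = "average")
    ord <- order(-x, genes)
    w <- (n_gene - midrank + 1)^weight_exponent
    steps <- numeric(n_gene)
    inside <- in_set[ord]
    steps[inside] <- w[ord][inside] / sum(w[in_set])
    steps[!inside] <- -1 / (n_gene - length(set))
    walk <- cumsum(steps)
    max(c(walk, 0)) + min(c(walk, 0))
  }, numeric(1))
  out <- data.frame(cell_id = colnames(norm), score = scores,
                    stringsAsFactors = FALSE)
  attr(out, "method") <- "rank_es"
  out
}

#' Median-split cancer/normal classification
#'
#' Threshold at the sample median of the score: strictly above the median is
#' `"cancer"`, at or below is `"normal"` (only scores higher than the
#' median define cancer, so boundary cells are normal). All-identical
#' scores yield all-normal with a warning.
#'
#' @param scores A score table (`cell_id`, `score`) or named numeric vector.
#' @param signature_name Optional tag recorded in the output.
#' @return A data.frame: `cell_id`, `label` (`"cancer"`/`"normal"`),
#'   `threshold` (the median used).
#' @export
classify_by_median <- function(scores, signature_name = NULL) {
  sc <- as_score_vector(scores)
  if (length(sc) < 2) stopf("classify_by_median: need >= 2 scored cells")
  med <- stats::median(sc)
  if (all(sc == sc[1])) warnf("classify_by_median: all scores identical; every cell labelled normal")
  out <- data.frame(cell_id = names(sc),
                    label = ifelse(sc > med, "cancer", "normal"),
                    threshold = med,
                    stringsAsFactors = FALSE)
  if (!is.null(signature_name)) out$signature <- signature_name
  out
}

#' @keywords internal
#' @noRd
as_score_vector <- function(scores) {
  if (is.data.frame(scores)) {
    stopifnot(all(c("cell_id", "score") %in% names(scores)))
    stats::setNames(scores$score, scores$cell_id)
  } else {
    if (is.null(names(scores))) stopf("scores must be named by cell id")
    scores
  }
}

#' Rank clusters by mean signature score and pick the stem-like cluster
#'
#' Clusters are ranked by the mean score of their cells; the top cluster is
#' the stem-cluster candidate and the margin over the runner-up is reported.
#' Exact ties at the top are broken by cluster label order and flagged.
#'
#' @param scores Score table or named numeric vector.
#' @param clusters Cluster labels named by cell id (or aligned with the
#'   score table).
#' @return A list: `ranking` (data.frame cluster, mean_score, n, ordered by
#'   decreasing mean), `top` (cluster label), `margin` (top minus runner-up
#'   mean; 0 with `single_cluster = TRUE` when there is only one cluster),
#'   `tie` (logical).
#' @export
identify_stem_cluster <- function(scores, clusters) {
  sc <- as_score_vector(scores)
  cl <- align_cell_vector(clusters, names(sc), "clusters")
  cl <- as.character(cl)
  means <- tapply(sc, cl, mean)
  ns <- tapply(sc, cl, length)
  ord <- order(-means, names(means))
  ranking <- data.frame(cluster = names(means)[ord],
                        mean_score = as.numeric(means)[ord],
                        n = as.integer(ns)[ord],
                        stringsAsFactors = FALSE)
  single <- nrow(ranking) == 1
  margin <- if (single) 0 else ranking$mean_score[1] - ranking$mean_score[2]
  tie <- !single && margin == 0
  if (tie) warnf("identify_stem_cluster: tie at the top; broken by cluster label order")
  list(ranking = ranking, top = ranking$cluster[1], margin = margin,
       tie = tie, single_cluster = single)
}

#' Stage-wise proportion dynamics
#'
#' For each stage, the proportion of denominator cells at that stage
#' carrying the target label. Stages whose denominator is empty yield a
#' missing value, not zero.
#'
#' @param labels Per-cell labels named by cell id (e.g. output of
#'   [classify_by_median()], passed as `setNames(df$label, df$cell_id)`).
#' @param stages Per-cell stage named by cell id; determines stage order via
#'   its factor levels (or sorted unique values).
#' @param denominator Cell ids forming the denominator population (default:
#'   all labelled cells).
#' @param target The label counted in the numerator (default `"cancer"`).
#' @return A data.frame: `stage`, `n_denominator`, `n_target`, `proportion`.
#' @export
proportion_dynamics <- function(labels, stages, denominator = NULL,
                                target = "cancer") {
  if (is.null(names(labels))) stopf("labels must be named by cell id")
  if (is.null(names(stages))) stopf("stages must be named by cell id")
  if (is.null(denominator)) denominator <- names(labels)
  stage_levels <- if (is.factor(stages)) levels(stages) else sort(unique(as.character(stages)))
  denom <- intersect(denominator, names(stages))
  out <- lapply(stage_levels, function(st) {
    ids <- denom[as.character(stages[denom]) == st]
    n_t <- sum(labels[ids] == target, na.rm = TRUE)
    data.frame(stage = st,
               n_denominator = length(ids),
               n_target = n_t,
               proportion = if (length(ids)) n_t / length(ids) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
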