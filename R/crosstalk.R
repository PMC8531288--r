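# Ligand-receptor (cytokine-receptor) cross-talk summaries across clusters.

#' Read a ligand-receptor pair list
#'
#' Tab-separated file with a header and columns `ligand`, `receptor`,
#' `name`. Pairs whose ligand equals their receptor are rejected.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of pairs.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("ligand", "receptor", "name")
  if (!all(need %in% names(df))) {
    stopf("pair file must have columns %s", paste(need, collapse = ", "))
  }
  bad <- df$ligand == df$receptor
  if (any(bad)) stopf("pair(s) with ligand == receptor: %s", paste(df$name[bad], collapse = ", "))
  df
}

#' Per-cluster expression summary of ligand and receptor genes
#'
#' For every gene appearing in a resolvable pair: the mean log-normalized
#' expression and the fraction of cells with nonzero expression, per
#' cluster — the quantities a cross-talk dot plot displays. Pairs with
#' either gene absent from the matrix are dropped with a warning; it is an
#' error if none resolve.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param clusters Cluster labels named by cell id (or in column order).
#' @param pairs Data.frame from [read_lr_pairs()] (columns `ligand`,
#'   `receptor`, `name`).
#' @return A list: `summary` (data.frame gene, cluster, mean_expr,
#'   frac_expressing) and `pairs` (the resolvable pairs retained).
#' @export
pair_expression_summary <- function(norm, clusters, pairs) {
  cl <- as.character(align_cell_vector(clusters, colnames(norm), "clusters"))
  ok <- pairs$ligand %in% rownames(norm) & pairs$receptor %in% rownames(norm)
  if (!any(ok)) stopf("pair_expression_summary: no pair resolves against the gene universe")
  if (any(!ok)) {
    warnf("pair_expression_summary: dropping %d unresolvable pair(s): %s",
          sum(!ok), paste(pairs$name[!ok], collapse = ", "))
  }
  pairs <- pairs[ok, , drop = FALSE]
  genes <- unique(c(pairs$ligand, pairs$receptor))
  clevels <- sort(unique(cl))
  m <- as.matrix(norm[genes, , drop = FALSE])
  rows <- lapply(clevels, function(k) {
    sub <- m[, cl == k, drop = FALSE]
    data.frame(gene = genes,
               cluster = k,
               mean_expr = rowMeans(sub),
               frac_expressing = rowMeans(sub > 0),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, pairs = pairs)
}

#' Flag candidate source-to-target ligand-receptor interactions
#'
#' A (pair, source, target) triple is flagged iff the ligand passes in the
#' source cluster and the receptor passes in the target cluster, where
#' "passes" means: fraction expressing >= `min_fraction` AND the cluster's
#' mean expression is at least `min_z` standard deviations above the
#' across-cluster mean of that gene. The interaction score is the sum of
#' the two z-scores; output is sorted by score, descending. Raising either
#' threshold can only remove flags.
#'
#' @param summary Output of [pair_expression_summary()] (the list, or its
#'   `summary` data.frame together with `pairs`).
#' @param pairs Pair data.frame (ignored if `summary` is the full list).
#' @param source_clusters,target_clusters Cluster labels considered as
#'   ligand sources / receptor targets.
#' @param min_fraction Fraction-expressing floor.
#' @param min_z Z-score floor.
#' @return A data.frame: `name`, `ligand`, `receptor`, `source`, `target`,
#'   `ligand_z`, `receptor_z`, `ligand_fraction`, `receptor_fraction`,
#'   `score`, sorted by decreasing score.
#' @export
flag_interactions <- function(summary, pairs = NULL, source_clusters,
                              target_clusters, min_fraction = 0.1, min_z = 1) {
  if (is.list(summary) && !is.data.frame(summary) && !is.null(summary$summary)) {
    pairs <- summary$pairs
    summary <- summary$summary
  }
  if (is.null(pairs)) stopf("flag_interactions: pairs required")
  clusters <- unique(summary$cluster)
  if (length(clusters) < 2) stopf("flag_interactions: need >= 2 clusters for z-scores")
  # per-gene z of cluster means across clusters
  zs <- do.call(rbind, lapply(split(summary, summary$gene), function(d) {
    mu <- mean(d$mean_expr); sdv <- stats::sd(d$mean_expr)
    d$z <- if (is.na(sdv) || sdv == 0) 0 else (d$mean_expr - mu) / sdv
    d
  }))
  key <- function(g, k) paste(g, k, sep = "\r")
  idx <- stats::setNames(seq_len(nrow(zs)), key(zs$gene, zs$cluster))
  passes <- function(g, k) {
    i <- idx[[key(g, k)]]
    if (is.null(i)) return(NULL)
    list(ok = zs$frac_expressing[i] >= min_fraction & zs$z[i] >= min_z,
         z = zs$z[i], frac = zs$frac_expressing[i])
  }
  out <- list()
  for (pi in seq_len(nrow(pairs))) {
    for (s in source_clusters) {
      lg <- passes(pairs$ligand[pi], s)
      if (is.null(lg) || !lg$ok) next
      for (t in target_clusters) {
        rc <- passes(pairs$receptor[pi], t)
        if (is.null(rc) || !rc$ok) next
        out[[length(out) + 1]] <- data.frame(
          name = pairs$name[pi], ligand = pairs$ligand[pi],
          receptor = pairs$receptor[pi], source = s, target = t,
          ligand_z = lg$z, receptor_z = rc$z,
          ligand_fraction = lg$frac, receptor_fraction = rc$frac,
          score = lg$z + rc$z, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(name = character(), ligand = character(),
                      receptor = character(), source = character(),
                      target = character(), ligand_z = numeric(),
                      receptor_z = numeric(), ligand_fraction = numeric(),
                      receptor_fraction = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$score, res$name, res$source, res$target), , drop = FALSE]
  rownames(res) <- NULL
  res
}
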