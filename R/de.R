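# Differential expression (single-cell Wilcoxon, bulk Welch-on-TMM-log2CPM),
# signature gating, curated-marker augmentation, and ER-lineage calls.

#' Differential-expression gates
#'
#' The published gates: FDR < 0.05 and fold change > 1.5 (up) or < 0.67
#' (down), all strict.
#'
#' @param max_fdr BH-adjusted p-value cutoff (strict `<`).
#' @param min_fc_up Fold-change floor for up-genes (strict `>`).
#' @param max_fc_down Fold-change ceiling for down-genes (strict `<`).
#' @return A list of class `de_gates`.
#' @export
de_gates <- function(max_fdr = 0.05, min_fc_up = 1.5, max_fc_down = 0.67) {
  if (!(max_fc_down < 1 && 1 < min_fc_up)) {
    stopf("de_gates: need max_fc_down < 1 < min_fc_up")
  }
  if (max_fdr <= 0 || max_fdr >= 1) stopf("de_gates: max_fdr must be in (0,1)")
  structure(list(max_fdr = max_fdr, min_fc_up = min_fc_up,
                 max_fc_down = max_fc_down), class = "de_gates")
}

#' Wilcoxon rank-sum differential expression
#'
#' Per-gene two-sided rank-sum test of group A vs group B on log-normalized
#' expression, with midrank tie handling. When the smaller group has at most
#' `exact_max_n` cells the p-value is computed by exhaustive enumeration of
#' all assignments of the observed (mid)ranks to the two groups; otherwise
#' the normal approximation with tie-corrected variance and continuity
#' correction is used. P-values are BH-adjusted across genes. Fold change is
#' computed on expm1 of the per-group mean log-normalized values with a
#' pseudocount of 1.
#'
#' @param norm Log-normalized genes-by-cells matrix.
#' @param cells_a,cells_b Disjoint, non-empty cell-id vectors.
#' @param genes Genes to test (default all).
#' @param exact_max_n Largest min-group size for which the exact enumeration
#'   is used (default 8).
#' @return A data.frame with one row per gene: `gene`, `mean_a`, `mean_b`,
#'   `pct_a`, `pct_b` (fraction expressing), `fold_change`, `log2_fc`,
#'   `statistic` (group-A rank sum), `p_value`, `fdr`.
#' @export
wilcoxon_de <- function(norm, cells_a, cells_b, genes = NULL, exact_max_n = 8) {
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    stopf("wilcoxon_de: both groups must be non-empty")
  }
  if (length(intersect(cells_a, cells_b))) {
    stopf("wilcoxon_de: groups overlap (%d cell(s))",
          length(intersect(cells_a, cells_b)))
  }
  missing <- setdiff(c(cells_a, cells_b), colnames(norm))
  if (length(missing)) stopf("wilcoxon_de: %d cell id(s) not in matrix", length(missing))
  if (is.null(genes)) genes <- rownames(norm)
  a <- as.matrix(norm[genes, cells_a, drop = FALSE])
  b <- as.matrix(norm[genes, cells_b, drop = FALSE])
  na <- length(cells_a); nb <- length(cells_b); n <- na + nb
  exact <- min(na, nb) <= exact_max_n
  comb <- if (exact) utils::combn(n, na) else NULL

  res <- vapply(seq_along(genes), function(i) {
    x <- a[i, ]; y <- b[i, ]
    r <- rank(c(x, y))
    w <- sum(r[seq_len(na)])
    e0 <- na * (n + 1) / 2
    if (exact) {
      tsums <- colSums(matrix(r[comb], nrow = na))
      p <- mean(abs(tsums - e0) >= abs(w - e0) - 1e-9)
    } else {
      ties <- table(r)
      sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
      if (sig2 <= 0) {
        p <- 1
      } else {
        z <- (w - e0 - sign(w - e0) * 0.5) / sqrt(sig2)
        p <- min(1, 2 * stats::pnorm(-abs(z)))
      }
    }
    c(w = w, p = p)
  }, numeric(2))

  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  fc <- (expm1(mean_a) + 1) / (expm1(mean_b) + 1)
  data.frame(
    gene = genes,
    mean_a = mean_a, mean_b = mean_b,
    pct_a = rowMeans(a > 0), pct_b = rowMeans(b > 0),
    fold_change = fc, log2_fc = log2(fc),
    statistic = res["w", ],
    p_value = res["p", ],
    fdr = stats::p.adjust(res["p", ], method = "BH"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' TMM scaling factors for bulk counts
#'
#' Trimmed-mean-of-M-values between-sample normalization: the reference is
#' the sample whose upper-quartile depth-adjusted expression is closest to
#' the mean; each sample's factor is a precision-weighted mean of its
#' log-ratios (M) against the reference after trimming the most extreme 30%
#' of M values and 5% of average log-expression (A) values on each side.
#' Factors are rescaled so they multiply to 1.
#'
#' @param bulk Gene-by-sample count matrix (>= 2 samples, no all-zero
#'   sample).
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return Named numeric vector of per-sample factors multiplying to 1.
#' @export
tmm_factors <- function(bulk, trim_m = 0.30, trim_a = 0.05) {
  validate_count_matrix(bulk, "bulk matrix")
  if (ncol(bulk) < 2) stopf("tmm_factors: need >= 2 samples")
  lib <- Matrix::colSums(bulk)
  if (any(lib == 0)) stopf("tmm_factors: all-zero sample(s) present")
  m <- as.matrix(bulk)
  f75 <- vapply(seq_len(ncol(m)), function(j) {
    stats::quantile(m[, j] / lib[j], 0.75, names = FALSE)
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(j) {
    obs <- m[, j]; refv <- m[, ref]
    keep <- obs > 0 & refv > 0
    if (!any(keep)) return(1)
    p_o <- obs[keep] / lib[j]; p_r <- refv[keep] / lib[ref]
    M <- log2(p_o / p_r)
    A <- (log2(p_o) + log2(p_r)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    w <- (lib[j] - obs[keep]) / (lib[j] * obs[keep]) +
         (lib[ref] - refv[keep]) / (lib[ref] * refv[keep])
    nk <- length(M)
    loM <- floor(nk * trim_m) + 1; hiM <- nk + 1 - loM
    loA <- floor(nk * trim_a) + 1; hiA <- nk + 1 - loA
    rM <- rank(M); rA <- rank(A)
    sel <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(sel)) return(1)
    2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f <- vapply(seq_len(ncol(m)), one_factor, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(bulk)
  f
}

#' Bulk differential expression (moderated t on TMM-log2-CPM)
#'
#' Normalizes counts to log2 counts-per-million using TMM effective library
#' sizes (pseudocount 0.5) and tests the treatment group against the other
#' group with an empirical-Bayes moderated t-test (limma with a
#' mean-variance trend), which shares variance information across genes —
#' essential for power at 2-3 replicates per group. P-values are
#' BH-adjusted across genes with nonzero row sums (zero-sum genes get NA).
#' Fold change is the ratio of normalized group mean CPMs (pseudocount 0.5
#' on both sides), so its sign always agrees with the group-mean ordering.
#' A gene identical across all samples has zero effect and p = 1.
#'
#' @param bulk Gene-by-sample count matrix.
#' @param groups Group label per sample (exactly two distinct labels, >= 2
#'   replicates each).
#' @param treatment The label treated as numerator of the fold change;
#'   default the lexicographically later label.
#' @return A data.frame per gene: `gene`, `mean_treat`, `mean_control`
#'   (mean CPM), `fold_change`, `log2_fc`, `statistic` (moderated t),
#'   `p_value`, `fdr`.
#' @export
bulk_de <- function(bulk, groups, treatment = NULL) {
  validate_count_matrix(bulk, "bulk matrix")
  groups <- as.character(groups)
  if (length(groups) != ncol(bulk)) stopf("bulk_de: one group label per sample required")
  levs <- sort(unique(groups))
  if (length(levs) != 2) stopf("bulk_de: exactly two groups required")
  if (min(table(groups)) < 2) stopf("bulk_de: need >= 2 replicates per group")
  if (is.null(treatment)) treatment <- levs[2]
  if (!treatment %in% levs) stopf("bulk_de: treatment label '%s' not in groups", treatment)

  f <- tmm_factors(bulk)
  eff_lib <- Matrix::colSums(bulk) * f
  cpm <- sweep(as.matrix(bulk), 2, eff_lib / 1e6, `/`)
  lcpm <- log2(cpm + 0.5)
  ti <- groups == treatment

  # genes with no variation at all across samples carry no evidence; flag
  # them up front so floating-point residuals cannot manufacture statistics
  rng <- apply(lcpm, 1, function(r) diff(range(r)))
  degenerate <- rng < 1e-12
  if (all(degenerate)) {
    stat <- rep(0, nrow(lcpm))
    p <- rep(1, nrow(lcpm))
  } else {
    design <- cbind(intercept = 1, treat = as.numeric(ti))
    fit <- limma::eBayes(limma::lmFit(lcpm, design), trend = TRUE)
    stat <- fit$t[, "treat"]
    p <- fit$p.value[, "treat"]
    stat[degenerate] <- 0
    p[degenerate] <- 1
  }

  mean_t <- rowMeans(cpm[, ti, drop = FALSE])
  mean_c <- rowMeans(cpm[, !ti, drop = FALSE])
  fc <- (mean_t + 0.5) / (mean_c + 0.5)
  expressed <- Matrix::rowSums(bulk) > 0
  p[!expressed] <- NA_real_
  fdr <- rep(NA_real_, length(p))
  fdr[expressed] <- stats::p.adjust(p[expressed], method = "BH")
  sd_log("bulk_de: %d genes, %d in BH background (row sum > 0)",
         nrow(bulk), sum(expressed))
  data.frame(
    gene = rownames(bulk),
    mean_treat = mean_t, mean_control = mean_c,
    fold_change = fc, log2_fc = log2(fc),
    statistic = as.numeric(stat), p_value = as.numeric(p), fdr = fdr,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Gate a DE result into a gene signature
#'
#' Up-genes: FDR strictly below the gate and fold change strictly above
#' `min_fc_up`. Down-genes: FDR strictly below the gate and fold change
#' strictly below `max_fc_down`. An empty signature is allowed but warned.
#'
#' @param de A data.frame with columns `gene`, `fold_change`, `fdr` (as
#'   produced by [wilcoxon_de()] or [bulk_de()]).
#' @param gates A [de_gates()] object.
#' @param name Signature name.
#' @return A [gene_signature()].
#' @export
build_signature <- function(de, gates = de_gates(), name = "signature") {
  stopifnot(all(c("gene", "fold_change", "fdr") %in% names(de)))
  ok <- !is.na(de$fdr) & de$fdr < gates$max_fdr
  up <- de$gene[ok & de$fold_change > gates$min_fc_up]
  dn <- de$gene[ok & de$fold_change < gates$max_fc_down]
  if (!length(up) && !length(dn)) warnf("build_signature: '%s' is empty", name)
  sd_log("build_signature '%s': %d up, %d down of %d genes",
         name, length(up), length(dn), nrow(de))
  gene_signature(name, up, dn)
}

#' Add curated marker genes to a signature
#'
#' Curated genes are unioned into the up set. Genes absent from the supplied
#' universe are dropped with a warning; a curated gene currently in the down
#' set is moved to the up set with a warning. Adding an already-present gene
#' is a no-op.
#'
#' @param sig A [gene_signature()].
#' @param curated_genes Character vector of curated marker gene ids.
#' @param universe Optional gene universe used to screen curated genes.
#' @return The augmented [gene_signature()].
#' @export
augment_signature <- function(sig, curated_genes, universe = NULL) {
  curated <- unique(as.character(curated_genes))
  if (!is.null(universe)) {
    absent <- setdiff(curated, universe)
    if (length(absent)) {
      warnf("augment_signature: dropping %d curated gene(s) not in universe: %s",
            length(absent), paste(absent, collapse = ", "))
      curated <- setdiff(curated, absent)
    }
  }
  conflict <- intersect(curated, sig$down_genes)
  if (length(conflict)) {
    warnf("augment_signature: moving %s from down to up", paste(conflict, collapse = ", "))
  }
  gene_signature(sig$name,
                 union(sig$up_genes, curated),
                 setdiff(sig$down_genes, conflict))
}

#' Classify clusters as ER-high or ER-low by receptor expression
#'
#' A cluster is called ER-high iff its fraction of cells expressing the
#' estrogen-receptor gene (nonzero counts) exceeds `expr_threshold`; every
#' cell inherits its cluster's call.
#'
#' @param norm Log-normalized matrix (zeros coincide with zero counts).
#' @param clusters Factor/vector of cluster labels named by cell id, or in
#'   column order of `norm`.
#' @param er_gene Receptor gene id (default `"Esr1"`, the mouse symbol).
#' @param expr_threshold Fraction-expressing cutoff in [0,1) (default 0.5).
#' @return A list: `cluster_calls` (data.frame cluster, frac_expressing,
#'   call) and `cell_calls` (data.frame cell_id, cluster, call with values
#'   `"ERhigh"`/`"ERlow"`).
#' @export
classify_er_lineage <- function(norm, clusters, er_gene = "Esr1",
                                expr_threshold = 0.5) {
  if (!er_gene %in% rownames(norm)) stopf("classify_er_lineage: gene '%s' not in matrix", er_gene)
  if (expr_threshold == 0) warnf("classify_er_lineage: threshold 0 calls every cluster with any positive cell ERhigh")
  cl <- align_cell_vector(clusters, colnames(norm), "clusters")
  pos <- as.numeric(norm[er_gene, ] > 0)
  frac <- tapply(pos, cl, mean)
  calls <- ifelse(frac > expr_threshold, "ERhigh", "ERlow")
  cluster_calls <- data.frame(cluster = names(frac),
                              frac_expressing = as.numeric(frac),
                              call = as.character(calls),
                              stringsAsFactors = FALSE)
  cell_calls <- data.frame(cell_id = colnames(norm),
                           cluster = as.character(cl),
                           call = as.character(calls[as.character(cl)]),
                           stringsAsFactors = FALSE)
  list(cluster_calls = cluster_calls, cell_calls = cell_calls)
}

# Align a per-cell vector (possibly named) with a cell-id ordering.
#' @keywords internal
#' @noRd
align_cell_vector <- function(x, cell_ids, what = "vector") {
  if (!is.null(names(x))) {
    missing <- setdiff(cell_ids, names(x))
    if (length(missing)) stopf("%s missing for %d cell(s)", what, length(missing))
    x <- x[cell_ids]
  } else if (length(x) != length(cell_ids)) {
    stopf("%s has length %d but there are %d cells", what, length(x), length(cell_ids))
  }
  x
}
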