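# Per-cell QC metrics and compartment-specific filtration.
#
# Epithelial and immune cells sequence with very different depth, so one set
# of thresholds cannot serve both: the presets below carry the published
# compartment-specific bounds (epithelial: counts > 5,000, genes > 2,000,
# mito < 8%; immune: counts > 1,000, genes > 500, mito < 8%; human: genes
# > 400 and < 7,000, mito < 20%, no total-count bound). All bounds are
# strict inequalities; boundary cells are removed.

#' QC filtration criteria
#'
#' @param preset One of `"epithelial"`, `"immune"`, `"human"`, `"custom"`.
#'   Presets fill the bounds below; `"custom"` takes them as given.
#' @param min_counts Strict lower bound on total counts (`NULL` = no bound).
#' @param min_genes Strict lower bound on detected genes.
#' @param max_genes Strict upper bound on detected genes (`NULL` = no bound).
#' @param max_pct_mito Strict upper bound on the mitochondrial count
#'   fraction, in (0, 1].
#' @return A list of class `qc_criteria`.
#' @examples
#' qc_criteria("epithelial")
#' qc_criteria("custom", min_counts = 500, min_genes = 200, max_pct_mito = 0.1)
#' @export
qc_criteria <- function(preset = c("custom", "epithelial", "immune", "human"),
                        min_counts = NULL, min_genes = NULL,
                        max_genes = NULL, max_pct_mito = NULL) {
  preset <- match.arg(preset)
  cr <- switch(preset,
    epithelial = list(min_counts = 5000, min_genes = 2000, max_genes = NULL,
                      max_pct_mito = 0.08),
    immune = list(min_counts = 1000, min_genes = 500, max_genes = NULL,
                  max_pct_mito = 0.08),
    human = list(min_counts = NULL, min_genes = 400, max_genes = 7000,
                 max_pct_mito = 0.20),
    custom = list(min_counts = min_counts, min_genes = min_genes,
                  max_genes = max_genes, max_pct_mito = max_pct_mito))
  if (preset != "custom") {
    # individual preset bounds can still be overridden explicitly
    ov <- list(min_counts = min_counts, min_genes = min_genes,
               max_genes = max_genes, max_pct_mito = max_pct_mito)
    ov <- ov[!vapply(ov, is.null, logical(1))]
    cr[names(ov)] <- ov
  }
  cr$preset <- preset
  class(cr) <- "qc_criteria"
  validate_qc_criteria(cr)
  cr
}

#' @keywords internal
#' @noRd
validate_qc_criteria <- function(cr) {
  num <- c(cr$min_counts, cr$min_genes, cr$max_genes, cr$max_pct_mito)
  if (any(num < 0)) stopf("qc_criteria: bounds must be non-negative")
  if (!is.null(cr$min_genes) && !is.null(cr$max_genes) &&
      cr$min_genes >= cr$max_genes) {
    stopf("qc_criteria: min_genes must be < max_genes")
  }
  if (!is.null(cr$max_pct_mito) &&
      (cr$max_pct_mito <= 0 || cr$max_pct_mito > 1)) {
    stopf("qc_criteria: max_pct_mito must be in (0,1]")
  }
  invisible(cr)
}

#' @export
print.qc_criteria <- function(x, ...) {
  fmt <- function(v) if (is.null(v)) "-" else format(v)
  cat(sprintf(
    "<qc_criteria> %s: counts > %s, genes > %s, genes < %s, mito < %s\n",
    x$preset, fmt(x$min_counts), fmt(x$min_genes), fmt(x$max_genes),
    fmt(x$max_pct_mito)))
  invisible(x)
}

#' Compute per-cell QC metrics
#'
#' @param counts Gene-by-cell count matrix with gene ids as rownames.
#' @param mito_prefix Prefix identifying mitochondrial gene ids (`"mt-"` for
#'   mouse, `"MT-"` for human).
#' @return A data.frame with one row per cell: `cell_id`, `n_count` (library
#'   size), `n_feature` (detected genes), `pct_mito` (mitochondrial count
#'   fraction in [0,1]; 0 for all-zero cells, which are flagged in
#'   `zero_total`).
#' @export
compute_qc_metrics <- function(counts, mito_prefix = "mt-") {
  validate_count_matrix(counts)
  mito <- startsWith(rownames(counts), mito_prefix)
  if (!any(mito)) warnf("no gene id matches mito prefix '%s'; pct_mito is 0 for all cells", mito_prefix)
  n_count <- Matrix::colSums(counts)
  n_feature <- Matrix::colSums(counts > 0)
  mito_count <- if (any(mito)) Matrix::colSums(counts[mito, , drop = FALSE]) else rep(0, ncol(counts))
  zero <- n_count == 0
  pct <- ifelse(zero, 0, mito_count / pmax(n_count, 1))
  if (any(zero)) sd_log("%d all-zero cell(s) flagged", sum(zero))
  data.frame(cell_id = colnames(counts),
             n_count = as.numeric(n_count),
             n_feature = as.integer(n_feature),
             pct_mito = as.numeric(pct),
             zero_total = zero,
             stringsAsFactors = FALSE)
}

#' Filter cells by QC criteria
#'
#' A cell is kept iff it passes every configured bound, each with a strict
#' inequality. Removal counts are reported per criterion; a cell failing
#' several bounds is counted once under each bound it fails.
#'
#' @param metrics Data.frame from [compute_qc_metrics()].
#' @param criteria A [qc_criteria()] object.
#' @return A list: `kept` (cell ids), `n_input`, `n_kept`, and `removed_by`
#'   (named integer vector of per-criterion removal counts).
#' @export
filter_cells <- function(metrics, criteria) {
  stopifnot(is.data.frame(metrics),
            all(c("cell_id", "n_count", "n_feature", "pct_mito") %in% names(metrics)))
  validate_qc_criteria(criteria)
  pass <- rep(TRUE, nrow(metrics))
  removed <- integer()
  check <- function(ok, label) {
    removed[label] <<- sum(!ok)
    pass <<- pass & ok
  }
  if (!is.null(criteria$min_counts)) check(metrics$n_count > criteria$min_counts, "min_counts")
  if (!is.null(criteria$min_genes)) check(metrics$n_feature > criteria$min_genes, "min_genes")
  if (!is.null(criteria$max_genes)) check(metrics$n_feature < criteria$max_genes, "max_genes")
  if (!is.null(criteria$max_pct_mito)) check(metrics$pct_mito < criteria$max_pct_mito, "max_pct_mito")
  sd_log("QC filter (%s): %d/%d cells kept", criteria$preset, sum(pass), nrow(metrics))
  list(kept = metrics$cell_id[pass],
       n_input = nrow(metrics),
       n_kept = sum(pass),
       removed_by = removed)
}
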