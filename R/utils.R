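# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
sd_log <- function(fmt, ...) {
  if (isTRUE(getOption("stemdyn.verbose", FALSE))) {
    message(sprintf(paste0("[stemdyn] ", fmt), ...))
  }
  invisible(NULL)
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Entries must be non-negative integers; dimnames must be unique ids.
#' @keywords internal
#' @noRd
validate_count_matrix <- function(m, what = "count matrix") {
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stopf("%s must carry gene ids (rownames) and cell ids (colnames)", what)
  }
  if (anyDuplicated(rownames(m))) stopf("%s has duplicate gene ids", what)
  if (anyDuplicated(colnames(m))) stopf("%s has duplicate cell ids", what)
  x <- if (inherits(m, "sparseMatrix")) m@x else as.numeric(m)
  if (length(x) && min(x) < 0) stopf("%s has negative entries", what)
  if (length(x) && any(abs(x - round(x)) > 1e-9)) {
    stopf("%s has non-integral entries", what)
  }
  invisible(m)
}

#' @keywords internal
#' @noRd
as_dgc <- function(m) {
  if (!inherits(m, "Matrix")) m <- Matrix::Matrix(m, sparse = TRUE)
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Derive a reproducible child seed from a base seed, kept inside 32-bit range.
#' @keywords internal
#' @noRd
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(index)) %% 2147483587)
}
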