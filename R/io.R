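#' Read a gene-by-cell count matrix from MatrixMarket triplet files
#'
#' Reads the standard sparse-matrix exchange trio used by droplet scRNA-seq
#' pipelines: a MatrixMarket coordinate file (1-based indices) plus
#' one-id-per-line TSV files for gene and cell identifiers. Entries absent
#' from the coordinate file are zero.
#'
#' @param matrix_path Path to the MatrixMarket (`.mtx`) file.
#' @param genes_path Path to the gene-id file, one id per line (first
#'   tab-separated field is used).
#' @param cells_path Path to the cell-id file, same layout.
#' @return A sparse `dgCMatrix` with genes as rows and cells as columns;
#'   dimnames carry the ids in file order.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- Matrix::sparseMatrix(i = 1, j = 1, x = 5, dims = c(2, 2))
#' dimnames(m) <- list(c("g1", "g2"), c("c1", "c2"))
#' write_count_matrix(m, file.path(dir, "m.mtx"),
#'                    file.path(dir, "genes.tsv"), file.path(dir, "cells.tsv"))
#' counts <- read_count_matrix(file.path(dir, "m.mtx"),
#'                             file.path(dir, "genes.tsv"),
#'                             file.path(dir, "cells.tsv"))
#' @export
read_count_matrix <- function(matrix_path, genes_path, cells_path) {
  m <- Matrix::readMM(matrix_path)
  gene_ids <- read_id_column(genes_path)
  cell_ids <- read_id_column(cells_path)
  if (nrow(m) != length(gene_ids)) {
    stopf("matrix declares %d rows but gene file has %d ids",
          nrow(m), length(gene_ids))
  }
  if (ncol(m) != length(cell_ids)) {
    stopf("matrix declares %d columns but cell file has %d ids",
          ncol(m), length(cell_ids))
  }
  m <- as_dgc(m)
  dimnames(m) <- list(gene_ids, cell_ids)
  validate_count_matrix(m)
  sd_log("read count matrix: %d genes x %d cells from %s",
         nrow(m), ncol(m), matrix_path)
  m
}

#' @keywords internal
#' @noRd
read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ids <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) stopf("duplicate ids in %s", path)
  ids
}

#' Write a count matrix as MatrixMarket triplet files
#'
#' Inverse of [read_count_matrix()]; indices are written 1-based per the
#' MatrixMarket standard.
#'
#' @param counts Gene-by-cell count matrix with dimnames.
#' @param matrix_path,genes_path,cells_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_count_matrix <- function(counts, matrix_path, genes_path, cells_path) {
  validate_count_matrix(counts)
  Matrix::writeMM(as_dgc(counts), matrix_path)
  writeLines(rownames(counts), genes_path)
  writeLines(colnames(counts), cells_path)
  invisible(c(matrix_path, genes_path, cells_path))
}

#' Construct a gene signature
#'
#' A signature is a named set of up-regulated genes with an optional set of
#' down-regulated genes, as produced by differential-expression gating.
#' Duplicates within a list are removed; the two lists must be disjoint.
#'
#' @param name Signature name.
#' @param up_genes Character vector of up-regulated gene ids.
#' @param down_genes Character vector of down-regulated gene ids (may be empty).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, up_genes, down_genes = character()) {
  stopifnot(is.character(name), length(name) == 1L)
  up <- unique(as.character(up_genes))
  dn <- unique(as.character(down_genes))
  overlap <- intersect(up, dn)
  if (length(overlap)) {
    stopf("signature '%s': genes in both up and down sets: %s",
          name, paste(overlap, collapse = ", "))
  }
  structure(list(name = name, up_genes = up, down_genes = dn),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s: %d up, %d down\n",
              x$name, length(x$up_genes), length(x$down_genes)))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>...`. GMT has no native
#' down-gene field, so paired signatures are encoded as two lines with
#' `_UP` / `_DN` suffixes and merged here into one signature named by the
#' common stem. A `_DN` line without a matching `_UP` line yields a signature
#' with an empty up set. Duplicate genes within a line are dropped with a
#' warning.
#'
#' @param path Path to the GMT file.
#' @return A named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  raw <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stopf("GMT line has %d field(s); need name, description and >=1 gene: %s",
            length(fields), substr(ln, 1, 60))
    }
    nm <- fields[[1]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warnf("GMT set '%s': %d duplicate gene(s) removed",
            nm, sum(duplicated(genes)))
      genes <- unique(genes)
    }
    if (nm %in% names(raw)) stopf("duplicate GMT set name '%s'", nm)
    raw[[nm]] <- genes
  }
  merge_up_dn_sets(raw)
}

#' @keywords internal
#' @noRd
merge_up_dn_sets <- function(raw) {
  nms <- names(raw)
  is_up <- grepl("_UP$", nms)
  is_dn <- grepl("_DN$", nms)
  stems <- ifelse(is_up | is_dn, sub("_(UP|DN)$", "", nms), nms)
  out <- list()
  for (stem in unique(stems)) {
    members <- nms[stems == stem]
    up <- character(); dn <- character()
    for (m in members) {
      if (grepl("_DN$", m)) dn <- c(dn, raw[[m]]) else up <- c(up, raw[[m]])
    }
    out[[stem]] <- gene_signature(stem, up, dn)
  }
  out
}

#' Write gene signatures to a GMT file
#'
#' Signatures with a non-empty down set are written as two lines with the
#' `_UP` / `_DN` suffix convention understood by [read_gmt()].
#'
#' @param signatures A list of [gene_signature()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- character()
  for (sig in signatures) {
    if (length(sig$down_genes)) {
      lines <- c(lines,
                 paste(c(paste0(sig$name, "_UP"), "up-regulated", sig$up_genes),
                       collapse = "\t"),
                 paste(c(paste0(sig$name, "_DN"), "down-regulated", sig$down_genes),
                       collapse = "\t"))
    } else {
      lines <- c(lines,
                 paste(c(sig$name, "gene set", sig$up_genes), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a rectangular table as CSV
#'
#' Deterministic column order (as given), header row, standard CSV quoting.
#' Numeric fields round-trip through [read_table()] to at least 12
#' significant digits.
#'
#' @param rows A data.frame, or a list of same-length named lists.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) {
    if (!is.list(rows)) stopf("rows must be a data.frame or a list of records")
    if (length(rows) == 0L) stopf("cannot infer columns from an empty record list; pass a data.frame")
    lens <- vapply(rows, length, integer(1))
    if (length(unique(lens)) != 1L) stopf("ragged records: lengths %s", paste(unique(lens), collapse = ","))
    nms <- names(rows[[1]])
    if (is.null(nms) || any(!nzchar(nms))) stopf("records must be named")
    if (!all(vapply(rows, function(r) identical(names(r), nms), logical(1)))) {
      stopf("records have inconsistent field names")
    }
    rows <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  utils::write.csv(format_numerics(rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @keywords internal
#' @noRd
format_numerics <- function(df, digits = 15) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(df[[j]], digits = digits, format = "g")
    }
  }
  df
}

#' Read a CSV table written by [write_table()]
#'
#' @param path Path to the CSV file.
#' @return A data.frame.
#' @export
read_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a run-configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) holding stage parameters and the
#' global random seed; returned as a nested list.
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stopf("unsupported config extension '%s' (use yaml or json)", ext))
  if (!is.list(cfg)) stopf("config did not parse to a list")
  cfg
}
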