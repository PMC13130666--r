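## ---------------------------------------------------------------------------
## Plain-text I/O: Matrix Market counts + CSV annotations, GMT gene sets.
## ---------------------------------------------------------------------------

#' Write an annotated count matrix to a directory
#'
#' Counts go to `matrix.mtx` (Matrix Market), gene annotations to
#' `genes.csv`, cell annotations to `cells.csv`.
#'
#' @param data an [annotated_counts()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_annotated_counts <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(data$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.csv(data$gene_meta, file.path(dir, "genes.csv"), row.names = FALSE)
  utils::write.csv(data$cell_meta, file.path(dir, "cells.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an annotated count matrix written by [write_annotated_counts()]
#'
#' @param dir directory containing `matrix.mtx`, `genes.csv`, `cells.csv`.
#' @return an [annotated_counts()] object.
#' @export
read_annotated_counts <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- utils::read.csv(file.path(dir, "genes.csv"), stringsAsFactors = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"), stringsAsFactors = FALSE)
  rownames(counts) <- genes$symbol
  colnames(counts) <- cells$cell_id
  cells$n_genes_detected <- NULL
  cells$mito_fraction <- NULL
  annotated_counts(counts, cells, genes)
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, genes,
#'   tab-separated).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "tumorstates") {
  lines <- vapply(names(sets), function(n)
    paste(c(n, description, sets[[n]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
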