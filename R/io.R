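#' Read a count matrix from Matrix Market or dense delimited text
#'
#' Supports the 10x-droplet layout — a coordinate-format \code{.mtx} file
#' (1-based indices, genes as rows) with companion single-column gene and
#' barcode files — and dense delimited text with a header row of cell ids
#' and gene ids in the first column.
#'
#' @param path path to the \code{.mtx} file or dense text file.
#' @param format \code{"auto"} (by extension), \code{"mtx"} or
#'   \code{"dense"}.
#' @param genes_path,barcodes_path companion files for mtx input; default
#'   to \code{genes.tsv} / \code{barcodes.tsv} next to the matrix.
#' @param sep field separator for dense input (default tab).
#' @param cells_in_rows set TRUE when a dense input is transposed
#'   (cells x genes).
#' @return A \code{\link{count_matrix}}.
#' @export
read_count_matrix <- function(path, format = c("auto", "mtx", "dense"),
                              genes_path = NULL, barcodes_path = NULL,
                              sep = "\t", cells_in_rows = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (format == "mtx") {
    m <- methods::as(Matrix::readMM(path), "CsparseMatrix")
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.tsv")
    if (is.null(barcodes_path)) barcodes_path <- file.path(dir, "barcodes.tsv")
    genes <- utils::read.table(genes_path, sep = "\t",
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.table(barcodes_path, sep = "\t",
                                  stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m))
      stop(sprintf("genes file has %d entries but matrix has %d rows",
                   length(genes), nrow(m)), call. = FALSE)
    if (length(barcodes) != ncol(m))
      stop(sprintf("barcodes file has %d entries but matrix has %d columns",
                   length(barcodes), ncol(m)), call. = FALSE)
    count_matrix(m, genes, barcodes)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("dense matrix contains non-numeric fields", call. = FALSE)
    if (cells_in_rows) m <- t(m)
    count_matrix(m)
  }
}

#' Write a count matrix in the 10x-droplet text layout
#'
#' @param cm a \code{count_matrix}.
#' @param dir output directory (created if missing); writes
#'   \code{matrix.mtx}, \code{genes.tsv}, \code{barcodes.tsv}.
#' @return \code{dir}, invisibly.
#' @export
write_count_matrix <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- cm$counts
  if (!methods::is(m, "sparseMatrix"))
    m <- Matrix::Matrix(m, sparse = TRUE)
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  writeLines(cm$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Write detection results as text artifacts
#'
#' Emits \code{cells.tsv} (cell_id, label, score), \code{clusters.json}
#' (cluster memberships, sizes, skewness, run parameters), \code{run.log}
#' (stage log, when the result carries one) and, when given,
#' \code{config.json} with the resolved configuration. The data artifacts
#' are byte-reproducible under identical input and seed; the log carries
#' wall-clock timestamps.
#'
#' @param res a \code{rare_cell_result}.
#' @param dir output directory.
#' @param config optional resolved configuration list.
#' @return \code{dir}, invisibly.
#' @export
write_result <- function(res, dir, config = NULL) {
  stopifnot(inherits(res, "rare_cell_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- data.frame(cell_id = names(res$per_cell_label),
                    label = ifelse(is.na(res$per_cell_label), "none",
                                   res$per_cell_label),
                    score = unname(res$per_cell_score))
  utils::write.table(tab, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summary <- list(
    clusters = lapply(unname(res$clusters), function(cl)
      cl[c("cluster_id", "size_k", "skewness_value", "top_cell",
           "member_cells")]),
    parameters = res$parameters)
  jsonlite::write_json(summary, file.path(dir, "clusters.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(config))
    jsonlite::write_json(config, file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(res$log))
    writeLines(res$log, file.path(dir, "run.log"))
  invisible(dir)
}
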