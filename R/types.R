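#' Construct a validated count matrix
#'
#' The basic pipeline input: a gene-by-cell matrix of non-negative integer
#' counts with unique gene and cell identifiers. Sparse
#' (\code{\link[Matrix]{dgCMatrix-class}}) and dense base matrices are both
#' accepted and preserved; downstream code only relies on \code{Matrix}
#' generics.
#'
#' @param counts gene x cell matrix-like object of non-negative integers.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   \code{rownames(counts)}.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   \code{colnames(counts)}.
#' @return An object of class \code{count_matrix} with fields \code{counts},
#'   \code{gene_ids}, \code{cell_ids}.
#' @examples
#' m <- matrix(rpois(12, 2), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' cm <- count_matrix(m)
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts)) {
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("length(gene_ids) != nrow(counts)", call. = FALSE)
  if (length(cell_ids) != ncol(counts))
    stop("length(cell_ids) != ncol(counts)", call. = FALSE)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene_ids not allowed", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("duplicate cell_ids not allowed", call. = FALSE)
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else counts
  if (any(!is.finite(vals))) stop("counts must be finite", call. = FALSE)
  if (any(vals < 0)) stop("counts must be non-negative", call. = FALSE)
  if (max(abs(vals - round(vals)), 0) > 1e-8)
    stop("counts must be integers", call. = FALSE)
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

# internal fast path: subsetting an already-validated count_matrix
new_count_matrix_unchecked <- function(counts, gene_ids, cell_ids) {
  dimnames(counts) <- list(gene_ids, cell_ids)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes x %d cells (%s storage)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (methods::is(x$counts, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

new_norm_matrix <- function(values, gene_ids, cell_ids, size_factors, method) {
  structure(list(values = values, gene_ids = gene_ids, cell_ids = cell_ids,
                 normalization_record = list(method = method,
                                             size_factors = size_factors)),
            class = "norm_matrix")
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %d genes x %d cells, normalization: %s\n",
              length(x$gene_ids), length(x$cell_ids),
              x$normalization_record$method))
  invisible(x)
}

new_feature_set <- function(selected_gene_ids, standardized_variance,
                            elbow_index) {
  stopifnot(length(selected_gene_ids) == length(standardized_variance),
            elbow_index == length(selected_gene_ids))
  structure(list(selected_gene_ids = selected_gene_ids,
                 standardized_variance = standardized_variance,
                 elbow_index = elbow_index),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> %d genes retained (top std. variance %.3g)\n",
              x$elbow_index, x$standardized_variance[1]))
  invisible(x)
}

new_embedding <- function(coordinates, explained_variance) {
  structure(list(coordinates = coordinates,
                 explained_variance = explained_variance),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells x %d components\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  invisible(x)
}

# Coordinates of an embedding-or-matrix argument; lets the core detector
# run directly on a numeric matrix in tests and iterative mode.
embedding_coords <- function(emb) {
  if (inherits(emb, "embedding")) emb$coordinates
  else as.matrix(emb)
}

new_neighbor_table <- function(neighbor_index, D, metric, cell_ids) {
  stopifnot(all(dim(neighbor_index) == dim(D)))
  structure(list(K = ncol(D), N = nrow(D), neighbor_index = neighbor_index,
                 D = D, metric = metric, cell_ids = cell_ids),
            class = "neighbor_table")
}

#' @export
print.neighbor_table <- function(x, ...) {
  cat(sprintf("<neighbor_table> %d cells, K = %d, metric = %s\n",
              x$N, x$K, x$metric))
  invisible(x)
}

#' @export
print.skewness_curve <- function(x, ...) {
  cat(sprintf("<skewness_curve> k = %d..%d, threshold %.3g, %d candidate(s)",
              min(x$k), max(x$k), x$threshold, length(x$candidate_k)))
  if (length(x$candidate_k))
    cat(": k =", paste(x$candidate_k, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
print.rare_cell_result <- function(x, ...) {
  cat(sprintf("<rare_cell_result> %d confirmed rare cluster(s)\n",
              length(x$clusters)))
  for (cl in x$clusters)
    cat(sprintf("  %s: size %d, skewness %.2f, top cell %s\n",
                cl$cluster_id, cl$size_k, cl$skewness_value, cl$top_cell))
  invisible(x)
}
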