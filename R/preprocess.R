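#' Filter genes and cells from a count matrix
#'
#' Applies the standard droplet-data quality filters: genes detected in too
#' few cells are removed first, then cells expressing too few genes. The
#' gene filter is applied once and not revisited after cells are dropped
#' (single pass), so a retained gene is guaranteed to pass its threshold
#' with respect to the pre-filter cell set.
#'
#' @param raw a \code{\link{count_matrix}}.
#' @param min_cells_per_gene keep genes with nonzero counts in at least this
#'   many cells (default 3).
#' @param min_genes_per_cell keep cells expressing at least this many genes
#'   (default 200).
#' @return A filtered \code{count_matrix}.
#' @export
filter_counts <- function(raw, min_cells_per_gene = 3,
                          min_genes_per_cell = 200) {
  stopifnot(inherits(raw, "count_matrix"),
            min_cells_per_gene >= 0, min_genes_per_cell >= 0)
  x <- raw$counts
  gene_keep <- Matrix::rowSums(x > 0) >= min_cells_per_gene
  if (!any(gene_keep))
    stop(sprintf("no genes survive filtering (min_cells_per_gene = %d)",
                 min_cells_per_gene), call. = FALSE)
  x <- x[gene_keep, , drop = FALSE]
  cell_keep <- Matrix::colSums(x > 0) >= min_genes_per_cell
  if (!any(cell_keep))
    stop(sprintf("no cells survive filtering (min_genes_per_cell = %d)",
                 min_genes_per_cell), call. = FALSE)
  x <- x[, cell_keep, drop = FALSE]
  new_count_matrix_unchecked(x, raw$gene_ids[gene_keep],
                             raw$cell_ids[cell_keep])
}

#' Global median normalization with log2 transform
#'
#' Each cell's size factor is its total count divided by the median of all
#' cell totals; normalized expression is \code{log2(count / size_factor + 1)}.
#' Zero counts map to zero, so sparse inputs stay sparse.
#'
#' @param filtered a \code{\link{count_matrix}}; every cell must have a
#'   positive total count.
#' @return A \code{norm_matrix} carrying the per-cell size factors.
#' @export
median_normalize <- function(filtered) {
  stopifnot(inherits(filtered, "count_matrix"))
  totals <- Matrix::colSums(filtered$counts)
  if (any(totals <= 0))
    stop(sprintf("cell(s) with zero total count: %s (run filter_counts first)",
                 paste(utils::head(filtered$cell_ids[totals <= 0], 5),
                       collapse = ", ")),
         call. = FALSE)
  sf <- totals / stats::median(totals)
  x <- filtered$counts
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    # scale columns on the nonzero slots only; log2(0/sf + 1) = 0
    ncol_nz <- diff(x@p)
    x@x <- log2(x@x / rep.int(sf, ncol_nz) + 1)
  } else {
    # block-wise to keep temporaries small on large dense inputs
    out <- matrix(0, nrow(x), ncol(x))
    for (s in seq(1L, ncol(x), by = 2048L)) {
      e <- min(s + 2047L, ncol(x))
      out[, s:e] <- log2(x[, s:e, drop = FALSE] /
                           rep(sf[s:e], each = nrow(x)) + 1)
    }
    dimnames(out) <- dimnames(x)
    x <- out
  }
  new_norm_matrix(x, filtered$gene_ids, filtered$cell_ids, sf, "median")
}

#' Wrap a pre-normalized matrix without renormalizing
#'
#' For inputs already normalized upstream; values are used as-is.
#' @param filtered a \code{count_matrix} (values may be any non-negative
#'   reals here; the integer check is skipped by reading the matrix field
#'   directly if needed).
#' @return A \code{norm_matrix} with unit size factors.
#' @export
skip_normalize <- function(filtered) {
  stopifnot(inherits(filtered, "count_matrix"))
  x <- filtered$counts
  if (methods::is(x, "sparseMatrix")) {
    x <- methods::as(x, "CsparseMatrix")
    x@x <- log2(x@x + 1)
  } else {
    x <- log2(x + 1)
  }
  new_norm_matrix(x, filtered$gene_ids, filtered$cell_ids,
                  rep(1, length(filtered$cell_ids)), "none")
}

#' Elbow of a non-increasing curve by maximum distance to chord
#'
#' Finds the index maximizing the perpendicular distance between the curve
#' \code{(i, values[i])} and the straight chord joining its endpoints, after
#' scaling both axes to the unit interval so the rule is scale-free.
#' When the maximizing point lies below the chord (the usual convex-decay
#' case) it is the first point of the discarded tail, so the returned elbow
#' is the index just before it; when it lies above the chord it is itself
#' the last point of the head and is returned directly. Ties go to the
#' smaller index.
#'
#' @param values numeric vector, typically sorted non-increasing.
#' @return Integer index: the number of leading points to retain.
#' @export
elbow_point <- function(values) {
  n <- length(values)
  if (n < 3) return(n)
  x <- (seq_len(n) - 1) / (n - 1)
  rng <- diff(range(values))
  if (rng == 0) return(1L)
  y <- (values - min(values)) / rng
  # signed vertical offset from chord joining (0, y1) and (1, yn);
  # perpendicular distance is |offset| / sqrt(1 + slope^2), same scaling
  # for every point, so the argmax over |offset| is the argmax distance
  off <- y - (y[1] + x * (y[n] - y[1]))
  i <- which.max(abs(off))
  if (off[i] < 0) max(i - 1L, 1L) else i
}

#' Variance-stabilized feature selection
#'
#' Ranks genes by the variance of their standardized raw counts, the "vst"
#' scheme popularized by Seurat: a local regression (span 0.3) of
#' log10(variance) on log10(mean) over all expressed genes yields a
#' predicted standard deviation per gene; counts are standardized by it,
#' clipped above at sqrt(N); the variance of the clipped standardized
#' counts is the ranking statistic. The number of genes retained is chosen
#' by \code{\link{elbow_point}} on the sorted statistic, clamped to
#' [500, 5000] when enough genes are available.
#'
#' @param norm a \code{norm_matrix} (only identifiers are used; the
#'   statistic is computed on raw counts as the scheme prescribes).
#' @param raw the \code{count_matrix} the normalized matrix came from
#'   (same gene/cell sets).
#' @param span local-regression span for the mean-variance trend.
#' @param clamp length-2 integer bounds on the number of retained genes.
#' @return A \code{feature_set}.
#' @export
vst_select_features <- function(norm, raw, span = 0.3,
                                clamp = c(500L, 5000L)) {
  stopifnot(inherits(raw, "count_matrix"))
  if (!is.null(norm)) stopifnot(inherits(norm, "norm_matrix"))
  x <- raw$counts
  n <- ncol(x)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  mu <- Matrix::rowMeans(x)
  sumsq <- Matrix::rowSums(x^2)
  v <- (sumsq - n * mu^2) / (n - 1)
  v <- pmax(v, 0)
  pos <- which(v > 0)
  if (length(pos) < 2)
    stop("fewer than 2 genes with positive variance", call. = FALSE)

  lm10 <- log10(mu[pos]); lv10 <- log10(v[pos])
  fit <- tryCatch(
    stats::fitted(stats::loess(lv10 ~ lm10, span = span,
                               degree = 2, family = "gaussian")),
    error = function(e) NULL)
  if (is.null(fit) || any(!is.finite(fit))) {
    # degenerate loess (tiny fixtures): quadratic trend in log10 space
    fit <- stats::fitted(stats::lm(lv10 ~ lm10 + I(lm10^2)))
  }
  sd_pred <- sqrt(10^fit)
  clip <- sqrt(n)

  # variance of clipped standardized counts, using the sparse structure:
  # zeros standardize to -mu/sd (never clipped upward since mu >= 0)
  std_var <- numeric(length(v))  # zero-variance genes stay 0
  if (methods::is(x, "sparseMatrix")) {
    xs <- x[pos, , drop = FALSE]
    xt <- methods::as(Matrix::t(xs), "CsparseMatrix")  # cells x genes
    p <- xt@p
    vals <- xt@x
    mpos <- mu[pos]; spos <- sd_pred
    sv <- vapply(seq_along(pos), function(j) {
      nz <- if (p[j + 1] > p[j]) vals[(p[j] + 1):p[j + 1]] else numeric(0)
      z <- pmin((nz - mpos[j]) / spos[j], clip)
      z0 <- -mpos[j] / spos[j]
      n0 <- n - length(z)
      s1 <- sum(z) + n0 * z0
      s2 <- sum(z^2) + n0 * z0^2
      (s2 - s1^2 / n) / (n - 1)
    }, numeric(1))
  } else {
    # gene blocks bound the temporaries on large dense inputs
    sv <- numeric(length(pos))
    mup <- mu[pos]
    for (s in seq(1L, length(pos), by = 512L)) {
      e <- min(s + 511L, length(pos))
      z <- pmin((x[pos[s:e], , drop = FALSE] - mup[s:e]) / sd_pred[s:e], clip)
      zm <- rowMeans(z)
      sv[s:e] <- (rowSums(z^2) - n * zm^2) / (n - 1)
    }
  }
  std_var[pos] <- sv

  ord <- order(-std_var, seq_along(std_var))
  ord <- ord[std_var[ord] > 0]
  sorted_var <- std_var[ord]

  lo <- min(clamp[1], length(ord))
  hi <- min(clamp[2], length(ord))
  if (length(ord) < clamp[1])
    warning(sprintf(
      "only %d genes with positive standardized variance (< lower bound %d); keeping all",
      length(ord), clamp[1]), call. = FALSE)
  idx <- elbow_point(sorted_var)
  idx <- max(lo, min(hi, idx))
  new_feature_set(raw$gene_ids[ord[seq_len(idx)]], sorted_var[seq_len(idx)],
                  as.integer(idx))
}

#' Principal-component embedding of selected features
#'
#' Centers and unit-variance scales each selected gene across cells
#' (constant genes are dropped), then computes cell scores on the top
#' principal components with a truncated SVD (\pkg{irlba}) for large
#' problems or a dense SVD for small ones. Component signs are fixed by
#' making each component's largest-magnitude gene loading positive.
#'
#' @param norm a \code{norm_matrix}.
#' @param features a \code{feature_set} naming the genes to embed.
#' @param n_components number of components requested (default 50); clamped
#'   with a warning when the data support fewer.
#' @param seed seed for the truncated solver's random initialization.
#' @param scale_max scaled values are clipped to \code{[-scale_max,
#'   scale_max]} (default 10, the field's standard). Without the clip,
#'   genes detected in only a few cells dominate after unit-variance
#'   scaling and cells sharing several of them masquerade as isolated
#'   rare pairs.
#' @return An \code{embedding} with cell x P \code{coordinates} and
#'   per-component \code{explained_variance}.
#' @export
pca_embed <- function(norm, features, n_components = 50, seed = 1,
                      scale_max = 10) {
  stopifnot(inherits(norm, "norm_matrix"), inherits(features, "feature_set"),
            n_components >= 2)
  sel <- match(features$selected_gene_ids, norm$gene_ids)
  if (anyNA(sel)) stop("feature_set genes absent from matrix", call. = FALSE)
  m <- Matrix::t(norm$values[sel, , drop = FALSE])   # cells x genes
  m <- as.matrix(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  m <- scale(m[, keep, drop = FALSE], center = mu[keep], scale = sdv[keep])
  m[m > scale_max] <- scale_max
  m[m < -scale_max] <- -scale_max
  n <- nrow(m); g <- ncol(m)
  max_p <- min(n - 1, g)
  if (n_components > max_p) {
    warning(sprintf("n_components clamped from %d to %d (min(#cells - 1, #features))",
                    n_components, max_p), call. = FALSE)
    n_components <- max_p
  }
  if (n_components >= max_p / 2 || min(n, g) <= 200) {
    s <- svd(m, nu = n_components, nv = n_components)
    d <- s$d[seq_len(n_components)]
    u <- s$u; v <- s$v
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    s <- irlba::irlba(m, nv = n_components, nu = n_components)
    d <- s$d; u <- s$u; v <- s$v
  }
  # deterministic sign: largest |loading| positive per component
  for (j in seq_len(n_components)) {
    i <- which.max(abs(v[, j]))
    if (v[i, j] < 0) { v[, j] <- -v[, j]; u[, j] <- -u[, j] }
  }
  scores <- u %*% diag(d, n_components, n_components)
  rownames(scores) <- norm$cell_ids
  colnames(scores) <- paste0("PC", seq_len(n_components))
  new_embedding(scores, d^2 / (n - 1))
}

#' Default neighbourhood size
#'
#' \code{K = min(max(50, ceiling(0.05 N)) + 10, N - 1)}: large enough to
#' cover rare clusters up to ~5\% of the population with headroom, never
#' exceeding N - 1.
#' @param n_cells number of cells.
#' @return Integer K.
#' @export
default_k <- function(n_cells) {
  as.integer(min(max(50, ceiling(0.05 * n_cells)) + 10, n_cells - 1))
}

#' Exact K-nearest-neighbour search
#'
#' Brute-force exact search over the embedding coordinates, blocked to
#' bound memory. Distance ties are broken by smaller cell index; self is
#' excluded. Returned distances are sorted ascending within each cell.
#'
#' @param emb an \code{embedding} or plain numeric matrix (cells x dims).
#' @param K number of neighbours, \code{2 <= K <= N - 1}.
#' @param metric \code{"euclidean"} or \code{"manhattan"}.
#' @param block_size cells per block in the blocked distance computation.
#' @return A \code{neighbor_table}.
#' @export
knn_search <- function(emb, K, metric = c("euclidean", "manhattan"),
                       block_size = 1024L) {
  metric <- match.arg(metric)
  x <- embedding_coords(emb)
  n <- nrow(x)
  if (K < 2 || K > n - 1)
    stop(sprintf("K must be in [2, %d] (N - 1); got %s", n - 1, K),
         call. = FALSE)
  idx <- matrix(0L, n, K)
  dd <- matrix(0, n, K)
  if (metric == "euclidean") sq <- rowSums(x^2)
  starts <- seq(1L, n, by = block_size)
  for (s in starts) {
    e <- min(s + block_size - 1L, n)
    rows <- s:e
    if (metric == "euclidean") {
      d2 <- sq[rows] - 2 * tcrossprod(x[rows, , drop = FALSE], x)
      d2 <- sweep(d2, 2, sq, "+")
      dblock <- sqrt(pmax(d2, 0))
    } else {
      dblock <- matrix(0, length(rows), n)
      for (j in seq_len(ncol(x)))
        dblock <- dblock + abs(outer(x[rows, j], x[, j], "-"))
    }
    for (i in seq_along(rows)) {
      m <- rows[i]
      dv <- dblock[i, ]
      dv[m] <- Inf                      # exclude self
      if (n > 4000) {
        # partial selection, then tie-stable ordering of the candidates
        kth <- sort(dv, partial = K)[K]
        cand <- which(dv <= kth)
        o <- cand[order(dv[cand], cand)][seq_len(K)]
      } else {
        o <- order(dv, seq_len(n))[seq_len(K)]
      }
      idx[m, ] <- o
      dd[m, ] <- dv[o]
    }
  }
  cid <- rownames(x)
  if (is.null(cid)) cid <- paste0("c", seq_len(n))
  new_neighbor_table(idx, dd, metric, cid)
}
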