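#' Confirm rare clusters from the skewness curve
#'
#' For each candidate size k the provisional cluster is the top cell at k
#' plus its k - 1 nearest neighbours; all k cells are tagged with
#' (k, skewness_k). A cell tagged by several candidates keeps the tag with
#' the largest skewness (ties to the smaller k). A size k is confirmed iff
#' the number of cells whose final tag is k equals exactly k — the
#' count-equals-k rule — so overlapping candidates knock each other out
#' unless one wins cleanly.
#'
#' @param curve a \code{skewness_curve}.
#' @param nbrs the \code{neighbor_table}.
#' @param ddelta_smooth the smoothed second-difference matrix (used for the
#'   per-cell score).
#' @return A \code{rare_cell_result} with confirmed \code{clusters},
#'   \code{per_cell_label} (cluster id or NA) and \code{per_cell_score}.
#' @export
assign_rare_cells <- function(curve, nbrs, ddelta_smooth) {
  stopifnot(inherits(curve, "skewness_curve"), inherits(nbrs, "neighbor_table"))
  N <- nbrs$N
  best_skew <- rep(-Inf, N)
  best_k <- rep(NA_integer_, N)
  for (k in curve$candidate_k) {
    i <- match(k, curve$k)
    top <- curve$per_k_top_cell[i]
    members <- c(top, nbrs$neighbor_index[top, seq_len(k - 1)])
    sk <- curve$skew[i]
    upd <- sk > best_skew[members] |
      (sk == best_skew[members] & k < best_k[members])
    upd[is.na(upd)] <- sk > best_skew[members][is.na(upd)]
    best_skew[members[upd]] <- sk
    best_k[members[upd]] <- k
  }
  labels <- rep(NA_character_, N)
  clusters <- list()
  confirmed <- 0L
  for (k in sort(unique(best_k[!is.na(best_k)]))) {
    cells <- which(best_k == k)
    if (length(cells) != k) next                 # count-equals-k rule
    confirmed <- confirmed + 1L
    cid <- paste0("R", confirmed)
    i <- match(k, curve$k)
    labels[cells] <- cid
    clusters[[cid]] <- list(
      cluster_id = cid, size_k = as.integer(k),
      member_cells = nbrs$cell_ids[cells], member_index = cells,
      skewness_value = curve$skew[i],
      top_cell = nbrs$cell_ids[curve$per_k_top_cell[i]])
  }
  # order clusters by decreasing skewness (discovery strength), re-id
  if (length(clusters) > 1) {
    o <- order(-vapply(clusters, `[[`, numeric(1), "skewness_value"))
    clusters <- clusters[o]
    relab <- labels
    for (j in seq_along(clusters)) {
      old <- clusters[[j]]$cluster_id
      relab[labels == old & !is.na(labels)] <- paste0("R", j)
      clusters[[j]]$cluster_id <- paste0("R", j)
    }
    labels <- relab
    names(clusters) <- vapply(clusters, `[[`, character(1), "cluster_id")
  }
  score <- per_cell_score(ddelta_smooth, curve)
  structure(list(clusters = clusters,
                 per_cell_label = stats::setNames(labels, nbrs$cell_ids),
                 per_cell_score = stats::setNames(score, nbrs$cell_ids),
                 parameters = list(threshold = curve$threshold, K = nbrs$K,
                                   metric = nbrs$metric)),
            class = "rare_cell_result")
}

#' Continuous per-cell rarity score
#'
#' \code{score(m) = max_k ddelta_smooth[m, k]} over candidate k (over all k
#' when no candidate exists), floored at 0. This is plumbing for ranking
#' comparisons (ROC/AUC), not part of the published decision rule; the
#' binary call comes from \code{\link{assign_rare_cells}}.
#'
#' @param ddelta_smooth cell x (K - 2) matrix.
#' @param curve a \code{skewness_curve}.
#' @return Numeric vector of length N, non-negative.
#' @export
per_cell_score <- function(ddelta_smooth, curve) {
  ks <- if (length(curve$candidate_k)) curve$candidate_k else curve$k
  cols <- match(ks, curve$k)
  m <- ddelta_smooth[, cols, drop = FALSE]
  pmax(apply(m, 1, max), 0)
}

#' Core detector on embedding coordinates
#'
#' Runs kNN search, gap statistics, skewness curve and assignment on a
#' ready-made embedding. Used by \code{\link{run_pipeline}} after
#' preprocessing, and directly useful for constructed-geometry studies.
#'
#' @param emb an \code{embedding} or numeric matrix (cells x dims).
#' @param k_max neighbourhood size; \code{NULL} for \code{\link{default_k}}.
#' @param metric distance metric.
#' @param threshold skewness threshold (default 2).
#' @param fence_mode see \code{\link{build_skewness_curve}}.
#' @return A \code{rare_cell_result}.
#' @export
detect_from_embedding <- function(emb, k_max = NULL,
                                  metric = c("euclidean", "manhattan"),
                                  threshold = 2,
                                  fence_mode = c("conventional", "as_printed")) {
  metric <- match.arg(metric)
  fence_mode <- match.arg(fence_mode)
  x <- embedding_coords(emb)
  if (is.null(k_max)) k_max <- default_k(nrow(x))
  nbrs <- knn_search(x, k_max, metric)
  prof <- gap_profile(nbrs)
  curve <- build_skewness_curve(prof$ddelta_smooth, nbrs, threshold, fence_mode)
  res <- assign_rare_cells(curve, nbrs, prof$ddelta_smooth)
  res$curve <- curve
  res
}

#' Iterated detection with removal of confirmed rare cells
#'
#' Runs the detector, removes the members of all confirmed clusters, and
#' repeats on the remaining cells until a round finds nothing or
#' \code{max_rounds} is reached. Because a single pass reports the rare
#' type with the largest gap most reliably, iterating uncovers further
#' hidden clusters.
#'
#' @param x a \code{count_matrix} (full pipeline per round) or numeric
#'   matrix / \code{embedding} of coordinates (core detector per round).
#' @param max_rounds maximum number of rounds, >= 1.
#' @param ... passed to \code{\link{run_pipeline}} (count input) or
#'   \code{\link{detect_from_embedding}} (coordinate input).
#' @return List of \code{rare_cell_result}, one per productive round, each
#'   with a \code{round} field.
#' @export
run_iterative <- function(x, max_rounds = 5, ...) {
  stopifnot(max_rounds >= 1)
  out <- list()
  for (round in seq_len(max_rounds)) {
    res <- tryCatch(
      if (inherits(x, "count_matrix")) run_pipeline(x, ...)
      else detect_from_embedding(x, ...),
      error = function(e)
        stop(sprintf("round %d: %s", round, conditionMessage(e)),
             call. = FALSE))
    res$round <- round
    out[[round]] <- res
    found <- unlist(lapply(res$clusters, `[[`, "member_cells"))
    if (length(found) == 0) break
    if (inherits(x, "count_matrix")) {
      keep <- !(x$cell_ids %in% found)
      x <- new_count_matrix_unchecked(x$counts[, keep, drop = FALSE],
                        x$gene_ids, x$cell_ids[keep])
    } else {
      coords <- embedding_coords(x)
      rn <- rownames(coords)
      if (is.null(rn)) rn <- paste0("c", seq_len(nrow(coords)))
      x <- coords[!(rn %in% found), , drop = FALSE]
    }
  }
  out
}
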