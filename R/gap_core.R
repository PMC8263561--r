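#' First difference of the neighbour-distance curve
#'
#' For each cell m, \code{delta[m, k] = D[m, k] - D[m, k - 1]} with the
#' convention \code{D[m, 0] = 0}, so the first column equals the distance
#' to the nearest neighbour. Because each row of D is sorted ascending,
#' every entry is non-negative.
#'
#' @param nbrs a \code{neighbor_table}.
#' @return cell x K numeric matrix.
#' @export
first_difference <- function(nbrs) {
  stopifnot(inherits(nbrs, "neighbor_table"))
  D <- nbrs$D
  cbind(D[, 1, drop = FALSE],
        D[, -1, drop = FALSE] - D[, -ncol(D), drop = FALSE])
}

#' Second difference of the neighbour-distance curve
#'
#' \code{ddelta[m, k] = 2 delta[m, k] - delta[m, k - 1] - delta[m, k + 1]}
#' for k = 2 .. K - 1. For a member of a rare cluster of size n this
#' statistic peaks at k = n, where the distance curve jumps across the gap
#' to the nearest abundant cluster.
#'
#' @param delta cell x K matrix from \code{\link{first_difference}}.
#' @return cell x (K - 2) matrix; column j corresponds to k = j + 1.
#' @export
second_difference <- function(delta) {
  K <- ncol(delta)
  if (K < 4) stop("K too small for second difference (need K >= 4)",
                  call. = FALSE)
  mid <- 2:(K - 1)
  dd <- 2 * delta[, mid, drop = FALSE] - delta[, mid - 1, drop = FALSE] -
    delta[, mid + 1, drop = FALSE]
  colnames(dd) <- paste0("k", mid)
  dd
}

#' Stabilize the second-difference table by nearest-neighbour averaging
#'
#' Each cell's value at every k is averaged with its first nearest
#' neighbour's value at the same k (computed from the unsmoothed table).
#'
#' @param ddelta cell x (K - 2) matrix.
#' @param nbrs the \code{neighbor_table} the statistics came from.
#' @return Matrix of the same shape.
#' @export
smooth_by_neighbor <- function(ddelta, nbrs) {
  stopifnot(inherits(nbrs, "neighbor_table"), nrow(ddelta) == nbrs$N)
  (ddelta + ddelta[nbrs$neighbor_index[, 1], , drop = FALSE]) / 2
}

#' Full gap profile from a neighbour table
#'
#' Convenience wrapper computing delta, ddelta and the smoothed ddelta.
#' @param nbrs a \code{neighbor_table} with K >= 4.
#' @return A \code{gap_profile} with fields \code{delta}, \code{ddelta},
#'   \code{ddelta_smooth}.
#' @export
gap_profile <- function(nbrs) {
  delta <- first_difference(nbrs)
  dd <- second_difference(delta)
  structure(list(delta = delta, ddelta = dd,
                 ddelta_smooth = smooth_by_neighbor(dd, nbrs)),
            class = "gap_profile")
}

#' Sample skewness (type 3)
#'
#' Moment-based skewness \code{g1 = m3 / m2^(3/2)} rescaled by
#' \code{((n - 1) / n)^(3/2)} — the "type 3" estimator, the default of the
#' classical R implementations.
#'
#' @param values numeric vector, length >= 3.
#' @return Skewness; 0 with a warning when the variance is zero.
#' @export
sample_skewness <- function(values) {
  n <- length(values)
  if (n < 3) stop("need at least 3 values", call. = FALSE)
  x <- values - mean(values)
  m2 <- mean(x^2)
  if (m2 == 0) {
    warning("zero variance; skewness set to 0", call. = FALSE)
    return(0)
  }
  mean(x^3) / m2^1.5 * ((n - 1) / n)^1.5
}

# Tukey fences on quartiles with the linear-interpolation convention
# (quantile type 7). fence_mode "as_printed" reproduces the near-degenerate
# published lower bound q1 + 1.5 IQR for replication studies.
fence_bounds <- function(values, fence_mode = c("conventional", "as_printed")) {
  fence_mode <- match.arg(fence_mode)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- if (fence_mode == "conventional") q[1] - 1.5 * iqr else q[1] + 1.5 * iqr
  c(lo, q[2] + 1.5 * iqr)
}

#' Skewness statistic at one candidate cluster size
#'
#' At neighbour index k the statistic asks: if a rare cluster of exactly k
#' cells existed, how strongly would its members' smoothed second
#' differences stand out from the abundant background? Steps: (a) take the
#' N smoothed values at this k and identify the top cell (largest value,
#' ties to the smaller index); (b) remove the k largest values; (c) keep
#' the remaining values inside the Tukey fences as the abundant set;
#' (d) average the values of the top cell and its k - 1 nearest neighbours
#' into a robust rare-cell representative r; (e) append exactly two copies
#' of r (two rather than k, to keep sensitivity for larger clusters);
#' (f) return the skewness of the combined vector.
#'
#' @param ddelta_smooth cell x (K - 2) smoothed second-difference matrix.
#' @param nbrs the \code{neighbor_table}.
#' @param k candidate cluster size, \code{2 <= k <= K - 1}.
#' @param fence_mode fence convention, see \code{\link{build_skewness_curve}}.
#' @return List with \code{skew}, \code{top_cell} (row index), \code{r}.
#' @export
skewness_at_k <- function(ddelta_smooth, nbrs, k,
                          fence_mode = c("conventional", "as_printed")) {
  fence_mode <- match.arg(fence_mode)
  K <- nbrs$K
  if (k < 2 || k > K - 1)
    stop(sprintf("k must be in [2, %d]", K - 1), call. = FALSE)
  v <- ddelta_smooth[, k - 1]
  top <- which.max(v)                       # ties -> smaller index
  ord <- order(v, seq_along(v), decreasing = c(TRUE, FALSE), method = "radix")
  rest <- v[ord[-seq_len(k)]]               # top k values removed
  fb <- fence_bounds(rest, fence_mode)
  abundant <- rest[rest >= fb[1] & rest <= fb[2]]
  r <- mean(v[c(top, nbrs$neighbor_index[top, seq_len(k - 1)])])
  if (length(abundant) < 3) {
    warning(sprintf("fewer than 3 abundant values after fencing at k = %d", k),
            call. = FALSE)
    return(list(skew = 0, top_cell = top, r = r))
  }
  list(skew = sample_skewness(c(abundant, r, r)), top_cell = top, r = r)
}

#' Dump gap-statistic tables to delimited text for inspection
#'
#' Writes \code{delta.tsv}, \code{ddelta.tsv}, \code{ddelta_smooth.tsv}
#' and \code{skew.tsv} into a directory.
#'
#' @param profile a \code{gap_profile}.
#' @param curve an optional \code{skewness_curve}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
dump_gap_tables <- function(profile, curve = NULL, dir) {
  stopifnot(inherits(profile, "gap_profile"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  wr(profile$delta, "delta.tsv")
  wr(profile$ddelta, "ddelta.tsv")
  wr(profile$ddelta_smooth, "ddelta_smooth.tsv")
  if (!is.null(curve))
    wr(data.frame(k = curve$k, skew = curve$skew,
                  candidate = curve$k %in% curve$candidate_k,
                  top_cell = curve$per_k_top_cell), "skew.tsv")
  invisible(dir)
}

#' Skewness curve over all candidate cluster sizes
#'
#' Evaluates \code{\link{skewness_at_k}} for every k in 2 .. K - 1 and
#' flags candidate sizes whose skewness exceeds the threshold (default 2).
#'
#' @param ddelta_smooth cell x (K - 2) smoothed second-difference matrix.
#' @param nbrs the \code{neighbor_table}.
#' @param threshold candidate flagging threshold on the skewness.
#' @param fence_mode \code{"conventional"} for the standard Tukey fences
#'   \code{[q1 - 1.5 IQR, q3 + 1.5 IQR]} (default), \code{"as_printed"} for
#'   the published lower bound \code{q1 + 1.5 IQR}.
#' @return A \code{skewness_curve} with fields \code{k}, \code{skew},
#'   \code{candidate_k}, \code{per_k_top_cell}, \code{threshold}.
#' @export
build_skewness_curve <- function(ddelta_smooth, nbrs, threshold = 2,
                                 fence_mode = c("conventional", "as_printed")) {
  fence_mode <- match.arg(fence_mode)
  ks <- 2:(nbrs$K - 1)
  skew <- numeric(length(ks))
  top <- integer(length(ks))
  for (i in seq_along(ks)) {
    s <- skewness_at_k(ddelta_smooth, nbrs, ks[i], fence_mode)
    skew[i] <- s$skew
    top[i] <- s$top_cell
  }
  structure(list(k = ks, skew = skew, threshold = threshold,
                 candidate_k = ks[skew > threshold],
                 per_k_top_cell = top),
            class = "skewness_curve")
}
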