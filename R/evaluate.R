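#' Confusion counts for rare-vs-not prediction
#'
#' @param predicted character/integer vector of cells called rare.
#' @param truth vector of truly rare cells.
#' @param all_cells vector of all cell identifiers (defines N).
#' @return A \code{confusion_counts} list with TP, FP, FN, TN.
#' @export
confusion_counts <- function(predicted, truth, all_cells) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  if (!all(predicted %in% all_cells) || !all(truth %in% all_cells))
    stop("predicted/truth must be subsets of all_cells", call. = FALSE)
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  tn <- length(all_cells) - tp - fp - fn
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn),
            class = "confusion_counts")
}

#' F1 score (harmonic mean of precision and recall)
#'
#' Returns 0 when precision + recall is 0 (no true positives).
#' @param c a \code{confusion_counts}.
#' @return F1 in [0, 1].
#' @export
f1_score <- function(c) {
  if (c$TP == 0) return(0)
  prec <- c$TP / (c$TP + c$FP)
  rec <- c$TP / (c$TP + c$FN)
  2 * prec * rec / (prec + rec)
}

#' Sensitivity and specificity
#'
#' An undefined ratio (zero denominator) is reported as NA, never silently
#' as 0.
#' @param c a \code{confusion_counts}.
#' @return Named numeric vector \code{c(sensitivity, specificity)}.
#' @export
sensitivity_specificity <- function(c) {
  sens <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  spec <- if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Rank AUC of a continuous score against binary truth
#'
#' The probability that a random positive outranks a random negative,
#' ties counted one half (the rank-sum formulation of the area under the
#' ROC curve).
#'
#' @param scores named numeric vector of per-cell scores.
#' @param truth vector of truly rare cell names (the positives).
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(scores, truth) {
  pos <- names(scores) %in% truth
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Two-sided rank-sum p for one gene; exact (no ties, small n) else normal
# approximation with tie correction and continuity correction.
rank_sum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  if (length(unique(c(a, b))) == 1) return(1)
  r <- rank(c(a, b), ties.method = "average")
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- table(c(a, b))
  if (m + n < 50 && all(ties == 1)) {
    p <- 2 * min(stats::pwilcox(U, m, n), 1 - stats::pwilcox(U - 1, m, n))
    return(min(p, 1))
  }
  mu <- m * n / 2
  tie_term <- sum(ties^3 - ties) / ((m + n) * (m + n - 1))
  sig <- sqrt(m * n / 12 * (m + n + 1 - tie_term))
  if (sig == 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sig
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per gene: a two-sided rank-sum test on normalized expression, a log2
#' fold-change computed as the difference of group-wise mean (log2)
#' expression, Benjamini-Hochberg adjustment across tested genes, and a DE
#' flag at the stated cutoffs. An optional raw-count pre-filter restricts
#' testing to genes whose counts exceed \code{prefilter_count} in at least
#' \code{prefilter_cells} cells.
#'
#' @param norm a \code{norm_matrix}.
#' @param group_a,group_b cell id vectors, each >= 2 cells.
#' @param fdr adjusted-p cutoff for the DE flag (default 0.05).
#' @param lfc absolute log2 fold-change cutoff for the DE flag (default 1).
#' @param raw optional \code{count_matrix} for the pre-filter.
#' @param prefilter_count,prefilter_cells raw-count pre-filter (used only
#'   when \code{raw} is given; default: counts > 2 in >= 3 cells).
#' @return A data.frame (gene, log2fc, p, p_adj, de).
#' @export
wilcoxon_de <- function(norm, group_a, group_b, fdr = 0.05, lfc = 1,
                        raw = NULL, prefilter_count = 2, prefilter_cells = 3) {
  stopifnot(inherits(norm, "norm_matrix"),
            length(group_a) >= 2, length(group_b) >= 2)
  ia <- match(group_a, norm$cell_ids)
  ib <- match(group_b, norm$cell_ids)
  if (anyNA(ia) || anyNA(ib)) stop("unknown cell ids", call. = FALSE)
  genes <- norm$gene_ids
  if (!is.null(raw)) {
    keep <- Matrix::rowSums(raw$counts > prefilter_count) >= prefilter_cells
    genes <- intersect(genes, raw$gene_ids[keep])
  }
  gi <- match(genes, norm$gene_ids)
  xa <- as.matrix(norm$values[gi, ia, drop = FALSE])
  xb <- as.matrix(norm$values[gi, ib, drop = FALSE])
  l2fc <- rowMeans(xa) - rowMeans(xb)
  p <- vapply(seq_along(gi), function(i) rank_sum_p(xa[i, ], xb[i, ]),
              numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(gene = genes, log2fc = l2fc, p = p, p_adj = p_adj,
             de = p_adj < fdr & abs(l2fc) > lfc,
             row.names = NULL, stringsAsFactors = FALSE)
}
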