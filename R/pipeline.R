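#' Resolved run configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults
#' reproduce the published settings where stated (gene/cell filters,
#' 50 components, skewness threshold 2, euclidean metric, median
#' normalization).
#'
#' @param min_cells_per_gene,min_genes_per_cell quality filters.
#' @param normalization \code{"median"} or \code{"none"} (input already
#'   normalized).
#' @param n_pcs number of principal components.
#' @param k_max neighbourhood size; \code{NULL} = \code{\link{default_k}}.
#' @param metric \code{"euclidean"} or \code{"manhattan"}.
#' @param skew_threshold candidate skewness threshold.
#' @param fence_mode Tukey-fence convention.
#' @param seed integer seed for all stochastic steps.
#' @param output_dir optional directory for result artifacts.
#' @param max_rounds rounds for iterative mode.
#' @return A \code{run_config} list.
#' @export
run_config <- function(min_cells_per_gene = 3, min_genes_per_cell = 200,
                       normalization = c("median", "none"),
                       n_pcs = 50, k_max = NULL,
                       metric = c("euclidean", "manhattan"),
                       skew_threshold = 2,
                       fence_mode = c("conventional", "as_printed"),
                       seed = 1, output_dir = NULL, max_rounds = 1) {
  structure(list(min_cells_per_gene = min_cells_per_gene,
                 min_genes_per_cell = min_genes_per_cell,
                 normalization = match.arg(normalization),
                 n_pcs = n_pcs, k_max = k_max,
                 metric = match.arg(metric),
                 skew_threshold = skew_threshold,
                 fence_mode = match.arg(fence_mode),
                 seed = as.integer(seed), output_dir = output_dir,
                 max_rounds = max_rounds),
            class = "run_config")
}

pipeline_log <- function(verbose, fmt, ..., sink = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  if (!is.null(sink)) sink$lines <- c(sink$lines, line)
  if (verbose) message(line)
  invisible(line)
}

#' Run the full rare-cell detection pipeline on a count matrix
#'
#' Stages: gene/cell filtering, median normalization (log2), variance-
#' stabilized feature selection, PCA embedding, exact kNN search,
#' distance-difference statistics, skewness curve, cluster assignment.
#' Deterministic under a fixed seed.
#'
#' @param counts a \code{\link{count_matrix}}.
#' @param config a \code{\link{run_config}}; individual fields can be
#'   overridden through \code{...}.
#' @param verbose log stage progress and dimensions.
#' @param ... overrides for \code{run_config} fields.
#' @return A \code{rare_cell_result}; the skewness curve is attached as
#'   \code{$curve} and the resolved config as \code{$config}. Artifacts are
#'   written when \code{output_dir} is set.
#' @export
run_pipeline <- function(counts, config = run_config(), verbose = FALSE, ...) {
  stopifnot(inherits(counts, "count_matrix"))
  dots <- list(...)
  if (length(dots)) config[names(dots)] <- dots
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  t0 <- Sys.time()
  logs <- new.env(); logs$lines <- character(0)
  pipeline_log(verbose, "input: %d genes x %d cells",
               nrow(counts$counts), ncol(counts$counts), sink = logs)
  filtered <- stage("filter", filter_counts(counts, config$min_cells_per_gene,
                                            config$min_genes_per_cell))
  pipeline_log(verbose, "filtered: %d genes x %d cells",
               nrow(filtered$counts), ncol(filtered$counts), sink = logs)
  norm <- stage("normalize",
                if (config$normalization == "median") median_normalize(filtered)
                else skip_normalize(filtered))
  feats <- stage("features", vst_select_features(norm, filtered))
  pipeline_log(verbose, "features: %d genes retained", feats$elbow_index, sink = logs)
  rm(filtered)                      # large intermediates: release eagerly
  emb <- stage("pca", pca_embed(norm, feats, config$n_pcs, seed = config$seed))
  pipeline_log(verbose, "embedding: %d components", ncol(emb$coordinates), sink = logs)
  rm(norm); invisible(gc(verbose = FALSE))
  k_max <- if (is.null(config$k_max)) default_k(nrow(emb$coordinates))
           else config$k_max
  res <- stage("detect",
               detect_from_embedding(emb, k_max, config$metric,
                                     config$skew_threshold,
                                     config$fence_mode))
  res$parameters$seed <- config$seed
  res$config <- config
  pipeline_log(verbose, "done in %.1fs: %d cluster(s)",
               as.numeric(difftime(Sys.time(), t0, units = "secs")),
               length(res$clusters), sink = logs)
  res$log <- logs$lines
  if (!is.null(config$output_dir))
    write_result(res, config$output_dir, unclass(config))
  res
}

#' One-call rare cell detection
#'
#' \code{detect_rare_cells(cm)} is \code{run_pipeline} with defaults;
#' arguments are \code{run_config} fields.
#' @param counts a \code{count_matrix}.
#' @param ... \code{\link{run_config}} fields.
#' @param verbose log progress.
#' @return A \code{rare_cell_result}.
#' @export
detect_rare_cells <- function(counts, ..., verbose = FALSE) {
  run_pipeline(counts, run_config(...), verbose = verbose)
}
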