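#' Simulation parameters for the gamma-Poisson group simulator
#'
#' A minimal "groups mode" of the Splat-style generative model: gene base
#' means are Gamma(mean_shape, mean_rate); per group, each gene is
#' differentially expressed with probability \code{de_prob}, multiplying
#' its mean by a log-normal factor (inverted with probability 1/2 so both
#' up- and down-regulation occur); cell library sizes are log-normal; the
#' expected count of gene g in cell c is the library size times the
#' group's normalized mean profile; counts are Poisson. Optional zero
#' inflation drops each entry with probability
#' \code{plogis(dropout_shape * (log(rate) - dropout_mid))} — with the
#' default \code{dropout_shape = -1}, lowly expressed entries drop out
#' more, and raising \code{dropout_mid} raises the overall zero fraction.
#' No batch effects, mean-variance (BCV) trend, or trajectory paths.
#'
#' Defaults follow the cited simulator's documented defaults; group sizes
#' default to 1200 cells in three groups at ratio 10:45:45.
#'
#' @param n_genes number of genes.
#' @param group_sizes integer vector of cells per group.
#' @param de_prob probability a gene is DE in a group.
#' @param de_fac_loc,de_fac_scale log-normal meanlog/sdlog of DE factors.
#' @param mean_shape,mean_rate gamma parameters of base gene means.
#' @param lib_loc,lib_scale log-normal meanlog/sdlog of library sizes.
#' @param dropout_mid logistic midpoint of the dropout curve; \code{NA}
#'   (default) disables dropout.
#' @param dropout_shape logistic slope of the dropout curve.
#' @param seed integer seed; every draw is reproducible from it.
#' @return A \code{sim_params} list.
#' @export
sim_params <- function(n_genes = 5000, group_sizes = c(120, 540, 540),
                       de_prob = 0.1, de_fac_loc = 0.1, de_fac_scale = 0.4,
                       mean_shape = 0.6, mean_rate = 0.3,
                       lib_loc = 11, lib_scale = 0.2,
                       dropout_mid = NA_real_, dropout_shape = -1,
                       seed = 1) {
  stopifnot(n_genes >= 1, all(group_sizes >= 1),
            de_prob >= 0, de_prob <= 1,
            de_fac_scale > 0, mean_shape > 0, mean_rate > 0, lib_scale > 0)
  structure(list(n_genes = as.integer(n_genes),
                 group_sizes = as.integer(group_sizes),
                 de_prob = de_prob, de_fac_loc = de_fac_loc,
                 de_fac_scale = de_fac_scale, mean_shape = mean_shape,
                 mean_rate = mean_rate, lib_loc = lib_loc,
                 lib_scale = lib_scale, dropout_mid = dropout_mid,
                 dropout_shape = dropout_shape, seed = as.integer(seed)),
            class = "sim_params")
}

#' The dropout-midpoint grid of the benchmarking protocol
#' @return Numeric vector of dropout_mid values spanning low to high
#'   zero-inflation.
#' @export
dropout_mid_grid <- function() {
  c(0.1068, 0.2033, 0.3090, 0.4050, 0.5023, 0.6078, 0.7041, 0.8026, 0.9067)
}

#' The DE-probability grid of the benchmarking protocol
#' @return Numeric vector of de_prob values.
#' @export
de_prob_grid <- function() c(0.1, 0.2, 0.4, 0.6, 0.8)

#' Simulate a grouped single-cell count matrix
#'
#' @param params a \code{\link{sim_params}} object.
#' @param chunk_size cells generated per chunk (memory bound for large
#'   simulations).
#' @return A \code{simulated_dataset}: fields \code{counts}
#'   (\code{count_matrix}), \code{true_labels} (named integer group per
#'   cell), \code{de_gene_flags} (gene x group logical), \code{params}.
#' @export
simulate_counts <- function(params, chunk_size = 2000L) {
  stopifnot(inherits(params, "sim_params"))
  G <- params$n_genes
  sizes <- params$group_sizes
  n_groups <- length(sizes)
  N <- sum(sizes)
  if (G < 1 || N < 1) stop("degenerate simulation size", call. = FALSE)
  set.seed(params$seed)

  base_mean <- stats::rgamma(G, shape = params$mean_shape,
                             rate = params$mean_rate)
  de_flags <- matrix(FALSE, G, n_groups)
  group_mean <- matrix(base_mean, G, n_groups)
  for (g in seq_len(n_groups)) {
    de <- stats::runif(G) < params$de_prob
    fac <- stats::rlnorm(G, params$de_fac_loc, params$de_fac_scale)
    flip <- stats::runif(G) < 0.5
    fac[flip] <- 1 / fac[flip]
    de_flags[, g] <- de
    group_mean[de, g] <- base_mean[de] * fac[de]
  }
  profile <- sweep(group_mean, 2, colSums(group_mean), "/")

  lib <- stats::rlnorm(N, params$lib_loc, params$lib_scale)
  labels <- rep(seq_len(n_groups), sizes)

  counts <- matrix(0L, G, N)         # integer storage halves the footprint
  use_drop <- is.finite(params$dropout_mid)
  for (s in seq(1L, N, by = chunk_size)) {
    e <- min(s + chunk_size - 1L, N)
    cols <- s:e
    rate <- profile[, labels[cols], drop = FALSE] *
      rep(lib[cols], each = G)
    cc <- stats::rpois(length(rate), rate)
    if (use_drop) {
      p_drop <- stats::plogis(params$dropout_shape *
                                (log(rate) - params$dropout_mid))
      cc[stats::runif(length(cc)) < p_drop] <- 0L
    }
    counts[, cols] <- cc
  }
  if (mean(counts == 0) > 0.4)
    counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  gene_ids <- sprintf("gene%0*d", nchar(G), seq_len(G))
  cell_ids <- sprintf("cell%0*d", nchar(N), seq_len(N))
  cm <- new_count_matrix_unchecked(counts, gene_ids, cell_ids)
  structure(list(counts = cm,
                 true_labels = stats::setNames(labels, cell_ids),
                 de_gene_flags = de_flags, params = params),
            class = "simulated_dataset")
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d genes x %d cells, %d group(s) (%s), de_prob %.2g\n",
              length(x$counts$gene_ids), length(x$counts$cell_ids),
              length(x$params$group_sizes),
              paste(x$params$group_sizes, collapse = ":"),
              x$params$de_prob))
  invisible(x)
}

#' Plant a rare group by subsampling a simulated dataset
#'
#' Simulates the full grouped dataset described by \code{params}, then
#' subsamples \code{rare_size} cells from group 1 and \code{major_sizes}
#' cells from the following groups, preserving ground-truth labels. This
#' mirrors the benchmarking design in which a large three-group simulation
#' is repeatedly subsampled to datasets with a planted rare type.
#'
#' @param params a \code{sim_params}; group 1 is the rare-type pool.
#' @param rare_size number of rare cells to plant (>= 2).
#' @param major_sizes cells drawn from groups 2, 3, ... (recycled order).
#' @param sim optional pre-simulated dataset from the same \code{params},
#'   to subsample repeatedly without re-simulating.
#' @param seed subsampling seed; defaults to \code{params$seed}.
#' @return A \code{simulated_dataset} of the subsample; labels are 1 for
#'   rare, 2, 3, ... for majors.
#' @export
plant_rare_group <- function(params, rare_size, major_sizes = c(500, 500),
                             sim = NULL, seed = params$seed) {
  stopifnot(rare_size >= 2)
  if (is.null(sim)) sim <- simulate_counts(params)
  sizes <- c(rare_size, major_sizes)
  pools <- sim$params$group_sizes
  if (length(sizes) > length(pools))
    stop("more major_sizes than simulated groups", call. = FALSE)
  if (any(sizes > pools[seq_along(sizes)]))
    stop(sprintf("requested sizes (%s) exceed simulated group sizes (%s)",
                 paste(sizes, collapse = ","),
                 paste(pools[seq_along(sizes)], collapse = ",")),
         call. = FALSE)
  set.seed(seed)
  take <- unlist(lapply(seq_along(sizes), function(g) {
    pool <- which(sim$true_labels == g)
    sort(sample(pool, sizes[g]))
  }))
  cm <- sim$counts
  sub <- new_count_matrix_unchecked(cm$counts[, take, drop = FALSE],
                      cm$gene_ids, cm$cell_ids[take])
  structure(list(counts = sub,
                 true_labels = sim$true_labels[take],
                 de_gene_flags = sim$de_gene_flags,
                 params = sim$params,
                 rare_cells = cm$cell_ids[take[seq_len(rare_size)]]),
            class = "simulated_dataset")
}

#' Swap differentially expressed genes into a DE-depleted dataset
#'
#' Sensitivity-to-DE-genes design: starting from the dataset with the DE
#' pool held out (the base set is all genes except \code{de_pool}),
#' \code{r} randomly chosen genes from \code{non_de_pool} are swapped out
#' and \code{r} genes from \code{de_pool} swapped back in, keeping the
#' total gene count constant. \code{r = 0} returns the base set unchanged.
#'
#' @param data a \code{simulated_dataset} containing all genes.
#' @param de_pool gene ids held out as the DE reservoir.
#' @param non_de_pool gene ids eligible for removal.
#' @param r number of genes to swap, \code{0 <= r <= min(|pools|)}.
#' @param seed swap seed.
#' @return A \code{simulated_dataset} on the modified gene set; the swap is
#'   recorded in field \code{swap}.
#' @export
replace_genes <- function(data, de_pool, non_de_pool, r, seed = 1) {
  stopifnot(inherits(data, "simulated_dataset"))
  genes <- data$counts$gene_ids
  de_pool <- intersect(de_pool, genes)
  non_de_pool <- intersect(non_de_pool, genes)
  if (length(intersect(de_pool, non_de_pool)))
    stop("de_pool and non_de_pool must be disjoint", call. = FALSE)
  if (r > min(length(de_pool), length(non_de_pool)))
    stop(sprintf("r = %d exhausts a pool (|de| = %d, |non-de| = %d)",
                 r, length(de_pool), length(non_de_pool)), call. = FALSE)
  set.seed(seed)
  de_in <- if (r > 0) sample(de_pool, r) else character(0)
  nde_out <- if (r > 0) sample(non_de_pool, r) else character(0)
  keep <- setdiff(genes, de_pool)        # base set: DE pool held out
  keep <- setdiff(keep, nde_out)
  keep <- genes[genes %in% c(keep, de_in)]   # original gene order
  cm <- data$counts
  out <- data
  out$counts <- new_count_matrix_unchecked(cm$counts[match(keep, genes), , drop = FALSE],
                             keep, cm$cell_ids)
  out$swap <- list(r = r, genes_in = de_in, genes_out = nde_out)
  out
}
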