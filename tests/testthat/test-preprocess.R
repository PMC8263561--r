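test_that("filter_counts applies gene-then-cell thresholds in one pass", {
  m <- matrix(c(1, 2, 0, 3,
                0, 1, 4, 2,
                0, 0, 5, 0), 3, 4, byrow = TRUE,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  cm <- count_matrix(m)
  f <- filter_counts(cm, min_cells_per_gene = 2, min_genes_per_cell = 0)
  expect_setequal(f$gene_ids, c("g1", "g2"))
  expect_equal(f$cell_ids, cm$cell_ids)

  expect_identical(filter_counts(cm, 0, 0)$counts, cm$counts)

  # brute-force predicate oracle on a random sparse fixture
  set.seed(11)
  big <- matrix(rbinom(200 * 100, 4, 0.05), 200, 100)
  bm <- count_matrix(big)
  ff <- filter_counts(bm, 3, 20)
  gene_keep <- vapply(seq_len(200), function(g) sum(big[g, ] > 0) >= 3,
                      logical(1))
  cell_keep <- vapply(seq_len(100), function(c)
    sum(big[gene_keep, c] > 0) >= 20, logical(1))
  expect_equal(ff$gene_ids, bm$gene_ids[gene_keep])
  expect_equal(ff$cell_ids, bm$cell_ids[cell_keep])

  expect_error(filter_counts(bm, 101, 0), "no genes survive")
  expect_error(filter_counts(bm, 0, 1000), "no cells survive")
})

test_that("median_normalize computes size factors and conserves structure", {
  m <- matrix(c(50, 100, 200,
                50, 100, 200), 2, 3, byrow = TRUE)
  nm <- median_normalize(count_matrix(m))
  expect_equal(unname(nm$normalization_record$size_factors), c(0.5, 1, 2))

  same <- count_matrix(matrix(c(3, 3, 1, 1, 2, 2), 3, 2, byrow = TRUE))
  nm2 <- median_normalize(same)
  expect_equal(unname(nm2$normalization_record$size_factors), c(1, 1))
  expect_equal(as.matrix(nm2$values), log2(as.matrix(same$counts) + 1),
               ignore_attr = TRUE)

  # conservation: totals divided by size factors all equal the median total
  set.seed(3)
  r <- count_matrix(matrix(rpois(300, 5) + 1, 20, 15))
  nr <- median_normalize(r)
  totals <- Matrix::colSums(r$counts)
  expect_equal(unname(totals / nr$normalization_record$size_factors),
               rep(median(totals), 15))

  # rank order of genes within each cell is conserved
  expect_equal(apply(as.matrix(nr$values), 2, rank),
               apply(as.matrix(r$counts), 2, rank))

  # sparse input stays sparse with identical values
  rs <- count_matrix(Matrix::Matrix(as.matrix(r$counts), sparse = TRUE))
  ns <- median_normalize(rs)
  expect_s4_class(ns$values, "sparseMatrix")
  expect_equal(as.matrix(ns$values), as.matrix(nr$values),
               ignore_attr = TRUE)

  zero <- count_matrix(matrix(c(1, 2, 0, 0), 2, 2))
  expect_error(median_normalize(zero), "zero total")
})

test_that("elbow_point matches the brute-force chord oracle", {
  expect_equal(elbow_point(c(10, 9.5, 9, 1, 0.9, 0.8, 0.7, 0.6, 0.5,
                             0.4, 0.3, 0.2, 0.1)), 3)
  set.seed(5)
  for (i in 1:20) {
    v <- sort(rexp(sample(10:200, 1), rate = runif(1, 0.1, 2)),
              decreasing = TRUE)
    expect_equal(elbow_point(v), oracle_elbow(v))
  }
})

test_that("vst feature selection ranks planted high-variance genes on top", {
  set.seed(7)
  n_genes <- 1000; n_cells <- 200
  base <- rgamma(n_genes, 2, 0.5)
  counts <- matrix(rpois(n_genes * n_cells, base), n_genes, n_cells)
  # 50 moderately expressed genes with an 8-fold shift in half the cells
  # (kept inside the populated mean range so the mean-variance trend is
  # anchored by unshifted genes there)
  shifted <- sample(setdiff(which(base > 0.5 & base < 2), 1), 50)
  grp <- seq_len(n_cells / 2)
  counts[shifted, grp] <- rpois(50 * length(grp), base[shifted] * 8)
  counts[1, ] <- 5                                    # a constant gene
  cm <- count_matrix(counts)
  nm <- median_normalize(cm)
  fs <- suppressWarnings(vst_select_features(nm, cm))
  expect_false("g1" %in% fs$selected_gene_ids)         # constant: never selected
  ranks <- match(paste0("g", shifted), fs$selected_gene_ids)
  expect_true(all(!is.na(ranks)) && all(ranks <= 100))
  expect_true(all(diff(fs$standardized_variance) <= 1e-12))
  expect_equal(fs$elbow_index, length(fs$selected_gene_ids))

  const <- count_matrix(matrix(3, 10, 5))
  expect_error(suppressWarnings(vst_select_features(NULL, const)),
               "positive variance")
})

test_that("pca_embed agrees with a dense eigendecomposition oracle", {
  set.seed(13)
  counts <- matrix(rpois(20 * 10, 10), 10, 20)     # 10 genes x 20 cells
  cm <- count_matrix(counts)
  nm <- median_normalize(cm)
  fs <- suppressWarnings(vst_select_features(nm, cm))
  emb <- suppressWarnings(pca_embed(nm, fs, n_components = 5))

  x <- t(as.matrix(nm$values[match(fs$selected_gene_ids, nm$gene_ids), ]))
  x <- scale(x)
  x <- x[, attr(x, "scaled:scale") > 0, drop = FALSE]
  x <- pmin(pmax(x, -10), 10)
  eg <- eigen(crossprod(x), symmetric = TRUE)
  scores <- x %*% eg$vectors[, 1:5]
  for (j in 1:5) {
    a <- emb$coordinates[, j]; b <- scores[, j]
    expect_lt(min(sum((a - b)^2), sum((a + b)^2)) / sum(b^2), 1e-16)
  }
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
})

test_that("pca_embed handles rank deficiency, duplicates and clamping", {
  set.seed(17)
  # cells exactly on a 2-D plane in feature space
  basis <- matrix(rnorm(2 * 12), 2, 12)
  coefs <- matrix(rnorm(30 * 2), 30, 2)
  vals <- coefs %*% basis + 5
  nm <- scgap:::new_norm_matrix(t(vals), paste0("g", 1:12),
                                paste0("c", 1:30), rep(1, 30), "none")
  fs <- scgap:::new_feature_set(paste0("g", 1:12), rep(1, 12), 12L)
  emb <- suppressWarnings(pca_embed(nm, fs, n_components = 6))
  expect_true(all(emb$explained_variance[3:6] <=
                    1e-8 * emb$explained_variance[1]))

  # duplicated cells embed identically
  vals2 <- cbind(vals[c(1:10, 1), ], 0)  # cell 11 duplicates cell 1
  counts <- matrix(rpois(11 * 8, 20), 8, 11)
  counts[, 11] <- counts[, 1]
  cm <- count_matrix(counts)
  nmd <- median_normalize(cm)
  fsd <- suppressWarnings(vst_select_features(nmd, cm))
  ed <- suppressWarnings(pca_embed(nmd, fsd, n_components = 3))
  expect_equal(ed$coordinates[11, ], ed$coordinates[1, ], ignore_attr = TRUE)

  expect_warning(pca_embed(nmd, fsd, n_components = 50), "clamped")
})

test_that("full-rank embedding preserves pairwise distances of scaled data", {
  set.seed(19)
  counts <- matrix(rpois(25 * 8, 15), 8, 25)
  cm <- count_matrix(counts)
  nm <- median_normalize(cm)
  fs <- suppressWarnings(vst_select_features(nm, cm))
  emb <- suppressWarnings(pca_embed(nm, fs, n_components = 24))
  x <- t(as.matrix(nm$values[match(fs$selected_gene_ids, nm$gene_ids), ]))
  x <- scale(x)
  x <- x[, attr(x, "scaled:scale") > 0, drop = FALSE]
  x <- pmin(pmax(x, -10), 10)
  d_feat <- as.matrix(dist(x))
  d_emb <- as.matrix(dist(emb$coordinates))
  expect_lt(max(abs(d_feat - d_emb)) / max(d_feat), 1e-8)
})

test_that("knn_search is exact, deterministic and permutation invariant", {
  # three cells on a line at 0, 1, 3
  x <- matrix(c(0, 1, 3), 3, 1)
  nb <- knn_search(x, 2)
  expect_equal(nb$neighbor_index[1, ], c(2L, 3L))
  expect_equal(nb$D[1, ], c(1, 3))

  set.seed(23)
  y <- matrix(rnorm(50 * 5), 50, 5)
  for (metric in c("euclidean", "manhattan")) {
    nb <- knn_search(y, 10, metric)
    or <- oracle_knn(y, 10, metric)
    expect_identical(nb$neighbor_index, or$index)
    expect_equal(nb$D, or$D, tolerance = 1e-12)
    expect_true(all(diff(t(nb$D)) >= -1e-12))       # sorted rows
  }

  # exact duplicates give zero first distance
  z <- rbind(y[1, ], y)
  expect_equal(knn_search(z, 3)$D[1, 1], 0)

  # permutation invariance up to relabeling
  perm <- sample(50)
  nb1 <- knn_search(y, 8)
  nb2 <- knn_search(y[perm, ], 8)
  inv <- integer(50); inv[perm] <- seq_len(50)
  for (m in 1:50)
    expect_equal(nb2$D[inv[m], ], nb1$D[m, ], tolerance = 1e-12)

  expect_error(knn_search(y, 1), "K must be in")
  expect_error(knn_search(y, 50), "K must be in")
})

test_that("default_k follows the documented formula", {
  expect_equal(default_k(1000), 60L)
  expect_equal(default_k(52), 51L)
  expect_equal(default_k(20000), 1010L)
})
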