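make_nbrs <- function(D, idx) {
  structure(list(K = ncol(D), N = nrow(D), neighbor_index = idx, D = D,
                 metric = "euclidean",
                 cell_ids = paste0("c", seq_len(nrow(D)))),
            class = "neighbor_table")
}

test_that("first and second differences satisfy their defining identities", {
  nb <- random_neighbor_table(8, 6, seed = 1)
  nb$D[1, ] <- c(0, 1, 2, 4, 4, 5)
  d <- first_difference(nb)
  expect_equal(d[1, ], c(0, 1, 1, 2, 0, 1))
  # telescoping: cumulative sum reproduces D
  expect_equal(t(apply(d, 1, cumsum)), nb$D)
  expect_true(all(d >= 0))

  # constant row
  nbc <- random_neighbor_table(4, 5, seed = 2)
  nbc$D[2, ] <- rep(3, 5)
  expect_equal(first_difference(nbc)[2, ], c(3, 0, 0, 0, 0))

  dd <- second_difference(d)
  K <- ncol(d)
  for (k in 2:(K - 1))
    expect_equal(dd[, k - 1], 2 * d[, k] - d[, k - 1] - d[, k + 1])

  # linear delta row gives identically zero second difference
  lin <- rbind(1:5, 2 * (1:5) + 3)
  expect_equal(unname(second_difference(lin)), matrix(0, 2, 3))
  # spec arithmetic example
  expect_equal(second_difference(rbind(c(1, 1, 5, 1, 1)))[1, 2],
               2 * 5 - 1 - 1, ignore_attr = TRUE)

  expect_error(second_difference(d[, 1:3]), "K too small")
})

test_that("neighbor smoothing averages each cell with its first neighbour", {
  # two mutual nearest neighbours
  D <- matrix(rep(c(1, 2, 3, 4), each = 2), 2, 4)
  idx <- matrix(c(2L, 1L, rep(1L, 6)), 2, 4)
  nb <- make_nbrs(D, idx)
  dd <- matrix(c(4, 6, 4, 6), 2, 2)
  sm <- smooth_by_neighbor(dd, nb)
  expect_equal(sm, matrix(5, 2, 2))

  # identical rows: smoothing is the identity
  nb2 <- random_neighbor_table(6, 5, seed = 3)
  dd2 <- matrix(rep(rnorm(3), each = 6), 6, 3)
  expect_equal(smooth_by_neighbor(dd2, nb2), dd2)

  # random fixture vs index-chasing oracle
  nb3 <- random_neighbor_table(20, 8, seed = 4)
  dd3 <- matrix(rnorm(20 * 6), 20, 6)
  sm3 <- smooth_by_neighbor(dd3, nb3)
  for (m in 1:20)
    expect_equal(sm3[m, ], (dd3[m, ] + dd3[nb3$neighbor_index[m, 1], ]) / 2)
})

test_that("sample_skewness matches the type-3 moment formula", {
  expect_equal(sample_skewness(1:5), 0)
  set.seed(5)
  for (i in 1:25) {
    x <- rexp(sample(5:50, 1))^runif(1, 0.5, 2)
    expect_equal(sample_skewness(x), oracle_skewness(x), tolerance = 1e-12)
    expect_equal(sample_skewness(-x), -sample_skewness(x))
  }
  expect_warning(s0 <- sample_skewness(rep(2, 5)), "zero variance")
  expect_equal(s0, 0)
  expect_error(sample_skewness(1:2), "at least 3")
})

test_that("skewness_at_k matches the independent step oracle and is monotone in r", {
  set.seed(6)
  for (i in 1:10) {
    nb <- random_neighbor_table(20, 8, seed = 100 + i)
    dd <- matrix(rnorm(20 * 6), 20, 6)
    sm <- smooth_by_neighbor(dd, nb)
    for (k in c(3, 5)) {
      got <- skewness_at_k(sm, nb, k)
      want <- oracle_skewness_at_k(sm, nb$neighbor_index, k)
      expect_equal(got$skew, want$skew, tolerance = 1e-12)
      expect_equal(got$top_cell, want$top)
    }
  }

  # abundant values flat, r far above: skewness positive and increasing in r
  nb <- random_neighbor_table(30, 6, seed = 7)
  base <- c(stats::rnorm(27, 0, 0.1), 0, 0, 0)
  last <- -Inf
  for (r_target in c(5, 20, 80)) {
    sm <- matrix(base, 30, 4)
    sm[28:30, 2] <- r_target                      # top 3 cells at k = 3
    nb$neighbor_index[28, 1:2] <- c(29L, 30L)
    s <- skewness_at_k(sm, nb, 3)$skew
    expect_gt(s, last)
    last <- s
  }
  expect_gt(last, 2)

  # r equal to the mean of a symmetric abundant set: skewness ~ 0
  nb2 <- random_neighbor_table(23, 6, seed = 8)
  sym <- c(-10:10 / 10, 2, 2)                     # top-2 removed at k = 2
  sm2 <- matrix(0, 23, 4)
  sm2[, 1] <- sym
  sm2[22:23, 1] <- 3
  nb2$neighbor_index[22, 1] <- 23L
  # make r hit the abundant mean exactly: average of cells 22,23 is 3; shift
  sm2[22:23, 1] <- 0
  s <- skewness_at_k(sm2, nb2, 2)$skew
  expect_lt(abs(s), 0.5)

  expect_error(skewness_at_k(matrix(0, 5, 3), random_neighbor_table(5, 5, 1), 1),
               "k must be")
})

test_that("build_skewness_curve flags the planted cluster size", {
  geom <- planted_geometry(n_rare = 5, n_major = 500, gap = 30, seed = 9)
  nb <- knn_search(geom$coords, 40)
  prof <- gap_profile(nb)
  curve <- build_skewness_curve(prof$ddelta_smooth, nb)
  expect_equal(curve$k[which.max(curve$skew)], 5)
  expect_true(5 %in% curve$candidate_k)
  # the top cell at k = 5 is one of the planted cells
  expect_true(nb$cell_ids[curve$per_k_top_cell[match(5, curve$k)]]
              %in% geom$rare)

  # threshold rule
  fake <- curve
  fake$k <- 2:4; fake$skew <- c(1.5, 2.5, 1.0)
  fake$candidate_k <- fake$k[fake$skew > fake$threshold]
  expect_equal(fake$candidate_k, 3)
})

test_that("homogeneous blobs rarely produce candidates", {
  hits <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    x <- matrix(rnorm(300 * 5), 300, 5)
    nb <- knn_search(x, 30)
    prof <- gap_profile(nb)
    curve <- build_skewness_curve(prof$ddelta_smooth, nb)
    if (length(curve$candidate_k) == 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("gap statistics are scale-equivariant and skewness scale-free", {
  geom <- planted_geometry(4, 100, gap = 12, seed = 10)
  nb1 <- knn_search(geom$coords, 20)
  nb2 <- knn_search(geom$coords * 7.3, 20)
  p1 <- gap_profile(nb1); p2 <- gap_profile(nb2)
  expect_equal(nb2$D, nb1$D * 7.3, tolerance = 1e-10)
  expect_equal(p2$delta, p1$delta * 7.3, tolerance = 1e-10)
  expect_equal(p2$ddelta_smooth, p1$ddelta_smooth * 7.3, tolerance = 1e-10)
  c1 <- build_skewness_curve(p1$ddelta_smooth, nb1)
  c2 <- build_skewness_curve(p2$ddelta_smooth, nb2)
  expect_equal(c2$skew, c1$skew, tolerance = 1e-8)
})

test_that("fence modes differ as documented", {
  set.seed(11)
  v <- c(rnorm(50), 8)
  conv <- scgap:::fence_bounds(v, "conventional")
  printed <- scgap:::fence_bounds(v, "as_printed")
  q <- quantile(v, c(0.25, 0.75), names = FALSE)
  expect_equal(conv, c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)))
  expect_equal(printed[1], q[1] + 1.5 * diff(q))
})

test_that("dump_gap_tables writes inspectable delimited text", {
  nb <- random_neighbor_table(10, 6, seed = 12)
  prof <- gap_profile(nb)
  curve <- build_skewness_curve(prof$ddelta_smooth, nb)
  dir <- withr::local_tempdir()
  dump_gap_tables(prof, curve, dir)
  expect_true(all(file.exists(file.path(
    dir, c("delta.tsv", "ddelta.tsv", "ddelta_smooth.tsv", "skew.tsv")))))
  back <- as.matrix(read.table(file.path(dir, "delta.tsv"), header = TRUE))
  expect_equal(unname(back), unname(prof$delta), tolerance = 1e-12)
})
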