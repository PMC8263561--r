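# Independent oracles and fixture builders. These re-derive expected values
# from first principles and must stay independent of the package internals
# they check.

# O(N^2) brute-force kNN: full distance matrix, explicit sort with
# smaller-index tie break.
oracle_knn <- function(x, K, metric = "euclidean") {
  n <- nrow(x)
  idx <- matrix(0L, n, K)
  dd <- matrix(0, n, K)
  for (m in seq_len(n)) {
    d <- numeric(n)
    for (j in seq_len(n)) {
      v <- x[m, ] - x[j, ]
      d[j] <- if (metric == "euclidean") sqrt(sum(v^2)) else sum(abs(v))
    }
    o <- setdiff(order(d, seq_len(n)), m)[seq_len(K)]
    idx[m, ] <- o
    dd[m, ] <- d[o]
  }
  list(index = idx, D = dd)
}

# moment-formula skewness, type 3
oracle_skewness <- function(x) {
  n <- length(x)
  m2 <- sum((x - mean(x))^2) / n
  m3 <- sum((x - mean(x))^3) / n
  (m3 / m2^1.5) * ((n - 1) / n)^1.5
}

# independent step-by-step implementation of the per-k skewness statistic
oracle_skewness_at_k <- function(ddelta_smooth, nbr_index, k,
                                 fence_mode = "conventional") {
  v <- ddelta_smooth[, k - 1]
  t_cell <- which(v == max(v))[1]                      # (a)
  ord <- order(-v, seq_along(v))
  kept <- v[ord][-(1:k)]                               # (b)
  q1 <- unname(quantile(kept, 0.25, type = 7))
  q3 <- unname(quantile(kept, 0.75, type = 7))
  iqr <- q3 - q1
  lo <- if (fence_mode == "conventional") q1 - 1.5 * iqr else q1 + 1.5 * iqr
  abundant <- kept[kept >= lo & kept <= q3 + 1.5 * iqr] # (c)
  r <- mean(v[c(t_cell, nbr_index[t_cell, 1:(k - 1)])]) # (d)
  if (length(abundant) < 3) return(list(skew = 0, top = t_cell))
  list(skew = oracle_skewness(c(abundant, r, r)), top = t_cell) # (e)-(f)
}

# chord-distance elbow oracle: brute-force perpendicular distances on the
# unit-scaled curve; when the farthest point is below the chord it begins
# the tail, so the elbow is the preceding index.
oracle_elbow <- function(v) {
  n <- length(v)
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (v - min(v)) / (max(v) - min(v))
  p1 <- c(0, y[1]); p2 <- c(1, y[n])
  u <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  d <- s <- numeric(n)
  for (i in seq_len(n)) {
    w <- c(x[i], y[i]) - p1
    perp <- w - sum(w * u) * u
    d[i] <- sqrt(sum(perp^2))
    s[i] <- sign(y[i] - (p1[2] + (p2[2] - p1[2]) * x[i]))
  }
  i <- which.max(d)
  if (s[i] < 0) max(i - 1, 1) else i
}

# a random sorted neighbour-distance fixture wrapped as a neighbor_table
random_neighbor_table <- function(n, K, seed) {
  set.seed(seed)
  D <- t(apply(matrix(rexp(n * K), n, K), 1, cumsum))
  idx <- t(vapply(seq_len(n),
                  function(m) sample(setdiff(seq_len(n), m), K,
                                     replace = K > n - 1),
                  integer(K)))
  structure(list(K = K, N = n, neighbor_index = idx, D = D,
                 metric = "euclidean", cell_ids = paste0("c", seq_len(n))),
            class = "neighbor_table")
}

# two-blob geometry: n_rare points in a tight cluster at distance `gap`
# from a diffuse blob of n_major points
planted_geometry <- function(n_rare, n_major, gap = 30, eps = 0.05,
                             dims = 5, seed = 1) {
  set.seed(seed)
  major <- matrix(rnorm(n_major * dims), n_major, dims)
  center <- c(gap, rep(0, dims - 1))
  rare <- sweep(matrix(rnorm(n_rare * dims, sd = eps), n_rare, dims),
                2, center, "+")
  x <- rbind(rare, major)
  rownames(x) <- paste0("c", seq_len(nrow(x)))
  list(coords = x, rare = rownames(x)[seq_len(n_rare)])
}
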