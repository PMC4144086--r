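# Independent straight-loop oracles used to cross-check the implementation.
# These deliberately avoid the package's own code paths: element-by-element
# loops, naive matrix powering, and power iteration instead of eigen().

oracle_euclidean <- function(x, y) {
  s <- 0
  for (i in seq_along(x)) s <- s + (x[i] - y[i])^2
  sqrt(s)
}

# naive k-th matrix power by schoolbook triple loop (tiny inputs only)
oracle_matrix_power <- function(a, k) {
  n <- nrow(a)
  ak <- diag(n)
  for (step in seq_len(k)) {
    nxt <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- 0
      for (t in seq_len(n)) acc <- acc + ak[i, t] * a[t, j]
      nxt[i, j] <- acc
    }
    ak <- nxt
  }
  ak
}

# Perron vector by plain power iteration on a vector (independent of eigen()
# and of the package's repeated matrix multiplication)
oracle_perron <- function(a, iters = 2000) {
  v <- rep(1, nrow(a))
  for (i in seq_len(iters)) {
    v <- as.vector(a %*% v)
    v <- v / sqrt(sum(v^2))
  }
  v / sum(v)
}

# Random connected non-bipartite graph on n <= 8 nodes. Draws support edges
# until the structural preconditions hold; weighted variants get uniform
# weights in [0.2, 1]. The finite-k walk ratio converges at rate
# (|lambda_2| / lambda_1)^k, so for checks pinned at k = 200 the family is
# additionally required to mix fast enough (ratio <= 0.85, i.e. residual
# below 0.85^200 ~ 8e-15) for that k to be in the asymptotic regime;
# slower-mixing graphs simply need larger k.
random_good_graph <- function(n, weighted = FALSE, max_ratio = 0.85) {
  repeat {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    on <- up[stats::runif(length(up)) < 0.5]
    if (length(on) < n) next
    a[on] <- if (weighted) stats::runif(length(on), 0.2, 1) else 1
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix((a > 0) * 1, mode = "undirected")
    if (!igraph::is_connected(g)) next
    if (igraph::bipartite_mapping(g)$res) next
    av <- sort(abs(eigen(a, symmetric = TRUE, only.values = TRUE)$values),
               decreasing = TRUE)
    if (av[2] / av[1] > max_ratio) next
    return(weighted_graph(a))
  }
}

# Straight-loop reimplementation of the full NIM pipeline (both variants):
# joint min-max scaling, loop distances, Gaussian similarities, Perron
# weights by power iteration, per-class weighted-average scores, arg-max.
oracle_nim <- function(train_x, train_labels, test_x, delta1, delta2 = delta1) {
  all_x <- rbind(train_x, test_x)
  n <- nrow(all_x); m <- ncol(all_x)
  n_train <- nrow(train_x)
  for (j in seq_len(m)) {
    lo <- min(all_x[, j]); hi <- max(all_x[, j])
    all_x[, j] <- if (hi > lo) (all_x[, j] - lo) / (hi - lo) else 0
  }
  dist <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    dist[i, j] <- oracle_euclidean(all_x[i, ], all_x[j, ])
  sim <- function(d, delta) exp(-d^2 / (2 * delta^2))
  a <- sim(dist, delta1); diag(a) <- 0
  w <- oracle_perron(a)
  s2 <- sim(dist, delta2); diag(s2) <- 0
  classes <- unique(as.character(train_labels))
  scores <- matrix(NA_real_, n - n_train, length(classes),
                   dimnames = list(NULL, classes))
  for (t in seq_len(n - n_train)) {
    for (ci in seq_along(classes)) {
      idx <- which(as.character(train_labels) == classes[ci])
      num <- 0; den <- 0
      for (i in idx) {
        num <- num + s2[n_train + t, i] * w[i]
        den <- den + w[i]
      }
      scores[t, ci] <- num / den
    }
  }
  pred <- classes[apply(scores, 1L, which.max)]
  list(scores = scores, predicted = pred)
}

# small labeled dataset helper
toy_dataset <- function(n_per_class = c(5, 5), m = 20, sep = 2, sd = 0.3,
                        seed = 42) {
  simulate_dataset(samples_per_class = n_per_class, n_features = m,
                   n_informative = max(2, m %/% 4), class_separation = sep,
                   noise_sd = sd, seed = seed)
}
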