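test_that("walk-ratio influence matches hand-computable walk counts", {
  g <- example_graph()
  # one step: influence of 1 on 2 is A(1,2)/degree(2) = 1/3
  expect_equal(walk_influence(g, 1, 2, 1), 1 / 3)
  # two steps: A^2(4,4) = deg(4) = 3 closed walks; 7 two-walks end at 4
  expect_equal(walk_influence(g, 4, 4, 2), 3 / 7)
  # node ids work as indices
  expect_equal(walk_influence(g, "4", "4", 2), 3 / 7)
  # against the schoolbook matrix-power oracle at several (i, j, k)
  for (k in 1:5) {
    ak <- oracle_matrix_power(g$weights, k)
    for (j in c(1, 4, 6))
      expect_equal(walk_influence(g, 2, j, k), ak[2, j] / sum(ak[, j]),
                   tolerance = 1e-12)
  }
  expect_error(walk_influence(g, 1, 2, 0), "positive integer")
  expect_error(walk_influence(g, 1, 9, 1), "out of range")
})

test_that("walk influences over all sources sum to one at any (j, k)", {
  set.seed(21)
  g <- random_good_graph(6, weighted = TRUE)
  for (k in c(1, 3, 10)) for (j in 1:6) {
    tot <- sum(vapply(1:6, function(i) walk_influence(g, i, j, k), numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("six-node example: node 4's limiting influence is 0.2517", {
  g <- example_graph()
  iv <- node_influence(g)
  expect_equal(round(unname(iv$values[4]), 4), 0.2517)
  expect_equal(sum(iv$values), 1, tolerance = 1e-14)
  # the finite-k path agrees
  pw <- node_influence(g, method = "power", k = 200)
  expect_equal(round(unname(pw$values[4]), 4), 0.2517)
  expect_equal(iv$values, pw$values, tolerance = 1e-8)
})

test_that("vertex-transitive graphs get uniform influence", {
  k3 <- weighted_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(node_influence(k3)$values), rep(1 / 3, 3))
  # odd cycle C5
  c5 <- matrix(0, 5, 5)
  for (i in 1:5) { j <- i %% 5 + 1; c5[i, j] <- 1; c5[j, i] <- 1 }
  expect_equal(unname(node_influence(weighted_graph(c5))$values),
               rep(1 / 5, 5), tolerance = 1e-12)
})

test_that("K4 minus an edge matches the closed-form two-block eigenproblem", {
  a <- matrix(1, 4, 4) - diag(4)
  a[3, 4] <- a[4, 3] <- 0
  iv <- node_influence(weighted_graph(a))
  lambda <- (1 + sqrt(17)) / 2
  expect_equal(unname(iv$values),
               c(lambda / (2 * lambda + 4), lambda / (2 * lambda + 4),
                 1 / (lambda + 2), 1 / (lambda + 2)),
               tolerance = 1e-12)
  # cross-check against the k = 200 walk ratio at every end column
  for (j in 1:4)
    expect_equal(walk_influence(weighted_graph(a), 1, j, 200),
                 unname(iv$values[1]), tolerance = 1e-10)
})

test_that("convergence diagnostics distinguish bipartite and disconnected graphs", {
  edge <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  diag_edge <- check_convergence(edge)
  expect_true(diag_edge$bipartite)

  k3 <- weighted_graph(matrix(1, 3, 3) - diag(3))
  diag_k3 <- check_convergence(k3)
  expect_false(diag_k3$bipartite)
  expect_gt(diag_k3$gap, 0)

  # C4: eigenvalues 2, 0, 0, -2 — extreme absolute values tie
  c4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; c4[i, j] <- 1; c4[j, i] <- 1 }
  diag_c4 <- check_convergence(weighted_graph(c4))
  expect_true(diag_c4$bipartite)
  expect_equal(diag_c4$gap, 0, tolerance = 1e-12)

  two_parts <- weighted_graph(rbind(cbind(matrix(1, 3, 3) - diag(3), matrix(0, 3, 3)),
                                    cbind(matrix(0, 3, 3), matrix(1, 3, 3) - diag(3))))
  expect_false(check_convergence(two_parts)$connected)

  # a self-loop is an odd closed walk: never bipartite
  loop <- matrix(c(1, 1, 1, 0), 2, 2)
  expect_false(check_convergence(weighted_graph(loop))$bipartite)
})

test_that("node_influence refuses the provably non-convergent cases", {
  edge <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(node_influence(edge), "bipartite")
  two_parts <- weighted_graph(rbind(cbind(matrix(1, 3, 3) - diag(3), matrix(0, 3, 3)),
                                    cbind(matrix(0, 3, 3), matrix(1, 3, 3) - diag(3))))
  expect_error(node_influence(two_parts), "disconnected")
})

test_that("bipartite walk ratios oscillate with the parity of k", {
  edge <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
  tr <- influence_trace(edge, 1, 12)
  # influence of node 1 on itself is 1 at even k, 0 at odd k — forever
  expect_equal(unname(tr[c(2, 4, 6, 8, 10, 12), 1]), rep(1, 6))
  expect_equal(unname(tr[c(1, 3, 5, 7, 9, 11), 1]), rep(0, 6))
  # whereas on the example graph the trace settles onto the limit
  g <- example_graph()
  tr2 <- influence_trace(g, 4, 120)
  limit <- unname(node_influence(g)$values[4])
  expect_equal(unname(tr2[120, ]), rep(limit, 6), tolerance = 1e-6)
})

test_that("influence limit equals the k = 200 walk ratio on random graphs", {
  set.seed(22)
  for (rep in 1:8) {
    g <- random_good_graph(sample(4:8, 1), weighted = rep %% 2 == 0)
    iv <- node_influence(g)
    n <- nrow(g$weights)
    for (j in seq_len(n))
      for (i in c(1L, n))
        expect_equal(walk_influence(g, i, j, 200), unname(iv$values[i]),
                     tolerance = 1e-8)
  }
})

test_that("influence is invariant to diagonal shifts and global scaling", {
  set.seed(23)
  for (rep in 1:5) {
    g <- random_good_graph(6, weighted = TRUE)
    iv <- node_influence(g)
    expect_equal(sum(iv$values), 1, tolerance = 1e-14)
    shifted <- weighted_graph(g$weights + 0.7 * diag(6))
    expect_equal(node_influence(shifted)$values, iv$values, tolerance = 1e-10)
    scaled <- weighted_graph(3.2 * g$weights)
    expect_equal(node_influence(scaled)$values, iv$values, tolerance = 1e-10)
  }
})

test_that("influence vectors export as two-column delimited text", {
  iv <- node_influence(example_graph())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_influence(iv, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(back$influence, unname(iv$values), tolerance = 1e-6)
  expect_equal(as.character(back$node_id), names(iv$values))
})
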