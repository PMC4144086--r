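test_that("config constructor enforces the per-variant bandwidth contract", {
  expect_s3_class(nim_config("nim1", delta = 1), "nim_config")
  expect_error(nim_config("nim1"), "delta")
  expect_error(nim_config("nim1", delta = -1), "positive")
  expect_error(nim_config("nim2", delta1 = 1), "delta2")
  cfg <- nim_config("nim2", delta1 = 0.5, delta2 = 2)
  expect_equal(c(cfg$delta1, cfg$delta2), c(0.5, 2))
})

test_that("predict_label is a first-class-tie arg-max", {
  expect_equal(predict_label(c(C1 = 0.3, C2 = 0.9)), "C2")
  expect_equal(predict_label(c(C1 = 0.5, C2 = 0.5)), "C1")
  expect_error(predict_label(numeric(0)), "empty")
  set.seed(31)
  for (rep in 1:10) {
    sc <- setNames(runif(4), paste0("K", 1:4))
    # linear-scan oracle
    best <- names(sc)[1]
    for (nm in names(sc)) if (sc[[nm]] > sc[[best]]) best <- nm
    expect_equal(predict_label(sc), best)
  }
})

test_that("class similarity is the influence-weighted average of similarities", {
  set.seed(32)
  d <- toy_dataset(c(3, 3), m = 8, seed = 32)
  norm <- minmax_normalize(d)
  g <- build_graph(norm, delta = 1)
  iv <- node_influence(g)
  labs <- setNames(d$labels, rownames(d$values))

  # single-member class: weights cancel, score is the similarity itself
  expect_equal(class_similarity(5, as.character(labs[1]), g, iv, labs[1]),
               unname(g$weights[5, 1]))

  # explicit loop oracle for a 3-member class with unequal weights
  members <- names(labs)[labs == "C2"]
  num <- 0; den <- 0
  for (mm in members) {
    num <- num + g$weights[2, mm] * iv$values[mm]
    den <- den + iv$values[mm]
  }
  expect_equal(class_similarity(2, "C2", g, iv, labs), unname(num / den),
               tolerance = 1e-12)
  expect_error(class_similarity(1, "C9", g, iv, labs), "no training samples")
})

test_that("equidistant class members give the bare kernel value", {
  # class members at distance 1 from the test point in orthogonal directions
  train <- rbind(a1 = c(1, 0, 0), a2 = c(0, 1, 0), a3 = c(0, 0, 1))
  test <- rbind(t1 = c(0, 0, 0))
  # bypass normalization effects by feeding an already-normalized cube
  g <- build_graph(rbind(train, test), delta = 0.9)
  iv <- node_influence(g)
  labs <- setNames(rep("A", 3), rownames(train))
  expect_equal(class_similarity(4, "A", g, iv, labs),
               similarity(1, 0.9), tolerance = 1e-12)
})

test_that("a test sample coinciding with a lone class member scores 1 there", {
  train <- expr_dataset(rbind(a = c(0, 0), b = c(10, 10)),
                        labels = c("A", "B"))
  test <- expr_dataset(rbind(t1 = c(0, 0)))
  res <- nim1(train, test, delta = 1)
  expect_equal(unname(res$scores[1, "A"]), 1)
  expect_equal(as.character(res$predicted), "A")
  expect_true(all(res$scores > 0 & res$scores <= 1))
})

test_that("class relabeling permutes scores but not the induced partition", {
  d <- toy_dataset(c(4, 4), m = 10, seed = 33)
  train <- subset_samples(d, 1:6)
  test <- subset_samples(d, 7:8)
  res <- nim1(train, test, delta = 1)
  swapped <- expr_dataset(train$values,
                          labels = factor(ifelse(train$labels == "C1", "C2", "C1"),
                                          levels = c("C1", "C2")))
  res_sw <- nim1(swapped, test, delta = 1)
  expect_equal(unname(res$scores[, "C1"]), unname(res_sw$scores[, "C2"]))
  expect_equal(unname(res$scores[, "C2"]), unname(res_sw$scores[, "C1"]))
  # same partition of test samples, names swapped
  expect_equal(as.character(res$predicted) == "C1",
               as.character(res_sw$predicted) == "C2")
})

test_that("nim2 with equal bandwidths reproduces nim1 bit-for-bit", {
  for (seed in 1:3) {
    d <- toy_dataset(c(4, 6), m = 12, seed = seed)
    train <- subset_samples(d, 1:7)
    test <- subset_samples(d, 8:10)
    delta <- 0.6 + 0.2 * seed
    r1 <- nim1(train, test, delta = delta)
    r2 <- nim2(train, test, delta1 = delta, delta2 = delta)
    expect_identical(r1$scores, r2$scores)
    expect_identical(r1$predicted, r2$predicted)
  }
})

test_that("a huge class-score bandwidth flattens all scores towards 1", {
  d <- toy_dataset(c(3, 3), m = 8, seed = 34)
  train <- subset_samples(d, 1:4)
  test <- subset_samples(d, 5:6)
  res <- nim2(train, test, delta1 = 1, delta2 = 1e10)
  expect_true(all(abs(res$scores - 1) < 1e-9))
  # ties resolve to the first declared class
  expect_equal(as.character(res$predicted), rep("C1", 2))
})

test_that("nim scores match the straight-loop pipeline oracle", {
  for (seed in c(41, 42)) {
    d <- toy_dataset(c(5, 4, 3), m = 15, seed = seed)
    train <- subset_samples(d, c(1:4, 6:8, 10:11))
    test <- subset_samples(d, c(5, 9, 12))
    ora <- oracle_nim(train$values, train$labels, test$values, 0.5, 2.0)
    res <- nim2(train, test, delta1 = 0.5, delta2 = 2.0)
    expect_equal(unname(res$scores), unname(ora$scores[, colnames(res$scores)]),
                 tolerance = 1e-10)
    expect_equal(as.character(res$predicted), ora$predicted)
  }
})

test_that("the pipeline is transductive: test samples reshape the weights", {
  d <- toy_dataset(c(4, 4), m = 10, seed = 35)
  train <- subset_samples(d, 1:6)
  r_one <- nim1(train, subset_samples(d, 7), delta = 1)
  r_two <- nim1(train, subset_samples(d, 7:8), delta = 1)
  w_one <- r_one$influence$values[1:6]
  w_two <- r_two$influence$values[1:6]
  expect_false(isTRUE(all.equal(unname(w_one), unname(w_two))))
})

test_that("structural misuse is rejected", {
  d <- toy_dataset(c(3, 3), m = 6, seed = 36)
  train <- subset_samples(d, 1:6)
  test <- subset_samples(d, 1:2)
  # declared class with no training samples
  bad <- expr_dataset(train$values[1:3, ],
                      labels = factor(rep("C1", 3), levels = c("C1", "C2")))
  expect_error(nim1(bad, test, delta = 1), "no training samples")
  expect_error(nim1(train, test, delta = 0), "positive")
  fit <- nim(train, delta = 1)
  expect_error(predict(fit, matrix(0, 2, 99)), "same features")
  # all-identical samples: flagged but still classifiable
  same <- expr_dataset(matrix(1, 4, 3), labels = c("A", "A", "B", "B"))
  expect_warning(nim1(same, expr_dataset(matrix(1, 1, 3)), delta = 1),
                 "identical")
})

test_that("model object has informative print and summary", {
  d <- toy_dataset(c(3, 3), m = 6, seed = 37)
  fit <- nim(d, delta = 1)
  expect_output(print(fit), "transductive")
  expect_output(summary(fit), "Training value range")
  res <- predict(fit, d$values[1:2, , drop = FALSE])
  expect_output(print(res), "NIM predictions")
  df <- as.data.frame(res)
  expect_equal(names(df)[1], "sample_id")
})
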