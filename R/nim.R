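#' Classifier configuration
#'
#' Bundles the tunable choices of the node-influence classifiers. NIM1 uses
#' a single kernel bandwidth `delta` for both the influence graph and the
#' class-scoring similarities; NIM2 decouples them: `delta1` for the graph
#' whose Perron vector supplies the training-sample weights, `delta2` for
#' the similarities entering the class scores. NIM1 is exactly NIM2 with
#' `delta1 = delta2`.
#'
#' @param variant `"nim1"` or `"nim2"`.
#' @param delta Positive bandwidth (NIM1).
#' @param delta1,delta2 Positive bandwidths (NIM2).
#' @param metric Distance metric, see [distance_matrix()].
#' @param diagonal Graph diagonal policy, see [build_graph()].
#' @param exponent Kernel convention, see [similarity()].
#' @param tie_break Tie resolution for equal class scores; only
#'   `"first_class"` (earliest class in declared order) is defined.
#' @return An object of class `nim_config`.
#' @examples
#' nim_config("nim1", delta = 1)
#' nim_config("nim2", delta1 = 0.5, delta2 = 2)
#' @export
nim_config <- function(variant = c("nim1", "nim2"), delta = NULL,
                       delta1 = NULL, delta2 = NULL, metric = "euclidean",
                       diagonal = c("zero", "one"),
                       exponent = c("squared", "raw"),
                       tie_break = "first_class") {
  variant <- match.arg(variant)
  diagonal <- match.arg(diagonal)
  exponent <- match.arg(exponent)
  metric <- match.arg(metric, .metrics)
  tie_break <- match.arg(tie_break)
  chk <- function(d, nm) {
    if (is.null(d) || !is.numeric(d) || length(d) != 1L || d <= 0)
      stop(nm, " must be a positive number")
    as.numeric(d)
  }
  if (variant == "nim1") {
    delta <- chk(delta, "delta")
    delta1 <- delta2 <- delta
  } else {
    delta1 <- chk(delta1, "delta1")
    delta2 <- chk(delta2, "delta2")
    delta <- NA_real_
  }
  structure(list(variant = variant, delta = delta, delta1 = delta1,
                 delta2 = delta2, metric = metric, diagonal = diagonal,
                 exponent = exponent, tie_break = tie_break),
            class = "nim_config")
}

#' @export
print.nim_config <- function(x, ...) {
  if (x$variant == "nim1")
    cat(sprintf("NIM1 config: delta = %g", x$delta))
  else
    cat(sprintf("NIM2 config: delta1 = %g, delta2 = %g", x$delta1, x$delta2))
  cat(sprintf(", metric = %s, diagonal = %s\n", x$metric, x$diagonal))
  invisible(x)
}

#' Pick the arg-max class with first-class tie-breaking
#'
#' @param class_scores Named numeric vector of class scores; names define
#'   the declared class order.
#' @param tie_break Tie rule; `"first_class"` resolves exact ties to the
#'   earliest class in that order.
#' @return The winning class name.
#' @examples
#' predict_label(c(C1 = 0.5, C2 = 0.5))  # "C1"
#' @export
predict_label <- function(class_scores, tie_break = "first_class") {
  tie_break <- match.arg(tie_break)
  if (length(class_scores) == 0L) stop("empty score map")
  names(class_scores)[which.max(class_scores)]  # which.max takes the first max
}

#' Influence-weighted similarity between a test sample and a class
#'
#' The class score is the influence-weighted average of the similarities
#' between the test sample and the class's training samples:
#' `sum_x S(test, x) w(x) / sum_x w(x)` over training samples x in the
#' class. The weights are the node-influence centralities computed on the
#' full train+test graph, restricted to training nodes, so centrally
#' located (high-influence) samples dominate their class's score. With
#' positive similarities the score always lies in (0, 1].
#'
#' @param test_index Node index or id of the test sample in `graph2`.
#' @param class_label The class to score.
#' @param graph2 The [weighted_graph] supplying the similarities (the
#'   `delta` graph for NIM1, the `delta2` graph for NIM2).
#' @param weights An `influence_vector` or named numeric vector of
#'   training-node weights.
#' @param train_labels Named vector/factor: class label per training node
#'   id.
#' @return The class score.
#' @export
class_similarity <- function(test_index, class_label, graph2, weights,
                             train_labels) {
  stopifnot(inherits(graph2, "weighted_graph"))
  if (inherits(weights, "influence_vector")) weights <- weights$values
  test_index <- .node_index(graph2, test_index)
  ids <- names(train_labels)
  if (is.null(ids)) stop("train_labels must be named by node id")
  members <- ids[as.character(train_labels) == as.character(class_label)]
  if (length(members) == 0L) stop("class '", class_label, "' has no training samples")
  w <- weights[members]
  if (anyNA(w)) stop("missing influence weight for a class member")
  s <- graph2$weights[test_index, members]
  sum(s * w) / sum(w)
}

# Shared engine behind nim1/nim2/predict.nim: joint normalization, the
# delta1 influence graph, Perron weights restricted to training nodes,
# delta2 similarities into per-class scores, arg-max labels.
.nim_pipeline <- function(train_values, train_labels, test_values, config) {
  n_train <- nrow(train_values)
  n_test <- nrow(test_values)
  if (n_train < 1L) stop("training set is empty")
  if (n_test < 1L) stop("test set is empty")
  if (anyNA(train_labels)) stop("all training samples must be labeled")
  classes <- levels(train_labels)
  missing_cls <- setdiff(classes, unique(as.character(train_labels)))
  if (length(missing_cls))
    stop("declared class with no training samples: ",
         paste(missing_cls, collapse = ", "))
  test_ids <- rownames(test_values)
  if (is.null(test_ids)) test_ids <- paste0("test_", seq_len(n_test))
  # resubstitution and the like: disambiguate internally, report input ids
  if (any(test_ids %in% rownames(train_values)))
    rownames(test_values) <- paste0("test_", seq_len(n_test))
  else
    rownames(test_values) <- test_ids
  combined <- expr_dataset(rbind(train_values, test_values))
  norm <- minmax_normalize(combined)
  d <- distance_matrix(norm, config$metric)
  if (nrow(d) > 1L && all(d[upper.tri(d)] == 0))
    warning("all samples are identical: every pairwise distance is zero")
  s1 <- similarity(d, config$delta1, config$exponent)
  diag(s1) <- if (config$diagonal == "zero") 0 else 1
  g1 <- weighted_graph(s1, delta = config$delta1)
  infl <- node_influence(g1)
  train_idx <- seq_len(n_train)
  w_train <- infl$values[train_idx]
  names(w_train) <- rownames(train_values)

  s2 <- if (config$delta2 == config$delta1) s1 else {
    m <- similarity(d, config$delta2, config$exponent)
    diag(m) <- if (config$diagonal == "zero") 0 else 1
    m
  }
  g2 <- weighted_graph(s2, delta = config$delta2)

  lab <- train_labels
  names(lab) <- rownames(train_values)
  scores <- matrix(NA_real_, n_test, length(classes),
                   dimnames = list(test_ids, classes))
  for (t in seq_len(n_test)) {
    for (cl in classes)
      scores[t, cl] <- class_similarity(n_train + t, cl, g2, w_train, lab)
  }
  predicted <- factor(apply(scores, 1L, predict_label, config$tie_break),
                      levels = classes)
  structure(list(scores = scores, predicted = predicted,
                 influence = infl, config = config,
                 n_train = n_train, n_test = n_test),
            class = "nim_prediction")
}

#' @export
print.nim_prediction <- function(x, digits = 4, ...) {
  cat(sprintf("NIM predictions for %d test sample(s) (%s, %d training samples):\n",
              x$n_test, toupper(x$config$variant), x$n_train))
  print(cbind(round(as.data.frame(x$scores), digits),
              predicted = as.character(x$predicted)))
  invisible(x)
}

#' @export
as.data.frame.nim_prediction <- function(x, ...) {
  data.frame(sample_id = rownames(x$scores), x$scores,
             predicted = as.character(x$predicted),
             check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fit a node-influence classifier
#'
#' `nim()` is the model constructor: it stores the labeled training
#' expression matrix together with the kernel configuration and returns a
#' classed model object. The method is transductive — test samples join
#' the training samples in one Gaussian similarity graph, the
#' node-influence centrality (Perron vector) of that full graph weights
#' the training samples, and each test sample is assigned to the class
#' with the highest influence-weighted similarity — so all pipeline work
#' happens in [predict.nim()], where the test samples are known. No
#' inductive out-of-sample mode exists: adding a test sample changes the
#' graph, hence the weights.
#'
#' @param x Numeric training matrix (samples x features) or an
#'   [expr_dataset] with labels (then `labels` is ignored).
#' @param labels Class labels for the training samples.
#' @param variant,delta,delta1,delta2,metric,diagonal,exponent,tie_break
#'   See [nim_config()]. If `variant` is omitted it is inferred: `"nim2"`
#'   when `delta1`/`delta2` are supplied, else `"nim1"`.
#' @param config Alternatively, a ready-made [nim_config()] (overrides the
#'   individual arguments).
#' @return An object of class `nim` with elements `train` (matrix),
#'   `labels` (factor) and `config`.
#' @seealso [predict.nim()], [nim1()], [nim2()], [loocv()]
#' @examples
#' set.seed(1)
#' d <- simulate_dataset(samples_per_class = c(5, 5), n_features = 30,
#'                       n_informative = 6, class_separation = 3,
#'                       noise_sd = 0.3, seed = 1)
#' fit <- nim(d$values, d$labels, delta = 1)
#' predict(fit, d$values[c(1, 6), , drop = FALSE])
#' @export
nim <- function(x, labels = NULL, variant = NULL, delta = NULL,
                delta1 = NULL, delta2 = NULL, metric = "euclidean",
                diagonal = "zero", exponent = "squared",
                tie_break = "first_class", config = NULL) {
  if (inherits(x, "expr_dataset")) {
    labels <- x$labels
    x <- x$values
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(labels)) stop("training labels are required")
  if (is.null(config)) {
    if (is.null(variant))
      variant <- if (!is.null(delta1) || !is.null(delta2)) "nim2" else "nim1"
    config <- nim_config(variant, delta = delta, delta1 = delta1,
                         delta2 = delta2, metric = metric,
                         diagonal = diagonal, exponent = exponent,
                         tie_break = tie_break)
  }
  d <- expr_dataset(x, labels = labels)  # validates ids, finiteness, labels
  structure(list(train = d$values, labels = d$labels, config = config),
            class = "nim")
}

#' @export
print.nim <- function(x, ...) {
  cat("Node-influence classifier (transductive)\n")
  print(x$config)
  tab <- table(x$labels)
  cat(sprintf("Training: %d samples x %d features; classes: %s\n",
              nrow(x$train), ncol(x$train),
              paste(sprintf("%s (%d)", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @export
summary.nim <- function(object, ...) {
  print(object)
  rng <- range(object$train)
  cat(sprintf("Training value range: [%.4g, %.4g]\n", rng[1L], rng[2L]))
  invisible(object)
}

#' Predict classes for test samples
#'
#' Runs the full transductive pipeline: joint min-max normalization of
#' training and test samples, pairwise distances, the Gaussian similarity
#' graph (bandwidth `delta`/`delta1`), node-influence weights from its
#' Perron vector restricted to the training nodes, influence-weighted
#' class scores (bandwidth `delta2` for NIM2), and arg-max labels.
#'
#' @param object A fitted [nim()] model.
#' @param newdata Numeric matrix of test samples (same features, same
#'   column order) or an [expr_dataset].
#' @param ... Unused.
#' @return A `nim_prediction`: per-sample class scores (each in (0, 1\]),
#'   predicted labels, and the influence vector of the joint graph.
#' @export
predict.nim <- function(object, newdata, ...) {
  if (inherits(newdata, "expr_dataset")) newdata <- newdata$values
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$train))
    stop("newdata must have the same features as the training data")
  .nim_pipeline(object$train, object$labels, newdata, object$config)
}

#' One-bandwidth node-influence classification (NIM1)
#'
#' Convenience wrapper: fit on `train`, predict `test`, one bandwidth for
#' both the influence graph and the class scores.
#'
#' @param train Labeled [expr_dataset] (or matrix plus `labels` via
#'   `config`-free use of [nim()]).
#' @param test [expr_dataset] or matrix of test samples.
#' @param config A [nim_config()] with `variant = "nim1"`, or `NULL` to
#'   build one from `delta`.
#' @param delta Kernel bandwidth when `config` is `NULL`.
#' @param ... Further arguments to [nim_config()].
#' @return A `nim_prediction`.
#' @export
nim1 <- function(train, test, config = NULL, delta = NULL, ...) {
  if (is.null(config)) config <- nim_config("nim1", delta = delta, ...)
  if (config$variant != "nim1") stop("config$variant must be 'nim1'")
  fit <- nim(train, config = config)
  predict(fit, test)
}

#' Two-bandwidth node-influence classification (NIM2)
#'
#' Like [nim1()] but with separate bandwidths: `delta1` for the influence
#' graph, `delta2` for the class-score similarities. With
#' `delta1 = delta2 = delta` the result is identical to `nim1(delta)`.
#'
#' @inheritParams nim1
#' @param delta1,delta2 Kernel bandwidths when `config` is `NULL`.
#' @return A `nim_prediction`.
#' @export
nim2 <- function(train, test, config = NULL, delta1 = NULL, delta2 = NULL,
                 ...) {
  if (is.null(config))
    config <- nim_config("nim2", delta1 = delta1, delta2 = delta2, ...)
  if (config$variant != "nim2") stop("config$variant must be 'nim2'")
  fit <- nim(train, config = config)
  predict(fit, test)
}
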