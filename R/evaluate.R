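#' Leave-one-out cross-validation
#'
#' Runs N folds; fold i holds out sample i as the sole test sample and
#' trains on the remaining N - 1. Because normalization is joint over all
#' samples and the bandwidth is fixed, the similarity graph over the full
#' cohort — and hence the influence vector — is identical in every fold;
#' the default path therefore computes them once and only re-restricts the
#' training weights per fold. `per_fold = TRUE` instead reruns the entire
#' pipeline in every fold; both paths give exactly equal predictions.
#'
#' A fold whose held-out sample leaves its class empty in the training set
#' (a singleton class) cannot be scored for that class; such folds are
#' recorded as errored, excluded from the accuracy denominator, and
#' flagged with a warning.
#'
#' @param dataset A fully labeled [expr_dataset] with at least 2 samples.
#' @param config A [nim_config()].
#' @param per_fold If `TRUE`, recompute normalization, graph and influence
#'   inside every fold (slow validation path).
#' @return An object of class `nim_eval`: `protocol`, `n_correct`,
#'   `n_total`, `accuracy` (= n_correct / n_total exactly), `predictions`
#'   data frame, `config`.
#' @seealso [holdout()], [grid_search()]
#' @export
loocv <- function(dataset, config, per_fold = FALSE) {
  stopifnot(inherits(dataset, "expr_dataset"), inherits(config, "nim_config"))
  n <- nrow(dataset$values)
  if (n < 2L) stop("LOOCV needs at least 2 samples")
  if (is.null(dataset$labels) || anyNA(dataset$labels))
    stop("LOOCV requires all samples to be labeled")
  labels <- dataset$labels
  classes <- levels(labels)
  ids <- rownames(dataset$values)

  predicted <- rep(NA_character_, n)
  errored <- rep(FALSE, n)

  if (per_fold) {
    for (i in seq_len(n)) {
      tr <- subset_samples(dataset, -i)
      te <- subset_samples(dataset, i)
      if (any(table(factor(tr$labels, levels = classes)) == 0L)) {
        errored[i] <- TRUE
        next
      }
      cfg <- config
      res <- .nim_pipeline(tr$values, factor(tr$labels, levels = classes),
                           te$values, cfg)
      predicted[i] <- as.character(res$predicted)
    }
  } else {
    # fold-invariant part, computed once
    norm <- minmax_normalize(dataset)
    d <- distance_matrix(norm, config$metric)
    s1 <- similarity(d, config$delta1, config$exponent)
    diag(s1) <- if (config$diagonal == "zero") 0 else 1
    infl <- node_influence(weighted_graph(s1, delta = config$delta1))
    s2 <- if (config$delta2 == config$delta1) s1 else {
      m <- similarity(d, config$delta2, config$exponent)
      diag(m) <- if (config$diagonal == "zero") 0 else 1
      m
    }
    g2 <- weighted_graph(s2, delta = config$delta2)
    for (i in seq_len(n)) {
      train_ids <- ids[-i]
      lab <- labels[-i]
      names(lab) <- train_ids
      if (any(table(factor(lab, levels = classes)) == 0L)) {
        errored[i] <- TRUE
        next
      }
      sc <- vapply(classes, function(cl)
        class_similarity(i, cl, g2, infl$values[train_ids], lab), numeric(1))
      predicted[i] <- predict_label(sc, config$tie_break)
    }
  }

  if (any(errored))
    warning(sum(errored), " fold(s) errored (singleton class) and were ",
            "excluded from the accuracy denominator")
  ok <- !errored
  n_total <- sum(ok)
  n_correct <- sum(predicted[ok] == as.character(labels)[ok])
  structure(list(protocol = "loocv",
                 n_correct = n_correct, n_total = n_total,
                 accuracy = n_correct / n_total,
                 predictions = data.frame(sample_id = ids,
                                          truth = as.character(labels),
                                          predicted = predicted,
                                          errored = errored,
                                          stringsAsFactors = FALSE),
                 config = config),
            class = "nim_eval")
}

#' Holdout (train/test split) evaluation
#'
#' Single fit/predict on a labeled split; accuracy over the test set.
#'
#' @param train,test Labeled [expr_dataset]s.
#' @param config A [nim_config()].
#' @return A `nim_eval` (see [loocv()]) with `protocol = "holdout"`.
#' @export
holdout <- function(train, test, config) {
  stopifnot(inherits(train, "expr_dataset"), inherits(test, "expr_dataset"),
            inherits(config, "nim_config"))
  if (nrow(test$values) == 0L) stop("test set is empty")
  if (is.null(test$labels) || anyNA(test$labels))
    stop("holdout evaluation requires labeled test samples")
  fit <- nim(train, config = config)
  res <- .nim_pipeline(fit$train, fit$labels, test$values, fit$config)
  truth <- as.character(test$labels)
  pred <- as.character(res$predicted)
  n_total <- length(truth)
  n_correct <- sum(pred == truth)
  structure(list(protocol = "holdout",
                 n_correct = n_correct, n_total = n_total,
                 accuracy = n_correct / n_total,
                 predictions = data.frame(sample_id = rownames(test$values),
                                          truth = truth, predicted = pred,
                                          errored = FALSE,
                                          stringsAsFactors = FALSE),
                 config = config),
            class = "nim_eval")
}

#' @export
print.nim_eval <- function(x, ...) {
  cat(sprintf("%s evaluation (%s): accuracy %.4f (%d/%d)\n",
              toupper(x$protocol), toupper(x$config$variant),
              x$accuracy, x$n_correct, x$n_total))
  invisible(x)
}

#' Bandwidth grid search
#'
#' Evaluates every point of a bandwidth grid with the chosen protocol. For
#' NIM1 the grid is the sequence `delta_min, delta_min + step, ...,
#' <= delta_max`; for NIM2 it is the Cartesian product of that axis with
#' itself for (delta1, delta2). The NIM2 diagonal delta1 = delta2
#' reproduces the NIM1 axis exactly, so the best NIM2 accuracy on a shared
#' axis is never below the best NIM1 accuracy.
#'
#' @param dataset Labeled [expr_dataset] (LOOCV protocol), or the training
#'   set when `test` is given (holdout protocol).
#' @param variant `"nim1"` or `"nim2"`.
#' @param delta_min,delta_max,step Grid bounds and spacing; all positive,
#'   `delta_max >= delta_min`.
#' @param test Optional labeled test [expr_dataset]; switches the protocol
#'   to holdout.
#' @param metric,diagonal,exponent Passed to [nim_config()].
#' @return An object of class `nim_grid`: `grid` (data frame with columns
#'   `delta1`, `delta2`, `accuracy`), `best` (rows attaining the maximum),
#'   `variant`, `protocol`.
#' @export
grid_search <- function(dataset, variant = c("nim1", "nim2"),
                        delta_min, delta_max, step, test = NULL,
                        metric = "euclidean", diagonal = "zero",
                        exponent = "squared") {
  variant <- match.arg(variant)
  if (delta_min <= 0 || step <= 0 || delta_max < delta_min)
    stop("invalid grid: need delta_min > 0, step > 0, delta_max >= delta_min")
  axis <- seq(delta_min, delta_max, by = step)
  pts <- if (variant == "nim1") data.frame(delta1 = axis, delta2 = axis)
         else expand.grid(delta1 = axis, delta2 = axis,
                          KEEP.OUT.ATTRS = FALSE)
  protocol <- if (is.null(test)) "loocv" else "holdout"
  acc <- vapply(seq_len(nrow(pts)), function(r) {
    cfg <- if (variant == "nim1")
      nim_config("nim1", delta = pts$delta1[r], metric = metric,
                 diagonal = diagonal, exponent = exponent)
    else
      nim_config("nim2", delta1 = pts$delta1[r], delta2 = pts$delta2[r],
                 metric = metric, diagonal = diagonal, exponent = exponent)
    if (protocol == "loocv") loocv(dataset, cfg)$accuracy
    else holdout(dataset, test, cfg)$accuracy
  }, numeric(1))
  grid <- cbind(pts, accuracy = acc)
  structure(list(grid = grid, best = grid[acc == max(acc), , drop = FALSE],
                 variant = variant, protocol = protocol),
            class = "nim_grid")
}

#' @export
print.nim_grid <- function(x, ...) {
  cat(sprintf("%s %s grid search over %d point(s); best accuracy %.4f at:\n",
              toupper(x$variant), toupper(x$protocol), nrow(x$grid),
              max(x$grid$accuracy)))
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' @describeIn grid_search Accuracy profile (NIM1) or surface (NIM2) plot.
#' @param x A `nim_grid`.
#' @param ... Further graphical parameters.
#' @export
plot.nim_grid <- function(x, ...) {
  if (x$variant == "nim1") {
    plot(x$grid$delta1, x$grid$accuracy, type = "b",
         xlab = expression(delta), ylab = "accuracy", ...)
  } else {
    d1 <- sort(unique(x$grid$delta1))
    d2 <- sort(unique(x$grid$delta2))
    z <- matrix(NA_real_, length(d1), length(d2))
    z[cbind(match(x$grid$delta1, d1), match(x$grid$delta2, d2))] <-
      x$grid$accuracy
    image(d1, d2, z, xlab = expression(delta[1]),
          ylab = expression(delta[2]), ...)
  }
  invisible(x)
}
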