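#' Weighted sample graph
#'
#' A symmetric nonnegative edge-weight matrix over samples (or abstract
#' nodes). This is the common currency between the similarity construction
#' and the influence centrality: the classifier treats the cohort of
#' samples as a dense, non-negatively weighted undirected network whose
#' edge weights are Gaussian kernel similarities.
#'
#' @param weights Square numeric matrix of edge weights; must be symmetric
#'   with all entries >= 0. Row/column names are taken as node ids.
#' @param node_ids Optional character vector of node ids (overrides
#'   dimnames).
#' @param delta Optional kernel bandwidth recorded for provenance when the
#'   graph was built from similarities.
#' @return An object of class `weighted_graph`: list with `weights`
#'   (named matrix) and `delta` (or `NA`).
#' @examples
#' g <- weighted_graph(matrix(c(0, 1, 1, 0), 2, 2))
#' @export
weighted_graph <- function(weights, node_ids = NULL, delta = NA_real_) {
  if (!is.matrix(weights)) weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  n <- nrow(weights)
  if (n != ncol(weights)) stop("weight matrix must be square")
  if (!isSymmetric.matrix(unname(weights), tol = 1e-12))
    stop("weight matrix must be symmetric")
  if (any(weights < 0)) stop("edge weights must be nonnegative")
  if (is.null(node_ids)) node_ids <- rownames(weights)
  if (is.null(node_ids)) node_ids <- as.character(seq_len(n))
  if (anyDuplicated(node_ids)) stop("node ids must be unique")
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(weights = weights, delta = delta), class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  n <- nrow(x$weights)
  m <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat(sprintf("Weighted graph: %d nodes, %d positive edges", n, m))
  if (!is.na(x$delta)) cat(sprintf(", delta = %g", x$delta))
  cat("\n")
  invisible(x)
}

#' @export
dim.weighted_graph <- function(x) dim(x$weights)

#' Euclidean distance between two vectors
#'
#' @param x,y Numeric vectors of equal length.
#' @return `sqrt(sum((x - y)^2))`; zero iff `x == y`.
#' @examples
#' euclidean_distance(c(0, 0), c(3, 4))  # 5
#' @export
euclidean_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  sqrt(sum((x - y)^2))
}

.metrics <- c("euclidean", "manhattan", "maximum")

#' Pairwise distance matrix over samples
#'
#' @param dataset An [expr_dataset] (typically min-max normalized) or a
#'   numeric samples-by-features matrix.
#' @param metric One of `"euclidean"` (the default and the recommended
#'   choice in the absence of prior knowledge), `"manhattan"`,
#'   `"maximum"`.
#' @return Symmetric nonnegative matrix with zero diagonal, dimnames =
#'   sample ids.
#' @export
distance_matrix <- function(dataset, metric = "euclidean") {
  metric <- match.arg(metric, .metrics)
  x <- if (inherits(dataset, "expr_dataset")) dataset$values else as.matrix(dataset)
  d <- as.matrix(stats::dist(x, method = metric))
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Gaussian kernel similarity of a distance
#'
#' `exp(-d^2 / (2 * delta^2))` — strictly decreasing in `d`, equal to 1
#' iff `d = 0`, always in (0, 1]. The bandwidth `delta` sets how fast
#' affinity decays with distance. `exponent = "raw"` uses
#' `exp(-d / (2 * delta^2))` instead, provided for reproduction studies of
#' the alternative kernel convention.
#'
#' @param d Nonnegative distance (vectorized).
#' @param delta Positive bandwidth.
#' @param exponent `"squared"` (Gaussian kernel, default) or `"raw"`.
#' @return Similarity in (0, 1].
#' @examples
#' similarity(5, 2.5)  # exp(-2)
#' @export
similarity <- function(d, delta, exponent = c("squared", "raw")) {
  exponent <- match.arg(exponent)
  if (!is.numeric(delta) || length(delta) != 1L || delta <= 0)
    stop("delta must be a positive number")
  if (any(d < 0)) stop("distances must be nonnegative")
  num <- if (exponent == "squared") d^2 else d
  exp(-num / (2 * delta^2))
}

#' Build the Gaussian similarity graph over all samples
#'
#' Computes pairwise distances and applies the Gaussian kernel to obtain a
#' dense non-negative weighted undirected network whose nodes are the
#' samples. For distinct samples every off-diagonal weight is strictly
#' positive, so the graph is complete — hence connected and non-bipartite,
#' which is exactly the precondition under which the walk-ratio influence
#' converges.
#'
#' @param dataset An [expr_dataset] (normalize first with
#'   [minmax_normalize()]) or numeric matrix.
#' @param delta Positive kernel bandwidth.
#' @param diagonal `"zero"` (default, no self-loops) or `"one"`
#'   (self-similarity 1). A uniform diagonal shift leaves all eigenvectors
#'   unchanged, so the influence centrality is provably unaffected by this
#'   choice; `"zero"` additionally keeps class scores free of self-matches.
#' @param metric Distance metric, see [distance_matrix()].
#' @param exponent Kernel convention, see [similarity()].
#' @return A [weighted_graph] with node order equal to sample order.
#' @export
build_graph <- function(dataset, delta, diagonal = c("zero", "one"),
                        metric = "euclidean", exponent = c("squared", "raw")) {
  diagonal <- match.arg(diagonal)
  exponent <- match.arg(exponent)
  d <- distance_matrix(dataset, metric)
  w <- similarity(d, delta, exponent)
  diag(w) <- if (diagonal == "zero") 0 else 1
  weighted_graph(w, delta = delta)
}

#' Write a graph's weight matrix as delimited text
#'
#' @param graph A [weighted_graph].
#' @param path Output path (`.tsv` tab, otherwise comma).
#' @return Invisibly, `path`.
#' @export
write_graph_matrix <- function(graph, path) {
  sep <- .infer_delimiter(path)
  out <- data.frame(node_id = rownames(graph$weights), graph$weights,
                    check.names = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
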