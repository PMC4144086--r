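#' Six-node example network
#'
#' The small worked-example graph for the influence centrality: six nodes,
#' undirected unit edges 1-2, 2-3, 2-4, 3-4, 4-5, 5-6 (degree sequence
#' 1, 3, 2, 3, 2, 1). It is connected and, thanks to the triangle 2-3-4,
#' non-bipartite, so the walk-ratio influence converges; node 4's limiting
#' influence is 0.2517 to four decimals.
#'
#' @return A [weighted_graph] with 0/1 weights and node ids "1".."6".
#' @examples
#' round(node_influence(example_graph())$values, 4)
#' @export
example_graph <- function() {
  a <- matrix(0, 6, 6)
  edges <- rbind(c(1, 2), c(2, 3), c(2, 4), c(3, 4), c(4, 5), c(5, 6))
  a[edges] <- 1
  a[edges[, 2:1]] <- 1
  weighted_graph(a, node_ids = as.character(1:6))
}

#' Synthetic-data specification
#'
#' Parameters of the Gaussian class-conditional generator, chosen to
#' emulate the regime of microarray cancer cohorts: thousands of features,
#' tens to a few hundred samples, 2-7 classes, imbalanced class sizes.
#'
#' Class means sit on per-class disjoint blocks of the informative
#' features, scaled so the Euclidean distance between any two class means
#' is `sqrt(2) * class_separation`; every feature (informative or not)
#' carries i.i.d. Gaussian noise with sd `noise_sd`. Non-informative
#' features are pure noise, emulating microarray dimensionality without
#' signal.
#'
#' @param n_classes Number of classes (>= 2); defaults to
#'   `length(samples_per_class)`.
#' @param samples_per_class Integer vector of class sizes (imbalance
#'   allowed); recycled to `n_classes`.
#' @param n_features Total number of features.
#' @param n_informative Number of class-informative features
#'   (`<= n_features`).
#' @param class_separation Distance scale between class means (in noise-sd
#'   units when `noise_sd = 1`).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer RNG seed; generation is deterministic given the
#'   spec.
#' @return An object of class `synth_spec`.
#' @seealso [simulate_dataset()]
#' @export
synth_spec <- function(n_classes = length(samples_per_class),
                       samples_per_class = c(10, 50),
                       n_features = 2000, n_informative = 20,
                       class_separation = 2, noise_sd = 1, seed = 1) {
  if (n_classes < 2L) stop("need at least 2 classes")
  samples_per_class <- rep_len(as.integer(samples_per_class), n_classes)
  if (any(samples_per_class < 1L)) stop("class sizes must be positive")
  if (n_features < 1L || n_informative < 1L || n_informative > n_features)
    stop("need 1 <= n_informative <= n_features")
  if (class_separation <= 0 || noise_sd <= 0)
    stop("class_separation and noise_sd must be positive")
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = samples_per_class,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 class_separation = class_separation,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic labeled expression dataset
#'
#' Draws samples from the Gaussian class-conditional model described in
#' [synth_spec()]. Deterministic given the spec (the caller's RNG state is
#' restored afterwards).
#'
#' @param spec A [synth_spec()]; alternatively pass the spec's fields via
#'   `...` to build one on the fly.
#' @param test_fraction Optional fraction in \[0, 1): if positive, that
#'   share of each class (rounded down, stratified) is flagged `"test"`
#'   and the rest `"train"`.
#' @param ... Fields forwarded to [synth_spec()] when `spec` is missing.
#' @return A labeled [expr_dataset] with classes `C1..Cn`.
#' @examples
#' d <- simulate_dataset(samples_per_class = c(4, 8), n_features = 50,
#'                       n_informative = 10, seed = 7)
#' table(d$labels)
#' @export
simulate_dataset <- function(spec = NULL, test_fraction = 0, ...) {
  if (is.null(spec)) spec <- synth_spec(...)
  stopifnot(inherits(spec, "synth_spec"))
  if (test_fraction < 0 || test_fraction >= 1)
    stop("test_fraction must be in [0, 1)")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(spec$seed)

  n <- sum(spec$samples_per_class)
  classes <- paste0("C", seq_len(spec$n_classes))
  labels <- factor(rep(classes, spec$samples_per_class), levels = classes)

  # per-class orthogonal mean directions on disjoint informative blocks,
  # unit-normalized so any two class means are sqrt(2)*separation apart
  if (spec$n_informative < spec$n_classes)
    stop("n_informative must be >= n_classes to give every class signal")
  blocks <- split(seq_len(spec$n_informative),
                  sort(rep_len(seq_len(spec$n_classes), spec$n_informative)))
  means <- matrix(0, spec$n_classes, spec$n_features)
  for (c in seq_len(spec$n_classes)) {
    b <- blocks[[c]]
    means[c, b] <- spec$class_separation / sqrt(length(b))
  }

  values <- means[as.integer(labels), , drop = FALSE] +
    matrix(stats::rnorm(n * spec$n_features, sd = spec$noise_sd),
           n, spec$n_features)
  dimnames(values) <- list(paste0("S", seq_len(n)),
                           paste0("g", seq_len(spec$n_features)))

  split <- NULL
  if (test_fraction > 0) {
    split <- rep("train", n)
    for (cl in classes) {
      idx <- which(labels == cl)
      n_test <- floor(length(idx) * test_fraction)
      if (n_test > 0) split[sample(idx, n_test)] <- "test"
    }
  }
  expr_dataset(values, labels = labels, split = split)
}
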