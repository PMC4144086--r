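#' Min-max normalization to [0, 1] per feature
#'
#' Maps every feature (column) linearly onto \[0, 1\]:
#' `(x - min) / (max - min)`, with statistics computed over all samples in
#' the dataset. The classifier is transductive — one similarity graph is
#' built over training and test samples together — so normalization is
#' applied to the combined data, never per split. Constant features map to
#' 0 rather than being dropped, keeping feature indices stable.
#'
#' The transform is idempotent on non-constant features (after one pass the
#' minimum is 0 and the maximum is 1) and preserves within-feature order.
#'
#' @param dataset An [expr_dataset].
#' @return An [expr_dataset] with all values in \[0, 1\]; ids, labels and
#'   split flags unchanged.
#' @examples
#' d <- expr_dataset(matrix(c(0, 5, 10), 3, 1))
#' minmax_normalize(d)$values
#' @export
minmax_normalize <- function(dataset) {
  stopifnot(inherits(dataset, "expr_dataset"))
  x <- dataset$values
  if (nrow(x) == 0L || ncol(x) == 0L) stop("cannot normalize an empty dataset")
  mins <- apply(x, 2L, min)
  rng <- apply(x, 2L, max) - mins
  const <- rng == 0
  rng[const] <- 1  # constant features map to 0 below
  out <- sweep(sweep(x, 2L, mins, "-"), 2L, rng, "/")
  out[, const] <- 0
  structure(list(values = out, labels = dataset$labels, split = dataset$split),
            class = "expr_dataset")
}
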