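#' Labeled expression dataset
#'
#' Container for a samples-by-features numeric expression matrix with
#' optional per-sample class labels and train/test split flags. This is the
#' input type of every downstream step: normalization, graph construction
#' and classification. Rows are samples (a point in m-dimensional gene
#' space), columns are features.
#'
#' @param values Numeric matrix, samples in rows and features in columns.
#'   Row names are taken as sample ids and column names as feature ids;
#'   defaults (`S1..`, `g1..`) are supplied when missing.
#' @param labels Optional vector (or factor) of per-sample class labels.
#'   `NA` is allowed only for samples flagged `"test"`. The factor level
#'   order defines the declared class order used for tie-breaking.
#' @param split Optional character vector of `"train"`/`"test"` flags, one
#'   per sample.
#'
#' @return An object of class `expr_dataset`: a list with elements
#'   `values`, `labels` (factor or `NULL`) and `split` (character or
#'   `NULL`).
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' d <- expr_dataset(x, labels = c("A", "A", "B"))
#' dim(d$values)
#' @export
expr_dataset <- function(values, labels = NULL, split = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (n < 1L) stop("dataset must contain at least one sample")
  if (is.null(rownames(values))) rownames(values) <- paste0("S", seq_len(n))
  if (is.null(colnames(values))) colnames(values) <- paste0("g", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample id: ", rownames(values)[duplicated(rownames(values))][1L])
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature id: ", colnames(values)[duplicated(colnames(values))][1L])
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at sample '%s', feature '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  if (!is.null(split)) {
    split <- as.character(split)
    if (length(split) != n) stop("split must have one flag per sample")
    if (!all(split %in% c("train", "test")))
      stop("split flags must be 'train' or 'test'")
  }
  if (!is.null(labels)) {
    if (length(labels) != n) stop("labels must have one entry per sample")
    # factor levels are the declared class set: kept even when empty, since
    # a declared class without training members must surface as an error
    labels <- if (is.factor(labels)) labels else
      factor(labels, levels = unique(as.character(labels[!is.na(labels)])))
    if (anyNA(labels)) {
      if (is.null(split) || any(is.na(labels) & split == "train"))
        stop("unlabeled samples are only allowed when flagged 'test'")
    }
  }
  structure(list(values = values, labels = labels, split = split),
            class = "expr_dataset")
}

#' @export
print.expr_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels, useNA = "ifany")
    cat("Classes:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  }
  if (!is.null(x$split))
    cat(sprintf("Split: %d train, %d test\n",
                sum(x$split == "train"), sum(x$split == "test")))
  invisible(x)
}

#' @export
dim.expr_dataset <- function(x) dim(x$values)

#' Number of samples / features
#' @param dataset An [expr_dataset].
#' @return Integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$values)

#' @rdname n_samples
#' @export
n_features <- function(dataset) ncol(dataset$values)

#' Subset a dataset by sample
#'
#' @param dataset An [expr_dataset].
#' @param idx Integer, logical or character index over samples.
#' @return An [expr_dataset] with the selected samples, labels and split
#'   flags carried along (label levels are preserved, not dropped, so the
#'   declared class order survives subsetting).
#' @export
subset_samples <- function(dataset, idx) {
  values <- dataset$values[idx, , drop = FALSE]
  labels <- if (is.null(dataset$labels)) NULL else dataset$labels[idx]
  # keep the declared class order even when a class drops out of the subset
  d <- structure(list(values = values, labels = labels,
                      split = if (is.null(dataset$split)) NULL else dataset$split[idx]),
                 class = "expr_dataset")
  d
}

.infer_delimiter <- function(path, delimiter = NULL) {
  if (!is.null(delimiter)) return(delimiter)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a labeled expression matrix from delimited text
#'
#' Expects one header row, sample ids in the first column, numeric feature
#' columns, and optionally a label column and a split column. The delimiter
#' is inferred from the file extension (`.csv` comma, `.tsv` tab) unless
#' given. Any cell that does not parse as a finite number is an error naming
#' the offending sample and column.
#'
#' @param path Path to a CSV/TSV file.
#' @param label_column Name of the label column, or `NULL` for an unlabeled
#'   dataset. A column named `label` is picked up automatically if present.
#' @param delimiter Field delimiter; inferred from the extension if `NULL`.
#' @param split_column Optional name of a train/test flag column.
#' @param transpose If `TRUE` the file stores genes in rows and samples in
#'   columns and is transposed after reading (labels are not supported in
#'   this orientation).
#' @return An [expr_dataset].
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path, label_column = "label", delimiter = NULL,
                         split_column = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .infer_delimiter(path, delimiter)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", fileEncoding = "UTF-8")
  if (ncol(raw) < 2L) stop("expected at least a sample-id column and one data column")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) stop("duplicate sample id: ", ids[duplicated(ids)][1L])
  body <- raw[, -1L, drop = FALSE]

  labels <- NULL
  if (!is.null(label_column) && label_column %in% names(body)) {
    labels <- body[[label_column]]
    labels[labels %in% c("", "NA")] <- NA
    body <- body[, setdiff(names(body), label_column), drop = FALSE]
  } else if (!is.null(label_column) && !identical(label_column, "label")) {
    stop("label column '", label_column, "' not found in ", path)
  }
  split <- NULL
  if (!is.null(split_column)) {
    if (!split_column %in% names(body))
      stop("split column '", split_column, "' not found in ", path)
    split <- body[[split_column]]
    body <- body[, setdiff(names(body), split_column), drop = FALSE]
  }

  values <- matrix(NA_real_, nrow(body), ncol(body),
                   dimnames = list(ids, names(body)))
  for (j in seq_len(ncol(body))) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop(sprintf("non-numeric cell '%s' at sample '%s', column '%s'",
                   body[[j]][bad[1L]], ids[bad[1L]], names(body)[j]))
    values[, j] <- v
  }
  if (transpose) {
    if (!is.null(labels) || !is.null(split))
      stop("transpose = TRUE is only supported for unlabeled matrices")
    values <- t(values)
  }
  expr_dataset(values, labels = labels, split = split)
}

#' Write a dataset as delimited text
#'
#' Values are written with 17 significant digits so that a written-then-read
#' dataset reproduces the original to full double precision.
#'
#' @param dataset An [expr_dataset].
#' @param path Output path; the extension selects the delimiter unless
#'   `delimiter` is given.
#' @param delimiter Field delimiter; inferred from the extension if `NULL`.
#' @return Invisibly, `path`.
#' @export
write_dataset <- function(dataset, path, delimiter = NULL) {
  stopifnot(inherits(dataset, "expr_dataset"))
  if (nrow(dataset$values) == 0L) stop("refusing to write an empty dataset")
  sep <- .infer_delimiter(path, delimiter)
  vals <- dataset$values
  out <- data.frame(sample_id = rownames(vals),
                    apply(vals, 2L, function(v) sprintf("%.17g", v)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(vals) == 1L) names(out)[-1L] <- colnames(vals)  # apply() drops dims
  if (!is.null(dataset$labels)) out$label <- as.character(dataset$labels)
  if (!is.null(dataset$split)) out$split <- dataset$split
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Split a dataset into train and test parts
#'
#' Uses the dataset's split flags.
#'
#' @param dataset An [expr_dataset] with split flags.
#' @return A list with elements `train` and `test`, both [expr_dataset]s.
#' @export
split_dataset <- function(dataset) {
  if (is.null(dataset$split)) stop("dataset has no split flags")
  list(train = subset_samples(dataset, dataset$split == "train"),
       test = subset_samples(dataset, dataset$split == "test"))
}
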