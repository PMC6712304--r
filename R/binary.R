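# Binarization and prevalence filtering: every feature X is reduced to its
# presence set Samples_X = { S : abundance(X, S) > threshold }.

#' Binarize a feature table into presence sets
#'
#' Applies the strict-inequality presence rule: a feature is present in a
#' sample when its abundance exceeds the threshold (`MinCount` for OTU
#' counts, `MinIntensity` for LC-MS intensities).  With a threshold of 0,
#' zero abundance is absent.
#'
#' @param table A [feature_table].
#' @param threshold Non-negative abundance threshold; presence requires
#'   `value > threshold` (strict).
#' @return A `binary_features` object: logical presence matrix (features x
#'   samples) plus the per-feature metadata carried over from `table`.
#' @export
#' @examples
#' m <- matrix(c(0, 5, 1000, 1001), 1, 4,
#'             dimnames = list("f1", paste0("s", 1:4)))
#' b <- binarize(feature_table(m, "microbial"), threshold = 1000)
#' sample_sets(b)$f1   # only "s4"
binarize <- function(table, threshold) {
  stopifnot(inherits(table, "feature_table"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold < 0)
    abort("`threshold` must be a single non-negative number")
  presence <- table$values > threshold
  structure(list(presence = presence,
                 kind = table$kind,
                 mz = table$mz,
                 taxonomy = table$taxonomy,
                 annotation = table$annotation,
                 threshold = threshold),
            class = "binary_features")
}

#' Construct binary features directly from presence sets
#'
#' Mostly useful in tests and small worked examples; the pipeline route is
#' [binarize()].
#'
#' @param sample_sets Named list of character vectors (sample ids per
#'   feature).
#' @param samples Character vector: the sample universe.
#' @param kind `"microbial"`, `"molecular"` or `"decoy"`.
#' @param mz Optional named numeric m/z per feature.
#' @return A `binary_features` object.
#' @export
binary_features <- function(sample_sets, samples,
                            kind = c("microbial", "molecular", "decoy"),
                            mz = NULL) {
  kind <- match.arg(kind)
  if (is.null(names(sample_sets)) || anyDuplicated(names(sample_sets)))
    abort("`sample_sets` must be a uniquely named list")
  if (anyDuplicated(samples)) abort("duplicate sample ids in universe")
  presence <- matrix(FALSE, length(sample_sets), length(samples),
                     dimnames = list(names(sample_sets), samples))
  for (i in seq_along(sample_sets)) {
    s <- sample_sets[[i]]
    if (length(setdiff(s, samples)))
      abort("sample_set of '", names(sample_sets)[i],
            "' is not a subset of the universe")
    presence[i, s] <- TRUE
  }
  if (!is.null(mz)) mz <- stats::setNames(as.numeric(mz), names(sample_sets))
  structure(list(presence = presence, kind = kind, mz = mz,
                 taxonomy = NULL, annotation = NULL, threshold = NA_real_),
            class = "binary_features")
}

#' @export
print.binary_features <- function(x, ...) {
  cat(sprintf("<binary_features> %s: %d features over %d samples\n",
              x$kind, nrow(x$presence), ncol(x$presence)))
  invisible(x)
}

#' @export
dim.binary_features <- function(x) dim(x$presence)

#' @export
feature_ids.binary_features <- function(x) rownames(x$presence)

#' @export
sample_ids.binary_features <- function(x) colnames(x$presence)

#' Presence sets of binary features
#' @param x A `binary_features` object.
#' @return Named list of character vectors: the samples each feature is
#'   present in.
#' @export
sample_sets <- function(x) {
  stopifnot(inherits(x, "binary_features"))
  samples <- colnames(x$presence)
  apply(x$presence, 1L, function(row) samples[row], simplify = FALSE)
}

#' Per-feature prevalence (number of samples present)
#' @param x A `binary_features` object.
#' @return Named integer vector.
#' @export
prevalence <- function(x) {
  stopifnot(inherits(x, "binary_features"))
  rowSums(x$presence)
}

#' Subset binary features by row
#' @param x A `binary_features` object.
#' @param i Row index (ids, positions, or logical).
#' @param ... Ignored.
#' @return A `binary_features` object.
#' @export
`[.binary_features` <- function(x, i, ...) {
  x$presence <- x$presence[i, , drop = FALSE]
  keep <- rownames(x$presence)
  for (nm in c("mz", "taxonomy", "annotation")) {
    if (!is.null(x[[nm]])) {
      v <- x[[nm]]
      if (is.null(names(v))) names(v) <- rownames(x$presence)  # defensive
      x[[nm]] <- v[keep]
    }
  }
  x
}

#' Drop rare features
#'
#' Keeps exactly the features present in at least `min_samples` samples,
#' preserving order.  The pipeline defaults are `min_samples = 2` for
#' molecular features and `min_samples = 10` for BGC families.
#'
#' @param features A `binary_features` object.
#' @param min_samples Non-negative integer.
#' @return Filtered `binary_features`.
#' @export
filter_prevalence <- function(features, min_samples) {
  stopifnot(inherits(features, "binary_features"))
  if (!is_count(min_samples))
    abort("`min_samples` must be a non-negative integer")
  features[prevalence(features) >= min_samples, ]
}

#' Bundle paired binary features over one sample universe
#'
#' @param molecules,microbes `binary_features` over identical sample ids
#'   (order may differ; microbes are re-aligned to the molecules' order).
#' @return A `binary_dataset`: list with `samples`, `molecules`, `microbes`.
#' @export
binary_dataset <- function(molecules, microbes) {
  stopifnot(inherits(molecules, "binary_features"),
            inherits(microbes, "binary_features"))
  su <- colnames(molecules$presence)
  if (!setequal(su, colnames(microbes$presence)))
    abort("molecules and microbes must share one sample universe")
  microbes$presence <- microbes$presence[, su, drop = FALSE]
  structure(list(samples = su, molecules = molecules, microbes = microbes),
            class = "binary_dataset")
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf(
    "<binary_dataset> %d samples, %d molecules, %d microbes\n",
    length(x$samples), nrow(x$molecules$presence), nrow(x$microbes$presence)))
  invisible(x)
}
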