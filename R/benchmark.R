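# Benchmark harness: compare molecular feature sets and association tests
# by the number of discoveries (and of unique microbial features in them)
# at given FDR levels, under both target-decoy and BH FDR control.

#' Binarize one molecular table at a ladder of thresholds
#'
#' Convenience builder for benchmarking a feature extractor across
#' binarization stringencies; the default ladder is 10, 10^2, ..., 10^6.
#'
#' @param table A molecular [feature_table].
#' @param thresholds Numeric vector of `MinIntensity` values.
#' @param min_samples Prevalence filter applied after binarization
#'   (default 2).
#' @return Named list of dataset descriptors, each
#'   `list(features = <binary_features>, mode = "binary")`, named
#'   `bin<threshold>`.
#' @export
binarized_sets <- function(table, thresholds = 10^(1:6), min_samples = 2L) {
  stopifnot(inherits(table, "feature_table"))
  out <- lapply(thresholds, function(t)
    list(features = filter_prevalence(binarize(table, t), min_samples),
         mode = "binary"))
  names(out) <- paste0("bin", format(thresholds, scientific = FALSE,
                                     trim = TRUE))
  out
}

.default_grid <- function(test) {
  if (test == "mi") seq(0.02, 1, by = 0.02) else 10^seq(-30, -2)
}

#' Benchmark feature sets and association tests against a microbial table
#'
#' For every (dataset, test) combination, runs the full scan, builds decoys
#' from the dataset's molecular features, scans the decoys against the same
#' microbes, and reports — per FDR level — the number of associations and
#' of unique microbial features in them, under TDA selection
#' ([select_at_fdr()]) and, for tests with P values, under BH selection
#' (edges with q value <= level).
#'
#' @param molecule_sets Named list of dataset descriptors:
#'   `list(features = <binary_features or feature_table>, mode =
#'   "binary"/"continuous")` (see [binarized_sets()]).
#' @param microbes Microbial features: `binary_features` (used for
#'   `"fisher"`/`"mi"`) and/or a [feature_table] (used for
#'   `"pearson"`/`"spearman"`); pass a list
#'   `list(binary = ..., continuous = ...)` to supply both.
#' @param tests Character vector from `"fisher"`, `"pearson"`, `"spearman"`,
#'   `"mi"`.  Binary datasets are only paired with `"fisher"`/`"mi"`,
#'   continuous datasets with `"pearson"`/`"spearman"`.
#' @param fdr_levels FDR levels to report (default 0.01, 0.05, 0.1, 0.2).
#' @param seed Seed for decoy construction.
#' @param n_per_target Decoys per target (default 10; see the vignette for
#'   why calibration-grade TDA uses more than one decoy).
#' @param grids Optional named list of selection threshold grids per test.
#' @return Tibble: `dataset`, `test`, `fdr_method`, `fdr_level`,
#'   `n_associations`, `n_unique_microbes`.
#' @export
benchmark_methods <- function(molecule_sets, microbes, tests = "fisher",
                              fdr_levels = c(0.01, 0.05, 0.1, 0.2),
                              seed = 1L, n_per_target = 10L, grids = NULL) {
  if (is.null(names(molecule_sets)) || anyDuplicated(names(molecule_sets)))
    abort("`molecule_sets` must be a uniquely named list")
  bad <- setdiff(tests, c("fisher", "pearson", "spearman", "mi"))
  if (length(bad)) abort("unknown association test: ", bad[1L])
  mic_bin <- if (inherits(microbes, "binary_features")) microbes
             else microbes$binary
  mic_cont <- if (inherits(microbes, "feature_table")) microbes
              else microbes$continuous
  rows <- list()
  for (ds_name in names(molecule_sets)) {
    ds <- molecule_sets[[ds_name]]
    for (tst in tests) {
      binary_test <- tst %in% c("fisher", "mi")
      if (binary_test != identical(ds$mode, "binary")) next
      mic <- if (binary_test) mic_bin else mic_cont
      if (is.null(mic))
        abort("no microbial features of the kind needed by test '", tst, "'")
      loose <- if (tst == "mi") 0 else 1
      real <- association_scan(ds$features, mic, test = tst,
                               threshold = loose)
      decoys <- make_decoys(ds$features, seed = seed,
                            n_per_target = n_per_target)
      decoy <- association_scan(decoys, mic, test = tst, threshold = loose)
      grid <- (grids[[tst]] %||% .default_grid(tst))
      for (q in fdr_levels) {
        sel <- select_at_fdr(real, decoy, q, thresholds = grid,
                             n_per_target = n_per_target)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          dataset = ds_name, test = tst, fdr_method = "tda",
          fdr_level = q, n_associations = nrow(sel),
          n_unique_microbes = length(unique(sel$microbe_id)))
        if (tst != "mi") {
          qv <- adjust_edges(real)$q_value
          keep <- qv <= q
          rows[[length(rows) + 1L]] <- tibble::tibble(
            dataset = ds_name, test = tst, fdr_method = "bh",
            fdr_level = q, n_associations = sum(keep),
            n_unique_microbes = length(unique(real$microbe_id[keep])))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Plot a benchmark table
#'
#' Discoveries (or unique microbial features) against the FDR level, one
#' line per dataset/test, faceted by FDR method.  Requires `ggplot2`.
#'
#' @param bench Output of [benchmark_methods()].
#' @param y `"n_associations"` or `"n_unique_microbes"`.
#' @return A `ggplot` object.
#' @export
plot_benchmark <- function(bench, y = c("n_associations",
                                        "n_unique_microbes")) {
  y <- match.arg(y)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    abort("plot_benchmark requires the `ggplot2` package")
  bench$method <- paste(bench$dataset, bench$test, sep = " / ")
  ggplot2::ggplot(bench,
                  ggplot2::aes(x = .data$fdr_level, y = .data[[y]],
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~fdr_method) +
    ggplot2::labs(x = "FDR level", y = y) +
    ggplot2::theme_minimal()
}
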