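# False discovery rate estimation: the target-decoy approach (decoy
# molecular features with size-matched random presence sets, scanned against
# the same microbes) and Benjamini-Hochberg adjustment of the scan P values.

#' Construct decoy molecular features
#'
#' For every target molecular feature X a decoy X_d is built whose presence
#' set is a uniformly random subset of the sample universe of size
#' |Samples_X| (binary features).  For continuous tables the decoy is the
#' target's intensity vector randomly permuted across samples, which
#' preserves both the presence-set size and the marginal intensity
#' distribution.  Decoys are null by construction; the decoy/target pass
#' ratio estimates the FDR.
#'
#' @param molecules Target molecular features: `binary_features` or (for
#'   continuous-mode scans) a [feature_table].
#' @param seed Integer RNG seed; the draw is bit-reproducible given the
#'   seed and does not disturb the caller's RNG state.
#' @param n_per_target Number of decoys per target (default 1, the paper
#'   convention).  Larger values reduce the variance of the TDA estimate;
#'   [tda_fdr()] normalizes the decoy count accordingly.
#' @return Decoys of the same class as `molecules`, with ids
#'   `decoy<r>:<target id>`, plus attributes `source_map` (tibble
#'   `decoy_id`, `target_id`), `seed` and `n_per_target`.
#' @export
make_decoys <- function(molecules, seed, n_per_target = 1L) {
  UseMethod("make_decoys")
}

.decoy_ids <- function(ids, n_per_target) {
  unlist(lapply(seq_len(n_per_target), function(r)
    paste0("decoy", r, ":", ids)))
}

#' @export
make_decoys.binary_features <- function(molecules, seed, n_per_target = 1L) {
  stopifnot(is_count(n_per_target), n_per_target >= 1)
  n <- ncol(molecules$presence)
  sizes <- rowSums(molecules$presence)
  ids <- rownames(molecules$presence)
  pres <- with_seed(seed, {
    out <- matrix(FALSE, length(ids) * n_per_target, n)
    row <- 0L
    for (r in seq_len(n_per_target)) {
      for (i in seq_along(ids)) {
        row <- row + 1L
        if (sizes[i] > 0L)
          out[row, sample.int(n, sizes[i])] <- TRUE
      }
    }
    out
  })
  dimnames(pres) <- list(.decoy_ids(ids, n_per_target),
                         colnames(molecules$presence))
  mz <- if (!is.null(molecules$mz))
    stats::setNames(rep(unname(molecules$mz), n_per_target), rownames(pres))
  out <- structure(list(presence = pres, kind = "decoy", mz = mz,
                        taxonomy = NULL, annotation = NULL,
                        threshold = molecules$threshold),
                   class = "binary_features")
  attr(out, "source_map") <- tibble::tibble(
    decoy_id = rownames(pres), target_id = rep(ids, n_per_target))
  attr(out, "seed") <- seed
  attr(out, "n_per_target") <- as.integer(n_per_target)
  out
}

#' @export
make_decoys.feature_table <- function(molecules, seed, n_per_target = 1L) {
  stopifnot(is_count(n_per_target), n_per_target >= 1)
  v <- molecules$values
  n <- ncol(v)
  perm <- with_seed(seed, {
    out <- matrix(0, nrow(v) * n_per_target, n)
    row <- 0L
    for (r in seq_len(n_per_target)) {
      for (i in seq_len(nrow(v))) {
        row <- row + 1L
        out[row, ] <- v[i, sample.int(n)]
      }
    }
    out
  })
  ids <- .decoy_ids(rownames(v), n_per_target)
  dimnames(perm) <- list(ids, colnames(v))
  out <- feature_table(perm, kind = molecules$kind,
                       mz = if (!is.null(molecules$mz))
                         rep(unname(molecules$mz), n_per_target))
  attr(out, "source_map") <- tibble::tibble(
    decoy_id = ids, target_id = rep(rownames(v), n_per_target))
  attr(out, "seed") <- seed
  attr(out, "n_per_target") <- as.integer(n_per_target)
  out
}

#' Target-decoy FDR at one threshold
#'
#' Counts the target and decoy associations passing the threshold and
#' estimates FDR = n_decoy / (n_per_target * n_real), capped at 1 and
#' defined as 1 when no target association passes.
#'
#' @param real_edges,decoy_edges Scan outputs from [association_scan()] run
#'   with the same test over the same universe (the decoy scan uses the
#'   same microbial features).
#' @param threshold Edge-retention threshold (P value cutoff, or MI cutoff
#'   for `test = "mi"`).
#' @param n_per_target Decoys per target used in [make_decoys()].
#' @return One-row tibble: `threshold`, `n_real`, `n_decoy`, `fdr_tda`.
#' @export
tda_fdr <- function(real_edges, decoy_edges, threshold, n_per_target = 1L) {
  t_real <- scan_test(real_edges)
  t_decoy <- scan_test(decoy_edges)
  if (!is.na(t_real) && !is.na(t_decoy) && !identical(t_real, t_decoy))
    abort("real and decoy edges come from different tests: ",
          t_real, " vs ", t_decoy)
  n_real <- sum(edge_passes(real_edges, threshold))
  n_decoy <- sum(edge_passes(decoy_edges, threshold))
  fdr <- if (n_real == 0L) 1 else min(1, n_decoy / (n_per_target * n_real))
  tibble::tibble(threshold = threshold, n_real = n_real, n_decoy = n_decoy,
                 fdr_tda = fdr)
}

#' Benjamini-Hochberg adjusted P values
#'
#' Standard step-up adjustment (via [stats::p.adjust()]), returned in input
#' order and capped at 1.
#'
#' @param p_values Numeric vector of raw P values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    abort("P values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Add BH q values to an edge table
#'
#' BH is applied over the full set of tested pairs actually searched; pass
#' `m` when the edge table was pre-filtered at scan time so the correction
#' still refers to the whole family.
#'
#' @param edges Scan output with a `p_value` column.
#' @param m Family size (default: number of tested pairs recorded by the
#'   scan, falling back to `nrow(edges)`).
#' @return `edges` with a `q_value` column.
#' @export
adjust_edges <- function(edges, m = NULL) {
  if (all(is.na(edges$p_value)))
    abort("BH adjustment needs P values; MI edges have none (use TDA)")
  m <- m %||% attr(edges, "scan")$n_pairs %||% nrow(edges)
  if (any(!is.finite(edges$p_value) | edges$p_value < 0 | edges$p_value > 1))
    abort("P values must lie in [0, 1]")
  edges$q_value <- stats::p.adjust(edges$p_value, method = "BH",
                                   n = max(m, nrow(edges)))
  edges
}

#' FDR curve over a threshold grid
#'
#' One row per threshold: target and decoy pass counts, the TDA estimate,
#' and the number of edges selected by BH at that level (`n_pass_bh`, the
#' count of edges with BH q value <= threshold; `NA` for MI, which has no P
#' values).  The default grid is the log10 ladder 1e-30 ... 1e-2.
#'
#' @inheritParams tda_fdr
#' @param thresholds Sorted numeric grid of thresholds.
#' @return Tibble with columns `threshold`, `n_real`, `n_decoy`, `fdr_tda`,
#'   `n_pass_bh`.
#' @export
fdr_curve <- function(real_edges, decoy_edges,
                      thresholds = 10^seq(-30, -2), n_per_target = 1L) {
  if (is.unsorted(thresholds)) abort("`thresholds` must be sorted")
  rows <- lapply(thresholds, function(t)
    tda_fdr(real_edges, decoy_edges, t, n_per_target))
  out <- do.call(rbind, rows)
  if (!identical(scan_test(real_edges), "mi") && nrow(real_edges) > 0) {
    q <- adjust_edges(real_edges)$q_value
    out$n_pass_bh <- vapply(thresholds, function(t) sum(q <= t), integer(1))
  } else {
    out$n_pass_bh <- NA_integer_
  }
  out
}

#' Select edges at a target TDA FDR
#'
#' Scans a fixed threshold grid and returns the target edges passing the
#' most permissive grid threshold whose TDA estimate is <= `q`.  Returns an
#' empty edge set when no grid threshold qualifies (in particular when no
#' target edge passes anywhere, where the estimate is 1 by convention).
#'
#' @inheritParams fdr_curve
#' @param q Target FDR level in (0, 1).
#' @return The selected subset of `real_edges`, with attribute `selection`
#'   (the chosen grid row).
#' @export
select_at_fdr <- function(real_edges, decoy_edges, q,
                          thresholds = 10^seq(-30, -2), n_per_target = 1L) {
  stopifnot(is.numeric(q), length(q) == 1L, q > 0, q < 1)
  curve <- fdr_curve(real_edges, decoy_edges, thresholds, n_per_target)
  # permissiveness grows with the P threshold but shrinks with an MI cutoff
  ord <- if (identical(scan_test(real_edges), "mi"))
    order(curve$threshold) else order(-curve$threshold)
  ok <- which(curve$fdr_tda[ord] <= q)
  if (length(ok) == 0L) {
    out <- real_edges[0L, ]
    attr(out, "selection") <- NULL
    return(out)
  }
  pick <- ord[ok[1L]]
  out <- real_edges[edge_passes(real_edges, curve$threshold[pick]), ]
  attr(out, "selection") <- curve[pick, ]
  out
}
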