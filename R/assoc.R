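# Pairwise molecule-microbe association: Fisher's exact test on presence
# sets, Pearson/Spearman correlation on continuous abundances, and the
# plug-in mutual information criterion on presence sets.

#' Pearson correlation test between two abundance vectors
#'
#' Sample Pearson r with the two-sided P value from the t distribution on
#' n - 2 degrees of freedom.  Constant vectors cannot be tested: the pair is
#' skipped (returns `NULL`) with a message.
#'
#' @param x_values,y_values Numeric vectors of equal length >= 3.
#' @return List with `statistic` (r) and `p_value`, or `NULL` for a constant
#'   input.
#' @export
pearson_test <- function(x_values, y_values) {
  n <- length(x_values)
  if (length(y_values) != n || n < 3L)
    abort("need two equal-length vectors with n >= 3")
  if (stats::sd(x_values) == 0 || stats::sd(y_values) == 0) {
    message("constant abundance vector: association skipped")
    return(NULL)
  }
  r <- stats::cor(x_values, y_values)
  p <- .cor_p(r, n)
  list(statistic = r, p_value = p)
}

#' Spearman rank correlation test
#'
#' Pearson correlation of mid-ranks (ties receive average ranks), with the
#' two-sided P value from the t approximation on n - 2 degrees of freedom.
#' Invariant under strictly monotone transforms of either input.
#'
#' @inheritParams pearson_test
#' @return List with `statistic` (rho) and `p_value`, or `NULL` for a
#'   constant input.
#' @export
spearman_test <- function(x_values, y_values) {
  n <- length(x_values)
  if (length(y_values) != n || n < 3L)
    abort("need two equal-length vectors with n >= 3")
  pearson_test(rank(x_values), rank(y_values))
}

# two-sided P for a correlation r at sample size n via t_{n-2}
.cor_p <- function(r, n) {
  rc <- pmin(1, pmax(-1, as.vector(r)))
  tt <- rc * sqrt((n - 2) / pmax(1 - rc^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  if (is.matrix(r)) p <- matrix(p, nrow(r), ncol(r), dimnames = dimnames(r))
  p
}

# vectorized plug-in MI (bits) from cooccurrence count and margins
mi_vec <- function(a, kx, ky, n) {
  b <- kx - a
  cc <- ky - a
  d <- n - a - b - cc
  joint <- cbind(a, b, cc, d) / n
  px <- kx / n
  py <- ky / n
  marg <- cbind(px * py, px * (1 - py), (1 - px) * py, (1 - px) * (1 - py))
  mi <- rowSums(xlog2x(joint)) -
    rowSums(ifelse(joint > 0, joint * log2(pmax(marg, .Machine$double.xmin)),
                   0))
  pmax(mi, 0)
}

#' Mutual information between two presence indicators
#'
#' Plug-in mutual information of the empirical joint distribution of the two
#' presence indicators, in bits, with the 0 log 0 = 0 convention.  Always
#' >= 0; exactly 0 when the empirical joint factorizes.
#'
#' @param x,y Presence sets (character vectors of sample ids) or logical
#'   presence vectors.
#' @param samples Sample universe.
#' @return Mutual information in bits.
#' @export
#' @examples
#' mutual_information(c("s1", "s2"), c("s1", "s2"), paste0("s", 1:4)) # 1 bit
mutual_information <- function(x, y, samples) {
  t <- contingency(x, y, samples)
  unname(mi_vec(t[1], t[1] + t[2], t[1] + t[3], sum(t)))
}

#' All-pairs molecule-microbe association scan
#'
#' Evaluates every (molecule, microbe) pair with the chosen test and keeps
#' the pairs passing the threshold: `p_value < threshold` for Fisher,
#' Pearson and Spearman, `statistic >= threshold` for mutual information
#' (which has no P value).  Each retained edge carries its direction from
#' [sign_of_association()] (Fisher/MI) or the sign of the correlation.
#' Output order is deterministic: molecule id, then microbe id.
#'
#' @param molecules,microbes For `test = "fisher"` or `"mi"`:
#'   `binary_features` over one sample universe (or pass a [binary_dataset]
#'   as `molecules` and omit `microbes`).  For `"pearson"`/`"spearman"`:
#'   [feature_table] objects over identical samples.
#' @param test One of `"fisher"`, `"pearson"`, `"spearman"`, `"mi"`.
#' @param threshold Retention threshold (see above).  Use `threshold = 1`
#'   (Fisher/Pearson/Spearman) or `0` (MI) to keep all testable pairs.
#' @param log10_intensities Log10-transform `x + 1` before the continuous
#'   tests (off by default; raw intensities are the paper-facing default).
#' @return A tibble of association edges with columns `molecule_id`,
#'   `microbe_id`, `mz`, `test`, `statistic`, `p_value`, `sign`, plus a
#'   `scan` attribute recording the settings.
#' @export
association_scan <- function(molecules, microbes = NULL,
                             test = c("fisher", "pearson", "spearman", "mi"),
                             threshold = 1e-10, log10_intensities = FALSE) {
  if (inherits(molecules, "binary_dataset")) {
    microbes <- molecules$microbes
    molecules <- molecules$molecules
  }
  if (is.character(test) && length(test) == 1L &&
      !test %in% c("fisher", "pearson", "spearman", "mi"))
    abort("unknown association test: ", test)
  test <- match.arg(test)

  if (test %in% c("fisher", "mi")) {
    if (!inherits(molecules, "binary_features") ||
        !inherits(microbes, "binary_features"))
      abort(test, " needs binarized features; see binarize()")
    su <- colnames(molecules$presence)
    if (!setequal(su, colnames(microbes$presence)))
      abort("molecules and microbes must share one sample universe")
    Pm <- molecules$presence
    Pb <- microbes$presence[, su, drop = FALSE]
    n <- length(su)
    A <- tcrossprod(Pm * 1, Pb * 1)          # cooccurrence counts
    kx <- unname(rowSums(Pm))
    ky <- unname(rowSums(Pb))
    long_a <- as.vector(A)
    long_kx <- rep(kx, times = length(ky))
    long_ky <- rep(ky, each = length(kx))
    if (test == "fisher") {
      stat_p <- fisher_p_vec(long_a, long_kx, long_ky, n)
      keep <- stat_p < threshold
      statistic <- {
        b <- long_kx - long_a; cc <- long_ky - long_a
        d <- n - long_a - b - cc
        (long_a * d) / (b * cc)
      }
      p_value <- stat_p
    } else {
      statistic <- mi_vec(long_a, long_kx, long_ky, n)
      keep <- statistic >= threshold
      p_value <- rep(NA_real_, length(statistic))
    }
    sign <- ifelse(long_a * n >= long_kx * long_ky, "positive", "negative")
    mol_id <- rep(rownames(Pm), times = length(ky))
    mic_id <- rep(rownames(Pb), each = length(kx))
    mz <- if (!is.null(molecules$mz))
      unname(molecules$mz[mol_id]) else rep(NA_real_, length(mol_id))
    edges <- tibble::tibble(molecule_id = mol_id[keep],
                            microbe_id = mic_id[keep],
                            mz = mz[keep],
                            test = test,
                            statistic = statistic[keep],
                            p_value = p_value[keep],
                            sign = sign[keep])
    n_pairs <- length(long_a)
  } else {
    if (!inherits(molecules, "feature_table") ||
        !inherits(microbes, "feature_table"))
      abort(test, " needs continuous feature_table inputs")
    su <- sample_ids(molecules)
    if (!setequal(su, sample_ids(microbes)))
      abort("molecules and microbes must share one sample universe")
    Xm <- molecules$values
    Xb <- microbes$values[, su, drop = FALSE]
    if (log10_intensities) {
      Xm <- log10(Xm + 1)
      Xb <- log10(Xb + 1)
    }
    if (test == "spearman") {
      Xm <- t(apply(Xm, 1L, rank))
      Xb <- t(apply(Xb, 1L, rank))
    }
    n <- length(su)
    ok_m <- apply(Xm, 1L, stats::sd) > 0
    ok_b <- apply(Xb, 1L, stats::sd) > 0
    n_skip <- sum(!ok_m) * nrow(Xb) + sum(ok_m) * sum(!ok_b)
    if (n_skip > 0)
      message(n_skip, " pair(s) skipped: constant abundance vector")
    R <- stats::cor(t(Xm[ok_m, , drop = FALSE]),
                    t(Xb[ok_b, , drop = FALSE]))
    P <- .cor_p(R, n)
    keep <- P < threshold
    idx <- which(keep, arr.ind = TRUE)
    mol_id <- rownames(R)[idx[, 1L]]
    mic_id <- colnames(R)[idx[, 2L]]
    mz <- if (!is.null(molecules$mz))
      unname(molecules$mz[mol_id]) else rep(NA_real_, length(mol_id))
    edges <- tibble::tibble(molecule_id = mol_id,
                            microbe_id = mic_id,
                            mz = mz,
                            test = test,
                            statistic = R[keep],
                            p_value = P[keep],
                            sign = ifelse(R[keep] >= 0,
                                          "positive", "negative"))
    n_pairs <- sum(ok_m) * sum(ok_b)
  }
  edges <- edges[order(edges$molecule_id, edges$microbe_id), ]
  attr(edges, "scan") <- list(test = test, threshold = threshold,
                              n_samples = length(su), n_pairs = n_pairs,
                              n_molecules = nrow(molecules$presence %||%
                                                   molecules$values),
                              n_microbes = nrow(microbes$presence %||%
                                                  microbes$values))
  edges
}

# threshold semantics per test: smaller-is-better P values vs
# larger-is-better MI statistics
edge_passes <- function(edges, threshold) {
  tst <- scan_test(edges)
  if (identical(tst, "mi")) edges$statistic >= threshold
  else edges$p_value < threshold
}

scan_test <- function(edges) {
  sc <- attr(edges, "scan")
  if (!is.null(sc$test)) return(sc$test)
  tst <- unique(edges$test)
  if (length(tst) > 1L) abort("edges mix association tests")
  if (length(tst) == 0L) NA_character_ else tst
}
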