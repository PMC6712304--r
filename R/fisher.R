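# Two-sided Fisher's exact test on 2x2 presence/absence tables.
#
# The all-pairs scan evaluates up to 10^8 tables, so the P value engine is
# written for batches: tables sharing margins (k_x, k_y, n) share one
# hypergeometric support, which is enumerated once per margin pair.
# For n <= 55 every point probability numerator choose(kx, a) *
# choose(n - kx, ky - a) and the common denominator choose(n, ky) are
# integers below 2^53, so the two-sided mass is accumulated by exact integer
# comparison (exact rational arithmetic in doubles).  Larger tables use
# log-space hypergeometric probabilities with the conventional 1 + 1e-7
# relative tie tolerance.

.EXACT_N_MAX <- 55L

#' Build a 2x2 contingency table from two presence sets
#'
#' @param x,y `binary_features` rows, character presence sets, or logical
#'   presence vectors over `samples`.
#' @param samples Character vector, the sample universe (ignored when both
#'   `x` and `y` are logical vectors of equal length).
#' @return Named integer vector `c(a, b, c, d)`: both present, x only,
#'   y only, neither.
#' @export
#' @examples
#' contingency(c("s1", "s2"), c("s3", "s4"), paste0("s", 1:4))
contingency <- function(x, y, samples) {
  as_logical <- function(v) {
    if (is.logical(v)) {
      if (length(v) != length(samples))
        abort("logical presence vector must match the universe length")
      v
    } else {
      if (length(setdiff(v, samples)))
        abort("presence set is not a subset of the sample universe")
      samples %in% v
    }
  }
  if (is.logical(x) && is.logical(y) && missing(samples))
    samples <- seq_along(x)
  xl <- as_logical(x)
  yl <- as_logical(y)
  a <- sum(xl & yl)
  b <- sum(xl & !yl)
  cc <- sum(!xl & yl)
  d <- sum(!xl & !yl)
  c(a = a, b = b, c = cc, d = d)
}

# Two-sided P values for batches of 2x2 tables given by the cooccurrence
# count `a`, the margins kx = a + b, ky = a + c, and the universe size n.
# Vectorized over tables; grouped internally by (kx, ky).
fisher_p_vec <- function(a, kx, ky, n) {
  stopifnot(length(kx) == length(a), length(ky) == length(a),
            length(n) == 1L)
  p <- numeric(length(a))
  key <- paste(kx, ky, sep = ":")
  for (grp in split(seq_along(a), key)) {
    kx1 <- kx[grp[1L]]
    ky1 <- ky[grp[1L]]
    lo <- max(0L, kx1 + ky1 - n)
    hi <- min(kx1, ky1)
    support <- lo:hi
    if (length(support) == 1L) {
      p[grp] <- 1
      next
    }
    if (n <= .EXACT_N_MAX) {
      num <- choose(kx1, support) * choose(n - kx1, ky1 - support)
      denom <- choose(n, ky1)
      obs <- num[a[grp] - lo + 1L]
      p[grp] <- vapply(obs, function(o) sum(num[num <= o]) / denom,
                       numeric(1))
    } else {
      ld <- stats::dhyper(support, ky1, n - ky1, kx1, log = TRUE)
      d <- exp(ld)
      obs <- ld[a[grp] - lo + 1L]
      p[grp] <- vapply(obs, function(o) {
        sum(d[ld <= o + log(1 + 1e-7)])
      }, numeric(1))
    }
  }
  pmin(p, 1)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact P value under the hypergeometric null with fixed margins, two-sided
#' in the usual sense: the total probability of all tables whose point
#' probability does not exceed that of the observed table.  Degenerate
#' margins (a single feasible table) give P = 1.
#'
#' @param t Contingency table from [contingency()] (or any numeric vector
#'   `c(a, b, c, d)`).
#' @return List with `estimate` (the sample odds ratio `ad/bc`) and
#'   `p_value`.
#' @export
#' @examples
#' fisher_exact(c(4, 0, 0, 4))$p_value   # 2/70
fisher_exact <- function(t) {
  t <- as.numeric(t)
  if (length(t) != 4L || any(!is.finite(t)) || any(t < 0) ||
      any(t != round(t)))
    abort("`t` must be four non-negative integer cells c(a, b, c, d)")
  a <- t[1]; b <- t[2]; cc <- t[3]; d <- t[4]
  n <- a + b + cc + d
  p <- if (n == 0) 1 else fisher_p_vec(a, a + b, a + cc, n)
  est <- (a * d) / (b * cc)
  list(estimate = est, p_value = p)
}

#' Direction of a cooccurrence association
#'
#' Positive when the observed cooccurrence exceeds its expectation under
#' independence (`a * n > (a + b) * (a + c)`); negative otherwise.  Exact
#' equality is called positive by convention and flagged.
#'
#' @param t 2x2 table `c(a, b, c, d)`.
#' @return Character `"positive"` or `"negative"`, with logical attribute
#'   `tie` set when observed equals expected.
#' @export
sign_of_association <- function(t) {
  t <- as.numeric(t)
  a <- t[1]; b <- t[2]; cc <- t[3]
  n <- sum(t)
  lhs <- a * n
  rhs <- (a + b) * (a + cc)
  out <- if (lhs >= rhs) "positive" else "negative"
  attr(out, "tie") <- lhs == rhs
  out
}
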