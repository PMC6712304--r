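# Independent oracles and small fixture builders used across the suite.

# Exhaustive two-sided Fisher P by definition: enumerate every 2x2 table
# with the observed margins, compute each table's point probability from
# the transposed hypergeometric decomposition C(ky, a') C(n - ky, kx - a') /
# C(n, kx), and sum the probabilities <= that of the observed table.
# For n <= 30 every numerator and the denominator are integers below 2^53,
# so the comparison and the sum are exact rational arithmetic.
oracle_fisher_p <- function(a, b, cc, d) {
  n <- a + b + cc + d
  kx <- a + b
  ky <- a + cc
  lo <- max(0L, kx + ky - n)
  hi <- min(kx, ky)
  supp <- lo:hi
  num <- choose(ky, supp) * choose(n - ky, kx - supp)
  obs <- num[a - lo + 1L]
  sum(num[num <= obs]) / choose(n, kx)
}

# all 2x2 tables (a, b, c, d) with a + b + c + d == n
all_tables_n <- function(n) {
  out <- list()
  for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
    out[[length(out) + 1L]] <- c(a, b, cc, n - a - b - cc)
  }
  do.call(rbind, out)
}

# Benjamini-Hochberg by the step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q <- vapply(seq_len(m), function(i) min(1, min(sorted[i:m] * m / (i:m))),
              numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force clade assignment: enumerate every internal node's leaf set
# via ape::prop.part and apply the selection rule by definition.  With
# percent > 50 the qualifying clades are nested, so the minimal one is
# unique and identified by its leaf set.
oracle_assign_leaves <- function(tree, marked, percent) {
  pp <- ape::prop.part(tree)
  n_tip <- length(tree$tip.label)
  total <- length(marked)
  root_set <- seq_len(n_tip)
  best <- NULL
  for (i in seq_along(pp)) {
    leaves <- tree$tip.label[pp[[i]]]
    if (setequal(pp[[i]], root_set)) next           # root: not a proper clade
    n_marked <- sum(marked %in% leaves)
    if (n_marked * 100 >= percent * total) {
      if (is.null(best) || length(leaves) < length(best)) best <- leaves
    }
  }
  if (is.null(best)) NULL else sort(best)
}

# small binary fixture: features as explicit presence sets over s1..sn
toy_binary <- function(sets, n, kind = "molecular", mz = NULL) {
  binary_features(sets, paste0("s", seq_len(n)), kind = kind, mz = mz)
}

toy_table <- function(values, kind = "microbial", ...) {
  feature_table(values, kind = kind, ...)
}

# deterministic planted simulation + standard binarization
planted_scan_inputs <- function(seed, n_planted = 20L, ...) {
  sim <- simulate_dataset(sim_config(n_planted = n_planted, seed = seed, ...))
  list(mol = filter_prevalence(binarize(sim$molecules, 0), 2L),
       mic = binarize(sim$microbes, 0),
       truth = sim$truth)
}
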