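# Deduplication of molecular features: feature extractors report one
# molecule as several features at nearly identical m/z.  A pair is a
# putative duplicate when it passes both the m/z gate and the cooccurrence
# gate; connected components of the duplicate graph become consensus
# features.

#' Candidate duplicate pairs of molecular features
#'
#' Returns exactly the unordered pairs with `|mz_i - mz_j| <= mz_tol`, a
#' two-sided Fisher's exact P value `<= p_threshold` for the cooccurrence of
#' their presence sets over the sample universe, and positive cooccurrence
#' (observed above expected; duplicates are one molecule reported twice, so
#' significant mutual exclusion never qualifies).  Candidates are generated
#' by sorting on m/z and sliding a window of width `mz_tol`, so only the
#' m/z-compatible fraction of the O(n^2) pairs is ever tested (both gates
#' are conjunctive, so the output is unchanged).
#'
#' @param molecules Molecular `binary_features` carrying m/z values.
#' @param mz_tol Absolute m/z tolerance in Thomson (default 0.01).
#' @param p_threshold Fisher P value cutoff (default 1e-5).  Deduplication
#'   P values are not multiplicity-corrected; this is a fixed gate.
#' @return Tibble with columns `id1`, `id2`, `delta_mz`, `p_value`.
#' @export
duplicate_pairs <- function(molecules, mz_tol = 0.01, p_threshold = 1e-5) {
  stopifnot(inherits(molecules, "binary_features"))
  if (is.null(molecules$mz)) abort("deduplication requires m/z values")
  if (!is.numeric(mz_tol) || mz_tol <= 0) abort("`mz_tol` must be > 0")
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    abort("`p_threshold` must be in (0, 1]")
  mz <- molecules$mz
  ord <- order(mz, names(mz))
  ids <- names(mz)[ord]
  mzs <- unname(mz[ord])
  n_feat <- length(ids)
  i1 <- integer(0); i2 <- integer(0)
  j <- 1L
  for (i in seq_len(n_feat)) {
    while (j <= n_feat && mzs[j] <= mzs[i] + mz_tol) j <- j + 1L
    if (j - 1L > i) {
      i1 <- c(i1, rep.int(i, j - 1L - i))
      i2 <- c(i2, (i + 1L):(j - 1L))
    }
  }
  if (length(i1) == 0L)
    return(tibble::tibble(id1 = character(), id2 = character(),
                          delta_mz = numeric(), p_value = numeric()))
  P <- molecules$presence
  n <- ncol(P)
  a <- rowSums(P[ids[i1], , drop = FALSE] & P[ids[i2], , drop = FALSE])
  kx <- rowSums(P[ids[i1], , drop = FALSE])
  ky <- rowSums(P[ids[i2], , drop = FALSE])
  p <- fisher_p_vec(a, kx, ky, n)
  # duplicates are one molecule reported twice: they must POSITIVELY
  # cooccur, so significant anti-cooccurrence never pairs
  keep <- p <= p_threshold & a * n > kx * ky
  out <- tibble::tibble(id1 = ids[i1][keep], id2 = ids[i2][keep],
                        delta_mz = abs(mzs[i2] - mzs[i1])[keep],
                        p_value = p[keep])
  swap <- out$id1 > out$id2
  tmp <- out$id1[swap]; out$id1[swap] <- out$id2[swap]; out$id2[swap] <- tmp
  out[order(out$id1, out$id2), ]
}

#' Merge duplicate molecular features into consensus features
#'
#' Builds the duplicate graph (nodes = molecular features, edges =
#' [duplicate_pairs()]) and merges each connected component into one
#' consensus feature whose m/z is the unweighted mean of the members' m/z
#' and whose presence set is the union of the members' presence sets.
#' Singleton components pass through unchanged; multi-member components are
#' named `dedup:` plus the lexicographically smallest member id.  Because
#' groups are connected components, transitive chains can merge features
#' whose pairwise m/z difference exceeds the tolerance.
#'
#' @inheritParams duplicate_pairs
#' @return A `dedup_result`: list with `features` (consensus
#'   `binary_features`), `groups` (tibble `member_id`, `consensus_id`,
#'   `consensus_mz`) and `pairs` (the duplicate pairs used).
#' @export
deduplicate <- function(molecules, mz_tol = 0.01, p_threshold = 1e-5) {
  pairs <- duplicate_pairs(molecules, mz_tol, p_threshold)
  ids <- feature_ids(molecules)
  g <- igraph::graph_from_data_frame(pairs[, c("id1", "id2")],
                                     directed = FALSE,
                                     vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  members <- split(ids, comp)
  consensus <- lapply(members, function(m) {
    m <- sort(m)
    cid <- if (length(m) == 1L) m else paste0("dedup:", m[1L])
    list(id = cid,
         members = m,
         mz = mean(molecules$mz[m]),
         pres = if (length(m) == 1L) molecules$presence[m, ]
                else colSums(molecules$presence[m, , drop = FALSE]) > 0)
  })
  ord <- order(vapply(consensus, `[[`, character(1), "id"))
  consensus <- consensus[ord]
  pres <- do.call(rbind, lapply(consensus, `[[`, "pres"))
  rownames(pres) <- unname(vapply(consensus, `[[`, character(1), "id"))
  colnames(pres) <- colnames(molecules$presence)
  feats <- structure(list(presence = pres, kind = "molecular",
                          mz = stats::setNames(
                            vapply(consensus, `[[`, numeric(1), "mz"),
                            rownames(pres)),
                          taxonomy = NULL, annotation = NULL,
                          threshold = molecules$threshold),
                     class = "binary_features")
  groups <- tibble::tibble(
    member_id = unname(unlist(lapply(consensus, `[[`, "members"))),
    consensus_id = rep(rownames(pres),
                       vapply(consensus, function(x) length(x$members),
                              integer(1))),
    consensus_mz = rep(unname(feats$mz),
                       vapply(consensus, function(x) length(x$members),
                              integer(1))))
  structure(list(features = feats, groups = groups, pairs = pairs),
            class = "dedup_result")
}

#' @export
print.dedup_result <- function(x, ...) {
  cat(sprintf("<dedup_result> %d features -> %d consensus features (%d merged groups)\n",
              nrow(x$groups), nrow(x$features$presence),
              sum(table(x$groups$consensus_id) > 1L)))
  invisible(x)
}
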