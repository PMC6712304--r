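# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort <- function(...) stop(..., call. = FALSE)

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state on
#' exit, so that seeded pipeline steps (decoy construction, simulation) do not
#' perturb the global random stream.
#'
#' @param seed Integer seed (< 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# xlogx with the 0 * log(0) = 0 convention, in bits; preserves dim
xlog2x <- function(x) {
  out <- x * 0
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
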