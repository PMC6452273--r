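#' @useDynLib cooccurphylo, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pchisq pt rbinom rexp rlnorm runif setNames sd
#' @importFrom utils head
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package funnel through this so that a seed argument fully determines output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Deterministically folds a master seed and a stage tag into a new seed in
#' `[1, 2^31 - 2]`, so that every stochastic stage of a run draws from its own
#' reproducible substream while the whole run is controlled by one seed.
#'
#' @param master integer master seed.
#' @param tag character tag naming the stage (e.g. `"screen"`).
#' @return a single integer seed.
#' @export
derive_seed <- function(master, tag) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483562 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
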