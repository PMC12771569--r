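#' @useDynLib mindstate, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft rnorm runif rexp rlnorm rbinom median sd var
#'   quantile pt t.test wilcox.test complete.cases aggregate
#' @importFrom utils write.table read.table head tail
NULL

MIND_STATES <- c("ON", "MW", "MB")

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's RNG stream. All stochastic operations in the package run through
#' this helper, which is what makes sessions bit-identical for a fixed seed.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Derive a child seed from a parent seed
#'
#' Deterministic splitting scheme used to fan one top-level seed out to
#' pipeline stages (and permutations) so that stages can be re-run in
#' isolation: `child = (parent + 1000003 * k) mod (2^31 - 1)`.
#'
#' @param seed parent integer seed.
#' @param k stage index (integer >= 1).
#' @return integer child seed.
#' @export
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(k)) %% 2147483647)
}

ms_log <- function(..., verbose = getOption("mindstate.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[mindstate] ", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
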