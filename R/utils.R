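#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number stream set from `seed`, then
#' restores the caller's stream, so seeded helpers do not perturb user code.
#' With `seed = NULL` the expression runs against the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(code)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ct <- function(...) stop(..., call. = FALSE)
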