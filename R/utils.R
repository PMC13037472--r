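# internal helpers -----------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a component seed from a single pipeline seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived from
#' one user-supplied integer, so that stages are individually reproducible
#' and re-ordering stages does not change their draws.  The result is always
#' a positive integer below 2^31.
#'
#' @param seed integer master seed.
#' @param stream small non-negative integer identifying the component.
#' @return a valid integer seed.
#' @export
split_seed <- function(seed, stream = 0L) {
  # arithmetic kept in doubles (< 2^53, exact), reduced into integer range
  x <- (as.numeric(seed) %% 2147483647) * 7919 + as.numeric(stream) * 104729
  as.integer(x %% 2147483629) + 1L
}

# fixed 6-significant-digit float formatting used by all writers so that
# identical inputs always produce byte-identical files
fmt_num <- function(x) {
  if (is.numeric(x) && !is.integer(x)) sprintf("%.6g", x) else as.character(x)
}

stop_ <- function(...) stop(..., call. = FALSE)
warn_ <- function(...) warning(..., call. = FALSE)

# seed a stochastic operation without clobbering the caller's RNG stream:
# sets the seed for the calling function's scope and restores the previous
# .Random.seed state when that function exits
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  withr::defer({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, envir = env)
  set.seed(seed)
}
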