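`%||%` <- function(a, b) if (is.null(a)) b else a

stop_mrd <- function(...) stop(..., call. = FALSE)

#' @keywords internal
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_mrd(msg)
  invisible(TRUE)
}

# single RNG scope helper: run expr under a local seed without disturbing
# the caller's RNG stream when a seed is supplied
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation (keeps values < 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}
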