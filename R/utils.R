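#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package route through this so that a
## (inputs, seed) pair is bit-reproducible regardless of surrounding code.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

## Derive a child seed from a base seed and a stream index; keeps every
## sub-computation on its own reproducible stream while staying < 2^31.
child_seed <- function(seed, index) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000000L) * 2011L + as.integer(index) %% 2011L
}

rr_log <- function(..., verbose = getOption("rrscreen.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[rrscreen] ", ...)
  invisible(NULL)
}

stop2 <- function(...) stop(..., call. = FALSE)

## Missing-value code used by feature extractors on degenerate input
## (e.g. ACF of a constant window). NA_real_ keeps arithmetic honest and is
## what downstream selection/summaries drop explicitly.
rr_na <- NA_real_
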