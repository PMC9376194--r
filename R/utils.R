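#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Deterministic per-stage seed derivation from one master seed.
#' Keeps results below .Machine$integer.max so seeds remain valid R integers.
#' @noRd
.deriveSeed <- function(master, stage) {
  as.integer((as.numeric(master) * 131L + as.numeric(stage) * 7919L) %%
               (.Machine$integer.max - 1L)) + 1L
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("%s contains non-finite values", what)
  invisible(TRUE)
}
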