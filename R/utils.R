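# Run code with a temporary RNG state.  If seed is NULL the expression is
# evaluated as-is; otherwise the caller's .Random.seed is restored on exit
# so seeded internals never perturb the session RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# type-1 (inverse ECDF) empirical quantile, the convention used for all
# tertile cutoffs in this package
quantile1 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 1, na.rm = FALSE, names = FALSE)
}
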