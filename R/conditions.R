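## Classed error conditions used throughout the package.  Every error
## raised here carries a specific class (e.g. "degenerateSpectrum") plus
## the umbrella class "cocrystalDS_error", so callers can handle failure
## modes individually with tryCatch().

.stopc <- function(class, msg, ...) {
  if (length(list(...))) msg <- sprintf(msg, ...)
  stop(errorCondition(msg, class = c(class, "cocrystalDS_error")))
}

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
## RNG state afterwards.  seed = NULL means "use the current RNG stream"
## (needed by the closed-loop simulator, which seeds once per run).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Universal gas constant, J mol^-1 K^-1 (CODATA).
.RGAS <- 8.314462618
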