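#' @keywords internal
"_PACKAGE"

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored on exit. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_nm <- function(...) stop(..., call. = FALSE)

# Solve log-normal (meanlog, sdlog) from a printed median and interquartile
# range; quartile ratio pins sdlog since q75/q25 = exp(2 * 0.6745 * sdlog).
lnorm_from_quartiles <- function(median, q25, q75) {
  if (!(q25 > 0 && q75 > q25 && median > 0))
    stop_nm("log-normal calibration needs 0 < q25 < q75 and median > 0")
  sdlog <- log(q75 / q25) / (2 * qnorm(0.75))
  list(meanlog = log(median), sdlog = sdlog)
}
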