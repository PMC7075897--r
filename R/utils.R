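#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx median rlnorm rnorm rpois runif
#' @importFrom utils read.delim write.table packageVersion
NULL

# Run code with a private RNG stream seeded from `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic 32-bit sub-seed for a named pipeline stage.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) + 1000003 * h) %% .Machine$integer.max)
}

msg <- function(...) message("[proxireg] ", ...)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
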