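# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic round-half-up (base round() is round-half-even).
roundHalfUp <- function(x) floor(x + 0.5)

# Linear resampling of a sequence to length L over a common [0, 1] support.
resampleLinear <- function(v, L) {
  stopifnot(L >= 2L)
  if (length(v) == L) return(as.numeric(v))
  if (length(v) == 1L) return(rep(as.numeric(v), L))
  stats::approx(seq(0, 1, length.out = length(v)), v,
                xout = seq(0, 1, length.out = L))$y
}

rmsValue <- function(x) sqrt(mean(x^2))

# Derive a child seed from a base seed, kept within 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12289) %% 2147483587)
}

assertScalarPositive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
  invisible(x)
}
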