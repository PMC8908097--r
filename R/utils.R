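# Small shared helpers: moments, seed handling, provenance fingerprints.

#' Sample skewness
#'
#' Moment estimator of skewness, `m3 / m2^(3/2)` with central moments
#' computed with denominator `n`. Zero-variance input returns `NA`.
#'
#' @param x numeric vector; `NA`s are dropped.
#' @return A single numeric value.
#' @export
sample_skewness <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) return(NA_real_)
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 <= 0) return(NA_real_)
  mean(xc^3) / m2^1.5
}

# Run `expr` under a local RNG stream seeded with `seed`; restores the
# caller's RNG state. A NULL seed runs in the ambient stream.
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

#' Derive a child RNG seed from a master seed
#'
#' Deterministic integer mixing so that each stage/level of an experiment
#' gets an independent, reproducible stream and adding a level does not
#' perturb the streams of other levels. Result is in `[1, 2^31 - 2]`.
#'
#' @param master integer master seed.
#' @param index non-negative integer identifying the stage or level.
#' @return An integer seed.
#' @export
derive_seed <- function(master, index) {
  m <- 2147483647           # 2^31 - 1 (Mersenne prime modulus)
  s <- (as.double(master) %% m) + 1
  s <- (s * 48271) %% m     # minimal-standard LCG mixing
  s <- (s + (as.double(index) + 1) * 1299721) %% m
  s <- (s * 48271) %% m
  as.integer(if (s < 1) 1 else s)
}

# Polynomial rolling hash (mod 2^31 - 1) over the deparsed object; used to
# stamp output files with a short provenance fingerprint (not cryptographic).
fingerprint <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  m <- 2147483647
  for (b in bytes) h <- (h * 131 + b) %% m
  sprintf("%08x", as.integer(h))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
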