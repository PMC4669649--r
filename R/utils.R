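# Internal numerical helpers.

# Evaluate a seeded expression without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit seed from a master seed; stays inside 32-bit range.
deriveSeed <- function(seed, i) {
  as.integer((abs(as.numeric(seed)) %% 1000003) * 2048 + (i %% 2048) +
               1013 * ((i %/% 2048) %% 1024))
}

# Bivariate normal density with closed-form 2x2 inverse/determinant.
dbvnorm <- function(x, mu, sigma, log = FALSE) {
  a <- sigma[1L, 1L]; b <- sigma[1L, 2L]; d <- sigma[2L, 2L]
  det2 <- a * d - b * b
  dx <- x[, 1L] - mu[1L]
  dy <- x[, 2L] - mu[2L]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det2
  lg <- -log(2 * pi) - 0.5 * log(det2) - 0.5 * q
  if (log) lg else exp(lg)
}

# Symmetrize and, when near-singular (smaller eigenvalue < ratio * larger),
# inflate the diagonal by eps * trace/2 (or eps when the trace is zero).
regularizeCov <- function(sigma, eps = 1e-6, ratio = 1e-10) {
  sigma <- (sigma + t(sigma)) / 2
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2L] <= 0 || ev[2L] < ratio * ev[1L]) {
    tr <- sigma[1L, 1L] + sigma[2L, 2L]
    bump <- if (tr > 0) eps * tr / 2 else eps
    sigma <- sigma + diag(bump, 2L)
  }
  sigma
}

genotypeIndex <- function(g) match(g, GENOTYPE_LEVELS)
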