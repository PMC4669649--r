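# Shared in-code fixtures for the test suite.

# A tiny deterministic panel: 3 samples x 2 SNPs.
tinyPanel <- function() {
  r <- matrix(c(10, 5, 1,
                8, 4, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("snpA", "snpB"), c("s1", "s2", "s3")))
  g <- matrix(c(1, 5, 9,
                2, 4, 7), nrow = 2, byrow = TRUE,
              dimnames = dimnames(r))
  IntensityPanel(red = r, green = g)
}

# A hand-specified ClusterModel with well-separated unit-scale clusters.
unitClusterModel <- function(snp = "snpX", sd = 0.2) {
  new("ClusterModel", snp = snp, group = "G1", refSnp = NA_character_,
      means = list(c(4, 0.5), c(2, 2), c(0.5, 4)),
      covs = replicate(3, diag(sd^2, 2), simplify = FALSE),
      counts = c(10L, 10L, 10L), refCounts = c(0L, 0L, 0L))
}

# Draw one synthetic SNP's intensities at unit scale from given genotypes.
drawUnitSnp <- function(genotypes, sd = 0.2) {
  mu <- rbind(c(4, 0.5), c(2, 2), c(0.5, 4))
  k <- match(genotypes, c("AA", "AB", "BB"))
  cbind(rnorm(length(k), mu[k, 1], sd), rnorm(length(k), mu[k, 2], sd))
}

# Construct a GmmFit directly from a responsibility matrix (for the
# posterior-rate operations, which depend only on responsibilities).
fitFromResp <- function(resp, nObserved = nrow(resp)) {
  new("GmmFit", snp = "snpX", weights = rep(1 / 3, 3),
      means = list(c(4, 0.5), c(2, 2), c(0.5, 4)),
      covs = replicate(3, diag(0.04, 2), simplify = FALSE),
      resp = resp, loglik = c(-10, -9), converged = TRUE, collapsed = FALSE,
      nObserved = as.integer(nObserved))
}

# Independent bivariate-normal density using generic solve()/det() —
# deliberately a different code path from the package's closed form.
refDmvnorm <- function(x, mu, sigma) {
  xc <- sweep(x, 2, mu)
  q <- rowSums((xc %*% solve(sigma)) * xc)
  exp(-q / 2) / (2 * pi * sqrt(det(sigma)))
}

# Independent E-step: brute-force normalized weighted densities.
refResponsibilities <- function(x, weights, means, covs) {
  d <- sapply(1:3, function(k) weights[k] * refDmvnorm(x, means[[k]],
                                                       covs[[k]]))
  d / rowSums(d)
}
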