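#' Simulation configuration for synthetic intensity panels
#'
#' Describes the generative model the caller assumes: per SNP, three
#' bivariate-Gaussian genotype clusters in (r, g) intensity space; genotypes
#' drawn under Hardy-Weinberg equilibrium at a configurable minor-allele
#' frequency; a subset of samples carrying known genotypes. Default geometry
#' places the AA cluster at (4000, 500), AB at (2250, 2250) and BB at
#' (500, 4000) with diagonal within-cluster standard deviation 200, so the
#' allelic-contrast projections sit near +0.78 / 0 / -0.78 as on two-channel
#' arrays. Per-SNP multiplicative lognormal brightness jitter emulates
#' probe-to-probe variation.
#'
#' @param nSamples number of cohort samples.
#' @param nSnps number of SNPs.
#' @param nKnown number of samples with known genotypes (<= nSamples).
#' @param maf scalar or length-nSnps vector of minor-allele frequencies in
#'   [0, 0.5].
#' @param clusterMeans 3 x 2 matrix of base cluster means (rows AA, AB, BB;
#'   columns r, g).
#' @param clusterSd within-cluster channel standard deviation (scalar or
#'   length 3).
#' @param snpJitter standard deviation of the per-SNP lognormal brightness
#'   factor (0 disables jitter).
#' @param missingKnownRate fraction of known-genotype entries masked as
#'   missing.
#' @param seed integer seed.
#' @return a classed list used by [generatePanel()].
#' @export
simulationConfig <- function(nSamples, nSnps, nKnown,
                             maf = 0.2,
                             clusterMeans = rbind(AA = c(4000, 500),
                                                  AB = c(2250, 2250),
                                                  BB = c(500, 4000)),
                             clusterSd = 200,
                             snpJitter = 0.1,
                             missingKnownRate = 0,
                             seed = 20151203) {
  if (nKnown > nSamples) stop("nKnown must not exceed nSamples")
  maf <- rep_len(maf, nSnps)
  if (any(maf < 0 | maf > 0.5)) stop("maf must lie in [0, 0.5]")
  if (missingKnownRate < 0 || missingKnownRate >= 1)
    stop("missingKnownRate must lie in [0, 1)")
  structure(list(nSamples = nSamples, nSnps = nSnps, nKnown = nKnown,
                 maf = maf, clusterMeans = clusterMeans,
                 clusterSd = rep_len(clusterSd, 3L),
                 snpJitter = snpJitter,
                 missingKnownRate = missingKnownRate,
                 seed = as.integer(seed)),
            class = "simulationConfig")
}

#' Generate a synthetic two-channel intensity panel with known truth
#'
#' For each SNP: genotypes are drawn under HWE at the SNP's MAF (B is the
#' minor allele); each sample's (r, g) intensity pair is drawn from its
#' genotype's bivariate normal cluster, after applying the SNP's brightness
#' jitter to all three cluster means; negative draws are truncated at zero.
#' The first \code{nKnown} samples (in a seeded random order) form the
#' known-genotype table, with entries masked at \code{missingKnownRate}.
#' Deterministic for a given seed.
#'
#' @param config a [simulationConfig()], or nothing if the individual
#'   arguments are given.
#' @param ... arguments forwarded to [simulationConfig()] when \code{config}
#'   is missing.
#' @return list with \code{panel} (\linkS4class{IntensityPanel}),
#'   \code{known} (\linkS4class{KnownGenotypes}) and \code{truth}
#'   (\linkS4class{SyntheticTruth}).
#' @examples
#' sim <- generatePanel(nSamples = 50, nSnps = 3, nKnown = 20, maf = 0.3,
#'                      seed = 1)
#' sim$panel
#' @export
generatePanel <- function(config = NULL, ...) {
  if (is.null(config)) config <- simulationConfig(...)
  stopifnot(inherits(config, "simulationConfig"))
  withSeed(config$seed, {
    n <- config$nSamples
    S <- config$nSnps
    sampleIds <- sprintf("sample%03d", seq_len(n))
    snpIds <- sprintf("snp%04d", seq_len(S))
    red <- matrix(0, S, n, dimnames = list(snpIds, sampleIds))
    green <- red
    genoTruth <- matrix(NA_character_, S, n,
                        dimnames = list(snpIds, sampleIds))
    meansTruth <- vector("list", S)
    sdsTruth <- vector("list", S)
    for (i in seq_len(S)) {
      q <- config$maf[i]                     # freq of minor allele B
      probs <- c((1 - q)^2, 2 * q * (1 - q), q^2)
      geno <- sample(GENOTYPE_LEVELS, n, replace = TRUE, prob = probs)
      jitter <- if (config$snpJitter > 0)
        exp(rnorm(1L, 0, config$snpJitter)) else 1
      mu <- config$clusterMeans * jitter
      k <- genotypeIndex(geno)
      red[i, ] <- pmax(0, rnorm(n, mu[k, 1L], config$clusterSd[k]))
      green[i, ] <- pmax(0, rnorm(n, mu[k, 2L], config$clusterSd[k]))
      genoTruth[i, ] <- geno
      meansTruth[[i]] <- lapply(1:3, function(kk) unname(mu[kk, ]))
      sdsTruth[[i]] <- config$clusterSd
    }
    knownIds <- sort(sample(sampleIds, config$nKnown))
    km <- genoTruth[, knownIds, drop = FALSE]
    if (config$missingKnownRate > 0 && length(km) > 0) {
      mask <- runif(length(km)) < config$missingKnownRate
      km[mask] <- NA_character_
    }
    list(panel = IntensityPanel(red = red, green = green),
         known = KnownGenotypes(km),
         truth = new("SyntheticTruth", genotypes = genoTruth,
                     means = setNames(meansTruth, snpIds),
                     sds = setNames(sdsTruth, snpIds),
                     maf = setNames(config$maf, snpIds),
                     knownIds = knownIds))
  })
}

#' Generate a rare-SNP fixture panel
#'
#' Emits a panel of \code{nRare} rare SNPs (MAF <= 0.01 enforced) together
#' with a backbone of common SNPs at MAF 0.5, so rare SNPs lacking three
#' observed clusters always have well-populated G1 reference SNPs nearby.
#' Depending on the sampled genotypes a rare SNP displays three, two or one
#' observed cluster. Rare and backbone SNPs are interleaved in array order.
#'
#' @param nSamples cohort size.
#' @param nRare number of rare SNPs.
#' @param maf rare-SNP minor-allele frequency (must be <= 0.01).
#' @param seed integer seed.
#' @param nKnown known-genotype samples (default 60).
#' @param nBackbone number of common backbone SNPs (default
#'   \code{max(10, nRare)}).
#' @param ... forwarded to [simulationConfig()] (geometry, jitter, ...).
#' @return as [generatePanel()], plus \code{rareSnps} (ids of the rare SNPs).
#' @export
makeRarePanelFixture <- function(nSamples, nRare, maf, seed = 20151203,
                                 nKnown = 60, nBackbone = max(10, nRare),
                                 ...) {
  if (maf > 0.01) stop("rare SNPs require maf <= 0.01")
  if (nRare < 1L) stop("nRare must be >= 1")
  nSnps <- nRare + nBackbone
  # interleave: backbone on even positions so every rare SNP has neighbours
  mafVec <- rep(0.5, nSnps)
  rarePos <- round(seq(2, nSnps, length.out = nRare))
  rarePos <- pmin(pmax(rarePos, 1L), nSnps)
  rarePos <- unique(rarePos)
  while (length(rarePos) < nRare)  # collisions at tiny nSnps
    rarePos <- c(rarePos, setdiff(seq_len(nSnps), rarePos)[1L])
  mafVec[rarePos] <- maf
  cfg <- simulationConfig(nSamples = nSamples, nSnps = nSnps,
                          nKnown = nKnown, maf = mafVec, seed = seed, ...)
  out <- generatePanel(cfg)
  out$rareSnps <- snpIds(out$panel)[sort(rarePos)]
  out
}
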