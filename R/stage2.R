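#' Simulate augmentation subjects from a stage-one cluster model
#'
#' Draws exactly \code{m/3} subjects from each genotype cluster's bivariate
#' normal distribution. Equal allocation across the three clusters boosts the
#' representation of rare genotypes without changing which observed
#' homozygote cluster is the larger one.
#'
#' @param model a \linkS4class{ClusterModel}.
#' @param m total number of simulated subjects (non-negative, divisible by 3).
#' @param seed integer seed; draws are reproducible.
#' @return list with \code{y} (m x 2 matrix of simulated intensities) and
#'   \code{component} (integer labels 1/2/3 = AA/AB/BB of origin).
#' @export
simulateAugmentedSamples <- function(model, m, seed = 20151203) {
  m <- as.integer(m)
  if (m < 0L) stop("m must be non-negative")
  if (m %% 3L != 0L)
    stop("m must be divisible by 3 so each cluster receives m/3 subjects")
  if (m == 0L)
    return(list(y = matrix(numeric(0), 0L, 2L), component = integer(0)))
  per <- m %/% 3L
  y <- withSeed(seed, {
    blocks <- lapply(1:3, function(k)
      MASS::mvrnorm(per, mu = model@means[[k]],
                    Sigma = regularizeCov(model@covs[[k]])))
    do.call(rbind, blocks)
  })
  list(y = unname(y), component = rep(1:3, each = per))
}

#' Responsibilities and log-likelihood of a three-component bivariate GMM
#'
#' The E-step: for each subject, the posterior probability of each component
#' is its weighted bivariate-normal density normalized across components.
#'
#' @param x n x 2 numeric matrix of (r, g) intensities.
#' @param weights numeric(3) mixing proportions.
#' @param means list of three numeric(2) means.
#' @param covs list of three 2x2 covariance matrices.
#' @return list with \code{resp} (n x 3, rows sum to 1), \code{loglik}
#'   (scalar observed-data log-likelihood) and \code{colsum} (effective
#'   component weights).
#' @export
gmmResponsibilities <- function(x, weights, means, covs) {
  n <- nrow(x)
  lg <- matrix(0, n, 3L)
  for (k in 1:3)
    lg[, k] <- log(weights[k]) + dbvnorm(x, means[[k]], covs[[k]], log = TRUE)
  mx <- lg[, 1L]
  mx <- pmax(mx, lg[, 2L], lg[, 3L])
  w <- exp(lg - mx)
  tot <- rowSums(w)
  list(resp = w / tot, loglik = sum(log(tot) + mx), colsum = colSums(w / tot))
}

#' Fit a three-component bivariate Gaussian mixture by EM
#'
#' Fits the mixture to the augmented intensity rows of one SNP (observed
#' cohort stacked above simulated subjects). Initialization comes from the
#' stage-one cluster model with equal mixing weights; the E-step computes
#' responsibilities, the M-step updates the weighted means, covariances
#' (responsibility-weighted, denominator = effective component weight) and
#' mixing proportions. Iterates until the relative log-likelihood change
#' falls below \code{tol} or \code{maxIter} is hit. Covariances are
#' re-regularized each iteration if near-singular. If a component's effective
#' weight vanishes the fit is returned flagged (\code{collapsed = TRUE},
#' \code{converged = FALSE}).
#'
#' @param x n* x 2 numeric matrix (observed rows first, then simulated).
#' @param init a \linkS4class{ClusterModel} supplying initial means and
#'   covariances.
#' @param tol relative log-likelihood convergence tolerance.
#' @param maxIter iteration cap.
#' @param nObserved number of leading observed rows (defaults to all rows).
#' @param snp SNP id for bookkeeping.
#' @return a \linkS4class{GmmFit}.
#' @export
emFitGmm <- function(x, init, tol = 1e-8, maxIter = 500L,
                     nObserved = nrow(x), snp = init@snp) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite intensity in EM input")
  if (nrow(x) < 6L) stop("need at least 6 subjects to fit 3 clusters")
  weights <- rep(1 / 3, 3L)
  means <- init@means
  covs <- lapply(init@covs, regularizeCov)
  trace <- numeric(0)
  converged <- FALSE
  collapsed <- FALSE
  prev <- -Inf
  e <- NULL
  for (it in seq_len(maxIter)) {
    e <- gmmResponsibilities(x, weights, means, covs)
    trace <- c(trace, e$loglik)
    if (is.finite(prev) &&
        abs(e$loglik - prev) < tol * (abs(prev) + .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    prev <- e$loglik
    nk <- colSums(e$resp)
    if (any(nk < 1e-8)) {  # component collapse: flag and stop
      collapsed <- TRUE
      break
    }
    for (k in 1:3) {
      rk <- e$resp[, k]
      mu <- colSums(x * rk) / nk[k]
      xc <- sweep(x, 2L, mu)
      S <- crossprod(xc * rk, xc) / nk[k]
      means[[k]] <- mu
      covs[[k]] <- regularizeCov(S)
    }
    weights <- nk / nrow(x)
  }
  new("GmmFit", snp = snp, weights = weights, means = means, covs = covs,
      resp = e$resp, loglik = trace, converged = converged,
      collapsed = collapsed, nObserved = as.integer(nObserved))
}

#' Map mixture components to genotype labels
#'
#' Orders the fitted component means on the allelic contrast scale
#' \code{b = (r - g)/(r + g)}: the component with the largest b (red/A signal)
#' is AA, the middle one AB, the smallest BB. Ties are broken by component
#' index and flagged.
#'
#' @param fit a \linkS4class{GmmFit} (or any object with a \code{means} list
#'   of three 2-vectors).
#' @return character(3): the genotype label of components 1..3, with
#'   attribute \code{tie} set TRUE if two components had equal contrast.
#' @examples
#' # means at (10,1), (5,5), (1,10) label as AA, AB, BB
#' @export
mapComponentsToGenotypes <- function(fit) {
  means <- if (is(fit, "GmmFit") || is(fit, "ClusterModel")) fit@means else
    fit
  b <- vapply(means, function(mu) {
    s <- mu[1L] + mu[2L]
    if (s == 0) NA_real_ else (mu[1L] - mu[2L]) / s
  }, numeric(1))
  if (sum(is.na(b)) > 1L)
    stop("component labelling undefined: multiple components with r + g = 0")
  tie <- anyDuplicated(b[!is.na(b)]) > 0L
  ord <- order(-b, seq_along(b), na.last = TRUE)  # decreasing b, index ties
  labels <- character(3L)
  labels[ord] <- GENOTYPE_LEVELS
  attr(labels, "tie") <- tie
  labels
}

#' Posterior rates from a converged mixture fit
#'
#' Each subject is hard-assigned to its maximum-responsibility component
#' (ties toward the lower component index); its posterior rate (PR) is the
#' responsibility of that component. The average posterior rate (APR) is the
#' mean PR over all augmented subjects — the per-cluster PR sums divided by
#' the total augmented cluster sizes. An observed-only APR over the cohort
#' rows is reported alongside.
#'
#' @param fit a \linkS4class{GmmFit}.
#' @param nObserved number of leading observed rows (defaults to the fit's).
#' @return list with \code{assignment} (integer component per subject),
#'   \code{pr} (numeric per subject), \code{apr} (augmented),
#'   \code{aprObserved}, and \code{clusterSizes} (integer(3)).
#' @export
posteriorRates <- function(fit, nObserved = fit@nObserved) {
  resp <- fit@resp
  k <- max.col(resp, ties.method = "first")
  pr <- resp[cbind(seq_len(nrow(resp)), k)]
  list(assignment = k,
       pr = pr,
       apr = mean(pr),
       aprObserved = mean(pr[seq_len(nObserved)]),
       clusterSizes = tabulate(k, nbins = 3L))
}

#' Assign genotypes from a mixture fit with posterior-rate gating
#'
#' A SNP passes only if its APR (over the augmented data) exceeds
#' \code{aprThreshold}; at a failing SNP every observed subject is NoCall. At
#' a passing SNP each observed subject receives the genotype label of its
#' assigned component unless its PR falls below \code{prThreshold}, in which
#' case it goes to the null component (NoCall). Simulated subjects are never
#' emitted.
#'
#' @param fit a \linkS4class{GmmFit}.
#' @param labels component-to-genotype map from [mapComponentsToGenotypes()].
#' @param aprThreshold,prThreshold cutoffs in (0,1), default 0.85.
#' @param nObserved number of leading observed rows.
#' @return list with \code{calls} (character, length nObserved), \code{pr},
#'   \code{apr}, \code{aprObserved}, \code{pass}, \code{clusterSizes}.
#' @export
assignGenotypes <- function(fit, labels = mapComponentsToGenotypes(fit),
                            aprThreshold = 0.85, prThreshold = 0.85,
                            nObserved = fit@nObserved) {
  rates <- posteriorRates(fit, nObserved)
  obs <- seq_len(nObserved)
  pass <- rates$apr > aprThreshold
  callsOut <- rep("NoCall", nObserved)
  if (pass) {
    callsOut <- labels[rates$assignment[obs]]
    callsOut[rates$pr[obs] < prThreshold] <- "NoCall"
  }
  list(calls = callsOut, pr = rates$pr[obs], apr = rates$apr,
       aprObserved = rates$aprObserved, pass = pass,
       clusterSizes = rates$clusterSizes)
}

#' Call genotypes for a panel: the full two-stage pipeline
#'
#' Orchestrates, per SNP: training/testing split of the known-genotype
#' samples, featured-SNP classification, reference-SNP selection for SNPs
#' lacking three well-populated clusters, cluster-parameter estimation,
#' simulation of \code{m} augmentation subjects, EM fitting of the
#' three-component mixture on the augmented data, and posterior-rate-gated
#' genotype assignment. Fully deterministic for a given \code{config@seed}.
#'
#' @param panel an \linkS4class{IntensityPanel}.
#' @param known a \linkS4class{KnownGenotypes}; must be non-empty (the method
#'   requires samples with known genotypes) and every known sample id must
#'   match a panel sample id.
#' @param config a \linkS4class{CallConfig}.
#' @return a \linkS4class{CallSet}.
#' @examples
#' sim <- generatePanel(nSamples = 60, nSnps = 4, nKnown = 30, maf = 0.3,
#'                      seed = 11)
#' cs <- callGenotypes(sim$panel, sim$known, CallConfig(m = 30, window = 3))
#' table(calls(cs))
#' @export
callGenotypes <- function(panel, known, config = CallConfig()) {
  validObject(config)
  if (ncol(calls(known)) == 0L)
    stop("known-genotype table is empty: the method requires a collection ",
         "of samples with known genotypes")
  if (!all(knownSampleIds(known) %in% sampleIds(panel)))
    stop("every known-genotype sample id must match a panel sample id")
  stage1 <- buildClusterModels(panel, known, config)
  snps <- snpIds(panel)
  samples <- sampleIds(panel)
  n <- length(samples)
  r <- redIntensity(panel)
  g <- greenIntensity(panel)

  cm <- matrix("NoCall", length(snps), n, dimnames = list(snps, samples))
  pr <- matrix(NA_real_, length(snps), n, dimnames = list(snps, samples))
  report <- data.frame(
    snp_id = snps, group = stage1$statuses$group, ref_snp_id = stage1$refs,
    m = config@m, apr = NA_real_, apr_observed = NA_real_, snp_pass = FALSE,
    converged = NA, pi1 = NA_real_, pi2 = NA_real_, pi3 = NA_real_,
    stringsAsFactors = FALSE)

  for (i in seq_along(snps)) {
    model <- stage1$models[[i]]
    if (is.null(model)) next  # no reference available: SNP left uncalled
    sim <- simulateAugmentedSamples(model, config@m,
                                    seed = deriveSeed(config@seed, i))
    x <- rbind(cbind(r[i, ], g[i, ]), sim$y)
    fit <- emFitGmm(x, model, tol = config@emTol,
                    maxIter = config@emMaxIter, nObserved = n,
                    snp = snps[i])
    labels <- mapComponentsToGenotypes(fit)
    asg <- assignGenotypes(fit, labels, config@aprThreshold,
                           config@prThreshold, nObserved = n)
    cm[i, ] <- asg$calls
    pr[i, ] <- asg$pr
    report$apr[i] <- asg$apr
    report$apr_observed[i] <- asg$aprObserved
    report$snp_pass[i] <- asg$pass
    report$converged[i] <- fit@converged
    report[i, c("pi1", "pi2", "pi3")] <- as.list(fit@weights)
  }
  new("CallSet", calls = cm, pr = pr, snpReport = report)
}
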