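test_that("augmentation draws exactly m/3 subjects per cluster", {
  cm <- unitClusterModel()
  sim <- simulateAugmentedSamples(cm, 600, seed = 5)
  expect_equal(nrow(sim$y), 600)
  expect_equal(unname(table(sim$component)), rep(200L, 3), ignore_attr = TRUE)
  expect_equal(simulateAugmentedSamples(cm, 0)$component, integer(0))
  expect_error(simulateAugmentedSamples(cm, 7), "divisible by 3")
  expect_identical(simulateAugmentedSamples(cm, 30, seed = 9)$y,
                   simulateAugmentedSamples(cm, 30, seed = 9)$y)
})

test_that("simulated clusters follow the stated component distributions", {
  cm <- unitClusterModel(sd = 0.2)
  sim <- simulateAugmentedSamples(cm, 30000, seed = 31)
  for (k in 1:3) {
    rows <- sim$y[sim$component == k, ]
    se <- 0.2 / sqrt(nrow(rows))
    expect_true(all(abs(colMeans(rows) - cm@means[[k]]) < 4 * se))
  }
})

test_that("E-step responsibilities match an independent density computation", {
  set.seed(2101)
  x <- drawUnitSnp(sample(c("AA", "AB", "BB"), 10, replace = TRUE))
  w <- c(0.5, 0.3, 0.2)
  means <- list(c(4, 0.5), c(2, 2), c(0.5, 4))
  covs <- list(matrix(c(0.05, 0.01, 0.01, 0.04), 2),
               diag(0.04, 2),
               matrix(c(0.03, -0.01, -0.01, 0.05), 2))
  e <- gmmResponsibilities(x, w, means, covs)
  expect_equal(e$resp, refResponsibilities(x, w, means, covs),
               tolerance = 1e-12)
  expect_equal(rowSums(e$resp), rep(1, 10), tolerance = 1e-12)
  # log-likelihood agrees with the direct sum of log mixture densities
  dens <- sapply(1:3, function(k) w[k] * refDmvnorm(x, means[[k]], covs[[k]]))
  expect_equal(e$loglik, sum(log(rowSums(dens))), tolerance = 1e-10)
})

test_that("EM log-likelihood is non-decreasing on random instances", {
  set.seed(555)
  for (i in 1:10) {
    g <- sample(c("AA", "AB", "BB"), 90, replace = TRUE)
    x <- drawUnitSnp(g, sd = runif(1, 0.1, 0.6))
    fit <- emFitGmm(x, unitClusterModel(), tol = 1e-10, maxIter = 200)
    expect_true(all(diff(fit@loglik) >= -1e-8 * pmax(1, abs(fit@loglik[-1]))))
  }
})

test_that("EM at a symmetric equal-count instance keeps weights at 1/3", {
  set.seed(808)
  g <- rep(c("AA", "AB", "BB"), each = 100)
  x <- drawUnitSnp(g, sd = 0.15)
  fit <- emFitGmm(x, unitClusterModel(sd = 0.15), tol = 1e-12, maxIter = 500)
  expect_true(fit@converged)
  expect_equal(fit@weights, rep(1 / 3, 3), tolerance = 1e-6)
})

test_that("converged parameters match the mclust reference EM", {
  skip_if_not_installed("mclust")
  set.seed(4242)
  for (i in 1:20) {
    g <- sample(rep(c("AA", "AB", "BB"), times = sample(10:40, 3,
                                                        replace = TRUE)))
    x <- drawUnitSnp(g, sd = 0.2)
    init <- unitClusterModel(sd = 0.25)
    fit <- emFitGmm(x, init, tol = 1e-12, maxIter = 1000)
    sig <- array(unlist(init@covs), c(2, 2, 3))
    par <- list(pro = rep(1 / 3, 3),
                mean = do.call(cbind, init@means),
                variance = list(modelName = "VVV", d = 2, G = 3, sigma = sig,
                                cholsigma = array(apply(sig, 3, chol),
                                                  c(2, 2, 3))))
    ref <- mclust::emVVV(data = x, parameters = par,
                         control = mclust::emControl(tol = c(1e-12, 1e-12)))
    expect_equal(fit@weights, ref$parameters$pro, tolerance = 1e-6)
    expect_equal(do.call(cbind, fit@means), ref$parameters$mean,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(array(unlist(fit@covs), c(2, 2, 3)),
                 ref$parameters$variance$sigma, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("EM rejects non-finite input and flags component collapse", {
  x <- drawUnitSnp(rep("AA", 20))
  x[3, 1] <- NA
  expect_error(emFitGmm(x, unitClusterModel()), "non-finite")
  set.seed(6)
  xAA <- drawUnitSnp(rep("AA", 200), sd = 0.05)  # single far-away cluster
  fit <- emFitGmm(xAA, unitClusterModel(sd = 0.05), tol = 1e-10)
  expect_true(fit@collapsed)
  expect_false(fit@converged)
})

test_that("components are labelled by their allelic contrast", {
  f <- fitFromResp(diag(3))
  f@means <- list(c(10, 1), c(5, 5), c(1, 10))
  expect_equal(as.vector(mapComponentsToGenotypes(f)), c("AA", "AB", "BB"))
  # permuting components permutes labels consistently
  f@means <- list(c(1, 10), c(10, 1), c(5, 5))
  expect_equal(as.vector(mapComponentsToGenotypes(f)), c("BB", "AA", "AB"))
  # equal contrasts: tie broken by index and flagged
  f@means <- list(c(2, 2), c(5, 5), c(1, 10))
  lab <- mapComponentsToGenotypes(f)
  expect_true(attr(lab, "tie"))
  expect_equal(as.vector(lab), c("AA", "AB", "BB"))
})

test_that("posterior rates follow the per-cluster averaging formula", {
  oneHot <- fitFromResp(diag(3)[c(1, 2, 3, 1), ])
  pr1 <- posteriorRates(oneHot)
  expect_equal(pr1$pr, rep(1, 4))
  expect_equal(pr1$apr, 1)

  unif <- fitFromResp(matrix(1 / 3, 5, 3))
  pru <- posteriorRates(unif)
  expect_equal(pru$pr, rep(1 / 3, 5))
  expect_equal(pru$apr, 1 / 3)
  expect_equal(pru$assignment, rep(1L, 5))  # ties go to the lower index

  resp <- rbind(c(0.9, 0.05, 0.05),
                c(0.2, 0.7, 0.1),
                c(0.1, 0.2, 0.7),
                c(0.6, 0.3, 0.1))
  mixed <- posteriorRates(fitFromResp(resp))
  # hand-summed: cluster 1 holds rows 1 and 4, clusters 2 and 3 one row each
  expect_equal(mixed$clusterSizes, c(2L, 1L, 1L))
  expect_equal(mixed$apr, (0.9 + 0.6 + 0.7 + 0.7) / 4)
  # observed-only variant restricted to leading rows
  expect_equal(posteriorRates(fitFromResp(resp, nObserved = 2))$aprObserved,
               (0.9 + 0.7) / 2)
})

test_that("APR gates the SNP and low PR subjects become NoCall", {
  resp <- rbind(c(0.84, 0.08, 0.08),
                c(0.08, 0.84, 0.08))
  failFit <- fitFromResp(resp)
  out <- assignGenotypes(failFit, aprThreshold = 0.85, prThreshold = 0.85)
  expect_false(out$pass)
  expect_equal(out$calls, c("NoCall", "NoCall"))

  resp <- rbind(c(1, 0, 0),
                c(0.80, 0.15, 0.05),
                c(0, 0, 1))
  passFit <- fitFromResp(resp)
  out <- assignGenotypes(passFit, aprThreshold = 0.85, prThreshold = 0.85)
  expect_true(out$pass)   # APR = (1 + 0.8 + 1)/3 = 0.933
  expect_equal(out$calls, c("AA", "NoCall", "BB"))
})

test_that("full pipeline is deterministic and enforces its prerequisite", {
  sim <- generatePanel(nSamples = 80, nSnps = 5, nKnown = 30, maf = 0.3,
                       seed = 21)
  cfg <- CallConfig(m = 60, window = 4, seed = 77)
  a <- callGenotypes(sim$panel, sim$known, cfg)
  b <- callGenotypes(sim$panel, sim$known, cfg)
  expect_identical(calls(a), calls(b))
  expect_identical(posteriorRate(a), posteriorRate(b))
  expect_identical(snpReport(a), snpReport(b))

  emptyKnown <- KnownGenotypes(matrix(character(0), 0, 0))
  expect_error(callGenotypes(sim$panel, emptyKnown, cfg),
               "known genotypes")
  badKnown <- KnownGenotypes(matrix("AA", 1, 1,
                                    dimnames = list("snp0001", "ghost")))
  expect_error(callGenotypes(sim$panel, badKnown, cfg), "match")
})

test_that("simulated subjects never leak into emitted calls", {
  sim <- generatePanel(nSamples = 40, nSnps = 3, nKnown = 20, maf = 0.4,
                       seed = 33)
  cs <- callGenotypes(sim$panel, sim$known, CallConfig(m = 300, window = 2,
                                                       seed = 1))
  expect_equal(dim(calls(cs)), c(3L, 40L))
  expect_setequal(colnames(calls(cs)), sampleIds(sim$panel))
})
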