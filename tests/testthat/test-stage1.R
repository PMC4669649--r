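test_that("training/testing allocation follows the ceiling rule", {
  ids <- paste0("s", 1:141)
  sp21 <- splitKnownSamples(ids, ratio = c(2, 1), seed = 3)
  expect_length(sp21@training, 94)
  expect_length(sp21@testing, 47)
  sp11 <- splitKnownSamples(ids, ratio = c(1, 1), seed = 3)
  expect_length(sp11@training, 71)
  expect_length(sp11@testing, 70)
  expect_setequal(c(sp21@training, sp21@testing), ids)
  expect_length(intersect(sp21@training, sp21@testing), 0)
})

test_that("splits are reproducible under a seed and guarded on tiny inputs", {
  ids <- paste0("s", 1:20)
  a <- splitKnownSamples(ids, c(2, 1), seed = 99)
  b <- splitKnownSamples(ids, c(2, 1), seed = 99)
  expect_identical(a@training, b@training)
  expect_false(identical(
    a@training, splitKnownSamples(ids, c(2, 1), seed = 100)@training))
  expect_error(splitKnownSamples(ids[1:2], c(2, 1)), "at least 3")
})

test_that("featured-SNP classification applies the three-by-three rule", {
  expect_equal(featuredSnpGroup(
    c(rep("AA", 10), rep("AB", 5), rep("BB", 3)))$group, "G1")
  expect_equal(featuredSnpGroup(c(rep("AA", 40), rep("AB", 2)))$group, "G2")
  # boundary: exactly three in each cluster is still G1
  expect_equal(featuredSnpGroup(rep(c("AA", "AB", "BB"), 3))$group, "G1")
  empty <- featuredSnpGroup(rep(NA_character_, 5))
  expect_equal(empty$c, 0L)
  expect_equal(empty$group, "G2")
})

test_that("classification agrees with a literal rule re-evaluation", {
  set.seed(4021)
  for (i in 1:1000) {
    counts <- rpois(3, sample(0:6, 3, replace = TRUE))
    g <- rep(c("AA", "AB", "BB"), counts)
    st <- featuredSnpGroup(sample(g))
    literal <- if (sum(counts > 0) < 3 || counts[1] < 3 ||
                   counts[2] < 3 || counts[3] < 3) "G2" else "G1"
    expect_identical(st$group, literal)
  }
})

test_that("allelic-contrast projection is bounded and handles r + g = 0", {
  expect_equal(projectIntensity(5, 5), 0)
  expect_equal(projectIntensity(1, 0), 1)
  expect_equal(projectIntensity(3, 1), 0.5)
  expect_true(is.na(projectIntensity(0, 0)))
  set.seed(1)
  b <- projectIntensity(runif(100, 0, 50), runif(100, 0, 50))
  expect_true(all(b >= -1 & b <= 1))
})

test_that("candidate windows take nearest G1 SNPs with lower-index ties", {
  groups <- rep("G2", 21)
  groups[c(9, 11)] <- "G1"
  expect_setequal(candidateReferenceSet(10, groups, R = 2), c(9, 11))
  # R = 1 with equidistant candidates: lower index wins
  expect_equal(candidateReferenceSet(10, groups, R = 1), 9)
  expect_length(candidateReferenceSet(10, rep("G2", 21), R = 5), 0)
  # the target itself is never a candidate
  groups[10] <- "G1"
  expect_false(10 %in% candidateReferenceSet(10, groups, R = 5))
})

test_that("reference selection is exact for zero-distance and single candidates", {
  b <- c(0.5, -0.2, 0.8, 0.1)
  cands <- cbind(exact = b, off = b + 0.3)
  sel <- selectReferenceSnp(b, cands, s = rep(1, 4))
  expect_equal(sel$chosen, "exact")
  expect_equal(sel$d, 0)
  single <- selectReferenceSnp(b, cbind(only = b + 5), s = rep(1, 4))
  expect_equal(single$chosen, "only")
})

test_that("reference selection matches the exhaustive brute-force oracle", {
  set.seed(77)
  for (i in 1:100) {
    la <- 10
    bT <- runif(la, -1, 1)
    bC <- matrix(runif(la * 20, -1, 1), la, 20,
                 dimnames = list(NULL, paste0("c", 1:20)))
    s <- runif(la, 0.1, 2)
    oracle <- which.min(vapply(1:20, function(j)
      sqrt(sum((bT - bC[, j])^2 / s^2)), numeric(1)))
    sel <- selectReferenceSnp(bT, bC, s)
    expect_equal(sel$chosen, paste0("c", oracle))
    expect_equal(sel$d, sqrt(sum((bT - bC[, oracle])^2 / s^2)))
  }
})

test_that("samples without a usable scale or projection are dropped symmetrically", {
  b <- c(0.5, NA, 0.2)          # sample 2 undefined at target
  cands <- cbind(c1 = c(0.5, 0, 0.9), c2 = c(0.4, 9, 0.2))
  sel <- selectReferenceSnp(b, cands, s = c(1, 1, 1))
  expect_equal(unname(sel$distances[["c2"]]),
               sqrt(0.1^2))     # only samples 1 and 3 contribute
  expect_equal(sel$chosen, "c2")
})

test_that("per-sample scale falls back to the pooled value when degenerate", {
  bm <- rbind(s1 = c(0.1, 0.5, 0.9), s2 = c(0.3, 0.3, 0.3))  # s2 sd = 0
  sc <- sampleProjectionScale(bm)
  expect_equal(sc[["s1"]], sd(c(0.1, 0.5, 0.9)))
  expect_equal(sc[["s2"]], sd(as.vector(bm)))
  allFlat <- rbind(c(0.3, 0.3), c(0.3, 0.3))
  expect_true(all(is.na(sampleProjectionScale(allFlat))))
})

test_that("G1 cluster estimation reproduces hand-computed mean and covariance", {
  x <- rbind(c(1, 0), c(3, 2), c(2, 1),          # AA
             c(0, 5), c(2, 5), c(1, 5),          # AB
             c(0, 9), c(1, 10), c(2, 11))        # BB
  g <- rep(c("AA", "AB", "BB"), each = 3)
  cm <- estimateClusterParams(x, g, snp = "t")
  expect_equal(cm@group, "G1")
  expect_equal(cm@means[[1]], c(2, 1))
  # sample covariance [[1,1],[1,1]] is singular, so the stated diagonal
  # regularizer (eps * trace/2) is added
  expect_equal(cm@covs[[1]], matrix(1, 2, 2) + diag(1e-6, 2))
  expect_equal(cm@counts, rep(3L, 3))
})

test_that("G1 estimation matches an independent two-pass oracle", {
  set.seed(88)
  x <- drawUnitSnp(rep(c("AA", "AB", "BB"), each = 20))
  g <- rep(c("AA", "AB", "BB"), each = 20)
  cm <- estimateClusterParams(x, g, snp = "t")
  for (k in 1:3) {
    rows <- x[g == c("AA", "AB", "BB")[k], ]
    mu <- c(sum(rows[, 1]), sum(rows[, 2])) / nrow(rows)  # two-pass: mean...
    S <- matrix(0, 2, 2)                                  # ...then moments
    for (w in seq_len(nrow(rows)))
      S <- S + tcrossprod(rows[w, ] - mu)
    S <- S / (nrow(rows) - 1)
    expect_equal(cm@means[[k]], unname(mu), tolerance = 1e-12)
    expect_equal(cm@covs[[k]], unname(S), tolerance = 1e-12)
  }
})

test_that("G2 estimation pools target and reference rows per cluster", {
  xT <- rbind(c(0, 0), c(2, 2))
  gT <- c("AA", "AA")
  xR <- rbind(c(1, 1), c(1, 1), c(1, 1),
              c(5, 5), c(5, 6), c(6, 5),
              c(9, 9), c(9, 8), c(8, 9))
  gR <- rep(c("AA", "AB", "BB"), each = 3)
  cm <- estimateClusterParams(xT, gT, refIntensity = xR, refGenotypes = gR,
                              snp = "t", refSnp = "r")
  expect_equal(cm@group, "G2")
  expect_equal(cm@refSnp, "r")
  expect_equal(cm@means[[1]], c(1, 1))       # pooled over 2 + 3 = 5 rows
  expect_equal(cm@counts[1] + cm@refCounts[1], 5L)
  # pooled covariance: denominator l_ask + l_ark - 1 around the pooled mean
  pooled <- rbind(xT, xR[1:3, ])
  sampleCov <- crossprod(sweep(pooled, 2, c(1, 1))) / 4
  expect_equal(cm@covs[[1]],
               sampleCov + diag(1e-6 * sum(diag(sampleCov)) / 2, 2),
               tolerance = 1e-12)
})

test_that("pooled estimates are invariant to row order of the combined stack", {
  set.seed(19)
  xT <- drawUnitSnp(c("AA", "AA", "AB"))
  gT <- c("AA", "AA", "AB")
  gR <- rep(c("AA", "AB", "BB"), each = 4)
  xR <- drawUnitSnp(gR)
  a <- estimateClusterParams(xT, gT, refIntensity = xR, refGenotypes = gR,
                             snp = "t", refSnp = "r")
  perm <- sample(length(gR))
  b <- estimateClusterParams(xT, gT, refIntensity = xR[perm, ],
                             refGenotypes = gR[perm], snp = "t", refSnp = "r")
  expect_equal(a@means, b@means)
  expect_equal(a@covs, b@covs)
})

test_that("degenerate clusters are regularized and contracts enforced", {
  x <- rbind(c(1, 1), c(1, 1), c(1, 1),
             c(5, 5), c(5, 6), c(6, 5),
             c(9, 9), c(9, 8), c(8, 9))
  g <- rep(c("AA", "AB", "BB"), each = 3)
  cm <- estimateClusterParams(x, g, snp = "t")
  expect_equal(cm@covs[[1]], diag(1e-6, 2))  # identical points -> eps * I
  ev <- eigen(cm@covs[[1]], only.values = TRUE)$values
  expect_true(all(ev > 0))
  # G2 without a reference, or with a non-G1 reference, is rejected
  expect_error(estimateClusterParams(x[1:3, ], g[1:3], snp = "t"),
               "reference")
  expect_error(estimateClusterParams(
    x[1:3, ], g[1:3], refIntensity = x[1:5, ], refGenotypes = g[1:5],
    snp = "t", refSnp = "r"), "must be G1")
})
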