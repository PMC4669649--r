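#' Split known-genotype samples into training and testing groups
#'
#' Randomly allocates the known-genotype samples (the QC subset) into a
#' training group, used to estimate genotype-cluster parameters, and a
#' testing group held out for evaluation. For a ratio p:q the training size is
#' \code{ceiling(n_a * p / (p + q))}: 141 samples give 94/47 at 2:1 and 71/70
#' at 1:1.
#'
#' @param known a \linkS4class{KnownGenotypes} or a character vector of sample
#'   ids.
#' @param ratio length-2 positive numeric, training:testing.
#' @param seed integer seed; the same seed reproduces the same split.
#' @return a \linkS4class{TrainTestSplit}.
#' @examples
#' sp <- splitKnownSamples(paste0("s", 1:141), ratio = c(2, 1), seed = 7)
#' length(sp@training)  # 94
#' @export
splitKnownSamples <- function(known, ratio = c(2, 1), seed = 20151203) {
  ids <- if (is(known, "KnownGenotypes")) knownSampleIds(known) else
    as.character(known)
  ratio <- as.integer(ratio)
  if (length(ratio) != 2L || any(ratio < 1L))
    stop("ratio must be two positive integers")
  na <- length(ids)
  if (na < sum(ratio))
    stop("need at least ", sum(ratio), " known samples for a ",
         paste(ratio, collapse = ":"), " split; got ", na)
  lTrain <- as.integer(ceiling(na * ratio[1L] / sum(ratio)))
  train <- withSeed(seed, sample(ids, lTrain))
  new("TrainTestSplit", training = sort(train),
      testing = sort(setdiff(ids, train)), ratio = ratio)
}

#' Classify a featured SNP by its training-genotype support
#'
#' A featured SNP (the SNP restricted to known-genotype samples) belongs to
#' group G1 when its training samples show all three genotypes with at least
#' three samples each; otherwise it belongs to G2 and will borrow cluster
#' structure from a reference SNP.
#'
#' @param genotypes character vector of training genotypes at one SNP
#'   (AA/AB/BB, NA for missing; missing entries are excluded from counts).
#' @return list with \code{counts} (named AA/AB/BB), \code{c} (number of
#'   distinct observed genotypes) and \code{group} ("G1" or "G2").
#' @examples
#' featuredSnpGroup(c(rep("AA", 10), rep("AB", 5), rep("BB", 3)))$group  # G1
#' featuredSnpGroup(c(rep("AA", 40), rep("AB", 2)))$group               # G2
#' @export
featuredSnpGroup <- function(genotypes) {
  g <- genotypes[!is.na(genotypes)]
  counts <- setNames(tabulate(genotypeIndex(g), nbins = 3L), GENOTYPE_LEVELS)
  cDistinct <- sum(counts > 0L)
  group <- if (cDistinct < 3L || any(counts < 3L)) "G2" else "G1"
  list(counts = counts, c = cDistinct, group = group)
}

#' Classify every SNP of a panel
#'
#' @param known a \linkS4class{KnownGenotypes}.
#' @param trainingIds character, training sample ids (subset of the known
#'   samples).
#' @param snpOrder character, SNP ids in array order (defaults to the SNPs of
#'   \code{known}); SNPs absent from \code{known} count as zero support.
#' @return data.frame with one row per SNP: counts, number of distinct
#'   genotypes, and group.
#' @export
classifyFeaturedSnps <- function(known, trainingIds,
                                 snpOrder = snpIds(known)) {
  km <- calls(known)
  trainingIds <- intersect(trainingIds, colnames(km))
  out <- data.frame(snp_id = snpOrder, nAA = 0L, nAB = 0L, nBB = 0L,
                    c = 0L, group = "G2", stringsAsFactors = FALSE)
  present <- snpOrder %in% rownames(km)
  for (i in which(present)) {
    st <- featuredSnpGroup(km[snpOrder[i], trainingIds])
    out$nAA[i] <- st$counts[["AA"]]
    out$nAB[i] <- st$counts[["AB"]]
    out$nBB[i] <- st$counts[["BB"]]
    out$c[i] <- st$c
    out$group[i] <- st$group
  }
  out
}

#' Project two-channel intensities to the allelic contrast scale
#'
#' \code{b = (r - g) / (r + g)}, in [-1, 1]: +1 is pure A (red) signal, -1
#' pure B (green). Undefined where \code{r + g = 0}; such entries are returned
#' as NA and the affected sample is dropped from distance computations.
#'
#' @param r,g non-negative numeric vectors of equal length.
#' @return numeric vector of projected values.
#' @examples
#' projectIntensity(c(5, 1, 3), c(5, 0, 1))  # 0, 1, 0.5
#' @export
projectIntensity <- function(r, g) {
  s <- r + g
  b <- ifelse(s > 0, (r - g) / s, NA_real_)
  b
}

#' Candidate reference SNPs near a target
#'
#' Returns up to \code{R} G1 SNPs nearest the target in array (row) order —
#' the search window for reference selection. Ties at equal index distance go
#' to the lower index. The target itself is never a candidate.
#'
#' @param targetIndex integer position of the target SNP in array order.
#' @param groups character vector ("G1"/"G2") for all SNPs in array order.
#' @param R maximum number of candidates.
#' @return integer vector of candidate positions (possibly empty), ordered by
#'   increasing distance from the target.
#' @export
candidateReferenceSet <- function(targetIndex, groups, R = 100L) {
  if (R < 1L) stop("R must be >= 1")
  g1 <- setdiff(which(groups == "G1"), targetIndex)
  if (!length(g1)) return(integer(0))
  d <- abs(g1 - targetIndex)
  ord <- order(d, g1)
  g1[ord][seq_len(min(R, length(g1)))]
}

#' Select the reference SNP by minimum Mahalanobis-type distance
#'
#' For a target SNP lacking three well-populated clusters, picks among
#' candidate G1 SNPs the one whose projected training-intensity profile is
#' closest to the target's: \code{d(r) = sqrt(sum_h (b_hs - b_hr)^2 / s_h^2)}
#' over training samples h, where \code{s_h} scales each sample's
#' contribution (see [sampleProjectionScale()]). Samples with undefined
#' projection at the target or any candidate, or with non-positive scale, are
#' dropped from every candidate's sum so the comparison stays symmetric.
#'
#' @param bTarget numeric vector, projected training intensities at the
#'   target.
#' @param bCandidates numeric matrix (training samples x candidates) of
#'   projected intensities, with candidate SNP ids as column names.
#' @param s numeric vector of per-sample scales \code{s_h}.
#' @param tieOrder optional integer vector ranking candidates for tie-breaks
#'   (e.g. by array-order distance then index); defaults to column order.
#' @return list with \code{chosen} (candidate id or NA), \code{d} (minimum
#'   distance) and \code{distances} (named vector over candidates).
#' @export
selectReferenceSnp <- function(bTarget, bCandidates, s,
                               tieOrder = seq_len(ncol(bCandidates))) {
  if (is.null(dim(bCandidates)))
    bCandidates <- matrix(bCandidates, ncol = 1L)
  nc <- ncol(bCandidates)
  if (nc == 0L)
    return(list(chosen = NA_character_, d = NA_real_,
                distances = numeric(0)))
  keep <- is.finite(bTarget) & is.finite(s) & s > 0 &
    rowSums(!is.finite(bCandidates)) == 0L
  if (!any(keep))
    stop("no training sample usable for reference-SNP distance computation")
  diff <- (bCandidates[keep, , drop = FALSE] - bTarget[keep]) / s[keep]
  d <- sqrt(colSums(diff * diff))
  names(d) <- colnames(bCandidates)
  best <- which(d == min(d))
  if (length(best) > 1L) best <- best[order(tieOrder[best])][1L]
  list(chosen = if (is.null(colnames(bCandidates))) as.character(best) else
    colnames(bCandidates)[best], d = d[[best]], distances = d)
}

#' Per-sample scale for the reference-selection distance
#'
#' The scale \code{s_h} for training sample h is the standard deviation of
#' h's projected intensities across the target SNP and its candidate window.
#' A zero or undefined per-sample value falls back to the pooled standard
#' deviation across all samples and SNPs in the window; samples still lacking
#' a positive scale are excluded from the distance sums.
#'
#' @param bMatrix numeric matrix (training samples x SNPs) of projected
#'   intensities over \code{{target} U candidates}.
#' @return numeric vector of scales (NA where no positive scale exists).
#' @export
sampleProjectionScale <- function(bMatrix) {
  s <- apply(bMatrix, 1L, function(v) stats::sd(v[is.finite(v)]))
  pooled <- stats::sd(bMatrix[is.finite(bMatrix)])
  bad <- !is.finite(s) | s == 0
  if (is.finite(pooled) && pooled > 0) s[bad] <- pooled
  s[!is.finite(s) | s == 0] <- NA_real_
  s
}

#' Estimate the three genotype clusters of one SNP from training samples
#'
#' For a G1 SNP the per-genotype mean and covariance (denominator
#' \code{count - 1}) come from the SNP's own training rows. For a G2 SNP the
#' target's training rows are stacked with the reference SNP's training rows,
#' partitioned by known genotype, and the pooled mean and pooled covariance
#' (denominator \code{l_ask + l_ark - 1}) are taken around the pooled mean.
#' Near-singular covariances are regularized by a small diagonal inflation.
#'
#' @param targetIntensity numeric matrix (training samples x 2, columns r, g)
#'   for the target SNP.
#' @param targetGenotypes character vector of the same length (AA/AB/BB/NA).
#' @param status result of [featuredSnpGroup()] on \code{targetGenotypes}
#'   (computed if NULL).
#' @param refIntensity,refGenotypes same shapes for the reference SNP
#'   (required when the SNP is G2; the reference must be G1).
#' @param snp,refSnp SNP identifiers for bookkeeping.
#' @return a \linkS4class{ClusterModel}.
#' @export
estimateClusterParams <- function(targetIntensity, targetGenotypes,
                                  status = NULL,
                                  refIntensity = NULL, refGenotypes = NULL,
                                  snp = "snp", refSnp = NA_character_) {
  targetIntensity <- as.matrix(targetIntensity)
  if (is.null(status)) status <- featuredSnpGroup(targetGenotypes)
  g2 <- status$group == "G2"
  if (g2) {
    if (is.null(refIntensity) || is.null(refGenotypes))
      stop("a G2 SNP requires a reference SNP's training data")
    refStatus <- featuredSnpGroup(refGenotypes)
    if (refStatus$group != "G1")
      stop("reference SNP must be G1 (three clusters with >= 3 samples each)")
    refIntensity <- as.matrix(refIntensity)
  }
  kTarget <- genotypeIndex(targetGenotypes)
  means <- vector("list", 3L)
  covs <- vector("list", 3L)
  counts <- integer(3L)
  refCounts <- integer(3L)
  for (k in 1:3) {
    rows <- targetIntensity[which(kTarget == k), , drop = FALSE]
    counts[k] <- nrow(rows)
    if (g2) {
      refRows <- refIntensity[which(genotypeIndex(refGenotypes) == k), ,
                              drop = FALSE]
      refCounts[k] <- nrow(refRows)
      rows <- rbind(rows, refRows)
    }
    if (nrow(rows) < 2L)
      stop("cluster ", GENOTYPE_LEVELS[k], " of SNP ", snp,
           " has fewer than 2 pooled training samples")
    means[[k]] <- colMeans(rows)
    covs[[k]] <- regularizeCov(stats::cov(rows))
  }
  new("ClusterModel", snp = snp, group = status$group,
      refSnp = if (g2) refSnp else NA_character_,
      means = means, covs = covs, counts = counts, refCounts = refCounts)
}

# Stage-I driver: classify every SNP, pick references for G2 targets, and
# estimate per-SNP cluster models from the training samples.
buildClusterModels <- function(panel, known, config) {
  split <- splitKnownSamples(known, config@ratio, config@seed)
  train <- intersect(split@training, sampleIds(panel))
  snps <- snpIds(panel)
  statuses <- classifyFeaturedSnps(known, train, snpOrder = snps)
  km <- calls(known)
  r <- redIntensity(panel)[, train, drop = FALSE]
  g <- greenIntensity(panel)[, train, drop = FALSE]
  b <- (r - g) / (r + g)
  b[!is.finite(b)] <- NA_real_

  geno <- matrix(NA_character_, length(snps), length(train),
                 dimnames = list(snps, train))
  common <- intersect(snps, rownames(km))
  geno[common, ] <- km[common, train]

  models <- setNames(vector("list", length(snps)), snps)
  refs <- rep(NA_character_, length(snps))
  for (i in seq_along(snps)) {
    s <- snps[i]
    xi <- cbind(r[i, ], g[i, ])
    if (statuses$group[i] == "G1") {
      models[[i]] <- estimateClusterParams(xi, geno[i, ], snp = s)
      next
    }
    cand <- candidateReferenceSet(i, statuses$group, config@window)
    if (!length(cand)) next  # no reference available; SNP cannot be modelled
    bWin <- t(b[c(i, cand), , drop = FALSE])  # samples x ({target} U window)
    sH <- sampleProjectionScale(bWin)
    sel <- selectReferenceSnp(
      bTarget = bWin[, 1L],
      bCandidates = bWin[, -1L, drop = FALSE],
      s = sH,
      tieOrder = seq_along(cand))  # candidates already sorted by nearness
    j <- match(sel$chosen, snps)
    models[[i]] <- estimateClusterParams(
      xi, geno[i, ], status = featuredSnpGroup(geno[i, ]),
      refIntensity = cbind(r[j, ], g[j, ]), refGenotypes = geno[j, ],
      snp = s, refSnp = sel$chosen)
    refs[i] <- sel$chosen
  }
  list(split = split, statuses = statuses, models = models, refs = refs)
}
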