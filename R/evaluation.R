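#' Tabulate genotype calls
#'
#' @param x character vector of calls (AA/AB/BB/NoCall; NA counts as NoCall).
#' @return named integer vector \code{c(AA, AB, BB, NoCall)}.
#' @export
countGenotypes <- function(x) {
  x[is.na(x)] <- "NoCall"
  setNames(tabulate(match(x, CALL_LEVELS), nbins = 4L), CALL_LEVELS)
}

.asCounts <- function(counts) {
  if (is.character(counts)) counts <- countGenotypes(counts)
  if (is.null(names(counts))) names(counts) <- CALL_LEVELS[seq_along(counts)]
  full <- setNames(numeric(4L), CALL_LEVELS)
  full[names(counts)] <- counts
  if (any(full < 0)) stop("genotype counts must be non-negative")
  full
}

#' Call rate
#'
#' The fraction of attempted genotypes that received a valid (non-NoCall)
#' assignment.
#'
#' @param counts named counts (AA/AB/BB/NoCall), or a character vector of
#'   calls.
#' @return numeric in [0, 1].
#' @examples
#' callRate(c(AA = 90, AB = 0, BB = 5, NoCall = 5))  # 0.95
#' @export
callRate <- function(counts) {
  counts <- .asCounts(counts)
  total <- sum(counts)
  if (total == 0) stop("no genotypes to rate")
  sum(counts[GENOTYPE_LEVELS]) / total
}

#' Concordance between two call vectors
#'
#' Agreement fraction over positions where both vectors carry a valid call
#' (neither NoCall nor NA). Against a truth vector this is call accuracy.
#'
#' @param a,b character vectors of equal length.
#' @return numeric in [0, 1], or NA if no position is jointly called.
#' @export
concordance <- function(a, b) {
  if (length(a) != length(b)) stop("call vectors must have equal length")
  ok <- !is.na(a) & !is.na(b) & a != "NoCall" & b != "NoCall"
  if (!any(ok)) return(NA_real_)
  mean(a[ok] == b[ok])
}

#' Minor allele frequency from genotype counts
#'
#' \code{freq(B) = (nAB + 2 nBB) / (2 n)} over called genotypes; the MAF is
#' the smaller of the two allele frequencies, hence always in [0, 0.5].
#'
#' @param counts named counts or a character call vector (see [callRate()]).
#' @return numeric in [0, 0.5].
#' @examples
#' minorAlleleFrequency(c(AA = 90, AB = 10, BB = 0))  # 0.05
#' @export
minorAlleleFrequency <- function(counts) {
  counts <- .asCounts(counts)
  n <- sum(counts[GENOTYPE_LEVELS])
  if (n == 0) stop("no called genotypes")
  fB <- (counts[["AB"]] + 2 * counts[["BB"]]) / (2 * n)
  min(fB, 1 - fB)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of the called genotype counts
#' against HWE proportions (p^2, 2pq, q^2) with the A-allele frequency
#' estimated from the data. Cells with zero expected count contribute zero; a
#' monomorphic SNP yields chi-square 0 and p = 1. Systematic HWE failure in a
#' population flags likely calling error.
#'
#' @param counts named counts or a character call vector (see [callRate()]).
#' @return list with \code{chisq}, \code{df} (always 1), \code{p}, and
#'   \code{pA} (estimated A-allele frequency).
#' @examples
#' hweChiSquare(c(AA = 30, AB = 40, BB = 30))$chisq  # 4
#' @export
hweChiSquare <- function(counts) {
  counts <- .asCounts(counts)
  obs <- counts[GENOTYPE_LEVELS]
  n <- sum(obs)
  if (n == 0) stop("no called genotypes")
  pA <- (2 * obs[["AA"]] + obs[["AB"]]) / (2 * n)
  expd <- n * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
  nz <- expd > 0
  chisq <- sum((obs[nz] - expd[nz])^2 / expd[nz])
  list(chisq = chisq, df = 1L, p = stats::pchisq(chisq, df = 1L,
                                                 lower.tail = FALSE),
       pA = pA)
}

# True MAF per SNP from a truth genotype matrix (SNPs x samples).
.truthMaf <- function(truthCalls) {
  apply(truthCalls, 1L, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    minorAlleleFrequency(countGenotypes(g))
  })
}

#' MAF-stratified call-rate and accuracy report
#'
#' Aggregates call rate and accuracy (against truth genotypes) for the SNPs
#' whose truth-derived MAF falls below each cutoff — the standard way to
#' examine rare-variant calling performance. MAF is computed from the truth
#' genotypes of all truth-bearing samples.
#'
#' @param callset a \linkS4class{CallSet}.
#' @param truth a \linkS4class{KnownGenotypes} (or SNPs x samples character
#'   matrix) of true genotypes.
#' @param bins numeric MAF cutoffs, descending (default 0.1, 0.05, 0.01).
#' @return data.frame with columns \code{maf_below}, \code{n_snps},
#'   \code{call_rate}, \code{accuracy} (NA where a bin is empty).
#' @export
mafStratifiedReport <- function(callset, truth, bins = c(0.1, 0.05, 0.01)) {
  tm <- if (is(truth, "KnownGenotypes")) calls(truth) else as.matrix(truth)
  cm <- calls(callset)
  snpsCommon <- intersect(rownames(cm), rownames(tm))
  samplesCommon <- intersect(colnames(cm), colnames(tm))
  maf <- .truthMaf(tm[snpsCommon, , drop = FALSE])
  out <- data.frame(maf_below = bins, n_snps = 0L,
                    call_rate = NA_real_, accuracy = NA_real_)
  for (j in seq_along(bins)) {
    sel <- snpsCommon[!is.na(maf) & maf < bins[j]]
    out$n_snps[j] <- length(sel)
    if (!length(sel)) next
    cc <- cm[sel, samplesCommon, drop = FALSE]
    tt <- tm[sel, samplesCommon, drop = FALSE]
    out$call_rate[j] <- callRate(as.vector(cc))
    out$accuracy[j] <- concordance(as.vector(cc), as.vector(tt))
  }
  out
}

#' Evaluate a call set against truth genotypes
#'
#' Computes the overall call rate and accuracy (over samples with truth),
#' the MAF-stratified report, and a per-SNP HWE test on the called cohort
#' genotypes with a failure flag at level \code{alpha}. An optional
#' sample-to-population map stratifies the HWE tests by population.
#'
#' @param callset a \linkS4class{CallSet}.
#' @param truth a \linkS4class{KnownGenotypes} or character matrix of true
#'   genotypes.
#' @param bins MAF cutoffs for [mafStratifiedReport()].
#' @param alpha HWE significance threshold (default 1e-4).
#' @param populations optional named character vector mapping sample id to
#'   population label.
#' @return list with \code{overall} (data.frame), \code{byMaf} (data.frame)
#'   and \code{hwe} (data.frame, one row per SNP x population).
#' @export
evaluateCalls <- function(callset, truth, bins = c(0.1, 0.05, 0.01),
                          alpha = 1e-4, populations = NULL) {
  tm <- if (is(truth, "KnownGenotypes")) calls(truth) else as.matrix(truth)
  cm <- calls(callset)
  snpsCommon <- intersect(rownames(cm), rownames(tm))
  samplesCommon <- intersect(colnames(cm), colnames(tm))
  cc <- cm[snpsCommon, samplesCommon, drop = FALSE]
  tt <- tm[snpsCommon, samplesCommon, drop = FALSE]
  overall <- data.frame(
    n_snps = length(snpsCommon), n_samples = length(samplesCommon),
    call_rate = callRate(as.vector(cc)),
    accuracy = concordance(as.vector(cc), as.vector(tt)))

  pops <- if (is.null(populations))
    setNames(rep("all", ncol(cm)), colnames(cm)) else populations
  hwe <- do.call(rbind, lapply(unique(pops), function(p) {
    ids <- intersect(names(pops)[pops == p], colnames(cm))
    do.call(rbind, lapply(rownames(cm), function(s) {
      cnt <- countGenotypes(cm[s, ids])
      if (sum(cnt[GENOTYPE_LEVELS]) == 0)
        return(data.frame(snp_id = s, population = p, chisq = NA_real_,
                          p_value = NA_real_, hwe_fail = NA))
      h <- hweChiSquare(cnt)
      data.frame(snp_id = s, population = p, chisq = h$chisq,
                 p_value = h$p, hwe_fail = h$p < alpha)
    }))
  }))
  list(overall = overall,
       byMaf = mafStratifiedReport(callset, tm, bins),
       hwe = hwe)
}
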