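#' @import methods
#' @importFrom stats cov pchisq rnorm runif sd setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom MASS mvrnorm
NULL

GENOTYPE_LEVELS <- c("AA", "AB", "BB")
CALL_LEVELS <- c(GENOTYPE_LEVELS, "NoCall")

#' IntensityPanel: two-channel raw intensities for a SNP panel
#'
#' Container for raw two-channel (red/green) SNP-array intensities, built on
#' \linkS4class{SummarizedExperiment}. Rows are SNPs (row order defines array
#' adjacency, used when searching for nearby reference SNPs), columns are
#' samples. Two assays, \code{red} and \code{green}, hold the per-SNP,
#' per-sample non-negative intensities.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}.
#' @seealso [IntensityPanel()], [readIntensityPanel()]
#' @export
setClass("IntensityPanel", contains = "SummarizedExperiment")

setValidity("IntensityPanel", function(object) {
  msg <- NULL
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("red", "green") %in% an))
    msg <- c(msg, "assays 'red' and 'green' are required")
  else {
    r <- SummarizedExperiment::assay(object, "red")
    g <- SummarizedExperiment::assay(object, "green")
    if (anyNA(r) || anyNA(g))
      msg <- c(msg, "intensities must not contain NA")
    else if (min(r) < 0 || min(g) < 0)
      msg <- c(msg, "intensities must be non-negative")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct an IntensityPanel
#'
#' @param red,green numeric matrices of non-negative intensities with SNPs as
#'   rows and samples as columns; both must carry identical dimnames.
#' @return an \linkS4class{IntensityPanel}.
#' @examples
#' r <- matrix(c(10, 2, 8, 3), 2, 2,
#'             dimnames = list(c("snp1", "snp2"), c("s1", "s2")))
#' g <- matrix(c(1, 9, 2, 7), 2, 2, dimnames = dimnames(r))
#' IntensityPanel(red = r, green = g)
#' @export
IntensityPanel <- function(red, green) {
  red <- as.matrix(red)
  green <- as.matrix(green)
  if (!identical(dim(red), dim(green)))
    stop("'red' and 'green' must have identical dimensions")
  if (!identical(dimnames(red), dimnames(green)))
    stop("'red' and 'green' must have identical dimnames")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(red = red, green = green))
  new("IntensityPanel", se)
}

#' KnownGenotypes: truth genotypes for a quality-control sample subset
#'
#' Genotypes (AA/AB/BB, NA for missing) for the subset of samples whose
#' genotypes are known in advance (e.g. HapMap replicates on the array).
#' These samples anchor stage-one cluster estimation.
#'
#' @slot calls character matrix, SNPs x known samples, entries in
#'   \code{c("AA","AB","BB", NA)}.
#' @export
setClass("KnownGenotypes", representation(calls = "matrix"))

setValidity("KnownGenotypes", function(object) {
  m <- object@calls
  msg <- NULL
  if (!is.character(m)) msg <- c(msg, "calls must be a character matrix")
  bad <- !is.na(m) & !(m %in% GENOTYPE_LEVELS)
  if (any(bad))
    msg <- c(msg, paste0("invalid genotype token(s): ",
                         paste(unique(m[bad]), collapse = ", ")))
  if (nrow(m) > 0 && (is.null(rownames(m)) || anyDuplicated(rownames(m))))
    msg <- c(msg, "SNP ids (rownames) must be present and unique")
  if (ncol(m) > 0 && (is.null(colnames(m)) || anyDuplicated(colnames(m))))
    msg <- c(msg, "sample ids (colnames) must be present and unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a KnownGenotypes object
#'
#' @param calls character matrix (SNPs x samples) with entries AA/AB/BB or NA.
#' @return a \linkS4class{KnownGenotypes}.
#' @export
KnownGenotypes <- function(calls) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "character"
  new("KnownGenotypes", calls = calls)
}

#' CallConfig: run configuration for the two-stage caller
#'
#' @slot ratio integer(2), training:testing allocation ratio for the
#'   known-genotype samples (default 2:1).
#' @slot m integer, number of simulated augmentation subjects per SNP; must be
#'   divisible by 3 so each genotype cluster receives m/3 subjects.
#' @slot window integer, number of candidate reference SNPs searched around a
#'   target SNP lacking three well-populated clusters.
#' @slot aprThreshold numeric in (0,1); a SNP passes only if its average
#'   posterior rate exceeds this (default 0.85).
#' @slot prThreshold numeric in (0,1); a subject whose maximum posterior falls
#'   below this is assigned to the null component (NoCall; default 0.85).
#' @slot emTol numeric, relative log-likelihood convergence tolerance.
#' @slot emMaxIter integer, EM iteration cap.
#' @slot seed integer, master seed for all stochastic steps.
#' @export
setClass("CallConfig",
  representation(ratio = "integer", m = "integer", window = "integer",
                 aprThreshold = "numeric", prThreshold = "numeric",
                 emTol = "numeric", emMaxIter = "integer", seed = "integer"),
  prototype(ratio = c(2L, 1L), m = 3000L, window = 100L,
            aprThreshold = 0.85, prThreshold = 0.85,
            emTol = 1e-8, emMaxIter = 500L, seed = 20151203L))

setValidity("CallConfig", function(object) {
  msg <- NULL
  if (length(object@ratio) != 2L || any(object@ratio < 1L))
    msg <- c(msg, "ratio must be two positive integers")
  if (object@m < 0L) msg <- c(msg, "m must be non-negative")
  if (object@m %% 3L != 0L)
    msg <- c(msg, "m must be divisible by 3 (equal simulated subjects per cluster)")
  if (object@window < 1L) msg <- c(msg, "window must be >= 1")
  for (nm in c("aprThreshold", "prThreshold")) {
    v <- slot(object, nm)
    if (v <= 0 || v >= 1) msg <- c(msg, paste(nm, "must lie in (0,1)"))
  }
  if (object@emTol <= 0) msg <- c(msg, "emTol must be positive")
  if (object@emMaxIter < 1L) msg <- c(msg, "emMaxIter must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Construct a CallConfig
#'
#' @param ratio length-2 numeric, training:testing allocation ratio.
#' @param m simulated augmentation subjects per SNP (divisible by 3).
#' @param window number of candidate reference SNPs searched per target.
#' @param aprThreshold,prThreshold posterior-rate cutoffs in (0,1).
#' @param emTol,emMaxIter EM convergence controls.
#' @param seed master seed.
#' @return a \linkS4class{CallConfig}.
#' @export
CallConfig <- function(ratio = c(2, 1), m = 3000, window = 100,
                       aprThreshold = 0.85, prThreshold = 0.85,
                       emTol = 1e-8, emMaxIter = 500, seed = 20151203) {
  new("CallConfig", ratio = as.integer(ratio), m = as.integer(m),
      window = as.integer(window), aprThreshold = aprThreshold,
      prThreshold = prThreshold, emTol = emTol,
      emMaxIter = as.integer(emMaxIter), seed = as.integer(seed))
}

#' TrainTestSplit: allocation of known-genotype samples
#'
#' @slot training,testing character vectors of sample ids (disjoint; their
#'   union is the full known-genotype set).
#' @slot ratio integer(2) allocation ratio used.
#' @export
setClass("TrainTestSplit",
  representation(training = "character", testing = "character",
                 ratio = "integer"))

setValidity("TrainTestSplit", function(object) {
  if (length(intersect(object@training, object@testing)) > 0)
    "training and testing sets must be disjoint" else TRUE
})

#' ClusterModel: stage-one genotype cluster parameters for one SNP
#'
#' Per-genotype (AA, AB, BB) bivariate mean and covariance estimated from
#' training samples, either directly (a SNP with three well-populated
#' clusters, \code{group = "G1"}) or pooled with a reference SNP's training
#' samples (\code{group = "G2"}).
#'
#' @slot snp target SNP id.
#' @slot group "G1" (direct) or "G2" (combined with reference SNP).
#' @slot refSnp reference SNP id, or NA for G1.
#' @slot means list of three numeric(2) mean vectors (AA, AB, BB).
#' @slot covs list of three 2x2 covariance matrices (regularized to be
#'   positive definite).
#' @slot counts integer(3), target training samples per cluster.
#' @slot refCounts integer(3), reference training samples per cluster (zeros
#'   for G1).
#' @export
setClass("ClusterModel",
  representation(snp = "character", group = "character", refSnp = "character",
                 means = "list", covs = "list", counts = "integer",
                 refCounts = "integer"))

setValidity("ClusterModel", function(object) {
  msg <- NULL
  if (!object@group %in% c("G1", "G2")) msg <- c(msg, "group must be G1 or G2")
  if (length(object@means) != 3L || length(object@covs) != 3L)
    msg <- c(msg, "means and covs must have three components")
  if (object@group == "G2" && is.na(object@refSnp))
    msg <- c(msg, "a G2 model requires a reference SNP")
  for (S in object@covs) {
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
      msg <- c(msg, "covariances must be symmetric")
  }
  if (is.null(msg)) TRUE else msg
})

#' GmmFit: fitted three-component bivariate Gaussian mixture for one SNP
#'
#' @slot snp SNP id.
#' @slot weights numeric(3) mixing proportions on the simplex.
#' @slot means list of three numeric(2) component means.
#' @slot covs list of three 2x2 SPD covariance matrices.
#' @slot resp n* x 3 responsibility matrix (posterior component memberships)
#'   at the returned parameters; rows sum to 1.
#' @slot loglik numeric, observed-data log-likelihood trace per iteration.
#' @slot converged logical, TRUE if the relative log-likelihood change fell
#'   below tolerance.
#' @slot collapsed logical, TRUE if a component's effective weight vanished.
#' @slot nObserved integer, number of leading rows that are observed (not
#'   simulated) subjects.
#' @export
setClass("GmmFit",
  representation(snp = "character", weights = "numeric", means = "list",
                 covs = "list", resp = "matrix", loglik = "numeric",
                 converged = "logical", collapsed = "logical",
                 nObserved = "integer"))

setValidity("GmmFit", function(object) {
  msg <- NULL
  if (abs(sum(object@weights) - 1) > 1e-6 || any(object@weights < -1e-12))
    msg <- c(msg, "weights must be non-negative and sum to 1")
  if (nrow(object@resp) > 0) {
    rs <- rowSums(object@resp)
    if (max(abs(rs - 1)) > 1e-9)
      msg <- c(msg, "responsibility rows must sum to 1")
  }
  if (is.null(msg)) TRUE else msg
})

#' CallSet: genotype calls with posterior-rate quality scores
#'
#' @slot calls character matrix (SNPs x observed samples) with entries
#'   AA/AB/BB/NoCall. Simulated augmentation subjects never appear.
#' @slot pr numeric matrix (SNPs x samples) of per-subject posterior rates
#'   (the posterior probability of the assigned component).
#' @slot snpReport data.frame with one row per SNP: group, reference SNP,
#'   m used, APR over the augmented data, observed-only APR, pass flag,
#'   convergence flag, component weights and means.
#' @export
setClass("CallSet",
  representation(calls = "matrix", pr = "matrix", snpReport = "data.frame"))

setValidity("CallSet", function(object) {
  msg <- NULL
  if (!all(object@calls %in% CALL_LEVELS))
    msg <- c(msg, "calls must be AA/AB/BB/NoCall")
  if (!identical(dim(object@calls), dim(object@pr)))
    msg <- c(msg, "calls and pr must have identical dimensions")
  pr <- object@pr[is.finite(object@pr)]
  if (length(pr) && (min(pr) < -1e-9 || max(pr) > 1 + 1e-9))
    msg <- c(msg, "posterior rates must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticTruth: ground truth accompanying a generated panel
#'
#' @slot genotypes character matrix (SNPs x samples) of true genotypes.
#' @slot means list (per SNP) of lists of three true cluster mean vectors.
#' @slot sds list (per SNP) of per-cluster channel standard deviations.
#' @slot maf numeric, true minor-allele frequency per SNP.
#' @slot knownIds character, sample ids included in the known-genotype table.
#' @export
setClass("SyntheticTruth",
  representation(genotypes = "matrix", means = "list", sds = "list",
                 maf = "numeric", knownIds = "character"))
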