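#' Accessors for panel and call objects
#'
#' \code{snpIds} and \code{sampleIds} return the SNP and sample identifiers
#' (array row order of \code{snpIds} defines SNP adjacency);
#' \code{redIntensity} / \code{greenIntensity} return the SNPs x samples
#' intensity matrices; \code{calls} returns the genotype call matrix;
#' \code{snpReport} the per-SNP quality report; \code{knownSampleIds} the ids
#' of samples with known genotypes.
#'
#' @param x an \linkS4class{IntensityPanel}, \linkS4class{KnownGenotypes},
#'   \linkS4class{CallSet} or \linkS4class{SyntheticTruth}.
#' @return see details above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("redIntensity", function(x) standardGeneric("redIntensity"))

#' @rdname accessors
#' @export
setGeneric("greenIntensity", function(x) standardGeneric("greenIntensity"))

#' @rdname accessors
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname accessors
#' @export
setGeneric("snpReport", function(x) standardGeneric("snpReport"))

#' @rdname accessors
#' @export
setGeneric("knownSampleIds", function(x) standardGeneric("knownSampleIds"))

#' @rdname accessors
#' @export
setMethod("snpIds", "IntensityPanel", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleIds", "IntensityPanel", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("redIntensity", "IntensityPanel",
  function(x) SummarizedExperiment::assay(x, "red"))

#' @rdname accessors
#' @export
setMethod("greenIntensity", "IntensityPanel",
  function(x) SummarizedExperiment::assay(x, "green"))

#' @rdname accessors
#' @export
setMethod("snpIds", "KnownGenotypes", function(x) rownames(x@calls))

#' @rdname accessors
#' @export
setMethod("knownSampleIds", "KnownGenotypes", function(x) colnames(x@calls))

#' @rdname accessors
#' @export
setMethod("calls", "KnownGenotypes", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("snpIds", "CallSet", function(x) rownames(x@calls))

#' @rdname accessors
#' @export
setMethod("sampleIds", "CallSet", function(x) colnames(x@calls))

#' @rdname accessors
#' @export
setMethod("calls", "CallSet", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("snpReport", "CallSet", function(x) x@snpReport)

#' Posterior rates of a CallSet
#'
#' @param x a \linkS4class{CallSet}.
#' @return SNPs x samples matrix of per-subject posterior rates.
#' @export
setGeneric("posteriorRate", function(x) standardGeneric("posteriorRate"))

#' @rdname posteriorRate
#' @export
setMethod("posteriorRate", "CallSet", function(x) x@pr)

setMethod("show", "KnownGenotypes", function(object) {
  cat("KnownGenotypes:", nrow(object@calls), "SNPs x",
      ncol(object@calls), "samples;",
      sum(is.na(object@calls)), "missing entries\n")
})

setMethod("show", "CallConfig", function(object) {
  cat("CallConfig: ratio", paste(object@ratio, collapse = ":"),
      "| m =", object@m, "| window =", object@window,
      "| APR >", object@aprThreshold, "| PR >=", object@prThreshold,
      "| seed =", object@seed, "\n")
})

setMethod("show", "TrainTestSplit", function(object) {
  cat("TrainTestSplit:", length(object@training), "training /",
      length(object@testing), "testing (ratio",
      paste(object@ratio, collapse = ":"), ")\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel for", object@snp, "[", object@group, "]")
  if (!is.na(object@refSnp)) cat(" ref:", object@refSnp)
  cat("\n  cluster counts (AA/AB/BB):",
      paste(object@counts, collapse = "/"),
      if (object@group == "G2")
        paste0("+ ref ", paste(object@refCounts, collapse = "/")) else "",
      "\n")
})

setMethod("show", "GmmFit", function(object) {
  cat("GmmFit for", object@snp, "-", nrow(object@resp), "subjects,",
      length(object@loglik), "EM iterations,",
      if (object@converged) "converged" else "NOT converged",
      if (object@collapsed) "(component collapsed)" else "", "\n")
  cat("  weights:", paste(signif(object@weights, 4), collapse = ", "), "\n")
})

setMethod("show", "CallSet", function(object) {
  np <- sum(object@snpReport$snp_pass)
  cat("CallSet:", nrow(object@calls), "SNPs x", ncol(object@calls),
      "samples;", np, "SNPs pass APR filter;",
      "call rate", signif(mean(object@calls != "NoCall"), 4), "\n")
})

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@genotypes), "SNPs x",
      ncol(object@genotypes), "samples;",
      length(object@knownIds), "known-genotype samples\n")
})
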