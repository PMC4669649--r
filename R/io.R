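#' Read a two-channel intensity panel from TSV
#'
#' Two plain-text layouts are supported. The \code{wide} layout has one row
#' per sample: a \code{sample_id} column followed by paired columns
#' \code{<snp>.r} and \code{<snp>.g}. The \code{long} layout has columns
#' \code{sample_id}, \code{snp_id}, \code{r}, \code{g}. SNP and sample order
#' is preserved as encountered in the file; SNP order defines array adjacency.
#'
#' @param path path to a tab-separated file with a header row.
#' @param format \code{"wide"} or \code{"long"}.
#' @return an \linkS4class{IntensityPanel}.
#' @details Malformed cells (non-numeric, negative or missing intensities,
#'   duplicate ids) raise an error naming the offending location; nothing is
#'   silently coerced.
#' @seealso [writeIntensityPanel()]
#' @export
readIntensityPanel <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (format == "wide") {
    if (names(df)[1L] != "sample_id")
      stop("wide panel must start with a 'sample_id' column")
    samples <- df[[1L]]
    if (anyDuplicated(samples)) stop("duplicate sample_id in ", path)
    cn <- names(df)[-1L]
    rc <- grepl("\\.r$", cn)
    gc <- grepl("\\.g$", cn)
    if (!all(rc | gc)) stop("unrecognized intensity column(s): ",
                            paste(cn[!(rc | gc)], collapse = ", "))
    snps <- sub("\\.r$", "", cn[rc])
    if (!identical(snps, sub("\\.g$", "", cn[gc])))
      stop("mismatched <snp>.r / <snp>.g column pairs")
    if (anyDuplicated(snps)) stop("duplicate snp id in ", path)
    red <- .parseIntensityBlock(df[cn[rc]], samples, snps, path)
    green <- .parseIntensityBlock(df[cn[gc]], samples, snps, path)
    IntensityPanel(red = red, green = green)
  } else {
    need <- c("sample_id", "snp_id", "r", "g")
    if (!all(need %in% names(df)))
      stop("long panel requires columns: ", paste(need, collapse = ", "))
    samples <- unique(df$sample_id)
    snps <- unique(df$snp_id)
    if (anyDuplicated(paste(df$sample_id, df$snp_id, sep = "\r")))
      stop("duplicate (sample_id, snp_id) pair in ", path)
    red <- matrix(NA_real_, length(snps), length(samples),
                  dimnames = list(snps, samples))
    green <- red
    i <- cbind(match(df$snp_id, snps), match(df$sample_id, samples))
    red[i] <- .parseIntensityCell(df$r, df$sample_id, df$snp_id, "r", path)
    green[i] <- .parseIntensityCell(df$g, df$sample_id, df$snp_id, "g", path)
    if (anyNA(red) || anyNA(green))
      stop("long panel is not a complete sample x SNP grid in ", path)
    IntensityPanel(red = red, green = green)
  }
}

.parseIntensityBlock <- function(block, samples, snps, path) {
  m <- matrix(NA_real_, length(snps), length(samples),
              dimnames = list(snps, samples))
  for (j in seq_along(snps)) {
    v <- suppressWarnings(as.numeric(block[[j]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("invalid intensity in ", path, " at sample '", samples[bad[1L]],
           "', column '", names(block)[j], "': '", block[[j]][bad[1L]], "'")
    m[j, ] <- v
  }
  m
}

.parseIntensityCell <- function(x, sample, snp, channel, path) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(!is.finite(v) | v < 0)
  if (length(bad))
    stop("invalid intensity in ", path, " at sample '", sample[bad[1L]],
         "', SNP '", snp[bad[1L]], "', channel '", channel, "': '",
         x[bad[1L]], "'")
  v
}

#' Write an intensity panel to TSV
#'
#' @param panel an \linkS4class{IntensityPanel}.
#' @param path output path.
#' @param format \code{"wide"} or \code{"long"} (see [readIntensityPanel()]).
#' @return invisibly, \code{path}.
#' @export
writeIntensityPanel <- function(panel, path, format = c("wide", "long")) {
  format <- match.arg(format)
  r <- redIntensity(panel); g <- greenIntensity(panel)
  if (format == "wide") {
    out <- data.frame(sample_id = colnames(r), check.names = FALSE)
    for (s in rownames(r)) {
      out[[paste0(s, ".r")]] <- r[s, ]
      out[[paste0(s, ".g")]] <- g[s, ]
    }
  } else {
    grid <- expand.grid(snp_id = rownames(r), sample_id = colnames(r),
                        stringsAsFactors = FALSE)
    out <- data.frame(sample_id = grid$sample_id, snp_id = grid$snp_id,
                      r = r[cbind(grid$snp_id, grid$sample_id)],
                      g = g[cbind(grid$snp_id, grid$sample_id)])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read known genotypes from long TSV
#'
#' Expects columns \code{sample_id}, \code{snp_id}, \code{genotype} with
#' genotype tokens in \code{AA/AB/BB/NA}. Pairs not listed are missing.
#'
#' @param path path to the tab-separated file.
#' @return a \linkS4class{KnownGenotypes}.
#' @export
readKnownGenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   na.strings = "NA")
  need <- c("sample_id", "snp_id", "genotype")
  if (!all(need %in% names(df)))
    stop("known-genotype table requires columns: ",
         paste(need, collapse = ", "))
  bad <- which(!is.na(df$genotype) & !(df$genotype %in% GENOTYPE_LEVELS))
  if (length(bad))
    stop("invalid genotype token in ", path, " at sample '",
         df$sample_id[bad[1L]], "', SNP '", df$snp_id[bad[1L]], "': '",
         df$genotype[bad[1L]], "'")
  samples <- unique(df$sample_id)
  snps <- unique(df$snp_id)
  m <- matrix(NA_character_, length(snps), length(samples),
              dimnames = list(snps, samples))
  if (nrow(df))
    m[cbind(match(df$snp_id, snps), match(df$sample_id, samples))] <-
      df$genotype
  KnownGenotypes(m)
}

#' Write known genotypes to long TSV
#'
#' @param known a \linkS4class{KnownGenotypes}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeKnownGenotypes <- function(known, path) {
  m <- calls(known)
  grid <- expand.grid(snp_id = rownames(m), sample_id = colnames(m),
                      stringsAsFactors = FALSE)
  out <- data.frame(sample_id = grid$sample_id, snp_id = grid$snp_id,
                    genotype = m[cbind(grid$snp_id, grid$sample_id)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write genotype calls to long TSV
#'
#' One row per (sample, SNP) with columns \code{sample_id}, \code{snp_id},
#' \code{genotype} (AA/AB/BB/NoCall), \code{PR}, \code{APR}, \code{snp_pass}.
#' Only observed cohort samples are written; simulated augmentation subjects
#' are internal to the fit and never emitted.
#'
#' @param callset a \linkS4class{CallSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeCalls <- function(callset, path) {
  cm <- calls(callset)
  pr <- posteriorRate(callset)
  rep <- snpReport(callset)
  grid <- expand.grid(snp_id = rownames(cm), sample_id = colnames(cm),
                      stringsAsFactors = FALSE)
  i <- cbind(grid$snp_id, grid$sample_id)
  out <- data.frame(sample_id = grid$sample_id, snp_id = grid$snp_id,
                    genotype = cm[i], PR = pr[i],
                    APR = rep$apr[match(grid$snp_id, rep$snp_id)],
                    snp_pass = rep$snp_pass[match(grid$snp_id, rep$snp_id)])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype calls written by [writeCalls()]
#'
#' @param path path to the calls TSV.
#' @return a \linkS4class{CallSet} (snpReport restricted to the columns the
#'   file carries: APR and pass flag).
#' @export
readCalls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE)
  need <- c("sample_id", "snp_id", "genotype", "PR", "APR", "snp_pass")
  if (!all(need %in% names(df)))
    stop("calls table requires columns: ", paste(need, collapse = ", "))
  bad <- which(!(df$genotype %in% CALL_LEVELS))
  if (length(bad))
    stop("invalid genotype token in ", path, ": '", df$genotype[bad[1L]], "'")
  snps <- unique(df$snp_id); samples <- unique(df$sample_id)
  cm <- matrix(NA_character_, length(snps), length(samples),
               dimnames = list(snps, samples))
  pr <- matrix(NA_real_, length(snps), length(samples),
               dimnames = list(snps, samples))
  i <- cbind(match(df$snp_id, snps), match(df$sample_id, samples))
  cm[i] <- df$genotype
  pr[i] <- df$PR
  first <- !duplicated(df$snp_id)
  rep <- data.frame(snp_id = df$snp_id[first], apr = df$APR[first],
                    snp_pass = df$snp_pass[first])
  new("CallSet", calls = cm, pr = pr, snpReport = rep)
}

#' Write the per-SNP quality report to TSV
#'
#' @param callset a \linkS4class{CallSet}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeSnpReport <- function(callset, path) {
  write.table(snpReport(callset), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognized fields mirror [CallConfig()]: \code{ratio} (e.g. \code{[2, 1]}
#' or \code{"2:1"}), \code{m}, \code{window}, \code{apr_threshold},
#' \code{pr_threshold}, \code{em_tol}, \code{em_max_iter}, \code{seed}.
#' Missing fields keep their defaults.
#'
#' @param path path to a YAML file.
#' @return a \linkS4class{CallConfig}.
#' @export
readCallConfig <- function(path) {
  y <- yaml::read_yaml(path)
  ratio <- y$ratio
  if (is.character(ratio))
    ratio <- as.integer(strsplit(ratio, ":", fixed = TRUE)[[1L]])
  def <- CallConfig()
  pick <- function(v, d) if (is.null(v)) d else v
  CallConfig(ratio = pick(ratio, def@ratio),
             m = pick(y$m, def@m),
             window = pick(y$window, def@window),
             aprThreshold = pick(y$apr_threshold, def@aprThreshold),
             prThreshold = pick(y$pr_threshold, def@prThreshold),
             emTol = pick(y$em_tol, def@emTol),
             emMaxIter = pick(y$em_max_iter, def@emMaxIter),
             seed = pick(y$seed, def@seed))
}
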