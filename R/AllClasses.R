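#' @import methods
NULL

#' GenotypeData: samples-by-SNPs dosage matrix with marker map
#'
#' Container for a biallelic SNP genotype matrix coded as counts of the
#' alternate allele (0/1/2, `NA` for missing calls), together with the
#' per-marker map (chromosome, 1-based position, reference and alternate
#' alleles) and per-sample metadata (e.g. subpopulation labels for
#' simulated panels).
#'
#' @slot dosage numeric matrix, samples x SNPs; entries in {0, 1, 2, NA}.
#' @slot snpInfo data.frame with one row per SNP: `id`, `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`.
#' @slot sampleInfo data.frame with one row per sample: `id` plus optional
#'   metadata columns.
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData",
  representation(
    dosage     = "matrix",
    snpInfo    = "data.frame",
    sampleInfo = "data.frame"
  )
)

setValidity("GenotypeData", function(object) {
  msg <- character()
  d <- object@dosage
  si <- object@snpInfo
  pi <- object@sampleInfo
  if (ncol(d) != nrow(si))
    msg <- c(msg, "ncol(dosage) must equal nrow(snpInfo)")
  if (nrow(d) != nrow(pi))
    msg <- c(msg, "nrow(dosage) must equal nrow(sampleInfo)")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(si)))
    msg <- c(msg, paste("snpInfo must have columns:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(si$id)) msg <- c(msg, "duplicated SNP ids")
    if (any(si$pos < 1)) msg <- c(msg, "positions must be 1-based (>= 1)")
  }
  if (!"id" %in% names(pi)) msg <- c(msg, "sampleInfo must have column 'id'")
  v <- d[!is.na(d)]
  if (length(v) && !all(v %in% 0:2))
    msg <- c(msg, "dosage entries must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param dosage samples x SNPs matrix of alternate-allele counts
#'   (0/1/2, `NA` missing).
#' @param snpInfo data.frame with `id`, `chrom`, `pos`, `ref`, `alt`.
#' @param sampleInfo optional data.frame with `id` column; defaults to the
#'   rownames of `dosage`.
#' @return A [GenotypeData-class] object.
#' @export
GenotypeData <- function(dosage, snpInfo, sampleInfo = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(snpInfo))
    stop("ncol(dosage) must equal nrow(snpInfo)")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(sampleInfo))
    sampleInfo <- data.frame(id = rownames(dosage), stringsAsFactors = FALSE)
  colnames(dosage) <- snpInfo$id
  new("GenotypeData", dosage = dosage,
      snpInfo = as.data.frame(snpInfo),
      sampleInfo = as.data.frame(sampleInfo))
}

#' @describeIn GenotypeData-class dosage matrix accessor
#' @param x a GenotypeData object
#' @export
dosage <- function(x) x@dosage

#' @describeIn GenotypeData-class marker map accessor
#' @export
snpInfo <- function(x) x@snpInfo

#' @describeIn GenotypeData-class sample metadata accessor
#' @export
sampleInfo <- function(x) x@sampleInfo

#' @describeIn GenotypeData-class number of samples
#' @export
nSamples <- function(x) nrow(x@dosage)

#' @describeIn GenotypeData-class number of SNPs
#' @export
nSnps <- function(x) ncol(x@dosage)

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nSamples(object), "samples x", nSnps(object), "SNPs\n")
  chs <- unique(object@snpInfo$chrom)
  cat("  chromosomes:", length(chs),
      paste0("(", paste(utils::head(chs, 4), collapse = ", "),
             if (length(chs) > 4) ", ..." else "", ")"), "\n")
  miss <- mean(is.na(object@dosage))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
})

#' @describeIn GenotypeData-class subset samples (i) and/or SNPs (j)
#' @param i sample index
#' @param j SNP index
#' @param drop ignored
#' @param ... ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nSamples(x))
  if (missing(j)) j <- seq_len(nSnps(x))
  if (is.character(j)) j <- match(j, x@snpInfo$id)
  new("GenotypeData",
      dosage = x@dosage[i, j, drop = FALSE],
      snpInfo = x@snpInfo[j, , drop = FALSE],
      sampleInfo = x@sampleInfo[i, , drop = FALSE])
})

#' Per-SNP minor allele frequency from non-missing calls
#' @param x a GenotypeData object
#' @return numeric vector in [0, 0.5], one entry per SNP
#' @export
mafs <- function(x) {
  p <- colMeans(x@dosage, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Per-SNP call rate (fraction of non-missing genotypes)
#' @param x a GenotypeData object
#' @export
callRates <- function(x) colMeans(!is.na(x@dosage))
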