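#' Write genotypes as a dosage TSV
#'
#' Samples in rows, one column per SNP headed by the SNP id
#' (`chrom_pos`); missing calls written as `NA`.  Note this dialect does
#' not carry allele labels.
#'
#' @param geno [GenotypeData-class].
#' @param path output file.
#' @export
writeGenotypesTSV <- function(geno, path) {
  d <- as.data.frame(dosage(geno))
  utils::write.table(cbind(sample = rownames(dosage(geno)), d), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotypes from a dosage TSV
#'
#' Inverse of [writeGenotypesTSV()].  SNP ids are parsed as `chrom_pos`;
#' allele labels are not represented in this dialect and come back as
#' `NA`.
#'
#' @param path file as written by [writeGenotypesTSV()].
#' @return [GenotypeData-class].
#' @export
readGenotypesTSV <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  samples <- d$sample
  d <- as.matrix(d[, setdiff(names(d), "sample"), drop = FALSE])
  rownames(d) <- samples
  ids <- colnames(d)
  us <- regexpr("_[^_]*$", ids)
  chrom <- substr(ids, 1, us - 1)
  pos <- as.integer(substr(ids, us + 1, nchar(ids)))
  GenotypeData(d, data.frame(id = ids, chrom = chrom, pos = pos,
                             ref = NA_character_, alt = NA_character_,
                             stringsAsFactors = FALSE))
}

#' Write genotypes as a minimal VCF v4.2 (GT field only)
#'
#' 1-based positions; dosage 0 -> 0/0, 1 -> 0/1, 2 -> 1/1, missing ./.
#'
#' @param geno [GenotypeData-class].
#' @param path output file.
#' @export
writeGenotypesVCF <- function(geno, path) {
  si <- snpInfo(geno)
  d <- dosage(geno)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", rownames(d)), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(si$chrom[j], si$pos[j], si$id[j],
            ifelse(is.na(si$ref[j]), "N", si$ref[j]),
            ifelse(is.na(si$alt[j]), "N", si$alt[j]),
            ".", "PASS", ".", "GT", gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses with `vcfR` and converts GT calls to alternate-allele dosage.
#'
#' @param path VCF path.
#' @return [GenotypeData-class].
#' @export
readGenotypesVCF <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  cnt <- function(x) {
    x <- gsub("\\|", "/", x)
    ifelse(x %in% c("0/0"), 0,
           ifelse(x %in% c("0/1", "1/0"), 1,
                  ifelse(x %in% c("1/1"), 2, NA_real_)))
  }
  d <- t(apply(gt, 1, cnt))
  dimnames(d) <- dimnames(gt)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- data.frame(id = ifelse(is.na(fix$ID) | fix$ID == ".",
                                 paste0(fix$CHROM, "_", fix$POS), fix$ID),
                     chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  GenotypeData(t(d), info)
}

#' Write long phenotypes as TSV
#' @param pheno long phenotype data.frame.
#' @param path output file.
#' @export
writePhenotypesTSV <- function(pheno, path) {
  utils::write.table(pheno[, c("variety", "trait", "year", "regime", "rep",
                               "value")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read long phenotypes from TSV
#' @param path file as written by [writePhenotypesTSV()].
#' @return long phenotype data.frame.
#' @export
readPhenotypesTSV <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Write an expression count table as TSV (gene, length, one column per
#' sample)
#' @param se `SummarizedExperiment` with assay `counts` and rowData
#'   `length`.
#' @param path output file.
#' @export
writeCountsTSV <- function(se, path) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  utils::write.table(
    cbind(data.frame(gene = rownames(cnt),
                     length = SummarizedExperiment::rowData(se)$length),
          as.data.frame(cnt)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression count table written by [writeCountsTSV()]
#' @param path counts TSV.
#' @param samples optional sample sheet (data.frame with `sample` column)
#'   used as colData.
#' @return `SummarizedExperiment`.
#' @export
readCountsTSV <- function(path, samples = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  cnt <- as.matrix(d[, setdiff(names(d), c("gene", "length")), drop = FALSE])
  rownames(cnt) <- d$gene
  cd <- if (!is.null(samples))
    S4Vectors::DataFrame(samples[match(colnames(cnt), samples$sample), ],
                         row.names = colnames(cnt))
  else S4Vectors::DataFrame(sample = colnames(cnt),
                            row.names = colnames(cnt))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = cnt),
    rowData = S4Vectors::DataFrame(gene_id = d$gene, length = d$length),
    colData = cd)
}
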