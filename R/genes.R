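#' Load gene models from a GFF3 file
#'
#' Parses the file with `rtracklayer` and keeps `gene` features, sorted by
#' chromosome and start.  Lines with fewer than 9 tab-separated fields are
#' excluded before parsing and collected in the `malformed` attribute.
#'
#' @param path GFF3 file path.
#' @return `GRanges` of gene models (1-based, inclusive) with `gene_id`;
#'   attribute `malformed` holds the offending line numbers.
#' @export
loadGFF <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(body & nf < 9)
  if (length(bad)) {
    tmp <- tempfile(fileext = ".gff3")
    writeLines(lines[-bad], tmp)
    path <- tmp
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop("no gene features in ", path)
  if (is.null(gr$gene_id) || all(is.na(gr$gene_id)))
    gr$gene_id <- if (!is.null(gr$ID)) as.character(gr$ID)
                  else sprintf("gene%05d", seq_along(gr))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  attr(gr, "malformed") <- bad
  gr
}

#' Write gene models as GFF3
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path output path.
#' @export
writeGFF3 <- function(genes, path) {
  g <- genes
  g$type <- "gene"
  g$source <- "qgomics"
  g$ID <- g$gene_id
  rtracklayer::export(g, path, format = "gff3")
  invisible(path)
}

#' Genes within a window of a SNP
#'
#' A gene is a candidate iff the minimum distance from the SNP position to
#' the gene body `[start, end]` is at most `window` bp (inclusive
#' boundary).  Relation is "within" when the SNP falls inside the gene
#' body; otherwise upstream/downstream is resolved on the gene's strand
#' (upstream = 5' of the transcription start).  Unstranded genes are
#' treated as plus strand.
#'
#' @param snp list or one-row data.frame with `chrom` and `pos` (and
#'   optionally `id`).
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param window window size in bp (> 0).
#' @return data.frame: gene, snp, chrom, relation, distance, window; empty
#'   (with a warning) when the SNP's chromosome is absent from the
#'   annotation.
#' @export
genesNearSnp <- function(snp, genes, window) {
  stopifnot(window > 0)
  empty <- data.frame(gene = character(), snp = character(),
                      chrom = character(), relation = character(),
                      distance = numeric(), window = numeric(),
                      stringsAsFactors = FALSE)
  if (!snp$chrom %in% as.character(GenomicRanges::seqnames(genes))) {
    warning("chromosome ", snp$chrom, " absent from annotation")
    return(empty)
  }
  on_chr <- genes[as.character(GenomicRanges::seqnames(genes)) == snp$chrom]
  st <- GenomicRanges::start(on_chr); en <- GenomicRanges::end(on_chr)
  dist <- ifelse(snp$pos < st, st - snp$pos,
                 ifelse(snp$pos > en, snp$pos - en, 0))
  keep <- dist <= window
  if (!any(keep)) return(empty)
  on_chr <- on_chr[keep]; st <- st[keep]; en <- en[keep]; dist <- dist[keep]
  strand_ <- as.character(GenomicRanges::strand(on_chr))
  plusish <- strand_ != "-"
  relation <- ifelse(dist == 0, "within",
               ifelse(snp$pos < st,
                      ifelse(plusish, "upstream", "downstream"),
                      ifelse(plusish, "downstream", "upstream")))
  data.frame(gene = on_chr$gene_id,
             snp = if (!is.null(snp$id)) snp$id
                   else paste0(snp$chrom, "_", snp$pos),
             chrom = snp$chrom, relation = relation,
             distance = dist, window = window,
             stringsAsFactors = FALSE)
}

# cluster significant SNPs of one trait into peaks (gap <= window joins)
# and return the lead SNP (smallest p, ties by smallest position) per peak
leadSnps <- function(sig, window) {
  out <- list()
  for (tr in unique(sig$trait)) {
    st <- sig[sig$trait == tr, ]
    for (ch in unique(st$chrom)) {
      d <- st[st$chrom == ch, ]
      d <- d[order(d$pos), ]
      peak <- cumsum(c(1, diff(d$pos) > window))
      for (pk in unique(peak)) {
        dd <- d[peak == pk, ]
        dd <- dd[order(dd$p, dd$pos), ]
        out[[length(out) + 1L]] <- dd[1, ]
      }
    }
  }
  do.call(rbind, out)
}

#' Candidate-gene table around lead SNPs, grouped by trait
#'
#' Significant SNPs are clustered into peaks per trait (SNPs closer than
#' the window are one peak); the lead SNP of each peak is the one with the
#' smallest p-value (ties broken by position).  All genes within the
#' window of each lead SNP form the candidate table.
#'
#' @param sig significant association results (snp, chrom, pos, trait,
#'   env, p, r2).
#' @param genes `GRanges` of gene models.
#' @param window window size in bp, e.g. 200000 or the LD-decay estimate.
#' @return data.frame: trait, snp, chrom, pos, p, r2, gene, relation,
#'   distance, window; attribute `counts` holds candidates per trait.
#' @export
candidateGeneTable <- function(sig, genes, window = 288000) {
  empty <- data.frame(trait = character(), snp = character(),
                      chrom = character(), pos = integer(), p = numeric(),
                      r2 = numeric(), gene = character(),
                      relation = character(), distance = numeric(),
                      window = numeric(), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  leads <- leadSnps(sig, window)
  rows <- list()
  for (i in seq_len(nrow(leads))) {
    ld <- leads[i, ]
    near <- suppressWarnings(
      genesNearSnp(list(chrom = ld$chrom, pos = ld$pos, id = ld$snp),
                   genes, window))
    if (!nrow(near)) next
    rows[[length(rows) + 1L]] <- data.frame(
      trait = ld$trait, snp = ld$snp, chrom = ld$chrom, pos = ld$pos,
      p = ld$p, r2 = if ("r2" %in% names(ld)) ld$r2 else NA_real_,
      gene = near$gene, relation = near$relation,
      distance = near$distance, window = window,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[order(out$trait, out$chrom, out$pos, out$distance), ]
  rownames(out) <- NULL
  attr(out, "counts") <- if (nrow(out))
    as.data.frame(table(trait = out$trait), responseName = "n_candidates")
    else data.frame(trait = character(), n_candidates = integer())
  out
}
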