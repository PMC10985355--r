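#' Up/down DEG ratios over a gene set
#'
#' Ratios of up- and downregulated genes among the tested genes of the
#' subset (the whole DEG table when `genes` is `NULL`).
#'
#' @param deg DEG table from [differentialExpression()].
#' @param genes optional gene-id subset.
#' @return list with up, down, n (tested genes); `NA` ratios with
#'   `empty = TRUE` for an empty subset.
#' @export
degRatios <- function(deg, genes = NULL) {
  if (!nrow(deg)) stop("empty DEG table")
  d <- if (is.null(genes)) deg else deg[deg$gene %in% genes, ]
  d <- d[!is.na(d$q), ]
  if (!nrow(d))
    return(list(up = NA_real_, down = NA_real_, n = 0L, empty = TRUE))
  list(up = mean(d$direction == "up"), down = mean(d$direction == "down"),
       n = nrow(d), empty = FALSE)
}

#' Compare DEG ratios inside GWAS intervals with the genome-wide ratios
#'
#' Intervals of +/- `window` bp around each significant SNP are merged
#' when overlapping, genes are assigned to the merged intervals, and DEG
#' status (up or down in the contrast) is compared between in-interval and
#' out-of-interval tested genes by Fisher's exact test.
#'
#' @param sig significant association results (chrom, pos columns).
#' @param genes `GRanges` of gene models with `gene_id`.
#' @param deg DEG table.
#' @param window interval half-width in bp (default 288000, an LD-decay
#'   scale estimate).
#' @return list with `interval` and `genome` ratio lists, `fisher_p`,
#'   `odds_ratio`, `n_intervals`, `interval_genes`, and the 2x2 `table`.
#'   A warning is given when no tested gene falls in any interval.
#' @export
intervalDegComparison <- function(sig, genes, deg, window = 288000) {
  if (!nrow(sig)) stop("no significant SNPs")
  iv <- GenomicRanges::reduce(GenomicRanges::GRanges(
    sig$chrom, IRanges::IRanges(pmax(1, sig$pos - window),
                                sig$pos + window)))
  hits <- GenomicRanges::findOverlaps(genes, iv)
  in_iv <- genes$gene_id[unique(S4Vectors::queryHits(hits))]
  tested <- deg[!is.na(deg$q), ]
  inside <- tested$gene %in% in_iv
  if (!any(inside)) {
    warning("no tested genes in any interval")
    return(list(interval = list(up = NA_real_, down = NA_real_, n = 0L),
                genome = degRatios(deg), fisher_p = NA_real_,
                odds_ratio = NA_real_, n_intervals = length(iv),
                interval_genes = in_iv, table = NULL))
  }
  is_deg <- tested$direction != "ns"
  tab <- table(factor(inside, c(TRUE, FALSE)),
               factor(is_deg, c(TRUE, FALSE)))
  ft <- stats::fisher.test(tab)
  list(interval = degRatios(deg, in_iv),
       genome = degRatios(deg),
       fisher_p = ft$p.value, odds_ratio = unname(ft$estimate),
       n_intervals = length(iv), interval_genes = in_iv, table = tab)
}

#' Overlap candidate genes with DEG calls
#'
#' Keeps candidates whose gene is a DEG (direction up or down) in at least
#' one supplied contrast, annotated with the contrast's direction and fold
#' change; also returns the Venn counts of the two gene sets.
#'
#' @param candidates candidate table from [candidateGeneTable()].
#' @param deg_list named list of DEG tables (one per contrast), or a
#'   single DEG table.
#' @return list with `validated` (data.frame), `venn` (candidates_only,
#'   degs_only, both).  Errors when fewer than half of the candidate genes
#'   appear in the DEG tables' gene universe (identifier mismatch).
#' @export
overlapGwasDegs <- function(candidates, deg_list) {
  if (is.data.frame(deg_list)) deg_list <- list(contrast = deg_list)
  universe <- unique(unlist(lapply(deg_list, function(d) d$gene)))
  cand_genes <- unique(candidates$gene)
  if (length(cand_genes) &&
      mean(cand_genes %in% universe) < 0.5)
    stop("more than half the candidate genes are absent from the DEG ",
         "tables: likely a gene-identifier namespace mismatch")
  deg_genes <- unique(unlist(lapply(deg_list, function(d)
    d$gene[!is.na(d$q) & d$direction != "ns"])))
  rows <- list()
  for (nm in names(deg_list)) {
    d <- deg_list[[nm]]
    hit <- d[!is.na(d$q) & d$direction != "ns" &
             d$gene %in% cand_genes, c("gene", "log2fc", "direction")]
    if (!nrow(hit)) next
    cc <- candidates[candidates$gene %in% hit$gene, ]
    cc$contrast <- nm
    idx <- match(cc$gene, hit$gene)
    cc$log2fc <- hit$log2fc[idx]
    cc$deg_direction <- hit$direction[idx]
    rows[[nm]] <- cc
  }
  validated <- if (length(rows)) do.call(rbind, rows) else
    cbind(candidates[0, ], contrast = character(0), log2fc = numeric(0),
          deg_direction = character(0))
  validated <- validated[!duplicated(
    validated[, c("gene", "snp", "contrast")]), , drop = FALSE]
  rownames(validated) <- NULL
  both <- length(intersect(cand_genes, deg_genes))
  list(validated = validated,
       venn = c(candidates_only = length(cand_genes) - both,
                degs_only = length(deg_genes) - both, both = both))
}

#' Write the final report bundle of a full pipeline run
#'
#' Writes the genetic-parameter table, stable/pleiotropic SNP tables,
#' candidate-gene and validated-candidate tables, QQ/Manhattan tables, QC
#' report and a run log (seed, settings) as TSV files in one directory.
#'
#' @param outputs named list of stage outputs; required names:
#'   `genetic_params`, `assoc`, `qc_report`, `candidates`, `deg`,
#'   `validated`; optional: `stable`, `pleiotropic`, `plots`,
#'   `interval_comparison`, `seed`, `config`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written; errors listing any missing stage.
#' @export
finalReport <- function(outputs, dir) {
  need <- c("genetic_params", "assoc", "qc_report", "candidates", "deg",
            "validated")
  miss <- setdiff(need, names(outputs))
  if (length(miss))
    stop("missing stage output(s): ", paste(miss, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) {
    p <- file.path(dir, f)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    wr(outputs$genetic_params, "genetic_params.tsv"),
    wr(outputs$assoc, "association.tsv"),
    wr(outputs$qc_report, "qc_report.tsv"),
    wr(outputs$candidates, "candidate_genes.tsv"),
    wr(outputs$deg, "deg.tsv"),
    wr(outputs$validated, "validated_candidates.tsv"))
  if (!is.null(outputs$stable))
    paths <- c(paths, wr(outputs$stable, "stable_snps.tsv"))
  if (!is.null(outputs$pleiotropic))
    paths <- c(paths, wr(outputs$pleiotropic, "pleiotropic_snps.tsv"))
  if (!is.null(outputs$plots)) {
    paths <- c(paths, wr(outputs$plots$qq, "qq.tsv"),
               wr(outputs$plots$manhattan, "manhattan.tsv"))
  }
  log <- c(paste("date:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           paste("seed:", outputs$seed %||% NA),
           paste("lambda:", outputs$plots$lambda %||% NA),
           paste("interval_fisher_p:",
                 outputs$interval_comparison$fisher_p %||% NA))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(c(paths, file.path(dir, "run_log.txt")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
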