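#' FPKM normalization
#'
#' `fpkm = count / (length_kb * libsize_millions)`.
#'
#' @param counts gene x sample count matrix.
#' @param lengths gene lengths in bp (> 0).
#' @param lib_sizes per-sample library sizes; defaults to column sums.
#' @return FPKM matrix of the same shape.
#' @export
fpkm <- function(counts, lengths, lib_sizes = colSums(counts)) {
  stopifnot(length(lengths) == nrow(counts),
            length(lib_sizes) == ncol(counts))
  if (any(lib_sizes <= 0)) stop("library sizes must be > 0")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  sweep(sweep(counts, 1, lengths / 1000, "/"), 2, lib_sizes / 1e6, "/")
}

#' FPKM matrix of a SummarizedExperiment
#'
#' @param se `SummarizedExperiment` with assay `counts` and rowData column
#'   `length`; library sizes from `metadata(se)$lib_sizes` when present.
#' @return FPKM matrix.
#' @export
fpkmSE <- function(se) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  len <- SummarizedExperiment::rowData(se)$length
  ls <- S4Vectors::metadata(se)$lib_sizes
  if (is.null(ls)) ls <- colSums(cnt)
  fpkm(cnt, len, ls[colnames(cnt)])
}

#' Differential expression by Welch t-test on log2(FPKM + c)
#'
#' For one contrast (treatment vs control within a variety/tissue cell):
#' `log2fc = log2((mean FPKM_treat + c) / (mean FPKM_ctrl + c))`, a
#' per-gene Welch t-test on `log2(FPKM + c)`, and Benjamini-Hochberg
#' q-values over the tested genes.  Genes with all-zero counts on both
#' sides are excluded from testing.  Direction is "up" iff
#' `log2fc >= lfc_threshold` and `q < q_threshold`, "down" for the
#' mirrored rule, otherwise "ns".
#'
#' @param se `SummarizedExperiment` as from [simulateExpression()] or
#'   built from a counts table.
#' @param treat,ctrl values of `treatment_col` defining the contrast.
#' @param treatment_col colData column holding the treatment factor.
#' @param subset optional logical vector over samples (e.g. one
#'   variety-by-tissue cell).
#' @param pseudo pseudo-count c added before logging (default 1).
#' @param lfc_threshold,q_threshold DEG calling thresholds (defaults 1 and
#'   0.05).
#' @return data.frame: gene, mean_ctrl, mean_treat, log2fc, p, q,
#'   direction; untested genes carry NA p/q and direction "ns".
#' @export
differentialExpression <- function(se, treat = "drought", ctrl = "control",
                                   treatment_col = "treatment",
                                   subset = NULL, pseudo = 1,
                                   lfc_threshold = 1, q_threshold = 0.05) {
  cd <- SummarizedExperiment::colData(se)
  keep <- if (is.null(subset)) rep(TRUE, ncol(se)) else subset
  grp <- cd[[treatment_col]][keep]
  f <- fpkmSE(se)[, keep, drop = FALSE]
  cnt <- SummarizedExperiment::assay(se, "counts")[, keep, drop = FALSE]
  it <- grp == treat; ic <- grp == ctrl
  if (sum(it) < 2 || sum(ic) < 2)
    stop("contrast ", treat, " vs ", ctrl, " needs >= 2 replicates per side")
  lt <- log2(f[, it, drop = FALSE] + pseudo)
  lc <- log2(f[, ic, drop = FALSE] + pseudo)
  mt <- rowMeans(f[, it, drop = FALSE]); mc <- rowMeans(f[, ic, drop = FALSE])
  lfc <- log2((mt + pseudo) / (mc + pseudo))
  vt <- apply(lt, 1, stats::var); vc <- apply(lc, 1, stats::var)
  nt <- sum(it); nc <- sum(ic)
  sed <- sqrt(vt / nt + vc / nc)
  tstat <- (rowMeans(lt) - rowMeans(lc)) / sed
  df <- (vt / nt + vc / nc)^2 /
    ((vt / nt)^2 / (nt - 1) + (vc / nc)^2 / (nc - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  testable <- !(rowSums(cnt[, it, drop = FALSE]) == 0 &
                rowSums(cnt[, ic, drop = FALSE]) == 0) & is.finite(p)
  q <- rep(NA_real_, length(p))
  q[testable] <- bhAdjust(p[testable])
  p[!testable] <- NA_real_
  direction <- rep("ns", length(p))
  direction[!is.na(q) & q < q_threshold & lfc >= lfc_threshold] <- "up"
  direction[!is.na(q) & q < q_threshold & lfc <= -lfc_threshold] <- "down"
  gid <- SummarizedExperiment::rowData(se)$gene_id
  if (is.null(gid)) gid <- rownames(se)
  data.frame(gene = gid, mean_ctrl = mc, mean_treat = mt, log2fc = lfc,
             p = p, q = q, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up adjustment with monotonicity enforcement.
#'
#' @param p vector of p-values in (0, 1].
#' @return q-values in p's order.
#' @export
bhAdjust <- function(p) stats::p.adjust(p, method = "BH")

#' Category enrichment of a DEG set by the hypergeometric tail
#'
#' One-sided hypergeometric p per category (draws = DEG count in the
#' background, white balls = category size in the background), BH-adjusted
#' across categories.  Categories with fewer than 2 annotated background
#' genes are skipped.
#'
#' @param deg_genes character vector of DEG identifiers.
#' @param annotation data.frame with columns `gene`, `category`.
#' @param background character vector of all tested genes.
#' @return data.frame: category, n_background, n_deg, expected, p, q,
#'   sorted by p.
#' @export
enrichment <- function(deg_genes, annotation, background) {
  if (!length(background)) stop("empty background")
  ann <- annotation[annotation$gene %in% background, ]
  deg_genes <- intersect(deg_genes, background)
  if (!any(ann$gene %in% deg_genes))
    stop("annotation covers no DEG")
  N <- length(unique(background))
  nd <- length(unique(deg_genes))
  cats <- split(unique(ann[, c("gene", "category")])$gene,
                unique(ann[, c("gene", "category")])$category)
  cats <- cats[lengths(cats) >= 2]
  rows <- lapply(names(cats), function(cat) {
    K <- length(cats[[cat]])
    k <- length(intersect(cats[[cat]], deg_genes))
    pv <- stats::phyper(k - 1, K, N - K, nd, lower.tail = FALSE)
    data.frame(category = cat, n_background = K, n_deg = k,
               expected = nd * K / N, p = pv, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bhAdjust(out$p)
  out[order(out$p), ]
}
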