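#' Simulate gene models on the simulated genome
#'
#' Places non-overlapping gene models of log-normal length uniformly on the
#' given chromosomes, with random strand.
#'
#' @param n_genes number of genes.
#' @param chrom_lengths named vector chrom -> bp.
#' @param mean_len_bp mean gene length in bp.
#' @param seed RNG seed.
#' @return `GRanges` with metadata column `gene_id`, sorted by position.
#' @export
simulateGeneModels <- function(n_genes, chrom_lengths = defaultChromLengths(),
                               mean_len_bp = 3000, seed = 1L) {
  set.seed(as.integer(seed))
  n_per <- as.vector(stats::rmultinom(1, n_genes,
                                      chrom_lengths / sum(chrom_lengths)))
  grl <- vector("list", length(chrom_lengths))
  for (ci in seq_along(chrom_lengths)) {
    m <- n_per[ci]
    if (m == 0) next
    len <- pmax(200, round(stats::rlnorm(m, log(mean_len_bp), 0.5)))
    start <- sort(sample.int(max(1, chrom_lengths[ci] - max(len)), m))
    grl[[ci]] <- GenomicRanges::GRanges(
      names(chrom_lengths)[ci],
      IRanges::IRanges(start = start, end = pmin(start + len - 1,
                                                 chrom_lengths[ci])),
      strand = sample(c("+", "-"), m, replace = TRUE))
  }
  gr <- suppressWarnings(do.call(c, grl[!vapply(grl, is.null, TRUE)]))
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  gr$gene_id <- sprintf("gene%05d", seq_along(gr))
  gr
}

#' Expression simulation configuration
#'
#' @param n_genes number of genes to simulate counts for (first `n_genes`
#'   gene models are used).
#' @param deg_fraction fraction of genes planted as differentially
#'   expressed under drought, in [0, 1).
#' @param lfc_mean,lfc_sd mean and SD of the planted absolute log2 fold
#'   change (sign drawn at random).
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param lib_size_range length-2 range of library sizes (fragments).
#' @param link_to_qtn_window_bp window around QTNs inside which a share of
#'   planted DEGs is placed.
#' @param qtn_deg_share share of planted DEGs drawn from genes within the
#'   QTN window (when enough such genes exist).
#' @param seed RNG seed.
#' @return object of class `ExprSimConfig`.
#' @export
exprSimConfig <- function(n_genes = 2000, deg_fraction = 0.10,
                          lfc_mean = 2, lfc_sd = 0.25, dispersion = 0.05,
                          lib_size_range = c(8e6, 12e6),
                          link_to_qtn_window_bp = 288000,
                          qtn_deg_share = 0.5, seed = 1L) {
  stopifnot(deg_fraction >= 0, deg_fraction < 1, dispersion > 0,
            length(lib_size_range) == 2)
  structure(list(n_genes = as.integer(n_genes), deg_fraction = deg_fraction,
                 lfc_mean = lfc_mean, lfc_sd = lfc_sd,
                 dispersion = dispersion, lib_size_range = lib_size_range,
                 link_to_qtn_window_bp = link_to_qtn_window_bp,
                 qtn_deg_share = qtn_deg_share, seed = as.integer(seed)),
            class = "ExprSimConfig")
}

#' Default RNA-seq sample sheet: contrasting variety pairs, two tissues
#'
#' Two high-yield and two low-yield varieties, leaf and seed tissue,
#' control vs drought treatment, `n_reps` biological replicates.
#'
#' @param n_reps replicates per cell.
#' @return data.frame with columns sample, variety, group, tissue,
#'   treatment, replicate.
#' @export
defaultExprSamples <- function(n_reps = 3) {
  g <- expand.grid(replicate = seq_len(n_reps),
                   treatment = c("control", "drought"),
                   tissue = c("leaf", "seed"),
                   variety = c("G19", "G41", "G111", "G114"),
                   stringsAsFactors = FALSE)
  g$group <- ifelse(g$variety %in% c("G19", "G41"), "high", "low")
  g$sample <- paste(g$variety, g$tissue, g$treatment, g$replicate, sep = "_")
  g[, c("sample", "variety", "group", "tissue", "treatment", "replicate")]
}

#' Simulate a negative-binomial expression count matrix with planted DEGs
#'
#' Baseline expression is log-normal per gene; planted DEGs multiply their
#' expected expression by `2^lfc` in drought samples.  A configurable share
#' of the planted DEGs is placed among genes lying within
#' `link_to_qtn_window_bp` of a supplied QTN, so that GWAS intervals are
#' enriched for DEGs by construction.  Expected fragment counts are
#' proportional to expression times gene length, scaled to each sample's
#' library size; counts are negative binomial.
#'
#' @param genes `GRanges` of gene models (with `gene_id`), lengths > 0.
#' @param cfg an [exprSimConfig()] object.
#' @param qtns optional data.frame with `chrom`, `pos` of planted QTNs.
#' @param samples sample sheet as from [defaultExprSamples()].
#' @return `SummarizedExperiment` with assay `counts`, `rowData` columns
#'   `gene_id` and `length`, the sample sheet as `colData`, and truth
#'   labels (`gene`, `lfc`, `near_qtn`) in `metadata(se)$truth`.
#' @export
simulateExpression <- function(genes, cfg, qtns = NULL,
                               samples = defaultExprSamples()) {
  stopifnot(inherits(cfg, "ExprSimConfig"))
  if (any(GenomicRanges::width(genes) <= 0)) stop("gene lengths must be > 0")
  set.seed(cfg$seed)
  genes <- genes[seq_len(min(cfg$n_genes, length(genes)))]
  ng <- length(genes)
  ns <- nrow(samples)
  len <- GenomicRanges::width(genes)
  gid <- genes$gene_id

  near <- rep(FALSE, ng)
  if (!is.null(qtns) && nrow(qtns)) {
    qgr <- GenomicRanges::GRanges(qtns$chrom,
                                  IRanges::IRanges(qtns$pos, qtns$pos))
    hit <- GenomicRanges::findOverlaps(
      genes, qgr, maxgap = cfg$link_to_qtn_window_bp)
    near[unique(S4Vectors::queryHits(hit))] <- TRUE
  }

  n_deg <- round(cfg$deg_fraction * ng)
  deg_idx <- integer(0)
  if (n_deg > 0) {
    n_near <- min(round(cfg$qtn_deg_share * n_deg), sum(near))
    deg_idx <- c(if (n_near > 0) sample(which(near), n_near),
                 sample(which(!near), n_deg - n_near))
  }
  lfc <- rep(0, ng)
  if (length(deg_idx))
    lfc[deg_idx] <- sample(c(-1, 1), length(deg_idx), replace = TRUE) *
      abs(stats::rnorm(length(deg_idx), cfg$lfc_mean, cfg$lfc_sd))

  base <- stats::rlnorm(ng, meanlog = log(50), sdlog = 1.2)
  libsz <- round(stats::runif(ns, cfg$lib_size_range[1], cfg$lib_size_range[2]))
  is_drought <- samples$treatment == "drought"
  counts <- matrix(0L, ng, ns, dimnames = list(gid, samples$sample))
  for (s in seq_len(ns)) {
    expr <- if (is_drought[s]) base * 2^lfc else base
    rate <- expr * len
    mu <- rate / sum(rate) * libsz[s]
    counts[, s] <- stats::rnbinom(ng, size = 1 / cfg$dispersion, mu = mu)
  }

  truth <- data.frame(gene = gid[deg_idx],
                      lfc = lfc[deg_idx],
                      near_qtn = near[deg_idx],
                      stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(gene_id = gid, length = len),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample))
  S4Vectors::metadata(se)$truth <- truth
  S4Vectors::metadata(se)$lib_sizes <- stats::setNames(libsz, samples$sample)
  se
}
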