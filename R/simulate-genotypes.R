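#' Default chromosome lengths for the simulated rapeseed-like genome
#'
#' Nineteen chromosomes named A01-A10 and C01-C09.  The A subgenome
#' totals ~284 Mbp and the C subgenome ~489 Mbp, split evenly within
#' each subgenome.
#'
#' @return named numeric vector of chromosome lengths in bp
#' @export
defaultChromLengths <- function() {
  a <- stats::setNames(rep(round(283.8e6 / 10), 10), sprintf("A%02d", 1:10))
  c_ <- stats::setNames(rep(round(488.6e6 / 9), 9), sprintf("C%02d", 1:9))
  c(a, c_)
}

#' Simulation configuration for the genotype generator
#'
#' Defaults emulate the structure of the variety panel the pipeline is
#' designed for: 119 varieties, ~29,310 biallelic SNPs on 19 chromosomes,
#' seven subpopulations, and linkage disequilibrium decaying on the
#' hundreds-of-kbp scale (nominal r-squared half-decay 288 kbp).
#'
#' @param n_samples number of diploid samples (varieties).
#' @param chrom_lengths named vector chrom -> length in bp; names must be
#'   drawn from A01..A10, C01..C09.
#' @param n_snps total number of SNPs across the genome.
#' @param n_subpops number of subpopulations.
#' @param fst Wright's fixation index controlling allele-frequency
#'   divergence of subpopulations (Balding-Nichols model); 0 <= fst < 1.
#' @param ld_block_len nominal r-squared half-decay length in bp; sets the
#'   per-bp haplotype decorrelation rate when `recomb_rate` is `NULL`.
#' @param recomb_rate per-bp haplotype decorrelation rate (the latent
#'   between-site correlation is `exp(-recomb_rate * distance)`); overrides
#'   `ld_block_len` when given.
#' @param maf_floor lower bound of the ancestral allele-frequency draw,
#'   in (0, 0.5].
#' @param missing_rate fraction of genotype calls set to missing, in [0, 1).
#' @param seed integer RNG seed.
#' @return object of class `SimConfig`.
#' @export
simConfig <- function(n_samples = 119,
                      chrom_lengths = defaultChromLengths(),
                      n_snps = 29310,
                      n_subpops = 7,
                      fst = 0.10,
                      ld_block_len = 288000,
                      recomb_rate = NULL,
                      maf_floor = 0.05,
                      missing_rate = 0.02,
                      seed = 1L) {
  stopifnot(fst >= 0, fst < 1,
            maf_floor > 0, maf_floor <= 0.5,
            missing_rate >= 0, missing_rate < 1,
            n_samples >= 2, n_snps >= 1, n_subpops >= 1)
  valid <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9))
  if (!all(names(chrom_lengths) %in% valid))
    stop("chromosome names must be drawn from A01..A10, C01..C09")
  if (is.null(recomb_rate)) {
    # the Hill-Weir-fitted r^2 half-decay of the latent-threshold model on
    # a QC-filtered panel is ~0.15 of the latent correlation length
    # (measured once at design time), so a nominal half-decay of L bp
    # needs rate = 0.15 / L
    recomb_rate <- 0.15 / ld_block_len
  }
  structure(list(n_samples = as.integer(n_samples),
                 chrom_lengths = chrom_lengths,
                 n_snps = as.integer(n_snps),
                 n_subpops = as.integer(n_subpops),
                 fst = fst,
                 ld_block_len = ld_block_len,
                 recomb_rate = recomb_rate,
                 maf_floor = maf_floor,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a structured SNP genotype panel
#'
#' Allele frequencies diverge between subpopulations under the
#' Balding-Nichols model around a common ancestral frequency drawn
#' uniformly from `[maf_floor, 1 - maf_floor]`.  Each haplotype is a
#' thresholded latent Gaussian AR(1) process along the chromosome: the
#' latent correlation between two sites is `exp(-recomb_rate * distance)`
#' and the allele is 1 where the latent value falls below the quantile of
#' the subpopulation allele frequency, so pairwise r-squared declines
#' smoothly with physical distance at a controllable scale.  Genotypes are
#' the sum of two haplotypes; missing calls are injected uniformly at
#' random.  Observed (sampled) minor allele frequencies can fall below
#' `maf_floor`; downstream QC is expected to remove them.
#'
#' @param cfg a [simConfig()] object.
#' @return [GenotypeData-class] with `sampleInfo$subpop` recording the true
#'   subpopulation of each sample.
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  cl <- cfg$chrom_lengths
  # allocate SNPs across chromosomes proportional to physical length
  n_per <- as.vector(stats::rmultinom(1, cfg$n_snps, cl / sum(cl)))
  names(n_per) <- names(cl)
  if (any(n_per > cl))
    stop("n_snps exceeds the number of representable positions on: ",
         paste(names(cl)[n_per > cl], collapse = ", "))

  n <- cfg$n_samples
  nh <- 2L * n
  S <- cfg$n_subpops
  subpop <- rep(seq_len(S), length.out = n)
  hap_sub <- rep(subpop, each = 2L)            # subpop of each haplotype

  snp_chrom <- character(0); snp_pos <- integer(0)
  hap_list <- vector("list", length(cl))
  for (ci in seq_along(cl)) {
    m <- n_per[ci]
    if (m == 0) { hap_list[[ci]] <- matrix(integer(0), nrow = nh, ncol = 0); next }
    pos <- sort(sample.int(cl[ci], m))
    snp_chrom <- c(snp_chrom, rep(names(cl)[ci], m))
    snp_pos <- c(snp_pos, pos)

    p0 <- stats::runif(m, cfg$maf_floor, 1 - cfg$maf_floor)
    # Balding-Nichols subpopulation frequencies
    pf <- matrix(0, nrow = S, ncol = m)
    if (cfg$fst == 0) {
      pf[] <- rep(p0, each = S)
    } else {
      a <- (1 - cfg$fst) / cfg$fst
      for (s in seq_len(S))
        pf[s, ] <- stats::rbeta(m, p0 * a, (1 - p0) * a)
    }
    thr <- stats::qnorm(pf)                    # S x m latent thresholds

    # latent AR(1) path per haplotype, thresholded at the subpop quantile
    z <- stats::rnorm(nh)
    a_gap <- exp(-cfg$recomb_rate * diff(pos))
    haps <- matrix(0L, nrow = nh, ncol = m)
    haps[, 1] <- (z < thr[hap_sub, 1]) + 0L
    for (j in seq_len(m - 1L)) {
      z <- a_gap[j] * z + sqrt(1 - a_gap[j]^2) * stats::rnorm(nh)
      haps[, j + 1L] <- (z < thr[hap_sub, j + 1L]) + 0L
    }
    hap_list[[ci]] <- haps
  }
  haps <- do.call(cbind, hap_list)
  geno <- haps[seq(1, nh, by = 2L), , drop = FALSE] +
          haps[seq(2, nh, by = 2L), , drop = FALSE]
  storage.mode(geno) <- "double"

  if (cfg$missing_rate > 0) {
    nmiss <- stats::rbinom(1, length(geno), cfg$missing_rate)
    if (nmiss > 0)
      geno[sample.int(length(geno), nmiss)] <- NA_real_
  }

  nucs <- c("A", "C", "G", "T")
  m_tot <- length(snp_pos)
  ref <- sample(nucs, m_tot, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nucs, r), 1), character(1))
  info <- data.frame(id = paste0(snp_chrom, "_", snp_pos),
                     chrom = snp_chrom, pos = snp_pos,
                     ref = ref, alt = unname(alt),
                     stringsAsFactors = FALSE)
  rownames(geno) <- sprintf("G%03d", seq_len(n))
  GenotypeData(geno, info,
               data.frame(id = rownames(geno), subpop = subpop,
                          stringsAsFactors = FALSE))
}
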