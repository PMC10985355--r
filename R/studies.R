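#' Mixed-model calibration study on a structured null panel
#'
#' Simulates panels of 119 varieties in seven subpopulations (fst 0.2)
#' with a phenotype driven only by subpopulation mean shifts and noise (a
#' structured null: no individual marker effect), runs the MLM with
#' kinship and five principal components on every SNP, and pools the
#' genomic inflation factors and the empirical type-I error at the
#' 1e-4 threshold.
#'
#' @param n_sims number of simulated panels.
#' @param n_samples,n_snps panel size.
#' @param seed integer seed.
#' @param alpha threshold for the type-I tally.
#' @return list with lambdas, lambda_median, n_sig, n_tests, type1_rate.
#' @export
mlmCalibrationStudy <- function(n_sims = 21, n_samples = 119,
                                n_snps = 5000, seed = 1, alpha = 1e-4) {
  chrl <- defaultChromLengths()[c("A01", "A03", "C02")] / 4
  base <- (as.integer(seed) %% 20000L) * 100000L
  lambdas <- numeric(n_sims); n_sig <- 0L; n_tests <- 0L
  for (s in seq_len(n_sims)) {
    cfg <- simConfig(n_samples = n_samples, chrom_lengths = chrl,
                     n_snps = n_snps, n_subpops = 7, fst = 0.2,
                     seed = base + s)
    g <- simulateGenotypes(cfg)
    set.seed(base + s + 10000L)
    sp <- sampleInfo(g)$subpop
    y <- stats::setNames(stats::rnorm(7, 0, 2)[sp] +
                           stats::rnorm(nSamples(g)),
                         sampleInfo(g)$id)
    K <- kinship(g)
    pcs <- pcaGenotypes(g, 5)$scores
    res <- mlmAssoc(g, y, K, covariates = pcs)
    lambdas[s] <- inflationAndPlots(res)$lambda
    n_sig <- n_sig + sum(res$p < alpha, na.rm = TRUE)
    n_tests <- n_tests + sum(!is.na(res$p))
  }
  list(lambdas = lambdas, lambda_median = stats::median(lambdas),
       n_sig = n_sig, n_tests = n_tests, type1_rate = n_sig / n_tests)
}

#' Broad-sense heritability recovery study
#'
#' Simulates 119-variety, 3-replicate single-environment trials at given
#' target heritabilities and estimates heritability back through the
#' per-environment ANOVA chain.
#'
#' @param h2_targets targets in [0, 1).
#' @param n_sims simulations per target.
#' @param seed integer seed.
#' @return data.frame with h2_target, median_estimate, mad.
#' @export
heritabilityRecoveryStudy <- function(h2_targets = c(0.3, 0.6, 0.9),
                                      n_sims = 50, seed = 1) {
  base <- (as.integer(seed) %% 20000L) * 100000L
  rows <- lapply(h2_targets, function(h2t) {
    est <- vapply(seq_len(n_sims), function(s) {
      cfg <- simConfig(n_samples = 119, chrom_lengths = c(A01 = 5e6),
                       n_snps = 300, n_subpops = 3,
                       seed = base + s + round(1e4 * h2t))
      g <- simulateGenotypes(cfg)
      arch <- traitArchitecture("T", h2_target = h2t,
                                env_effects = c(WW17 = 100),
                                residual_sd = 5)
      sim <- simulatePhenotypes(g, arch,
                                data.frame(year = 2017, regime = "WW"),
                                n_reps = 3,
                                seed = base + s + round(1e4 * h2t) + 50000L)
      at <- anovaPerEnvironment(sim$pheno, "T", 2017, "WW")
      vc <- varianceComponents(at)
      heritability(vc$sigma_g2, vc$sigma_p2)$h2 / 100
    }, numeric(1))
    data.frame(h2_target = h2t, median_estimate = stats::median(est),
               mad = stats::mad(est))
  })
  do.call(rbind, rows)
}

#' Power study for a planted QTN explaining ~20% of phenotypic variance
#'
#' Plants a single QTN whose structure-orthogonal dosage component
#' explains the target share of the variance of variety means, then asks
#' (a) whether the QTN is the minimum-p SNP of a covariate-adjusted GLM
#' scan and (b) whether the MLM detects it at p < 1e-4.
#'
#' @param n_sims number of simulations.
#' @param target_share share of phenotypic variance for the QTN.
#' @param seed integer seed.
#' @return list with glm_top_rate, mlm_power, n_sims.
#' @export
qtnPowerStudy <- function(n_sims = 50, target_share = 0.2, seed = 1) {
  base <- (as.integer(seed) %% 20000L) * 100000L
  top <- det <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    cfg <- simConfig(n_samples = 119,
                     chrom_lengths = c(A01 = 1e7, C02 = 1e7),
                     n_snps = 600, n_subpops = 7, fst = 0.1,
                     recomb_rate = 1 / 2e5, seed = base + s)
    g <- filterSnps(simulateGenotypes(cfg))$geno
    si <- snpInfo(g)
    pcs <- pcaGenotypes(g, 5)$scores
    cand <- which(mafs(g) >= 0.25)
    d <- dosage(g)[, cand, drop = FALSE]
    d[is.na(d)] <- 0
    vperp <- vapply(seq_along(cand), function(k)
      sum(stats::lm.fit(cbind(1, pcs), d[, k])$residuals^2) /
        (nrow(d) - 1), numeric(1))
    pickr <- order(-vperp)[5]
    j <- cand[pickr]
    # variance of variety means excluding the QTN is sigma_g2 + sigma_e2/r
    # = 9 + 9/3 = 12 under the settings below
    b <- sqrt(target_share / (1 - target_share) * 12 / vperp[pickr])
    arch <- traitArchitecture("T",
      qtn = data.frame(chrom = si$chrom[j], pos = si$pos[j], effect = b),
      h2_target = 0.5, env_effects = c(WW17 = 50), residual_sd = 3)
    sim <- simulatePhenotypes(g, arch,
                              data.frame(year = 2017, regime = "WW"),
                              3, seed = base + s + 20000L)
    ym <- tapply(sim$pheno$value, sim$pheno$variety, mean)
    rg <- glmAssoc(g, ym, covariates = pcs)
    top[s] <- which.min(rg$p) == j
    rm_ <- mlmAssoc(g, ym, kinship(g), covariates = pcs)
    det[s] <- !is.na(rm_$p[j]) && rm_$p[j] < 1e-4
  }
  list(glm_top_rate = mean(top), mlm_power = mean(det), n_sims = n_sims)
}

#' LD-decay recovery study
#'
#' Simulates single-chromosome panels with a nominal r-squared half-decay
#' of `target_bp` and re-estimates the decay distance with the Hill-Weir
#' fit.
#'
#' @param n_sims number of simulations.
#' @param target_bp nominal half-decay in bp.
#' @param seed integer seed.
#' @return list with median_distance, distances, target_bp.
#' @export
ldDecayRecoveryStudy <- function(n_sims = 20, target_bp = 300000,
                                 seed = 1) {
  base <- (as.integer(seed) %% 20000L) * 100000L
  dd <- vapply(seq_len(n_sims), function(s) {
    cfg <- simConfig(n_samples = 119, chrom_lengths = c(A01 = 2e7),
                     n_snps = 800, n_subpops = 1, fst = 0,
                     ld_block_len = target_bp, seed = base + s)
    g <- filterSnps(simulateGenotypes(cfg))$geno
    ld <- pairwiseLD(g, max_distance = 5e6, stats = "r2")
    ldDecay(ld, n = 2 * nSamples(g))$decay_distance
  }, numeric(1))
  list(median_distance = stats::median(dd, na.rm = TRUE), distances = dd,
       target_bp = target_bp)
}

#' Recovery study for planted strong DEGs
#'
#' Plants 10% DEGs at |log2FC| = 2 with low dispersion in a 3 vs 3
#' contrast and measures the fraction recalled at |log2fc| >= 1,
#' Q < 0.05.
#'
#' @param n_sims number of simulations.
#' @param n_genes genes per simulation.
#' @param seed integer seed.
#' @return list with median_recall, recalls.
#' @export
degRecoveryStudy <- function(n_sims = 50, n_genes = 1000, seed = 1) {
  base <- (as.integer(seed) %% 20000L) * 100000L
  genes <- simulateGeneModels(n_genes, c(A01 = 2e7), seed = base + 99999L)
  samp <- defaultExprSamples()[1:6, ]
  rec <- vapply(seq_len(n_sims), function(s) {
    cfg <- exprSimConfig(n_genes = n_genes, deg_fraction = 0.1,
                         lfc_mean = 2, lfc_sd = 0.1, dispersion = 0.01,
                         seed = base + s)
    se <- simulateExpression(genes, cfg, samples = samp)
    deg <- differentialExpression(se)
    truth <- S4Vectors::metadata(se)$truth
    mean(truth$gene %in% deg$gene[deg$direction != "ns"])
  }, numeric(1))
  list(median_recall = stats::median(rec), recalls = rec)
}

#' False-discovery control study under the full expression null
#'
#' Simulates expression with no planted DEGs and records, per simulation,
#' the false discovery proportion of the q < 0.05 rule (1 when any gene is
#' rejected, 0 otherwise, since every rejection is false under the null).
#' The mean over simulations estimates the realized FDR.
#'
#' @param n_sims number of simulations.
#' @param n_genes genes per simulation.
#' @param seed integer seed.
#' @return list with fdr, n_sims.
#' @export
degNullFdrStudy <- function(n_sims = 500, n_genes = 300, seed = 1) {
  base <- (as.integer(seed) %% 20000L) * 100000L
  genes <- simulateGeneModels(n_genes, c(A01 = 1e7), seed = base + 99998L)
  samp <- defaultExprSamples()[1:6, ]
  fdp <- vapply(seq_len(n_sims), function(s) {
    cfg <- exprSimConfig(n_genes = n_genes, deg_fraction = 0,
                         dispersion = 0.05, seed = base + s)
    se <- simulateExpression(genes, cfg, samples = samp)
    deg <- differentialExpression(se, lfc_threshold = 0)
    as.numeric(any(deg$direction != "ns", na.rm = TRUE))
  }, numeric(1))
  list(fdr = mean(fdp), n_sims = n_sims)
}
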