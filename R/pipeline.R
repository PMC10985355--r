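#' Run the full pipeline on a synthetic study
#'
#' End-to-end demonstration and integration harness: simulates a
#' structured genotype panel with planted QTNs (one pleiotropic across
#' two traits, one drought-specific), replicated multi-environment
#' phenotypes, and expression counts with DEGs enriched near the QTNs;
#' then runs QC, kinship/PCA, mixed-model association per trait and
#' environment, stability/pleiotropy screens, candidate-gene extraction,
#' DEG calling, and the GWAS-by-transcriptome interval comparison.
#'
#' @param seed integer seed driving every stage.
#' @param n_samples,n_snps,n_genes problem sizes (defaults are desk-scale;
#'   see the methods vignette).
#' @param n_subpops subpopulations in the simulated panel.
#' @param alpha association significance threshold.
#' @param window candidate/interval window in bp.
#' @param out_dir optional directory for [finalReport()].
#' @return list with all stage outputs and the simulation truth.
#' @export
runSyntheticStudy <- function(seed = 1, n_samples = 119, n_snps = 2000,
                              n_genes = 800, n_subpops = 7, alpha = 1e-4,
                              window = 288000, out_dir = NULL) {
  chrlen <- defaultChromLengths()[c("A01", "A02", "C01")] / 10
  cfg <- simConfig(n_samples = n_samples, chrom_lengths = chrlen,
                   n_snps = n_snps, n_subpops = n_subpops,
                   missing_rate = 0.02, seed = seed)
  geno <- simulateGenotypes(cfg)
  qc <- filterSnps(geno)
  g <- qc$geno

  si <- snpInfo(g)
  mafv <- mafs(g)
  pick <- function(k, exclude = integer(0)) {
    cand <- setdiff(which(mafv >= 0.2), exclude)
    cand[round(seq(1, length(cand), length.out = k))]
  }
  q1 <- pick(1)                      # pleiotropic: DTF and SY
  q2 <- pick(2, q1)[2]               # drought-specific for SY
  envs <- expand.grid(year = c(2017, 2018), regime = c("WW", "DS"),
                      stringsAsFactors = FALSE)
  ecodes <- envCode(envs$year, envs$regime)
  ds_envs <- ecodes[envs$regime == "DS"]
  arch <- list(
    traitArchitecture("DTF",
      qtn = data.frame(chrom = si$chrom[q1], pos = si$pos[q1], effect = 2.5),
      h2_target = 0.7,
      env_effects = stats::setNames(c(183, 181, 186, 181), ecodes),
      gxe_sd = 0.5, rep_sd = 0.5, residual_sd = 3, base_mean = 0),
    traitArchitecture("SY",
      qtn = data.frame(chrom = si$chrom[c(q1, q2)],
                       pos = si$pos[c(q1, q2)], effect = c(200, 250)),
      h2_target = 0.6,
      env_effects = stats::setNames(c(2600, 1350, 1900, 1100), ecodes),
      gxe_sd = 50, rep_sd = 50, residual_sd = 400, base_mean = 0,
      qtn_envs = list(NULL, as.list(ds_envs))))
  arch[[2]]$qtn_envs <- list(NULL, ds_envs)
  sim <- simulatePhenotypes(g, arch, envs, n_reps = 3, seed = seed + 1)

  params <- geneticParamsTable(sim$pheno)
  K <- kinship(g)
  pcs <- pcaGenotypes(g, 5)$scores

  assoc <- list()
  for (a in arch) for (e in seq_len(nrow(envs))) {
    d <- sim$pheno[sim$pheno$trait == a$trait &
                   sim$pheno$year == envs$year[e] &
                   sim$pheno$regime == envs$regime[e], ]
    ym <- tapply(d$value, d$variety, mean)
    assoc[[length(assoc) + 1L]] <-
      mlmAssoc(g, ym, K, covariates = pcs, trait = a$trait,
               env = ecodes[e])
  }
  assoc <- do.call(rbind, assoc)
  sig <- significantSnps(assoc, alpha)
  stable <- stableSnps(assoc, alpha)
  pleio <- pleiotropicSnps(assoc, alpha)
  plots <- inflationAndPlots(assoc)

  genes <- simulateGeneModels(n_genes, chrlen, seed = seed + 2)
  qtns <- unique(sim$truth$qtn[, c("chrom", "pos")])
  ecfg <- exprSimConfig(n_genes = n_genes, deg_fraction = 0.10,
                        link_to_qtn_window_bp = window, seed = seed + 3)
  se <- simulateExpression(genes, ecfg, qtns)
  cd <- SummarizedExperiment::colData(se)
  deg <- differentialExpression(se, subset = cd$tissue == "leaf" &
                                  cd$group == "high")

  cands <- candidateGeneTable(sig, genes, window)
  comp <- tryCatch(intervalDegComparison(sig, genes, deg, window),
                   error = function(e) NULL)
  validated <- overlapGwasDegs(cands, list(leaf_high = deg))

  out <- list(geno = g, qc_report = qc$report, pheno = sim$pheno,
              truth = c(sim$truth,
                        list(expr = S4Vectors::metadata(se)$truth)),
              genetic_params = params, kinship = K, pcs = pcs,
              assoc = assoc, sig = sig, stable = stable,
              pleiotropic = pleio, plots = plots, genes = genes,
              expression = se, deg = deg, candidates = cands,
              interval_comparison = comp,
              validated = validated$validated, venn = validated$venn,
              seed = seed)
  if (!is.null(out_dir))
    finalReport(c(out, list(validated = validated$validated)), out_dir)
  out
}
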