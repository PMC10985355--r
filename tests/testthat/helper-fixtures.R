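# small builders shared across test files

toyGeno <- function(d, chrom = "A01", pos = NULL, ref = NULL, alt = NULL) {
  d <- as.matrix(d)
  m <- ncol(d)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (length(chrom) == 1) chrom <- rep(chrom, m)
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("G", m)
  GenotypeData(d, data.frame(id = paste0(chrom, "_", pos), chrom = chrom,
                             pos = pos, ref = ref, alt = alt,
                             stringsAsFactors = FALSE))
}

quickPanel <- function(seed, n_samples = 119, n_snps = 400,
                       chrom_lengths = c(A01 = 1e7), n_subpops = 3,
                       fst = 0.1, ...) {
  simulateGenotypes(simConfig(n_samples = n_samples, n_snps = n_snps,
                              chrom_lengths = chrom_lengths,
                              n_subpops = n_subpops, fst = fst,
                              seed = seed, ...))
}

onePhenoEnv <- function(geno, h2, seed, residual_sd = 3, ...) {
  arch <- traitArchitecture("T", h2_target = h2,
                            env_effects = c(WW17 = 100),
                            residual_sd = residual_sd, ...)
  simulatePhenotypes(geno, arch, data.frame(year = 2017, regime = "WW"),
                     n_reps = 3, seed = seed)
}

envCodes <- function(envs)
  paste0(envs$regime, substr(as.character(envs$year), 3, 4))

varietyMeans <- function(pheno, trait = "T") {
  d <- pheno[pheno$trait == trait, ]
  tapply(d$value, d$variety, mean)
}
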