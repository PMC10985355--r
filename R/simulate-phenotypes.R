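#' Trait architecture for the phenotype generator
#'
#' Describes one simulated trait: its QTNs (positions and additive effects),
#' the target per-environment broad-sense heritability, environment mean
#' shifts, and the variance components of the trial design
#' (genotype-by-environment, replicate block, and plot residual).
#'
#' @param trait trait name.
#' @param qtn data.frame with columns `chrom`, `pos`, `effect` (additive
#'   effect in trait units per alternate allele); may have zero rows.
#' @param h2_target target per-environment broad-sense heritability in
#'   [0, 1); the polygenic variance is scaled to reach it.
#' @param env_effects named numeric vector of per-environment means
#'   (environment codes such as "WW17"); these are the expected values of
#'   an observation with no genetic or error deviation.
#' @param gxe_sd SD of the genotype-by-environment deviation (trait units).
#' @param rep_sd SD of the replicate block effect within an environment.
#' @param residual_sd plot residual SD (> 0 unless everything else is 0).
#' @param base_mean grand mean added to every observation (default 0; the
#'   per-environment mean is then `base_mean + env_effects[env]`).
#' @param qtn_envs optional list, one element per QTN row, of environment
#'   codes in which that QTN is active; `NULL` means active everywhere
#'   (a "stable" QTN).
#' @return object of class `TraitArchitecture`.
#' @export
traitArchitecture <- function(trait, qtn = data.frame(chrom = character(),
                                                      pos = integer(),
                                                      effect = numeric()),
                              h2_target = 0.6, env_effects = c(E1 = 0),
                              gxe_sd = 0, rep_sd = 0, residual_sd = 1,
                              base_mean = 0, qtn_envs = NULL) {
  stopifnot(h2_target >= 0, h2_target <= 1, residual_sd >= 0)
  if (!is.null(qtn_envs) && length(qtn_envs) != nrow(qtn))
    stop("qtn_envs must have one element per QTN")
  structure(list(trait = trait, qtn = qtn, h2_target = h2_target,
                 env_effects = env_effects, gxe_sd = gxe_sd,
                 rep_sd = rep_sd, residual_sd = residual_sd,
                 base_mean = base_mean, qtn_envs = qtn_envs),
            class = "TraitArchitecture")
}

envCode <- function(year, regime) paste0(regime, substr(as.character(year), 3, 4))

#' Simulate replicated multi-environment phenotypes
#'
#' For each trait, variety genetic value = sum of QTN dosage effects plus a
#' polygenic value built from genome-wide marker dosages with random
#' weights, scaled so the per-environment broad-sense heritability
#' (genotype variance over genotype + plot-residual variance) matches
#' `h2_target`.  Observations are
#' `base_mean + env_effect + QTN + polygenic + GxE + rep block + residual`.
#'
#' @param geno [GenotypeData-class] panel; QTNs must exist in its map.
#' @param arch list of [traitArchitecture()] objects (or a single one).
#' @param envs data.frame with columns `year` and `regime` (e.g. "WW"/"DS").
#' @param n_reps replicates per environment.
#' @param seed integer RNG seed.
#' @return list with `pheno` (long data.frame: variety, trait, year, regime,
#'   rep, value), and `truth`: per-trait QTN table (with SNP ids), realized
#'   per-trait-by-environment heritability, and variety genetic values.
#' @export
simulatePhenotypes <- function(geno, arch, envs, n_reps = 3, seed = 1L) {
  if (inherits(arch, "TraitArchitecture")) arch <- list(arch)
  stopifnot(all(vapply(arch, inherits, TRUE, "TraitArchitecture")),
            all(c("year", "regime") %in% names(envs)), n_reps >= 1)
  set.seed(as.integer(seed))
  d <- dosage(geno)
  # mean-impute missing dosages for genetic-value construction
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  n <- nrow(d)
  vars <- rownames(d)
  ecodes <- envCode(envs$year, envs$regime)
  ne <- length(ecodes)

  out <- vector("list", length(arch))
  truth_qtn <- vector("list", length(arch))
  truth_h2 <- vector("list", length(arch))
  gvals <- list()
  for (k in seq_along(arch)) {
    a <- arch[[k]]
    q <- a$qtn
    qcols <- integer(0)
    if (nrow(q)) {
      key <- paste0(q$chrom, "_", q$pos)
      qcols <- match(key, snpInfo(geno)$id)
      if (anyNA(qcols))
        stop("unknown QTN position(s) for trait ", a$trait, ": ",
             paste(key[is.na(qcols)], collapse = ", "))
    }
    ee <- a$env_effects[ecodes]
    if (anyNA(ee)) ee <- stats::setNames(rep(a$env_effects[1], ne), ecodes)

    # per-environment QTN genetic value (QTNs may be active in a subset)
    qtn_val <- matrix(0, n, ne, dimnames = list(vars, ecodes))
    if (length(qcols)) {
      for (e in seq_len(ne)) {
        act <- if (is.null(a$qtn_envs)) rep(TRUE, length(qcols))
               else vapply(a$qtn_envs,
                           function(z) is.null(z) || ecodes[e] %in% z, TRUE)
        if (any(act))
          qtn_val[, e] <- d[, qcols[act], drop = FALSE] %*% q$effect[act]
      }
    }
    var_qtn <- mean(apply(qtn_val, 2, stats::var))

    # polygenic value from genome-wide dosages, scaled to hit h2_target
    sigma_e2 <- a$residual_sd^2
    if (a$h2_target >= 1 && sigma_e2 > 0)
      stop("h2_target must be < 1 when residual_sd > 0")
    sg2_target <- if (a$h2_target < 1)
      a$h2_target / (1 - a$h2_target) * sigma_e2 else 0
    su2 <- max(0, sg2_target - var_qtn - a$gxe_sd^2)
    u <- rep(0, n)
    if (su2 > 0) {
      u <- as.vector(d %*% stats::rnorm(ncol(d)))
      u <- u - mean(u)
      su <- stats::sd(u)
      u <- if (su > 0) u * sqrt(su2) / su else stats::rnorm(n, 0, sqrt(su2))
    }

    gxe <- matrix(if (a$gxe_sd > 0) stats::rnorm(n * ne, 0, a$gxe_sd) else 0,
                  n, ne)
    g_env <- qtn_val + u + gxe
    h2_real <- apply(g_env, 2, function(g) {
      vg <- stats::var(g)
      if (vg + sigma_e2 == 0) NA_real_ else vg / (vg + sigma_e2)
    })

    rep_eff <- matrix(if (a$rep_sd > 0) stats::rnorm(ne * n_reps, 0, a$rep_sd)
                      else 0, ne, n_reps)
    rows <- vector("list", ne)
    for (e in seq_len(ne)) {
      eps <- matrix(if (sigma_e2 > 0) stats::rnorm(n * n_reps, 0, a$residual_sd)
                    else 0, n, n_reps)
      val <- a$base_mean + ee[e] + g_env[, e] +
             matrix(rep_eff[e, ], n, n_reps, byrow = TRUE) + eps
      rows[[e]] <- data.frame(variety = rep(vars, n_reps),
                              trait = a$trait,
                              year = envs$year[e], regime = envs$regime[e],
                              rep = rep(seq_len(n_reps), each = n),
                              value = as.vector(val),
                              stringsAsFactors = FALSE)
    }
    out[[k]] <- do.call(rbind, rows)
    truth_qtn[[k]] <- if (nrow(q))
      data.frame(trait = a$trait, id = paste0(q$chrom, "_", q$pos), q,
                 stringsAsFactors = FALSE)
      else NULL
    truth_h2[[k]] <- data.frame(trait = a$trait, env = ecodes,
                                year = envs$year, regime = envs$regime,
                                h2 = unname(h2_real),
                                stringsAsFactors = FALSE)
    gvals[[a$trait]] <- g_env
  }
  list(pheno = do.call(rbind, out),
       truth = list(qtn = do.call(rbind, truth_qtn),
                    h2 = do.call(rbind, truth_h2),
                    genetic_values = gvals))
}
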