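#' Per-environment ANOVA of a replicated variety trial
#'
#' Randomized-complete-block style two-way model `value ~ genotype +
#' replicate` fitted within one trait-by-environment cell.  The returned
#' table carries the mean squares the variance-component estimators need,
#' and the (harmonic-mean) replicate count as attribute `r`.
#'
#' @param pheno long phenotype data.frame with columns variety, trait,
#'   year, regime, rep, value.
#' @param trait trait name.
#' @param year,regime identify the environment.
#' @return data.frame with columns source (genotype, replicate, error),
#'   df, mean_sq, f_value, p_value; attributes `r` (harmonic-mean replicate
#'   count) and `grand_mean`.
#' @export
anovaPerEnvironment <- function(pheno, trait, year, regime) {
  d <- pheno[pheno$trait == trait & pheno$year == year &
             pheno$regime == regime, ]
  if (!nrow(d)) stop("no observations for ", trait, " in ",
                     envCode(year, regime))
  reps_per_g <- table(d$variety)
  if (length(reps_per_g) < 2) stop("need >= 2 genotypes")
  if (max(reps_per_g) < 2)
    stop("need >= 2 replicates: variance components undefined")
  d$genotype <- factor(d$variety)
  d$repf <- factor(d$rep)
  fit <- stats::aov(value ~ genotype + repf, data = d)
  at <- stats::anova(fit)
  src <- c(genotype = "genotype", repf = "replicate", Residuals = "error")
  out <- data.frame(source = unname(src[rownames(at)]),
                    df = at$Df, mean_sq = at$`Mean Sq`,
                    f_value = at$`F value`, p_value = at$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  # F and p for genotype/replicate against the residual mean square
  attr(out, "r") <- length(reps_per_g) / sum(1 / as.numeric(reps_per_g))
  attr(out, "grand_mean") <- mean(d$value)
  out
}

#' Combined ANOVA across years and watering regimes
#'
#' Fits `value ~ G * Y * E` (+ replicates within year-by-environment) by
#' least squares and forms F-tests treating year as random and genotype
#' and watering regime as fixed: fixed main effects are tested against
#' their interaction with year (G against GxY, E against YxE, GxE against
#' GxYxE); year and all year interactions are tested against the residual.
#'
#' @param pheno long phenotype data.frame.
#' @param trait trait name.
#' @return data.frame with source, df, mean_sq, f_value, p_value,
#'   error_term.
#' @export
combinedAnova <- function(pheno, trait) {
  d <- pheno[pheno$trait == trait, ]
  if (length(unique(d$year)) < 2 || length(unique(d$regime)) < 2) {
    warning("combined ANOVA needs >= 2 years and both regimes; ",
            "falling back to per-environment analysis")
    yr <- unique(d$year)[1]; rg <- unique(d$regime)[1]
    return(anovaPerEnvironment(pheno, trait, yr, rg))
  }
  d$G <- factor(d$variety); d$Y <- factor(d$year); d$E <- factor(d$regime)
  d$repfac <- factor(d$rep)
  # replicates are blocks nested within year-by-regime cells
  fit <- stats::aov(value ~ G * Y * E + Y:E:repfac, data = d)
  at <- stats::anova(fit)
  ms <- stats::setNames(at$`Mean Sq`, rownames(at))
  df <- stats::setNames(at$Df, rownames(at))
  err_of <- c(G = "G:Y", Y = "Residuals", E = "Y:E",
              `G:Y` = "Residuals", `G:E` = "G:Y:E", `Y:E` = "Residuals",
              `G:Y:E` = "Residuals", `Y:E:repfac` = "Residuals")
  src <- intersect(names(err_of), rownames(at))
  fv <- pv <- stats::setNames(rep(NA_real_, length(src)), src)
  for (s in src) {
    e <- err_of[[s]]
    if (!e %in% names(ms) || is.na(ms[e])) next
    if (ms[e] > 0) {
      fv[s] <- ms[s] / ms[e]
      pv[s] <- stats::pf(fv[s], df[s], df[e], lower.tail = FALSE)
    } else if (ms[s] == 0) { fv[s] <- 0; pv[s] <- 1 }
  }
  data.frame(source = c(src, "error"),
             df = c(df[src], df["Residuals"]),
             mean_sq = c(ms[src], ms["Residuals"]),
             f_value = c(fv, NA), p_value = c(pv, NA),
             error_term = c(unname(err_of[src]), NA),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Variance components from a per-environment ANOVA table
#'
#' Genotypic variance from expected mean squares,
#' `sigma_g2 = (MSG - MSE) / r`; environmental variance `sigma_e2 = MSE`;
#' phenotypic variance is their sum.  A negative genotypic estimate is
#' clamped to zero and flagged.
#'
#' @param anova table from [anovaPerEnvironment()], or a list with
#'   `MSG`, `MSE`, `r`.
#' @return list with sigma_g2, sigma_e2, sigma_p2, and logical
#'   `clamped` (TRUE when MSE > MSG).
#' @export
varianceComponents <- function(anova) {
  if (is.data.frame(anova)) {
    msg <- anova$mean_sq[anova$source == "genotype"]
    mse <- anova$mean_sq[anova$source == "error"]
    r <- attr(anova, "r")
  } else { msg <- anova$MSG; mse <- anova$MSE; r <- anova$r }
  if (is.null(r) || r == 0) stop("replicate count r must be > 0")
  sg2 <- (msg - mse) / r
  clamped <- sg2 < 0
  if (clamped) sg2 <- 0
  list(sigma_g2 = sg2, sigma_e2 = mse, sigma_p2 = sg2 + mse,
       clamped = clamped)
}

#' Environmental, genotypic and phenotypic coefficients of variation
#'
#' `ECV = sqrt(MSE)/mean * 100`, `GCV = sigma_g/mean * 100`,
#' `PCV = sigma_p/mean * 100`; `GCV <= PCV` always holds.
#'
#' @param vc variance components from [varianceComponents()].
#' @param mean_ trait mean (> 0).
#' @param MSE error mean square; defaults to `vc$sigma_e2`.
#' @return list with ecv, gcv, pcv (percent).
#' @export
coefficientsOfVariation <- function(vc, mean_, MSE = vc$sigma_e2) {
  if (mean_ <= 0) stop("trait mean must be > 0")
  list(ecv = sqrt(MSE) / mean_ * 100,
       gcv = sqrt(vc$sigma_g2) / mean_ * 100,
       pcv = sqrt(vc$sigma_p2) / mean_ * 100)
}

#' Classify a coefficient of variation as high/moderate/low
#'
#' Above 20% is "high", 10-20% "moderate", below 10% "low".
#' @param cv coefficient of variation in percent.
#' @return character vector of class labels.
#' @export
cvClass <- function(cv) {
  ifelse(cv > 20, "high", ifelse(cv >= 10, "moderate", "low"))
}

#' Broad-sense heritability (percent)
#'
#' `h2 = sigma_g2 / sigma_p2 * 100`.  Undefined (NA with a flag) when the
#' phenotypic variance is zero.
#'
#' @param sigma_g2 genotypic variance.
#' @param sigma_p2 phenotypic variance.
#' @return list with `h2` (percent, or NA) and logical `undefined`.
#' @export
heritability <- function(sigma_g2, sigma_p2) {
  if (sigma_p2 == 0) return(list(h2 = NA_real_, undefined = TRUE))
  list(h2 = sigma_g2 / sigma_p2 * 100, undefined = FALSE)
}

#' Standardized selection intensity for truncation selection
#'
#' Mean of the selected upper tail of a standard normal when the top
#' `p` fraction is kept: `i = dnorm(qnorm(1 - p)) / p`.  For p = 0.10 this
#' is 1.755.
#'
#' @param p selected proportion (default 0.10).
#' @return selection intensity.
#' @export
selectionIntensity <- function(p = 0.10) {
  stopifnot(p > 0, p < 1)
  stats::dnorm(stats::qnorm(1 - p)) / p
}

#' Genetic advance under truncation selection
#'
#' `GA = k * h2 * sigma_p` (heritability as a fraction) and
#' `GAM = GA / mean * 100`.
#'
#' @param h2 broad-sense heritability in percent.
#' @param sigma_p phenotypic standard deviation (trait units).
#' @param mean_ trait mean (> 0).
#' @param k selection intensity; the default 1.76 corresponds to keeping
#'   the top 10% of varieties.
#' @return list with ga (trait units) and gam (percent).
#' @export
geneticAdvance <- function(h2, sigma_p, mean_, k = 1.76) {
  if (mean_ <= 0) stop("trait mean must be > 0")
  ga <- k * (h2 / 100) * sigma_p
  list(ga = ga, gam = ga / mean_ * 100)
}

#' Genetic-parameter table over all trait-by-environment cells
#'
#' One row per trait and environment with descriptive statistics, variance
#' components, coefficients of variation, broad-sense heritability and
#' genetic advance — the standard summary table of a replicated
#' multi-environment trial.
#'
#' @param pheno long phenotype data.frame.
#' @param k selection intensity.
#' @return data.frame with columns trait, env, year, regime, mean, sd, min,
#'   max, sigma_g2, sigma_e2, sigma_p2, ecv, gcv, pcv, h2, ga, gam, k,
#'   clamped.
#' @export
geneticParamsTable <- function(pheno, k = 1.76) {
  cells <- unique(pheno[, c("trait", "year", "regime")])
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    tr <- cells$trait[i]; yr <- cells$year[i]; rg <- cells$regime[i]
    d <- pheno[pheno$trait == tr & pheno$year == yr & pheno$regime == rg, ]
    at <- anovaPerEnvironment(pheno, tr, yr, rg)
    vc <- varianceComponents(at)
    m <- mean(d$value)
    cv <- coefficientsOfVariation(vc, m)
    h <- heritability(vc$sigma_g2, vc$sigma_p2)
    ga <- if (is.na(h$h2)) list(ga = NA_real_, gam = NA_real_)
          else geneticAdvance(h$h2, sqrt(vc$sigma_p2), m, k)
    rows[[i]] <- data.frame(trait = tr, env = envCode(yr, rg),
                            year = yr, regime = rg,
                            mean = m, sd = stats::sd(d$value),
                            min = min(d$value), max = max(d$value),
                            sigma_g2 = vc$sigma_g2, sigma_e2 = vc$sigma_e2,
                            sigma_p2 = vc$sigma_p2,
                            ecv = cv$ecv, gcv = cv$gcv, pcv = cv$pcv,
                            h2 = h$h2, ga = ga$ga, gam = ga$gam, k = k,
                            clamped = vc$clamped,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Percent reduction of a trait under drought stress
#'
#' `100 * (1 - mean(DS environment means) / mean(WW environment means))`,
#' averaging the per-environment means over years within each regime.
#'
#' @param params a table with columns trait, regime, mean (e.g. from
#'   [geneticParamsTable()]).
#' @param trait trait name.
#' @param stressed,control regime codes (defaults "DS" and "WW").
#' @return percent reduction (negative if the trait increased).
#' @export
percentReduction <- function(params, trait, stressed = "DS", control = "WW") {
  d <- params[params$trait == trait, ]
  mw <- mean(d$mean[d$regime == control])
  md <- mean(d$mean[d$regime == stressed])
  if (!is.finite(mw) || !is.finite(md))
    stop("trait ", trait, " must be present under both regimes")
  100 * (1 - md / mw)
}

#' Pairwise trait correlations on variety means within a regime
#'
#' Pearson correlation of per-variety trait means (averaged over years and
#' replicates) with two-sided t-test p-values.
#'
#' @param pheno long phenotype data.frame.
#' @param regime regime code to subset to.
#' @return list with matrices `r` and `p`; constant traits give NA entries
#'   (flagged in `constant`).
#' @export
traitCorrelations <- function(pheno, regime) {
  d <- pheno[pheno$regime == regime, ]
  m <- stats::aggregate(value ~ variety + trait, data = d, FUN = mean)
  wide <- stats::reshape(m, idvar = "variety", timevar = "trait",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^value\\.", "", colnames(mat))
  if (nrow(mat) < 3) stop("need >= 3 varieties")
  constant <- apply(mat, 2, function(x) stats::sd(x) == 0)
  k <- ncol(mat)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(colnames(mat), colnames(mat)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (constant[i] || constant[j]) next
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(mat[, i], mat[, j])
    r[i, j] <- unname(ct$estimate); p[i, j] <- ct$p.value
  }
  list(r = r, p = p, constant = constant)
}

#' Compare a trait between two variety groups
#'
#' Welch two-sample t-test on per-variety means (averaged over years,
#' replicates and, by default, both regimes).
#'
#' @param pheno long phenotype data.frame.
#' @param high_ids,low_ids variety ids of the two groups.
#' @param trait trait name.
#' @param regime optional regime code to subset to.
#' @return list with group means, t statistic, df and p-value.
#' @export
contrastGroups <- function(pheno, high_ids, low_ids, trait, regime = NULL) {
  d <- pheno[pheno$trait == trait, ]
  if (!is.null(regime)) d <- d[d$regime == regime, ]
  m <- stats::aggregate(value ~ variety, data = d, FUN = mean)
  x <- m$value[m$variety %in% high_ids]
  y <- m$value[m$variety %in% low_ids]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 varieties")
  tt <- stats::t.test(x, y)
  list(mean_high = mean(x), mean_low = mean(y),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}
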