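#' Single-marker association by fixed-effect least squares (GLM)
#'
#' Ordinary least squares of a per-variety phenotype on SNP dosage plus an
#' intercept and optional structure covariates (principal-component scores
#' or a user-supplied Q matrix).  Two-sided t-test on the dosage
#' coefficient; samples with a missing genotype are dropped per SNP.  The
#' per-SNP R-squared is the nested-model sum-of-squares ratio
#' `(SSE_reduced - SSE_full) / SST` on the samples used.
#'
#' @param geno [GenotypeData-class].
#' @param y named numeric vector of per-variety phenotype means (names are
#'   sample ids).
#' @param covariates optional matrix of covariates (rows = samples, in
#'   `y`'s order after matching by name when rownames are present).
#' @param trait,env labels copied into the result.
#' @param model model tag recorded in the result (default "GLM+PC" when
#'   covariates are given, "GLM" otherwise).
#' @return data.frame: snp, chrom, pos, trait, env, model, effect, se, p,
#'   r2, n, untestable.
#' @export
glmAssoc <- function(geno, y, covariates = NULL, trait = "trait",
                     env = "env", model = NULL) {
  d <- dosage(geno)
  ids <- intersect(rownames(d), names(y))
  if (!length(ids)) stop("no samples shared between genotypes and phenotype")
  d <- d[ids, , drop = FALSE]
  yv <- y[ids]
  X0 <- matrix(1, length(yv), 1, dimnames = list(NULL, "intercept"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates)))
      covariates <- covariates[ids, , drop = FALSE]
    X0 <- cbind(1, covariates)
  }
  if (is.null(model)) model <- if (is.null(covariates)) "GLM" else "GLM+PC"
  m <- ncol(d)
  eff <- se <- pv <- r2 <- rep(NA_real_, m)
  nn <- integer(m); bad <- logical(m)
  for (j in seq_len(m)) {
    g <- d[, j]
    ok <- !is.na(g) & !is.na(yv)
    n <- sum(ok); nn[j] <- n
    if (n < ncol(X0) + 2 || stats::sd(g[ok]) == 0) { bad[j] <- TRUE; next }
    X <- cbind(X0[ok, , drop = FALSE], g = g[ok])
    yy <- yv[ok]
    f1 <- stats::lm.fit(X, yy)
    if (f1$rank < ncol(X)) { bad[j] <- TRUE; next }
    rss1 <- sum(f1$residuals^2)
    df1 <- n - ncol(X)
    XtXi <- chol2inv(chol(crossprod(X)))
    s2 <- rss1 / df1
    eff[j] <- f1$coefficients["g"]
    se[j] <- sqrt(s2 * XtXi[ncol(X), ncol(X)])
    tv <- eff[j] / se[j]
    pv[j] <- 2 * stats::pt(abs(tv), df1, lower.tail = FALSE)
    f0 <- stats::lm.fit(X0[ok, , drop = FALSE], yy)
    sst <- sum((yy - mean(yy))^2)
    r2[j] <- if (sst > 0) (sum(f0$residuals^2) - rss1) / sst else NA_real_
  }
  si <- snpInfo(geno)
  data.frame(snp = si$id, chrom = si$chrom, pos = si$pos,
             trait = trait, env = env, model = model,
             effect = eff, se = se, p = pv, r2 = r2, n = nn,
             untestable = bad, stringsAsFactors = FALSE)
}

# REML estimate of the variance ratio delta = sigma_e^2 / sigma_u^2 for
# y = X b + u + e, u ~ N(0, sigma_u^2 K), via the spectral decomposition
# of K (eigenvalues lam, rotation U).
remlDelta <- function(ystar, Xstar, lam, n) {
  q <- ncol(Xstar)
  ldXX <- determinant(crossprod(Xstar), logarithm = TRUE)$modulus
  negll <- function(ldelta) {
    delta <- exp(ldelta)
    w <- 1 / (lam + delta)
    XtWX <- crossprod(Xstar * w, Xstar)
    ch <- try(chol(XtWX), silent = TRUE)
    if (inherits(ch, "try-error")) return(1e10)
    beta <- backsolve(ch, forwardsolve(t(ch), crossprod(Xstar * w, ystar)))
    r <- ystar - Xstar %*% beta
    rwr <- sum(r^2 * w)
    s2 <- rwr / (n - q)
    0.5 * ((n - q) * log(s2) + sum(log(lam + delta)) +
           2 * sum(log(diag(ch))) - ldXX + (n - q))
  }
  opt <- stats::optimize(negll, c(-10, 10))
  exp(opt$minimum)
}

#' Single-marker association under the mixed linear model (P3D/EMMAX)
#'
#' `y = X beta + g a + u + e` with `u ~ N(0, sigma_u^2 K)`.  The variance
#' ratio is estimated once by REML on the null (no-marker) model through
#' the spectral decomposition of K and then held fixed for every SNP
#' (the P3D/EMMAX approximation); each marker is tested by a Wald t-test
#' under generalized least squares in the rotated space.  The per-SNP
#' R-squared is a likelihood-ratio analog, `1 - RSS_full / RSS_reduced`
#' on the whitened data.  Missing dosages are mean-imputed (P3D keeps the
#' sample set fixed across SNPs).
#'
#' @inheritParams glmAssoc
#' @param K kinship matrix from [kinship()]; if not positive definite it is
#'   ridged by a small jitter with a warning.
#' @return data.frame as in [glmAssoc()] with model tag "MLM+K" or
#'   "MLM+K+PC"; attribute `delta` records the fitted variance ratio.
#' @export
mlmAssoc <- function(geno, y, K, covariates = NULL, trait = "trait",
                     env = "env", model = NULL) {
  d <- dosage(geno)
  ids <- intersect(rownames(d), names(y))
  d <- d[ids, , drop = FALSE]
  yv <- y[ids]
  K <- K[ids, ids]
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    warning("K is not positive semi-definite; adding ridge")
    K <- K + diag(abs(min(ev$values)) + 1e-6, nrow(K))
    ev <- eigen(K, symmetric = TRUE)
  }
  lam <- pmax(ev$values, 1e-10)
  U <- ev$vectors
  X0 <- cbind(intercept = rep(1, length(yv)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates)))
      covariates <- covariates[ids, , drop = FALSE]
    X0 <- cbind(1, covariates)
  }
  if (is.null(model)) model <- if (is.null(covariates)) "MLM+K" else "MLM+K+PC"
  n <- length(yv)
  ystar <- crossprod(U, yv)
  X0s <- crossprod(U, X0)
  delta <- remlDelta(ystar, X0s, lam, n)
  w <- 1 / (lam + delta)
  sw <- sqrt(w)
  # whitened null design
  yw <- ystar * sw
  X0w <- X0s * sw
  f0 <- stats::lm.fit(X0w, yw)
  rss0 <- sum(f0$residuals^2)

  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  Gs <- crossprod(U, d) * sw          # whitened dosages, n x m
  m <- ncol(d)
  eff <- se <- pv <- r2 <- rep(NA_real_, m)
  bad <- apply(d, 2, stats::sd) == 0
  q <- ncol(X0w)
  df1 <- n - q - 1
  for (j in seq_len(m)) {
    if (bad[j]) next
    X <- cbind(X0w, g = Gs[, j])
    fit <- stats::lm.fit(X, yw)
    if (fit$rank < ncol(X)) { bad[j] <- TRUE; next }
    rss1 <- sum(fit$residuals^2)
    XtXi <- chol2inv(chol(crossprod(X)))
    s2 <- rss1 / df1
    eff[j] <- fit$coefficients["g"]
    se[j] <- sqrt(s2 * XtXi[q + 1, q + 1])
    tv <- eff[j] / se[j]
    pv[j] <- 2 * stats::pt(abs(tv), df1, lower.tail = FALSE)
    r2[j] <- 1 - rss1 / rss0
  }
  si <- snpInfo(geno)
  out <- data.frame(snp = si$id, chrom = si$chrom, pos = si$pos,
                    trait = trait, env = env, model = model,
                    effect = eff, se = se, p = pv, r2 = r2,
                    n = n, untestable = bad, stringsAsFactors = FALSE)
  attr(out, "delta") <- delta
  out
}

#' Phenotypic variance explained by one marker
#'
#' Nested-model computation `(SSE_reduced - SSE_full) / SST`, where the
#' reduced model holds the intercept and covariates and the full model
#' adds the marker, on identical samples.
#'
#' @param y phenotype vector.
#' @param g dosage vector.
#' @param covariates optional covariate matrix.
#' @return proportion of phenotypic variance (NA when SST is 0).
#' @export
snpR2 <- function(y, g, covariates = NULL) {
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  X0 <- if (is.null(covariates)) matrix(1, length(y), 1)
        else cbind(1, as.matrix(covariates)[ok, , drop = FALSE])
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  f0 <- stats::lm.fit(X0, y)
  f1 <- stats::lm.fit(cbind(X0, g), y)
  (sum(f0$residuals^2) - sum(f1$residuals^2)) / sst
}

#' Filter association results at a significance threshold
#'
#' Strict inequality `p < alpha`; duplicate (snp, trait, env) rows are
#' removed.
#'
#' @param results association data.frame with columns snp, trait, env, p.
#' @param alpha significance threshold (default 1e-4).
#' @return filtered data.frame.
#' @export
significantSnps <- function(results, alpha = 1e-4) {
  r <- results[!is.na(results$p) & results$p < alpha, , drop = FALSE]
  r <- r[!duplicated(r[, c("snp", "trait", "env")]), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' SNPs significant for the same trait in two or more environments
#'
#' @param results association results over several environments.
#' @param alpha significance threshold.
#' @return wide data.frame: snp, chrom, pos, trait, one p-value column per
#'   environment ("ns" where not significant), n_envs.
#' @export
stableSnps <- function(results, alpha = 1e-4) {
  sig <- significantSnps(results, alpha)
  envs <- sort(unique(results$env))
  if (length(envs) < 2) stop("need results from >= 2 environments")
  key <- unique(sig[, c("snp", "chrom", "pos", "trait")])
  cnt <- table(paste(sig$snp, sig$trait))
  keep <- cnt[paste(key$snp, key$trait)] >= 2
  key <- key[keep, , drop = FALSE]
  if (!nrow(key)) {
    out <- key
    for (e in envs) out[[e]] <- character(0)
    out$n_envs <- integer(0)
    return(out)
  }
  for (e in envs) {
    pe <- sig$p[match(paste(key$snp, key$trait, e),
                      paste(sig$snp, sig$trait, sig$env))]
    key[[e]] <- ifelse(is.na(pe), "ns", formatC(pe, format = "e", digits = 2))
  }
  key$n_envs <- rowSums(key[, envs, drop = FALSE] != "ns")
  rownames(key) <- NULL
  key
}

#' SNPs significant for two or more traits (pleiotropy screen)
#'
#' @param results association results over several traits.
#' @param alpha significance threshold.
#' @return data.frame: snp, chrom, pos, traits (comma-separated), n_traits.
#' @export
pleiotropicSnps <- function(results, alpha = 1e-4) {
  if (length(unique(results$trait)) < 2) stop("need results from >= 2 traits")
  sig <- significantSnps(results, alpha)
  byt <- unique(sig[, c("snp", "chrom", "pos", "trait")])
  spl <- split(byt$trait, byt$snp)
  multi <- names(spl)[vapply(spl, function(z) length(unique(z)) >= 2, TRUE)]
  if (!length(multi))
    return(data.frame(snp = character(), chrom = character(),
                      pos = integer(), traits = character(),
                      n_traits = integer(), stringsAsFactors = FALSE))
  idx <- match(multi, byt$snp)
  data.frame(snp = multi, chrom = byt$chrom[idx], pos = byt$pos[idx],
             traits = vapply(spl[multi],
                             function(z) paste(sort(unique(z)), collapse = ","),
                             character(1)),
             n_traits = vapply(spl[multi],
                               function(z) length(unique(z)), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# compact-letter display from a logical "significantly different" matrix
letterGroups <- function(diffmat) {
  lv <- rownames(diffmat)
  groups <- list()
  for (g in lv) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (all(!diffmat[g, groups[[k]]])) {
        groups[[k]] <- c(groups[[k]], g); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- g
  }
  letters_out <- stats::setNames(rep("", length(lv)), lv)
  for (k in seq_along(groups))
    for (g in groups[[k]])
      letters_out[g] <- paste0(letters_out[g], letters[k])
  letters_out
}

#' Allele-effect analysis at one SNP
#'
#' Varieties are grouped by genotype class (e.g. AA/AG/GG from dosage and
#' the ref/alt alleles); class trait means are compared by Tukey's honest
#' significant difference test at family level 0.05, and classes receive
#' compact letter groupings.  Classes with fewer than 2 members are
#' excluded from testing but reported.
#'
#' @param geno [GenotypeData-class].
#' @param y named per-variety phenotype vector.
#' @param snp SNP id.
#' @return list with `classes` data.frame (class, n, mean, letter, tested)
#'   and `tukey` (the pairwise comparison table).
#' @export
alleleEffects <- function(geno, y, snp) {
  j <- match(snp, snpInfo(geno)$id)
  if (is.na(j)) stop("unknown SNP: ", snp)
  si <- snpInfo(geno)[j, ]
  g <- dosage(geno)[, j]
  ids <- intersect(names(y)[!is.na(y)], rownames(dosage(geno))[!is.na(g)])
  g <- g[ids]; yv <- y[ids]
  lab <- c(paste0(si$ref, si$ref), paste0(si$ref, si$alt),
           paste0(si$alt, si$alt))[g + 1]
  cls <- data.frame(class = lab, y = yv, stringsAsFactors = FALSE)
  tabn <- table(cls$class)
  testable <- names(tabn)[tabn >= 2]
  if (length(testable) < 2) stop("need >= 2 genotype classes with >= 2 members")
  sub <- cls[cls$class %in% testable, ]
  sub$class <- factor(sub$class)
  fit <- stats::aov(y ~ class, data = sub)
  tk <- stats::TukeyHSD(fit, conf.level = 0.95)$class
  ln <- levels(sub$class)
  diffmat <- matrix(FALSE, length(ln), length(ln),
                    dimnames = list(ln, ln))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    sig <- tk[r, "p adj"] < 0.05
    diffmat[pair[1], pair[2]] <- diffmat[pair[2], pair[1]] <- sig
  }
  lett <- letterGroups(diffmat)
  means <- tapply(cls$y, cls$class, mean)
  out <- data.frame(class = names(tabn), n = as.integer(tabn),
                    mean = as.numeric(means[names(tabn)]),
                    letter = ifelse(names(tabn) %in% ln,
                                    lett[names(tabn)], ""),
                    tested = names(tabn) %in% ln,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(classes = out, tukey = as.data.frame(tk))
}

#' Genomic inflation factor and QQ/Manhattan plot tables
#'
#' `lambda = median(chi^2) / 0.4549` where the chi-squared values are
#' `qchisq(1 - p, df = 1)`.  Also returns the sorted observed vs expected
#' -log10 p table for a QQ plot and a per-SNP table with cumulative genome
#' coordinates (chromosomes ordered A01..A10, C01..C09) for a Manhattan
#' plot.
#'
#' @param results association data.frame with snp, chrom, pos, p.
#' @param min_tests minimum number of tests required.
#' @return list with `lambda`, `qq` (expected, observed), `manhattan`
#'   (snp, chrom, pos, cum_pos, logp).
#' @export
inflationAndPlots <- function(results, min_tests = 100) {
  r <- results[!is.na(results$p), ]
  if (nrow(r) < min_tests) stop("need >= ", min_tests, " tests")
  chisq <- stats::qchisq(r$p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1, lower.tail = FALSE)
  m <- nrow(r)
  qq <- data.frame(expected = sort(-log10(stats::ppoints(m))),
                   observed = sort(-log10(r$p)))
  chr_order <- c(sprintf("A%02d", 1:10), sprintf("C%02d", 1:9))
  chrs <- unique(r$chrom)
  chrs <- c(intersect(chr_order, chrs), setdiff(chrs, chr_order))
  offs <- 0; man <- list()
  for (ch in chrs) {
    d <- r[r$chrom == ch, ]
    d <- d[order(d$pos), ]
    man[[ch]] <- data.frame(snp = d$snp, chrom = ch, pos = d$pos,
                            cum_pos = offs + d$pos, logp = -log10(d$p),
                            stringsAsFactors = FALSE)
    offs <- offs + max(d$pos)
  }
  list(lambda = lambda, qq = qq, manhattan = do.call(rbind, man))
}
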