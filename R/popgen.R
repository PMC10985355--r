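#' SNP quality control
#'
#' Filters applied in fixed order: call rate, biallelic, minor allele
#' frequency, missingness; all boundaries inclusive (a SNP with MAF exactly
#' `min_maf` is retained).  Per-stage removal counts are reported.
#'
#' @param geno [GenotypeData-class].
#' @param min_call_rate minimum fraction of non-missing calls.
#' @param min_maf minimum minor allele frequency.
#' @param max_missing maximum fraction of missing calls.
#' @param biallelic_only drop SNPs whose ref/alt are not single distinct
#'   nucleotides.
#' @return list with `geno` (filtered; possibly 0 SNPs, with a warning) and
#'   `report` data.frame (stage, removed, remaining).
#' @export
filterSnps <- function(geno, min_call_rate = 0.90, min_maf = 0.05,
                       max_missing = 0.10, biallelic_only = TRUE) {
  if (nSnps(geno) == 0) stop("empty genotype matrix")
  stages <- c("call_rate", "biallelic", "maf", "missingness")
  removed <- stats::setNames(integer(4), stages)
  keep <- callRates(geno) >= min_call_rate
  removed["call_rate"] <- sum(!keep)
  g <- geno[, which(keep)]
  if (biallelic_only && nSnps(g) > 0) {
    si <- snpInfo(g)
    ok <- nchar(si$ref) == 1 & nchar(si$alt) == 1 & si$ref != si$alt &
      si$ref %in% c("A", "C", "G", "T") & si$alt %in% c("A", "C", "G", "T")
    ok[is.na(si$ref) | is.na(si$alt)] <- TRUE   # dosage-TSV dialect carries
    removed["biallelic"] <- sum(!ok)            # no allele labels
    g <- g[, which(ok)]
  }
  if (nSnps(g) > 0) {
    ok <- mafs(g) >= min_maf
    ok[is.na(ok)] <- FALSE
    removed["maf"] <- sum(!ok)
    g <- g[, which(ok)]
  }
  if (nSnps(g) > 0) {
    ok <- (1 - callRates(g)) <= max_missing
    removed["missingness"] <- sum(!ok)
    g <- g[, which(ok)]
  }
  if (nSnps(g) == 0) warning("all SNPs removed by QC")
  report <- data.frame(stage = stages, removed = unname(removed),
                       remaining = nSnps(geno) - cumsum(unname(removed)),
                       stringsAsFactors = FALSE)
  list(geno = g, report = report)
}

#' Polymorphism information content per SNP
#'
#' For a biallelic locus with allele frequencies p and q (from non-missing
#' calls): `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`; maximum 0.375 at p = 0.5,
#' 0 for a monomorphic locus.
#'
#' @param geno [GenotypeData-class].
#' @return named numeric vector, one value per SNP.
#' @export
pic <- function(geno) {
  p <- colMeans(dosage(geno), na.rm = TRUE) / 2
  q <- 1 - p
  stats::setNames(1 - (p^2 + q^2) - 2 * p^2 * q^2, snpInfo(geno)$id)
}

# EM estimate of haplotype frequencies for two unphased biallelic SNPs.
# g1, g2: dosage vectors (0/1/2), complete cases only.
# Returns c(pAB, pAb, paB, pab) for alleles (A,a) at locus 1, (B,b) at 2,
# where A and B are the "alt" (dosage-counted) alleles.
emHaplotypeFreqs <- function(g1, g2, tol = 1e-10, max_iter = 200) {
  n <- length(g1)
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  # start at linkage equilibrium
  f <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  dh <- g1 == 1 & g2 == 1            # double heterozygotes are ambiguous
  n_dh <- sum(dh)
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  # unambiguous haplotype counts: each individual contributes 2 haplotypes,
  # and outside the double heterozygote the phase is unique
  base <- c(AB = 0, Ab = 0, aB = 0, ab = 0)
  for (i in 0:2) for (j in 0:2) {
    k <- tab[i + 1, j + 1]
    if (k == 0 || (i == 1 && j == 1)) next
    nA <- i; nB <- j
    ab2 <- c(AB = min(nA, nB), Ab = 0, aB = 0, ab = 0)
    ab2["Ab"] <- nA - ab2[["AB"]]
    ab2["aB"] <- nB - ab2[["AB"]]
    ab2["ab"] <- 2 - ab2[["AB"]] - ab2[["Ab"]] - ab2[["aB"]]
    base <- base + ab2 * as.numeric(k)
  }
  for (it in seq_len(max_iter)) {
    # E-step: split double heterozygotes between AB/ab and Ab/aB phases
    denom <- f[1] * f[4] + f[2] * f[3]
    w <- if (denom > 0) f[1] * f[4] / denom else 0.5
    cnt <- base + n_dh * c(w, 1 - w, 1 - w, w)
    fn <- cnt / (2 * n)
    if (max(abs(fn - f)) < tol) { f <- fn; break }
    f <- fn
  }
  stats::setNames(f, c("AB", "Ab", "aB", "ab"))
}

# D, D', r from haplotype frequencies
ldFromHapFreqs <- function(f) {
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (dmax > 0) abs(D) / dmax else NA_real_
  denom <- pA * (1 - pA) * pB * (1 - pB)
  r <- if (denom > 0) D / sqrt(denom) else NA_real_
  c(D = D, dprime = unname(dprime), r = unname(r))
}

#' Pairwise linkage disequilibrium
#'
#' r-squared is the squared Pearson correlation of dosages over samples
#' with both calls present; D-prime is derived from EM-estimated haplotype
#' frequencies on the unphased diploid pair, normalized by its maximum.
#'
#' @param geno [GenotypeData-class] with position-sorted SNPs.
#' @param max_distance only pairs at most this many bp apart (default Inf).
#' @param within_chrom restrict to within-chromosome pairs.
#' @param stats which statistics to compute; dropping "dprime" skips the
#'   (slower) EM step.
#' @param min_obs pairs with fewer complete observations are skipped.
#' @return data.frame snp_a, snp_b, chrom, distance, r2 (and d_prime);
#'   attribute `n_skipped` counts pairs skipped for insufficient data.
#' @export
pairwiseLD <- function(geno, max_distance = Inf, within_chrom = TRUE,
                       stats = c("r2", "dprime"), min_obs = 5) {
  si <- snpInfo(geno)
  d <- dosage(geno)
  chroms <- if (within_chrom) unique(si$chrom) else "all"
  res <- list(); skipped <- 0L
  for (ch in chroms) {
    idx <- if (within_chrom) which(si$chrom == ch) else seq_len(ncol(d))
    if (length(idx) < 2) next
    pos <- si$pos[idx]
    sub <- d[, idx, drop = FALSE]
    pr <- list()
    for (i in seq_len(length(idx) - 1)) {
      j <- which(pos > pos[i] & pos - pos[i] <= max_distance)
      j <- j[j > i]
      if (length(j)) pr[[length(pr) + 1L]] <- cbind(i, j)
    }
    if (!length(pr)) next
    pr <- do.call(rbind, pr)
    r2 <- dp <- rep(NA_real_, nrow(pr))
    ncomp <- crossprod(!is.na(sub)) # complete observations per pair
    n_ok <- ncomp[pr] >= min_obs
    skipped <- skipped + sum(!n_ok)
    if ("r2" %in% stats) {
      cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
      r2[n_ok] <- cm[pr[n_ok, , drop = FALSE]]^2
    }
    if ("dprime" %in% stats) {
      for (k in which(n_ok)) {
        g1 <- sub[, pr[k, 1]]; g2 <- sub[, pr[k, 2]]
        cc <- !is.na(g1) & !is.na(g2)
        g1 <- g1[cc]; g2 <- g2[cc]
        if (stats::sd(g1) == 0 || stats::sd(g2) == 0) next
        dp[k] <- ldFromHapFreqs(emHaplotypeFreqs(g1, g2))["dprime"]
      }
    }
    keep <- !(is.na(r2) & is.na(dp))
    out <- data.frame(snp_a = si$id[idx[pr[, 1]]],
                      snp_b = si$id[idx[pr[, 2]]],
                      chrom = if (within_chrom) ch else si$chrom[idx[pr[, 1]]],
                      distance = pos[pr[, 2]] - pos[pr[, 1]],
                      r2 = r2, stringsAsFactors = FALSE)
    if ("dprime" %in% stats) out$d_prime <- dp
    res[[length(res) + 1L]] <- out[keep, , drop = FALSE]
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(snp_a = character(), snp_b = character(), chrom = character(),
               distance = numeric(), r2 = numeric())
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

# Hill-Weir expectation of r^2 at recombination-scaled distance C = rho * d
# for a sample of n sequences
hillWeirExpectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' LD decay curve and decay distance
#'
#' Bins mean r-squared in log-spaced distance bins and fits the Hill-Weir
#' expected-r-squared curve by least squares over the pairs.  The decay
#' distance is where the fitted curve falls to half its value at distance
#' zero.  If the fit fails, a binned half-of-maximum fallback is used and
#' flagged; if the curve never reaches half its intercept within the
#' observed range, the distance is reported right-censored (NA with
#' `censored = TRUE`).
#'
#' @param ld pair table from [pairwiseLD()] (needs >= 100 pairs).
#' @param n number of sampled chromosomes entering the Hill-Weir
#'   small-sample term (2 x samples for unphased diploids).
#' @param n_bins number of log-spaced distance bins for the summary curve.
#' @return list with `decay_distance` (bp), `censored`, `method`
#'   ("hill-weir" or "binned-halfmax"), `rho` (fitted per-bp rate),
#'   `curve` (binned means), `intercept`.
#' @export
ldDecay <- function(ld, n, n_bins = 30) {
  ld <- ld[!is.na(ld$r2) & ld$distance > 0, ]
  if (nrow(ld) < 100) stop("need >= 100 LD pairs")
  brks <- unique(exp(seq(log(max(1, min(ld$distance))),
                         log(max(ld$distance)), length.out = n_bins + 1)))
  bin <- cut(ld$distance, brks, include.lowest = TRUE)
  curve <- data.frame(
    distance = tapply(ld$distance, bin, stats::median),
    mean_r2 = tapply(ld$r2, bin, mean),
    n_pairs = as.vector(table(bin)))
  curve <- curve[!is.na(curve$mean_r2), ]

  # a curve with no decay signal cannot localize a half-decay point:
  # compare short-range and long-range mean r2 before fitting
  qd <- stats::quantile(ld$distance, c(0.1, 0.9))
  short_m <- mean(ld$r2[ld$distance <= qd[1]])
  long_m <- mean(ld$r2[ld$distance >= qd[2]])
  if (short_m - long_m < 0.02) {
    return(list(decay_distance = NA_real_, censored = TRUE,
                method = "flat", rho = NA_real_, curve = curve,
                intercept = short_m))
  }

  obj <- function(lrho)
    mean((ld$r2 - hillWeirExpectation(exp(lrho) * ld$distance, n))^2)
  fit <- try(stats::optimize(obj, c(log(1e-12), log(1)))$minimum,
             silent = TRUE)
  max_d <- max(ld$distance)
  if (!inherits(fit, "try-error")) {
    rho <- exp(fit)
    icpt <- hillWeirExpectation(0, n)
    half <- icpt / 2
    f <- function(dd) hillWeirExpectation(rho * dd, n) - half
    if (f(max_d) > 0) {
      return(list(decay_distance = NA_real_, censored = TRUE,
                  method = "hill-weir", rho = rho, curve = curve,
                  intercept = icpt))
    }
    dd <- stats::uniroot(f, c(1e-3, max_d))$root
    return(list(decay_distance = dd, censored = FALSE, method = "hill-weir",
                rho = rho, curve = curve, intercept = icpt))
  }
  # fallback: first binned distance at which mean r2 <= half the max bin
  half <- max(curve$mean_r2) / 2
  below <- which(curve$mean_r2 <= half)
  if (!length(below))
    return(list(decay_distance = NA_real_, censored = TRUE,
                method = "binned-halfmax", rho = NA_real_, curve = curve,
                intercept = max(curve$mean_r2)))
  list(decay_distance = curve$distance[min(below)], censored = FALSE,
       method = "binned-halfmax", rho = NA_real_, curve = curve,
       intercept = max(curve$mean_r2))
}

#' VanRaden centered genomic relationship matrix
#'
#' `G = Z Z' / (2 sum p(1-p))` with Z the dosage matrix centered at twice
#' the allele frequency.  Missing dosages are mean-imputed for this
#' computation only.
#'
#' @param geno [GenotypeData-class] (filtered).
#' @return symmetric n x n matrix.
#' @export
kinship <- function(geno) {
  d <- dosage(geno)
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs: kinship undefined")
  d <- d[, poly, drop = FALSE]; p <- p[poly]
  if (anyNA(d)) {
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- (2 * p)[idx[, 2]]
  }
  Z <- sweep(d, 2, 2 * p)
  G <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(G) <- list(rownames(d), rownames(d))
  G
}

#' Principal components of the genotype matrix
#'
#' Eigendecomposition of the covariance of centered dosages (missing
#' values mean-imputed).  Sign convention: within each component the
#' largest-magnitude SNP loading is made positive, so results are
#' deterministic.
#'
#' @param geno [GenotypeData-class] (filtered).
#' @param n_components number of PCs to return (truncated to the available
#'   rank, with a warning).
#' @return list with `scores` (samples x PCs), `explained` (fraction of
#'   variance per returned PC), `loadings`.
#' @export
pcaGenotypes <- function(geno, n_components = 5) {
  d <- dosage(geno)
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2]]
  }
  keep <- apply(d, 2, stats::sd) > 0
  pr <- stats::prcomp(d[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  rank <- sum(pr$sdev > 1e-10)
  if (n_components > rank) {
    warning("n_components truncated to rank ", rank)
    n_components <- rank
  }
  rot <- pr$rotation[, seq_len(n_components), drop = FALSE]
  sc <- pr$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(rot))) {
    s <- sign(rot[which.max(abs(rot[, j])), j])
    if (s < 0) { rot[, j] <- -rot[, j]; sc[, j] <- -sc[, j] }
  }
  list(scores = sc, explained = pr$sdev[seq_len(n_components)]^2 /
         sum(pr$sdev^2), loadings = rot)
}

# Likelihood-based confidence interval for |D'| of one SNP pair
# (profile over a grid with allele frequencies fixed at their MLEs),
# following the Haploview confidence-interval approach.
dprimeCI <- function(g1, g2, level = 0.90, grid = seq(0, 1, by = 0.01)) {
  pA <- mean(g1) / 2; pB <- mean(g2) / 2
  f0 <- emHaplotypeFreqs(g1, g2)
  D0 <- unname(f0["AB"] - pA * pB)
  sgn <- if (D0 >= 0) 1 else -1
  dmax <- if (sgn > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(c(low = NA_real_, high = NA_real_))
  tab <- table(factor(g1, 0:2), factor(g2, 0:2))
  ll <- vapply(grid, function(dp) {
    D <- sgn * dp * dmax
    f <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
           aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
    if (any(f < -1e-12)) return(-Inf)
    f <- pmax(f, 1e-12)
    s <- 0
    for (i in 0:2) for (j in 0:2) {
      k <- tab[i + 1, j + 1]
      if (k == 0) next
      # genotype probability summed over compatible haplotype pairs
      pr <- genoPairProb(f, i, j)
      s <- s + k * log(max(pr, 1e-300))
    }
    s
  }, numeric(1))
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  cw <- cumsum(w)
  alpha <- (1 - level) / 2
  c(low = grid[which(cw >= alpha)[1]],
    high = grid[which(cw >= 1 - alpha)[1]])
}

# probability of unphased two-locus genotype (i alt alleles at 1, j at 2)
# under HWE given haplotype frequencies f = (AB, Ab, aB, ab)
genoPairProb <- function(f, i, j) {
  haps <- rbind(AB = c(1, 1), Ab = c(1, 0), aB = c(0, 1), ab = c(0, 0))
  p <- 0
  for (a in 1:4) for (b in 1:4) {
    if (haps[a, 1] + haps[b, 1] == i && haps[a, 2] + haps[b, 2] == j)
      p <- p + f[a] * f[b]
  }
  unname(p)
}

#' Haplotype blocks by the confidence-interval (Gabriel) rule
#'
#' For each SNP pair in the region a likelihood-based 90% confidence
#' interval on |D'| is computed from unphased EM estimates.  A pair is in
#' "strong LD" when the CI upper bound is >= 0.98 and the lower bound
#' >= 0.70; it shows "strong recombination" when the upper bound is
#' < 0.90; other pairs are uninformative.  A candidate span is accepted as
#' a block when at least 95% of its informative pairs are in strong LD
#' (and its end pair is informative-strong).  Candidates are taken
#' greedily, longest (bp span) first, without overlap.
#'
#' @param geno [GenotypeData-class].
#' @param chrom chromosome to scan (required if `geno` has several).
#' @param from,to optional bp bounds of the region.
#' @param max_span_bp candidate spans wider than this are not considered.
#' @param min_obs minimum complete observations per pair.
#' @return data.frame of blocks: chrom, start, end, n_snps, snps
#'   (comma-separated ids); zero rows when fewer than 2 SNPs are in the
#'   region.
#' @export
haplotypeBlocks <- function(geno, chrom = NULL, from = -Inf, to = Inf,
                            max_span_bp = 500000, min_obs = 5) {
  si <- snpInfo(geno)
  if (is.null(chrom)) {
    if (length(unique(si$chrom)) > 1)
      stop("specify chrom: several chromosomes present")
    chrom <- si$chrom[1]
  }
  idx <- which(si$chrom == chrom & si$pos >= from & si$pos <= to)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      snps = character(), stringsAsFactors = FALSE)
  if (length(idx) < 2) return(empty)
  idx <- idx[order(si$pos[idx])]
  pos <- si$pos[idx]
  m <- length(idx)
  d <- dosage(geno)[, idx, drop = FALSE]
  # pair status: 1 strong LD, -1 strong recombination, 0 uninformative
  status <- matrix(0L, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (pos[j] - pos[i] > max_span_bp) break
    g1 <- d[, i]; g2 <- d[, j]
    cc <- !is.na(g1) & !is.na(g2)
    if (sum(cc) < min_obs) next
    if (stats::sd(g1[cc]) == 0 || stats::sd(g2[cc]) == 0) next
    ci <- dprimeCI(g1[cc], g2[cc])
    if (anyNA(ci)) next
    if (ci["high"] >= 0.98 && ci["low"] >= 0.70) status[i, j] <- 1L
    else if (ci["high"] < 0.90) status[i, j] <- -1L
  }
  cand <- list()
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (pos[j] - pos[i] > max_span_bp) break
    if (status[i, j] != 1L) next
    sub <- status[i:j, i:j]
    inf <- sum(sub != 0L); strong <- sum(sub == 1L)
    if (inf > 0 && strong / inf >= 0.95)
      cand[[length(cand) + 1L]] <- c(i = i, j = j, span = pos[j] - pos[i])
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "span"]), , drop = FALSE]
  used <- rep(FALSE, m)
  blocks <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, "i"]; j <- cand[k, "j"]
    if (any(used[i:j])) next
    used[i:j] <- TRUE
    blocks[[length(blocks) + 1L]] <- data.frame(
      chrom = chrom, start = pos[i], end = pos[j], n_snps = j - i + 1L,
      snps = paste(si$id[idx[i:j]], collapse = ","),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  out[order(out$start), , drop = FALSE]
}
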