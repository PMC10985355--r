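test_that("QC filters count removals per stage and keep boundary SNPs", {
  # 5 SNPs: ok / low maf / 20% missing / maf exactly 0.05 / multiallelic
  d <- rbind(c(0, 0, 0, 1, 2), c(1, 0, NA, 0, 1), c(2, 0, 0, 0, 0),
             c(1, 0, NA, 0, 1), c(0, 0, 0, 0, 2),
             c(1, 1, 0, 0, 1), c(2, 0, 0, 0, 0), c(1, 0, 0, 0, 1),
             c(0, 0, 0, 0, 2), c(1, 0, 0, 0, 1))
  # col2 maf = 0.05 exactly (1 alt allele in 20): retained by boundary rule
  d[, 2] <- c(1, rep(0, 9))
  g <- toyGeno(d, alt = c("G", "G", "G", "G", "GT"))
  # col3 has 2/10 missing -> call rate 0.8 < 0.9
  res <- filterSnps(g)
  expect_equal(sum(res$report$removed), 2)
  expect_equal(res$report$removed[res$report$stage == "call_rate"], 1)
  expect_equal(res$report$removed[res$report$stage == "biallelic"], 1)
  expect_true("A01_2000" %in% snpInfo(res$geno)$id)  # maf 0.05 kept
  # report reasons sum to input - output
  expect_equal(sum(res$report$removed), nSnps(g) - nSnps(res$geno))
  expect_equal(res$report$remaining[4], nSnps(res$geno))
  # all-pass input comes back identical
  ok <- toyGeno(rbind(c(0, 2), c(1, 1), c(2, 0), c(1, 1), c(0, 2),
                      c(2, 0), c(1, 1), c(0, 2), c(2, 0), c(1, 1)))
  res2 <- filterSnps(ok)
  expect_identical(dosage(res2$geno), dosage(ok))
  # everything-removed input warns and returns empty
  mono <- toyGeno(matrix(0, 10, 2))
  expect_warning(res3 <- filterSnps(mono), "removed")
  expect_equal(nSnps(res3$geno), 0)
})

test_that("PIC follows the biallelic formula and is bounded by heterozygosity", {
  g <- toyGeno(cbind(c(0, 1, 2, 1), c(0, 0, 0, 0)))
  v <- pic(g)
  expect_equal(unname(v[1]), 0.375)          # p = 0.5 maximum
  expect_equal(unname(v[2]), 0)              # monomorphic
  # p = 0.1 hand value
  d <- matrix(0, 10, 1); d[1, 1] <- 2
  expect_equal(unname(pic(toyGeno(d))), 0.1638, tolerance = 1e-4)
  # PIC <= expected heterozygosity for random panels
  gp <- quickPanel(31, n_samples = 40, n_snps = 200)
  p <- colMeans(dosage(gp), na.rm = TRUE) / 2
  expect_true(all(pic(gp) <= 1 - (p^2 + (1 - p)^2) + 1e-12))
})

test_that("r2 equals brute-force dosage correlation and D' its closed forms", {
  set.seed(13)
  d <- matrix(rbinom(20 * 6, 2, 0.4), 20, 6)
  d[2, 3] <- NA
  g <- toyGeno(d)
  ld <- pairwiseLD(g)
  for (k in seq_len(nrow(ld))) {
    i <- match(ld$snp_a[k], snpInfo(g)$id)
    j <- match(ld$snp_b[k], snpInfo(g)$id)
    cc <- complete.cases(d[, c(i, j)])
    expect_equal(ld$r2[k], cor(d[cc, i], d[cc, j])^2, tolerance = 1e-12)
  }
  # duplicated SNP: r2 = 1, D' = 1
  gdup <- toyGeno(cbind(d[, 1], d[, 1]))
  ld2 <- pairwiseLD(gdup)
  expect_equal(ld2$r2, 1, tolerance = 1e-9)
  expect_equal(ld2$d_prime, 1, tolerance = 1e-6)
  # two-haplotype population AB/ab: D = 0.25, D' = 1, r2 = 1
  hap <- rbind(c(0, 0), c(2, 2))
  gab <- toyGeno(hap[rep(1:2, 10), ])
  ld3 <- pairwiseLD(gab)
  expect_equal(ld3$r2, 1, tolerance = 1e-9)
  expect_equal(ld3$d_prime, 1, tolerance = 1e-6)
  # pairs with < 5 complete observations are skipped
  dsmall <- matrix(c(0, 1, 2, NA, NA, NA, NA, NA,
                     0, 1, 2, NA, NA, NA, NA, NA), 8, 2)
  lds <- pairwiseLD(toyGeno(dsmall))
  expect_equal(nrow(lds), 0)
  expect_equal(attr(lds, "n_skipped"), 1)
})

test_that("EM D' matches a grid-search likelihood oracle on toys", {
  # oracle: maximize the unphased two-locus likelihood over a fine grid of
  # haplotype frequencies (independent of the EM path)
  gridOracle <- function(g1, g2) {
    pA <- mean(g1) / 2; pB <- mean(g2) / 2
    tab <- table(factor(g1, 0:2), factor(g2, 0:2))
    best <- NULL; bestll <- -Inf
    lo <- max(0, pA + pB - 1)
    for (fab in seq(lo, min(pA, pB), length.out = 2001)) {
      f <- c(AB = fab, Ab = pA - fab, aB = pB - fab,
             ab = 1 - pA - pB + fab)
      if (any(f < -1e-12)) next
      f <- pmax(f, 1e-12)
      ll <- 0
      for (i in 0:2) for (j in 0:2) {
        k <- tab[i + 1, j + 1]
        if (k > 0) ll <- ll + k * log(qgomics:::genoPairProb(f, i, j))
      }
      if (ll > bestll) { bestll <- ll; best <- f }
    }
    qgomics:::ldFromHapFreqs(best)
  }
  set.seed(17)
  for (rep in 1:6) {
    g1 <- rbinom(18, 2, 0.5)
    g2 <- ifelse(runif(18) < 0.7, g1, rbinom(18, 2, 0.4))
    if (sd(g1) == 0 || sd(g2) == 0) next
    em <- qgomics:::ldFromHapFreqs(qgomics:::emHaplotypeFreqs(g1, g2))
    or <- gridOracle(g1, g2)
    expect_equal(em[["dprime"]], or[["dprime"]], tolerance = 5e-3)
  }
})

test_that("mean r2 of independent SNPs matches the 1/n expectation", {
  set.seed(19)
  n <- 119
  d <- matrix(rbinom(n * 120, 2, runif(120, 0.2, 0.8)[rep(1:120, each = n)]),
              n, 120)
  g <- toyGeno(d, pos = seq_len(120) * 10L)
  ld <- pairwiseLD(g, stats = "r2")
  ex <- 1 / (n - 1)
  se <- sd(ld$r2) / sqrt(nrow(ld))
  expect_lt(abs(mean(ld$r2) - ex), 3 * se + 0.002)
})

test_that("LD decay distance is recovered and censoring is reported", {
  # near-zero recombination: curve never falls to half its intercept
  g0 <- quickPanel(23, n_samples = 60, n_snps = 150,
                   chrom_lengths = c(A01 = 1e6), n_subpops = 1, fst = 0,
                   recomb_rate = 1e-12)
  ld0 <- pairwiseLD(g0, stats = "r2")
  dec0 <- ldDecay(ld0, n = 120)
  expect_true(dec0$censored)
  # shuffled positions destroy the distance structure
  gs <- quickPanel(24, n_samples = 80, n_snps = 300,
                   chrom_lengths = c(A01 = 2e7), n_subpops = 1, fst = 0,
                   recomb_rate = 1 / 2e6)
  set.seed(1)
  perm <- sample(nSnps(gs))
  ldS <- pairwiseLD(GenotypeData(dosage(gs)[, perm], snpInfo(gs)),
                    stats = "r2")
  decS <- ldDecay(ldS, n = 160)
  expect_true(decS$censored)        # flat curve: no localizable half point
  dec <- ldDecay(pairwiseLD(gs, stats = "r2"), n = 160)
  expect_false(dec$censored)
})

test_that("a 300-kbp configured half-decay is recovered by the fit", {
  st <- ldDecayRecoveryStudy(n_sims = 20, target_bp = 300000, seed = 301)
  expect_lt(abs(st$median_distance - 300000) / 300000, 0.30)
})

test_that("kinship matrix has VanRaden structure", {
  set.seed(29)
  d <- matrix(rbinom(40 * 300, 2, 0.4), 40, 300)
  d[3, ] <- d[1, ]                        # duplicated sample
  g <- toyGeno(d, pos = seq_len(300) * 100L)
  K <- kinship(g)
  expect_equal(K, t(K))
  expect_equal(K[1, 3], K[1, 1])
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)               # PSD up to tolerance
  # brute-force oracle for one entry
  p <- colMeans(d) / 2
  Z <- sweep(d, 2, 2 * p)
  expect_equal(K[2, 5], sum(Z[2, ] * Z[5, ]) / (2 * sum(p * (1 - p))),
               tolerance = 1e-12)
  expect_error(kinship(toyGeno(matrix(2, 5, 3))), "monomorphic|polymorphic")
})

test_that("parent-offspring relatedness is close to one half", {
  set.seed(31)
  m <- 3000
  p <- runif(m, 0.1, 0.9)
  fam <- 12
  # parents and a child built by Mendelian transmission
  par1 <- matrix(rbinom(fam * m, 2, rep(p, each = fam)), fam, m)
  par2 <- matrix(rbinom(fam * m, 2, rep(p, each = fam)), fam, m)
  child <- matrix(rbinom(fam * m, 1, par1 / 2) +
                  rbinom(fam * m, 1, par2 / 2), fam, m)
  d <- rbind(par1, par2, child)
  g <- toyGeno(d, pos = seq_len(m) * 10L)
  K <- kinship(g)
  po <- mean(c(diag(K[1:fam, 2 * fam + 1:fam]),
               diag(K[fam + 1:fam, 2 * fam + 1:fam])))
  expect_equal(po, 0.5, tolerance = 0.1)
})

test_that("genotype PCA separates structured panels deterministically", {
  g <- quickPanel(37, n_samples = 90, n_snps = 600, n_subpops = 3,
                  fst = 0.15, chrom_lengths = c(A01 = 2e7))
  pc <- pcaGenotypes(g, 5)
  sp <- sampleInfo(g)$subpop
  # silhouette of the true labels on the first two PCs
  sil <- function(x, lab) {
    dm <- as.matrix(dist(x))
    mean(sapply(seq_along(lab), function(i) {
      a <- mean(dm[i, lab == lab[i] & seq_along(lab) != i])
      b <- min(sapply(setdiff(unique(lab), lab[i]),
                      function(l) mean(dm[i, lab == l])))
      (b - a) / max(a, b)
    }))
  }
  expect_gt(sil(pc$scores[, 1:2], sp), 0.5)
  # scores are orthogonal; sign convention is deterministic
  cp <- crossprod(pc$scores)
  off <- cp; diag(off) <- 0
  expect_lt(max(abs(off)) / max(diag(cp)), 1e-8)
  pc2 <- pcaGenotypes(g, 5)
  expect_identical(pc$scores, pc2$scores)
  # unstructured panel: no separation
  g0 <- quickPanel(38, n_samples = 90, n_snps = 600, n_subpops = 3,
                   fst = 0, chrom_lengths = c(A01 = 2e7))
  expect_lt(sil(pcaGenotypes(g0, 2)$scores, sampleInfo(g0)$subpop), 0.2)
  # rank truncation warns
  tiny <- toyGeno(matrix(rbinom(12, 2, 0.5), 3, 4))
  expect_warning(pcaGenotypes(tiny, 4), "rank")
})

test_that("haplotype blocks follow the confidence-interval rule", {
  set.seed(41)
  # 4 SNPs in perfect LD -> one block of 4
  hap <- rep(c(0, 2), each = 10)
  d4 <- cbind(hap, hap, hap, hap)
  g4 <- toyGeno(d4, pos = c(100L, 200L, 300L, 400L))
  b4 <- haplotypeBlocks(g4)
  expect_equal(nrow(b4), 1)
  expect_equal(b4$n_snps, 4)
  expect_equal(c(b4$start, b4$end), c(100, 400))
  # two perfect-LD pairs separated by a freely recombining SNP
  pair1 <- rep(c(0, 2), each = 10)
  free <- rbinom(20, 2, 0.5)
  pair2 <- rep(c(0, 2), times = 10)
  d5 <- cbind(pair1, pair1, free, pair2, pair2)
  g5 <- toyGeno(d5, pos = c(100L, 200L, 5000L, 9000L, 9100L))
  b5 <- haplotypeBlocks(g5)
  expect_equal(nrow(b5), 2)
  expect_true(all(b5$n_snps == 2))
  # blocks never overlap and members are contiguous
  g <- quickPanel(43, n_samples = 60, n_snps = 40,
                  chrom_lengths = c(A01 = 2e5), n_subpops = 1, fst = 0,
                  recomb_rate = 1 / 5e4)
  bl <- haplotypeBlocks(g)
  if (nrow(bl) > 1) {
    o <- order(bl$start)
    expect_true(all(bl$end[o][-nrow(bl)] < bl$start[o][-1]))
  }
  # permuted sample labels destroy LD: few or no blocks
  dp <- dosage(g)
  for (j in seq_len(ncol(dp))) dp[, j] <- sample(dp[, j])
  bp <- haplotypeBlocks(GenotypeData(dp, snpInfo(g)))
  expect_lte(nrow(bp), max(1, nrow(bl) %/% 2))
  expect_equal(nrow(haplotypeBlocks(g4[, 1])), 0)
})
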