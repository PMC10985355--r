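toy_pheno <- function(values, reps = 2) {
  # values: named list genotype -> replicate values
  do.call(rbind, lapply(names(values), function(g)
    data.frame(variety = g, trait = "T", year = 2017, regime = "WW",
               rep = seq_along(values[[g]]), value = values[[g]],
               stringsAsFactors = FALSE)))
}

test_that("per-environment ANOVA matches a brute-force least-squares oracle", {
  ph <- toy_pheno(list(g1 = c(4, 6), g2 = c(8, 10), g3 = c(12, 14)))
  at <- suppressWarnings(anovaPerEnvironment(ph, "T", 2017, "WW"))
  # oracle: explicit least squares on the genotype+replicate design
  X_g <- model.matrix(~ factor(ph$variety))
  X_gr <- model.matrix(~ factor(ph$variety) + factor(ph$rep))
  rss <- function(X) sum(lm.fit(X, ph$value)$residuals^2)
  sst <- sum((ph$value - mean(ph$value))^2)
  ss_g <- sst - rss(X_g)                       # genotype SS (balanced)
  ss_e <- rss(X_gr)
  expect_equal(at$mean_sq[at$source == "genotype"], ss_g / 2)
  expect_equal(at$mean_sq[at$source == "genotype"], 32)
  # the additive fit is exact for this toy: the two-way residual MS is 0,
  # while the genotype-only within-group MS is 2
  expect_equal(at$mean_sq[at$source == "error"], ss_e / 2)
  expect_equal(rss(X_g) / 3, 2)
  expect_equal(attr(at, "r"), 2)
})

test_that("ANOVA degenerate cases: constant data and too few replicates", {
  ph <- toy_pheno(list(g1 = c(5, 5), g2 = c(5, 5), g3 = c(5, 5)))
  at <- suppressWarnings(anovaPerEnvironment(ph, "T", 2017, "WW"))
  expect_equal(at$mean_sq[at$source == "genotype"], 0)
  expect_equal(at$mean_sq[at$source == "error"], 0)
  ph1 <- toy_pheno(list(g1 = 4, g2 = 8, g3 = 12))
  expect_error(anovaPerEnvironment(ph1, "T", 2017, "WW"), "replicates")
})

test_that("genotype F-test p-values are uniform under the null", {
  set.seed(42)
  pv <- replicate(400, {
    ph <- data.frame(variety = rep(paste0("g", 1:8), each = 3),
                     trait = "T", year = 2017, regime = "WW",
                     rep = rep(1:3, 8), value = rnorm(24))
    at <- anovaPerEnvironment(ph, "T", 2017, "WW")
    at$p_value[at$source == "genotype"]
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("combined ANOVA detects planted effects and honors degenerate input", {
  mk <- function(seed, gxe = 0, yeff = 0) {
    set.seed(seed)
    g <- paste0("g", 1:20)
    d <- expand.grid(variety = g, year = c(2017, 2018),
                     regime = c("WW", "DS"), rep = 1:3,
                     stringsAsFactors = FALSE)
    gv <- rnorm(20, 0, 1); names(gv) <- g
    ge <- matrix(rnorm(40, 0, gxe), 20,
                 dimnames = list(g, c("WW", "DS")))
    ye <- c(`2017` = 0, `2018` = yeff)
    d$trait <- "T"
    d$value <- 10 + gv[d$variety] + ge[cbind(d$variety, d$regime)] +
      ye[as.character(d$year)] + rnorm(nrow(d), 0, 1)
    d
  }
  # identical data across years: year mean square is zero
  d <- mk(1)
  d2 <- d; d2$year <- 2018; d$year <- 2017
  dd <- rbind(d, d2)
  at <- combinedAnova(dd, "T")
  expect_equal(at$mean_sq[at$source == "Y"], 0)
  # planted GxE: detected in most runs
  hits <- sapply(1:30, function(s) {
    at <- combinedAnova(mk(s, gxe = 1), "T")
    at$p_value[at$source == "G:E"] < 0.05
  })
  expect_gte(mean(hits), 0.8)
  # no year effect: Y non-significant in most runs
  fp <- sapply(31:70, function(s) {
    at <- combinedAnova(mk(s), "T")
    at$p_value[at$source == "Y"] < 0.05
  })
  expect_gte(mean(!fp), 0.75)
  # single year falls back with a warning
  one <- mk(1)
  expect_warning(combinedAnova(one[one$year == 2017, ], "T"),
                 "per-environment")
})

test_that("variance components follow the EMS estimators with clamping", {
  vc <- varianceComponents(list(MSG = 10, MSE = 4, r = 3))
  expect_equal(vc$sigma_g2, 2)
  expect_equal(vc$sigma_e2, 4)
  expect_equal(vc$sigma_p2, 6)
  expect_false(vc$clamped)
  expect_equal(varianceComponents(list(MSG = 4, MSE = 4, r = 3))$sigma_g2, 0)
  vc2 <- varianceComponents(list(MSG = 2, MSE = 4, r = 3))
  expect_equal(vc2$sigma_g2, 0)
  expect_true(vc2$clamped)
  expect_error(varianceComponents(list(MSG = 1, MSE = 1, r = 0)), "r")
})

test_that("coefficients of variation and their classes", {
  cv <- coefficientsOfVariation(list(sigma_g2 = 0, sigma_e2 = 4,
                                     sigma_p2 = 4), 20, MSE = 4)
  expect_equal(cv$ecv, 10); expect_equal(cv$gcv, 0); expect_equal(cv$pcv, 10)
  cv2 <- coefficientsOfVariation(list(sigma_g2 = 2, sigma_e2 = 4,
                                      sigma_p2 = 6), 10, MSE = 4)
  expect_equal(cv2$gcv, 14.142, tolerance = 1e-4)
  expect_equal(cv2$pcv, 24.495, tolerance = 1e-4)
  expect_lte(cv2$gcv, cv2$pcv)
  expect_error(coefficientsOfVariation(list(sigma_g2 = 1, sigma_e2 = 1,
                                            sigma_p2 = 2), 0), "mean")
  expect_equal(cvClass(c(25, 15, 5, 10, 20)),
               c("high", "moderate", "low", "moderate", "moderate"))
})

test_that("heritability ratio with its degenerate cases", {
  # squared-CV ratio reproduces a printed worked value
  expect_equal(heritability(3.18^2, 4.15^2)$h2, 58.73, tolerance = 0.1)
  expect_equal(heritability(5, 5)$h2, 100)
  expect_equal(heritability(0, 5)$h2, 0)
  h <- heritability(0, 0)
  expect_true(h$undefined)
  expect_true(is.na(h$h2))
})

test_that("genetic advance from heritability and phenotypic SD", {
  # printed worked example: sigma_p = 3.59% of 186.00
  ga <- geneticAdvance(88.91, 0.0359 * 186.00, 186.00, k = 1.76)
  expect_equal(ga$ga, 10.45, tolerance = 0.02)
  expect_equal(geneticAdvance(0, 2, 10)$ga, 0)
  expect_equal(geneticAdvance(0, 2, 10)$gam, 0)
  ga2 <- geneticAdvance(50, 2, 10, k = 1.76)
  expect_equal(ga2$ga, 1.76)
  expect_equal(ga2$gam, 17.6)
})

test_that("chained parameter estimates agree with closed-form evaluation", {
  set.seed(7)
  for (i in 1:25) {
    xbar <- runif(1, 5, 500)
    pcv <- runif(1, 5, 60)
    gcv <- runif(1, 0.5, 1) * pcv
    k <- runif(1, 1, 3)
    sp2 <- (pcv / 100 * xbar)^2
    sg2 <- (gcv / 100 * xbar)^2
    h <- heritability(sg2, sp2)$h2
    ga <- geneticAdvance(h, sqrt(sp2), xbar, k)
    expect_equal(h, (gcv / pcv)^2 * 100, tolerance = 1e-10)
    expect_equal(ga$ga, k * (gcv / pcv)^2 * sqrt(sp2), tolerance = 1e-10)
    expect_equal(ga$gam, ga$ga / xbar * 100, tolerance = 1e-10)
  }
})

test_that("genetic-parameter table rows are mutually consistent", {
  set.seed(11)
  g <- quickPanel(5, n_samples = 40, n_snps = 80)
  envs <- expand.grid(year = c(2017, 2018), regime = c("WW", "DS"),
                      stringsAsFactors = FALSE)
  arch <- list(
    traitArchitecture("T1", h2_target = 0.6,
                      env_effects = setNames(c(100, 102, 95, 96),
                                             envCodes(envs)),
                      residual_sd = 4),
    traitArchitecture("T2", h2_target = 0.3,
                      env_effects = setNames(c(50, 51, 45, 46),
                                             envCodes(envs)),
                      residual_sd = 2))
  sim <- simulatePhenotypes(g, arch, envs, n_reps = 3, seed = 12)
  tab <- geneticParamsTable(sim$pheno)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$sigma_p2, tab$sigma_g2 + tab$sigma_e2)
  expect_true(all(tab$gcv <= tab$pcv + 1e-12))
  expect_equal(tab$h2, (tab$gcv / tab$pcv)^2 * 100, tolerance = 1e-8)
  expect_equal(tab$gam, tab$ga / tab$mean * 100, tolerance = 1e-8)
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 100))
})

test_that("percent reduction from regime means", {
  params <- data.frame(trait = "SY",
                       regime = c("WW", "WW", "WW", "DS", "DS", "DS"),
                       mean = c(2594.18, 1352.23, 5125.42,
                                1918.77, 1088.11, 1200.34))
  expect_equal(percentReduction(params, "SY"), 53.62, tolerance = 0.01)
  same <- data.frame(trait = "X", regime = c("WW", "DS"), mean = c(5, 5))
  expect_equal(percentReduction(same, "X"), 0)
  expect_error(percentReduction(params[params$regime == "WW", ], "SY"))
})

test_that("trait correlations on variety means", {
  g <- paste0("g", 1:6)
  base <- c(1, 3, 2, 5, 4, 6)
  ph <- rbind(
    data.frame(variety = g, trait = "A", year = 2017, regime = "WW",
               rep = 1, value = base),
    data.frame(variety = g, trait = "B", year = 2017, regime = "WW",
               rep = 1, value = 2 * base + 1),
    data.frame(variety = g, trait = "C", year = 2017, regime = "WW",
               rep = 1, value = -base))
  ct <- traitCorrelations(ph, "WW")
  expect_equal(ct$r["A", "B"], 1)
  expect_equal(ct$r["A", "C"], -ct$r["A", "B"])
  # hand value for x=(1,2,3), y=(2,4,7)
  ph2 <- rbind(
    data.frame(variety = c("a", "b", "c"), trait = "X", year = 2017,
               regime = "WW", rep = 1, value = c(1, 2, 3)),
    data.frame(variety = c("a", "b", "c"), trait = "Y", year = 2017,
               regime = "WW", rep = 1, value = c(2, 4, 7)))
  expect_equal(traitCorrelations(ph2, "WW")$r["X", "Y"], 0.9934,
               tolerance = 1e-4)
  # constant trait flagged
  ph3 <- rbind(ph, data.frame(variety = g, trait = "K", year = 2017,
                              regime = "WW", rep = 1, value = 7))
  ct3 <- traitCorrelations(ph3, "WW")
  expect_true(ct3$constant["K"])
  expect_true(all(is.na(ct3$r["K", ])))
})

test_that("variety-group contrasts: symmetry and power", {
  g <- paste0("g", 1:10)
  ph <- data.frame(variety = rep(g, each = 2), trait = "T", year = 2017,
                   regime = "WW", rep = rep(1:2, 10),
                   value = rep(c(4, 6, 8, 10, 12), each = 4))
  r1 <- contrastGroups(ph, g[1:5], g[6:10], "T")
  r2 <- contrastGroups(ph, g[6:10], g[1:5], "T")
  expect_equal(r1$t, -r2$t)
  expect_equal(r1$p, r2$p)
  # identical groups give t = 0
  r0 <- contrastGroups(ph, g[1:5], g[1:5], "T")
  expect_equal(r0$t, 0)
  expect_error(contrastGroups(ph, g[1], g[2:5], "T"), ">= 2")
  # planted 2-pooled-SD shift, n=10 per group, significant at 0.01
  set.seed(3)
  hits <- replicate(60, {
    v <- paste0("v", 1:20)
    val <- rnorm(20) + rep(c(2, 0), each = 10)
    ph <- data.frame(variety = v, trait = "T", year = 2017, regime = "WW",
                     rep = 1, value = val)
    contrastGroups(ph, v[1:10], v[11:20], "T")$p < 0.01
  })
  expect_gte(mean(hits), 0.9)
})

test_that("selection intensity equals the normal-tail mean deviation", {
  # brute-force oracle: numerical integration of the upper-tail mean
  p <- 0.10
  z <- qnorm(1 - p)
  oracle <- integrate(function(x) x * dnorm(x), z, Inf)$value / p
  expect_equal(selectionIntensity(p), oracle, tolerance = 1e-8)
  expect_equal(selectionIntensity(0.5),
               integrate(function(x) x * dnorm(x), 0, Inf)$value / 0.5,
               tolerance = 1e-8)
})
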