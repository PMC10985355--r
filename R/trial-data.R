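#' Published genetic-parameter summary of the reference drought trial
#'
#' Per trait-by-environment summary statistics (mean, SD, range,
#' coefficients of variation, broad-sense heritability, genetic advance)
#' of the 119-variety rapeseed drought trial whose design the package's
#' simulators emulate: 12 traits, two watering regimes (WW/DS), three
#' years.  In the published table the two CV columns are printed swapped
#' (the column labelled PCV holds the smaller value); here `gcv` and
#' `pcv` are reassigned so that `gcv <= pcv` holds, which also makes the
#' printed heritabilities consistent with `h2 = (gcv/pcv)^2 * 100`.
#'
#' @return data.frame with columns trait, env, regime, year, mean, sd,
#'   min, max, ecv, gcv, pcv, h2, ga, gam.
#' @export
trialSummary <- function() {
  path <- system.file("extdata", "trial_summary.tsv", package = "qgomics")
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$gcv <- pmin(d$cv_a, d$cv_b)
  d$pcv <- pmax(d$cv_a, d$cv_b)
  d$regime <- substr(d$env, 1, 2)
  d$year <- paste0("20", substr(d$env, 3, 4))
  d[, c("trait", "env", "regime", "year", "mean", "sd", "min", "max",
        "ecv", "gcv", "pcv", "h2", "ga", "gam")]
}
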