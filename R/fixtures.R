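#' @name fixtures
#' @title Published parameter tables shipped as fixtures
#'
#' @description
#' The national analysis draws its uncertain inputs from a published
#' parameter table: Beta distributions for smoking prevalence and service
#' uptake by IMD quintile, lognormal distributions for relative risks of
#' death, of smoking-related disease and of quitting, Beta distributions
#' for the average 12-month quit rates of varenicline and e-cigarette, and
#' a multivariate-normal block for the HRQoL regression coefficients.
#' Those printed values are stored here verbatim (the printed integer
#' `(alpha, beta)` and printed `(lm, lv)`, not re-derived values, so tests
#' against the printed table are exact).  Local-authority (York,
#' Sheffield) smoking prevalence is printed as means with 95% confidence
#' intervals and is converted to Beta distributions by moment matching
#' with a normal-approximation standard error.
#'
#' Costs and disutilities are not printed in the available text; the
#' shipped values are synthetic order-of-magnitude placeholders following
#' the stated "standard error equal to 10% of the mean" gamma rule, and
#' are flagged `synthetic` in the book's provenance metadata.
NULL

#' Quintile and disease labels
#'
#' `IMD`: deprivation quintile labels, `"IMD1"` (most deprived) to
#' `"IMD5"` (least deprived).  `DISEASES`: the six smoking-related
#' diseases tracked as events.
#' @export
IMD <- paste0("IMD", 1:5)

#' @rdname IMD
#' @export
DISEASES <- c("lung_cancer", "chd", "copd", "mi", "stroke", "asthma_ex")

AGE_BANDS_RR <- c("35_44", "45_54", "55_64", "65_74", "75plus")

HRQOL_COEF_NAMES <- c("age_25_34", "age_35_44", "age_45_54", "age_55_64",
                      "age_65_74", "age_75plus", "smoker",
                      "imd2", "imd3", "imd4", "imd5", "constant")

#' Printed national and local-authority parameter constants
#'
#' Accessors for the published values stored verbatim (see
#' [fixtures]).  `table1_constants()` returns the national table;
#' `table2_constants()` the local-authority prevalence means and 95%
#' confidence intervals; `region_population()` and
#' `region_quintile_shares()` the population sizes and deprivation
#' structures (England shares are 0.2 by construction; the
#' local-authority structures are synthetic presets).
#' @return Nested lists / named vectors of printed constants.
#' @export
table1_constants <- function() {
  list(
    prevalence = list(
      # printed mean (%), printed (alpha, beta)
      IMD1 = list(mean_pct = 17.17, shape1 = 2441, shape2 = 11775),
      IMD2 = list(mean_pct = 15.96, shape1 = 1516, shape2 = 7984),
      IMD3 = list(mean_pct = 14.09, shape1 = 887,  shape2 = 5406),
      IMD4 = list(mean_pct = 12.68, shape1 = 688,  shape2 = 4733),
      IMD5 = list(mean_pct = 11.38, shape1 = 601,  shape2 = 4676)
    ),
    rr_death_svn = list(                       # smokers v. nonsmokers, by age band
      `35_44`  = list(mean = 1.87, lm = 0.63, lv = 0.17),
      `45_54`  = list(mean = 2.28, lm = 0.82, lv = 0.11),
      `55_64`  = list(mean = 1.97, lm = 0.68, lv = 0.09),
      `65_74`  = list(mean = 1.83, lm = 0.61, lv = 0.08),
      `75plus` = list(mean = 1.37, lm = 0.31, lv = 0.08)
    ),
    rr_death_svf = list(mean = 1.11, lm = 0.09, lv = 0.02),  # smokers v. former
    rr_disease = list(                         # by IMD, least-deprived reference
      IMD1 = list(mean = 1.15, lm = 0.137, lv = 0.041),
      IMD2 = list(mean = 1.12, lm = 0.109, lv = 0.039),
      IMD3 = list(mean = 1.12, lm = 0.114, lv = 0.038),
      IMD4 = list(mean = 1.08, lm = 0.079, lv = 0.039),
      IMD5 = list(mean = 1)                    # fixed reference, never sampled
    ),
    hrqol_coef = c(age_25_34 = -0.0124, age_35_44 = -0.0544,
                   age_45_54 = -0.0681, age_55_64 = -0.0986,
                   age_65_74 = -0.107,  age_75plus = -0.1630,
                   smoker = -0.0340,
                   imd2 = 0.0320, imd3 = 0.0281, imd4 = 0.0545, imd5 = 0.0736,
                   constant = 0.903),
    quit_varenicline = list(mean = 0.19, shape1 = 6,  shape2 = 25),
    quit_ecigarette  = list(mean = 0.13, shape1 = 13, shape2 = 87),
    natural_quit = 0.02,
    rr_quit = list(                            # IMD1 reference, fixed
      IMD1 = list(mean = 1),
      IMD2 = list(mean = 1.35, lm = 0.297, lv = 0.168),
      IMD3 = list(mean = 1.22, lm = 0.195, lv = 0.201),
      IMD4 = list(mean = 1.27, lm = 0.236, lv = 0.154),
      IMD5 = list(mean = 1.36, lm = 0.308, lv = 0.168)
    ),
    uptake = list(
      IMD1 = list(mean_pct = 4.03,  shape1 = 96, shape2 = 2284),
      IMD2 = list(mean_pct = 6.48,  shape1 = 93, shape2 = 1349),
      IMD3 = list(mean_pct = 6.62,  shape1 = 93, shape2 = 1316),
      IMD4 = list(mean_pct = 10.14, shape1 = 90, shape2 = 795),
      IMD5 = list(mean_pct = 9.92,  shape1 = 90, shape2 = 817)
    )
  )
}

#' @rdname table1_constants
#' @export
table2_constants <- function() {
  list(
    york = list(
      IMD1 = c(mean = 16.91, lo = 11.86, hi = 21.96),
      IMD2 = c(mean = 14.56, lo = 9.95,  hi = 19.16),
      IMD3 = c(mean = 13.57, lo = 9.19,  hi = 17.96),
      IMD4 = c(mean = 11.64, lo = 7.62,  hi = 15.66),
      IMD5 = c(mean = 10.78, lo = 6.95,  hi = 14.60)
    ),
    sheffield = list(
      IMD1 = c(mean = 22.27, lo = 15.86, hi = 28.68),
      IMD2 = c(mean = 20.60, lo = 14.47, hi = 26.72),
      IMD3 = c(mean = 19.84, lo = 13.89, hi = 25.79),
      IMD4 = c(mean = 18.45, lo = 12.74, hi = 24.16),
      IMD5 = c(mean = 17.74, lo = 12.21, hi = 23.28)
    )
  )
}

# Synthetic stand-in for the unavailable supplementary cost/disutility
# table: plausible 2018 GBP magnitudes, SE = 10% of mean, gamma families.
synthetic_cost_constants <- function() {
  list(
    cost_intervention = c(varenicline = 163, ecigarette = 40),
    cost_disease = c(lung_cancer = 9000, chd = 3000, copd = 2000,
                     mi = 5000, stroke = 10000, asthma_ex = 300),
    disutility = c(lung_cancer = 0.15, chd = 0.07, copd = 0.08,
                   mi = 0.06, stroke = 0.12, asthma_ex = 0.02)
  )
}

#' @rdname table1_constants
#' @param region `"england"`, `"york"` or `"sheffield"`.
#' @export
region_population <- function(region) {
  switch(region,
    england   = 42994944,
    york      = 207000,
    sheffield = 574000,
    stop("unknown region: ", region)
  )
}

#' @rdname table1_constants
#' @export
region_quintile_shares <- function(region) {
  shares <- switch(region,
    england   = rep(0.2, 5),
    york      = c(0.05, 0.10, 0.20, 0.30, 0.35),
    sheffield = c(0.30, 0.25, 0.20, 0.15, 0.10),
    stop("unknown region: ", region)
  )
  names(shares) <- IMD
  shares
}
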