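test_that("smoker mortality decomposition reproduces the all-cause rate", {
  # no differential risk: smoker rate equals all-cause
  expect_equal(smoker_mortality_rate(0.01, 0.2, 0.3, 0.5, 1, 1), 0.01)
  # single-group population
  expect_equal(smoker_mortality_rate(0.01, 1, 0, 0, 1.11, 2), 0.01)
  # hand-computed case, and the defining weighted-average identity
  m_s <- smoker_mortality_rate(0.01, 0.2, 0.3, 0.5, 1.11, 2.0)
  expect_equal(m_s, 0.01 / (0.2 + 0.3 / 1.11 + 0.5 / 2), tolerance = 1e-12)
  expect_equal(0.2 * m_s + 0.3 * m_s / 1.11 + 0.5 * m_s / 2, 0.01,
               tolerance = 1e-12)
  # RRs above 1 push the smoker rate above all-cause
  expect_gt(m_s, 0.01)
  expect_error(smoker_mortality_rate(0.01, 0.2, 0.3, 0.5, 1.11, 0))
})

test_that("annual quit probability follows the first-cycle rule", {
  expect_equal(annual_quit_probability(0.19, 1.0, TRUE, "varenicline"), 0.19)
  expect_equal(annual_quit_probability(0.19, 1.36, FALSE, "varenicline"),
               0.02 * 1.36)
  # no-intervention arm ignores the intervention rate even in cycle 1
  expect_equal(annual_quit_probability(0.19, 1.2, TRUE, "none"), 0.02 * 1.2)
  expect_equal(annual_quit_probability(0.13, 0, TRUE, "ecigarette"), 0)
  expect_warning(p <- annual_quit_probability(0.9, 2, TRUE, "varenicline"),
                 "clamped")
  expect_equal(p, 1)
})

test_that("trace conserves occupancy, death is monotone, no relapse", {
  s <- draw_sample_seeded(england_book, 17)
  for (case in list(c("IMD1", "none", 25), c("IMD3", "varenicline", 40),
                    c("IMD5", "ecigarette", 70))) {
    tr <- run_cohort_trace(s, default_ext, case[1], case[2],
                           as.integer(case[3]))$trace
    occ <- tr[, c("smoker", "former", "dead")]
    expect_true(all(abs(rowSums(occ) - 1) < 1e-9))
    expect_true(all(occ >= -1e-12))
    expect_true(all(diff(tr$dead) >= -1e-12))
  }
  # no relapse: with mortality switched off, former occupancy can never fall
  ext0 <- default_ext
  ext0$mortality[] <- 0
  tr <- run_cohort_trace(s, ext0, "IMD2", "varenicline", 30)$trace
  expect_true(all(diff(tr$former) >= -1e-12))
  expect_true(all(diff(tr$smoker) <= 1e-12))
})

test_that("degenerate settings give closed-form QALY totals", {
  s <- draw_sample_seeded(england_book, 3)
  ext0 <- default_ext
  ext0$mortality[] <- 0
  ext0$incidence[] <- 0
  s$hrqol[] <- 0
  s$hrqol["constant"] <- 1
  s$rr_quit[] <- 0                      # no quitting
  s$settings$discount_rate <- 0
  s$quit_rate[] <- 0
  tr <- run_cohort_trace(s, ext0, "IMD1", "none", 40)
  n_cyc <- 100 - 40
  expect_equal(nrow(tr$trace), n_cyc)
  expect_equal(unname(tr$totals["qaly"]), n_cyc)   # one QALY per cycle
  # with discounting over a 2-cycle horizon: 1 + 1/(1+r)
  s$settings$discount_rate <- 0.035
  s$settings$age_cap <- 42
  tr2 <- run_cohort_trace(s, ext0, "IMD1", "none", 40)
  expect_equal(unname(tr2$totals["qaly"]), 1 + 1 / 1.035)
})

test_that("certain quitting in cycle 1 moves all survivors to former", {
  s <- draw_sample_seeded(england_book, 3)
  s$quit_rate["varenicline"] <- 1
  s$rr_quit[] <- 1
  tr <- run_cohort_trace(s, default_ext, "IMD2", "varenicline", 50)$trace
  expect_equal(tr$smoker[2], 0)
  expect_equal(tr$former[2] + tr$dead[2], 1)
})

test_that("vectorised lifetime outcomes equal the per-age trace average", {
  s <- draw_sample_seeded(england_book, 29)
  for (arm in c("none", "ecigarette")) {
    fast <- per_smoker_lifetime_outcomes(s, default_ext, "IMD4", arm)
    slow <- vapply(s$settings$entry_ages, function(a)
      run_cohort_trace(s, default_ext, "IMD4", arm, a)$totals, numeric(2))
    expect_equal(unname(fast["qaly"]), mean(slow["qaly", ]), tolerance = 1e-12)
    expect_equal(unname(fast["cost"]), mean(slow["cost", ]), tolerance = 1e-12)
  }
})

test_that("degenerate and two-point entrant age distributions are linear", {
  s <- draw_sample_seeded(england_book, 8)
  s$settings$entry_ages <- c(30L, 60L)
  s$settings$entry_age_weights <- c(1, 0)
  one <- per_smoker_lifetime_outcomes(s, default_ext, "IMD1", "none")
  tr30 <- run_cohort_trace(s, default_ext, "IMD1", "none", 30)$totals
  expect_equal(unname(one), unname(tr30), tolerance = 1e-12)
  s$settings$entry_age_weights <- c(0.5, 0.5)
  half <- per_smoker_lifetime_outcomes(s, default_ext, "IMD1", "none")
  tr60 <- run_cohort_trace(s, default_ext, "IMD1", "none", 60)$totals
  expect_equal(unname(half), unname((tr30 + tr60) / 2), tolerance = 1e-12)
})

test_that("equalising all quintile inputs equalises per-smoker outcomes", {
  s <- draw_sample_seeded(flat_book, 12)
  outs <- per_smoker_outcomes_all(s, flat_ext)
  for (arm in c("none", "varenicline", "ecigarette")) {
    expect_lt(max(abs(outs[, arm, "qaly"] - outs["IMD1", arm, "qaly"])), 1e-9)
    expect_lt(max(abs(outs[, arm, "cost"] - outs["IMD1", arm, "cost"])), 1e-9)
  }
})

test_that("raising the quit rate cannot lower QALYs or raise disease costs", {
  for (seed in c(101, 202)) {
    lo <- draw_sample_seeded(england_book, seed)
    hi <- lo
    hi$quit_rate["varenicline"] <- min(1, lo$quit_rate[["varenicline"]] + 0.2)
    o_lo <- per_smoker_lifetime_outcomes(lo, default_ext, "IMD3", "varenicline")
    o_hi <- per_smoker_lifetime_outcomes(hi, default_ext, "IMD3", "varenicline")
    expect_gte(o_hi[["qaly"]], o_lo[["qaly"]])
    expect_lte(o_hi[["cost"]], o_lo[["cost"]])  # same intervention cost
  }
})

test_that("population scaling follows uptake and linearity in N", {
  s <- draw_sample_seeded(england_book, 21)
  ps <- per_smoker_outcomes_all(s, default_ext)
  # zero uptake: active arm indistinguishable from no intervention
  s0 <- s; s0$uptake[] <- 0
  none <- population_arm_outcomes(s0, default_ext, "none", per_smoker = ps)
  act <- population_arm_outcomes(s0, default_ext, "varenicline", per_smoker = ps)
  expect_equal(act$qalys, none$qalys)
  expect_equal(act$costs, none$costs)
  # doubling the population doubles everything
  s2 <- s; s2$settings$population <- 2 * s$settings$population
  a1 <- population_arm_outcomes(s, default_ext, "ecigarette", per_smoker = ps)
  a2 <- population_arm_outcomes(s2, default_ext, "ecigarette", per_smoker = ps)
  expect_equal(unname(a2$qalys), unname(2 * a1$qalys), tolerance = 1e-12)
  # single-quintile toy equals the direct per-smoker computation
  s1q <- s
  s1q$settings$quintile_shares <- c(IMD1 = 1, IMD2 = 0, IMD3 = 0,
                                    IMD4 = 0, IMD5 = 0)
  out <- population_arm_outcomes(s1q, default_ext, "varenicline",
                                 per_smoker = ps)
  N <- s$settings$population
  smokers <- N * s$prevalence[["IMD1"]]
  treated <- smokers * s$uptake[["IMD1"]]
  manual <- smokers * ps["IMD1", "none", "qaly"] +
    treated * (ps["IMD1", "varenicline", "qaly"] - ps["IMD1", "none", "qaly"])
  expect_equal(sum(out$qalys), manual, tolerance = 1e-9)
})

test_that("trace exports a tidy CSV", {
  s <- draw_sample_seeded(england_book, 4)
  tr <- run_cohort_trace(s, default_ext, "IMD1", "none", 60)
  path <- tempfile(fileext = ".csv")
  write_cohort_trace(tr, path)
  tidy <- read.csv(path)
  expect_setequal(names(tidy),
                  c("cycle", "state", "occupancy", "disease", "events",
                    "cost", "qaly"))
  expect_equal(sum(!is.na(tidy$occupancy)), 3 * nrow(tr$trace))
  expect_equal(sum(!is.na(tidy$events)), 6 * nrow(tr$trace))
})
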