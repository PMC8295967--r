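test_that("PSA is bitwise reproducible under (seed, n) and order-invariant", {
  a <- suppressWarnings(run_psa(england_book, default_ext, n = 8, seed = 99))
  b <- suppressWarnings(run_psa(england_book, default_ext, n = 8, seed = 99))
  expect_identical(a$inputs, b$inputs)
  expect_identical(a$outputs, b$outputs)
  c <- suppressWarnings(run_psa(england_book, default_ext, n = 8, seed = 100))
  expect_false(identical(a$outputs, c$outputs))
})

test_that("PSA on an all-fixed book reproduces the deterministic base case", {
  psa <- run_psa(flat_book, flat_ext, n = 2, seed = 1,
                 comparisons = "varenicline vs none")
  bc <- base_case_results(flat_book, flat_ext,
                          comparisons = "varenicline vs none")[[1]]
  # quintile-varying inputs are fixed in the flat book, so iteration
  # variation comes only from the non-quintile parameters; check that the
  # fixed blocks hit the base case exactly by fixing the rest too
  expect_equal(dim(psa$outputs), c(2, 1, 3))
  all_fixed <- flat_book
  fix_at_mean <- function(spec)
    dist_spec("fixed", value = distribution_summary(spec)$mean)
  all_fixed$mortality_rr$rr_death_svn <-
    lapply(all_fixed$mortality_rr$rr_death_svn, fix_at_mean)
  all_fixed$mortality_rr$rr_death_svf <-
    fix_at_mean(all_fixed$mortality_rr$rr_death_svf)
  all_fixed$effectiveness$quit_varenicline <-
    fix_at_mean(all_fixed$effectiveness$quit_varenicline)
  all_fixed$effectiveness$quit_ecigarette <-
    fix_at_mean(all_fixed$effectiveness$quit_ecigarette)
  all_fixed$costs$intervention <- lapply(all_fixed$costs$intervention, fix_at_mean)
  all_fixed$costs$disease <- lapply(all_fixed$costs$disease, fix_at_mean)
  all_fixed$disutilities <- lapply(all_fixed$disutilities, fix_at_mean)
  mu <- all_fixed$hrqol$params$mean
  all_fixed$hrqol <- dist_spec("mvnormal", mean = mu,
                               sigma = matrix(0, length(mu), length(mu),
                                              dimnames = list(names(mu),
                                                              names(mu))))
  psa_f <- run_psa(all_fixed, flat_ext, n = 2, seed = 5,
                   comparisons = "varenicline vs none")
  bc_f <- base_case_results(all_fixed, flat_ext,
                            comparisons = "varenicline vs none")[[1]]
  expect_equal(unname(psa_f$outputs[1, 1, "inhb"]), bc_f$inhb, tolerance = 1e-9)
  expect_equal(unname(psa_f$outputs[2, 1, "delta"]), bc_f$delta,
               tolerance = 1e-6)
})

test_that("common random inputs make an arm's self-increment exactly zero", {
  # within one iteration all arms share one sample; comparing an arm to
  # itself must therefore give identically zero incremental outputs
  s <- draw_sample_seeded(england_book, 303)
  ps <- per_smoker_outcomes_all(s, default_ext)
  eq <- equity_settings_from(england_book, default_ext)
  arm <- population_arm_outcomes(s, default_ext, "varenicline", per_smoker = ps)
  self <- compare_arms(arm, arm, eq)
  expect_identical(self$inhb, 0)
  expect_identical(self$delta, 0)
})

test_that("decision probabilities are empirical proportions with binomial SEs", {
  psa <- suppressWarnings(run_psa(england_book, default_ext, n = 12, seed = 2))
  probs <- decision_probabilities(psa)
  for (j in seq_along(psa$comparisons)) {
    p_manual <- mean(psa$outputs[, j, "inhb"] > 0)
    expect_equal(probs$p_inhb_pos[j], p_manual)
    expect_equal(probs$se_inhb[j], sqrt(p_manual * (1 - p_manual) / 12))
  }
  expect_true(all(probs$p_inhb_pos >= 0 & probs$p_inhb_pos <= 1))
  # counting check on a hand-built object
  toy <- psa
  toy$outputs[, 1, "inhb"] <- rep(c(1, -1, 2, -3), 3)
  expect_equal(decision_probabilities(toy)$p_inhb_pos[1], 0.5)
})

test_that("summary table reports means, percentiles and row per comparison", {
  psa <- suppressWarnings(run_psa(england_book, default_ext, n = 30, seed = 3))
  tab <- psa_summary_table(psa)
  expect_equal(nrow(tab), length(psa$comparisons))
  j <- 1
  expect_equal(tab$mean_inhb[j], mean(psa$outputs[, j, "inhb"]))
  expect_equal(tab$inhb_lo[j],
               unname(quantile(psa$outputs[, j, "inhb"], 0.025)))
  # probabilities printed in percent to 2 dp
  expect_true(all(tab$p_inhb_pos_pct >= 0 & tab$p_inhb_pos_pct <= 100))
  expect_equal(tab$p_inhb_pos_pct, round(tab$p_inhb_pos_pct, 2))
})

test_that("probabilities and means are invariant to iteration order", {
  psa <- suppressWarnings(run_psa(england_book, default_ext, n = 16, seed = 8))
  perm <- sample(16)
  shuffled <- psa
  shuffled$inputs <- psa$inputs[perm, , drop = FALSE]
  shuffled$outputs <- psa$outputs[perm, , , drop = FALSE]
  expect_equal(decision_probabilities(shuffled)$p_inhb_pos,
               decision_probabilities(psa)$p_inhb_pos)
  expect_equal(psa_summary_table(shuffled)$mean_delta,
               psa_summary_table(psa)$mean_delta)
})

test_that("PSA CSV bundle round-trips inputs and scatter coordinates", {
  psa <- suppressWarnings(run_psa(england_book, default_ext, n = 6, seed = 44))
  dir <- tempfile("psa_")
  write_psa_csv(psa, dir)
  inputs <- read.csv(file.path(dir, "inputs.csv"))
  expect_equal(dim(inputs), dim(psa$inputs))
  expect_equal(names(inputs), colnames(psa$inputs))
  expect_equal(unname(as.matrix(inputs)), unname(psa$inputs),
               tolerance = 1e-12)
  scatter <- read.csv(file.path(dir, "scatter.csv"))
  expect_setequal(names(scatter), c("iteration", "comparison", "delta", "inhb"))
  expect_equal(nrow(scatter), 6 * length(psa$comparisons))
})
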