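test_that("pooled opportunity costs are distributed by quintile share", {
  s <- toy_equity(epsilon = 1)
  res <- incremental_net_health_benefit(rep(10, 5), rep(40000, 5), s)
  # total cost 200,000 -> 10 forgone QALYs split (3, 2.5, 2, 1.5, 1)
  expect_equal(unname(res$inhb_q), c(7, 7.5, 8, 8.5, 9))
  expect_equal(res$inhb, 40)
  # zero cost: iNHB_q is just the direct benefit
  res0 <- incremental_net_health_benefit(1:5, rep(0, 5), s)
  expect_equal(unname(res0$inhb_q), as.numeric(1:5))
  # uniform shares: equal deduction everywhere
  su <- toy_equity(shares = rep(0.2, 5))
  resu <- incremental_net_health_benefit(rep(1, 5), rep(20000, 5), su)
  expect_equal(unname(resu$inhb_q), rep(1 - 1, 5))
})

test_that("Atkinson EDE matches its closed forms", {
  h <- c(60, 70); w <- c(0.5, 0.5)
  expect_equal(atkinson_ede(h, w, 0), 65)                      # arithmetic
  expect_equal(atkinson_ede(h, w, 1), sqrt(60 * 70))           # geometric
  expect_equal(atkinson_ede(h, w, 2), 8400 / 130)              # harmonic
  # equal distribution is a fixed point for every aversion level
  for (eps in c(0, 0.5, 1, 2, 10.95))
    expect_equal(atkinson_ede(rep(70, 5), rep(0.2, 5), eps), 70)
  # EDE never exceeds the mean; gap grows with aversion
  h5 <- c(62, 65, 68, 71, 74); w5 <- rep(0.2, 5)
  edes <- vapply(c(0, 1, 2, 5, 10.95, 20), function(e)
    atkinson_ede(h5, w5, e), numeric(1))
  expect_true(all(edes <= mean(h5) + 1e-12))
  expect_true(all(diff(edes) < 0))
  expect_error(atkinson_ede(c(-1, 70), w, 2), "positive")
})

test_that("EDE is scale-invariant and monotone", {
  h <- c(50, 60, 70, 80, 90); w <- c(0.1, 0.2, 0.4, 0.2, 0.1)
  for (eps in c(0.5, 2, 10.95)) {
    expect_equal(atkinson_ede(3 * h, w, eps), 3 * atkinson_ede(h, w, eps))
    h_up <- h; h_up[2] <- h_up[2] + 5
    expect_gt(atkinson_ede(h_up, w, eps), atkinson_ede(h, w, eps))
  }
})

test_that("a mean-preserving progressive transfer raises EDE (Pigou-Dalton)", {
  w <- rep(0.2, 5)
  h <- c(62, 65, 68, 71, 74)
  h_t <- c(63, 65, 68, 71, 73)   # transfer 1 from best-off to worst-off
  for (eps in c(0.5, 1, 2, 10.95)) {
    expect_gt(atkinson_ede(h_t, w, eps), atkinson_ede(h, w, eps))
  }
  # no aversion: transfers are invisible
  expect_equal(atkinson_ede(h_t, w, 0), atkinson_ede(h, w, 0))
})

test_that("iEDE dilutes per-quintile iNHB per person and recovers identities", {
  s <- toy_equity(epsilon = 2, qale = c(62, 65, 68, 71, 74))
  expect_equal(incremental_ede(rep(0, 5), s), 0)
  # no aversion: iEDE equals total iNHB exactly
  s0 <- toy_equity(epsilon = 0, qale = c(62, 65, 68, 71, 74))
  inhb_q <- c(4, 3, 2, 1, 0) * 1000
  expect_equal(incremental_ede(inhb_q, s0), sum(inhb_q), tolerance = 1e-9)
  # benefit concentrated on the most deprived reduces inequality: iEDE > iNHB
  s2 <- toy_equity(epsilon = 2, qale = c(62, 65, 68, 71, 74))
  conc <- c(5000, 0, 0, 0, 0)
  expect_gt(incremental_ede(conc, s2), sum(conc))
  # oracle: direct EDE evaluation
  h0 <- c(62, 65, 68, 71, 74); N_q <- rep(1e6, 5)
  h1 <- h0 + conc / N_q
  manual <- sum(N_q) * (atkinson_ede(h1, rep(0.2, 5), 2) -
                        atkinson_ede(h0, rep(0.2, 5), 2))
  expect_equal(incremental_ede(conc, s2), manual)
  expect_error(incremental_ede(c(-70e6, 0, 0, 0, 0), s2), "IMD1")
})

test_that("equity impact plane quadrants follow the sign logic", {
  # the published national varenicline v. e-cigarette cell: iNHB 42,968,
  # inequality impact -6,417 (iEDE reconstructed as their sum)
  q <- equity_impact_summary(42968, 42968 - 6417)
  expect_equal(q$delta, -6417)
  expect_equal(q$quadrant, "win-lose")
  expect_equal(equity_impact_summary(0, 0)$quadrant, "boundary")
  expect_equal(equity_impact_summary(-5, 10)$quadrant, "lose-win")
  expect_equal(equity_impact_summary(-5, -10)$quadrant, "lose-lose")
  expect_equal(equity_impact_summary(5, 10)$quadrant, "win-win")
})

test_that("comparison results satisfy the decomposition identity", {
  s <- draw_sample_seeded(england_book, 61)
  ps <- per_smoker_outcomes_all(s, default_ext)
  eq <- equity_settings_from(england_book, default_ext)
  arms <- lapply(setNames(c("none", "varenicline", "ecigarette"),
                          c("none", "varenicline", "ecigarette")),
                 function(a) population_arm_outcomes(s, default_ext, a,
                                                    per_smoker = ps))
  cmp <- compare_arms(arms$varenicline, arms$none, eq)
  expect_equal(sum(cmp$inhb_q), cmp$inhb, tolerance = 1e-9)
  expect_equal(cmp$iede, cmp$inhb + cmp$delta, tolerance = 1e-9)
  expect_true(cmp$quadrant %in%
                c("win-win", "win-lose", "lose-win", "lose-lose", "boundary"))
  # aversion 0 kills the inequality impact for any input
  eq0 <- equity_settings_from(england_book, default_ext, epsilon = 0)
  cmp0 <- compare_arms(arms$varenicline, arms$ecigarette, eq0)
  expect_equal(cmp0$delta, 0, tolerance = 1e-9 * abs(cmp0$inhb))
})

test_that("the aversion sweep is flat at zero and monotone in magnitude", {
  sw <- epsilon_sweep(england_book, default_ext, epsilons = c(0, 2, 10.95),
                      comparisons = "varenicline vs none")
  expect_equal(nrow(sw), 3)
  expect_equal(sw$delta[sw$epsilon == 0], 0,
               tolerance = 1e-9 * abs(sw$inhb[1]))
  # iNHB does not depend on aversion; |delta| grows with it
  expect_equal(sw$inhb, rep(sw$inhb[1], 3), tolerance = 1e-12)
  expect_gt(abs(sw$delta[sw$epsilon == 10.95]),
            abs(sw$delta[sw$epsilon == 2]))
})

test_that("smoker-only dilution is exposed and differs from population dilution", {
  qale <- c(62, 65, 68, 71, 74)
  pop <- rep(1e6, 5)
  smokers <- pop * 0.15
  s_pop <- equity_settings(20000, c(.3, .25, .2, .15, .1), 2, qale, pop)
  s_smo <- equity_settings(20000, c(.3, .25, .2, .15, .1), 2, qale, pop,
                           dilution = "smokers", smoker_pop = smokers)
  inhb_q <- c(5000, 4000, 3000, 2000, 1000)
  expect_false(isTRUE(all.equal(incremental_ede(inhb_q, s_pop),
                                incremental_ede(inhb_q, s_smo))))
})
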