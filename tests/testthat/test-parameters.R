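test_that("fixture book means match the printed table at printed precision", {
  t1 <- table1_constants()
  # the printed mean column and the printed (alpha, beta) are mutually
  # inconsistent at the second decimal for IMD3-5; fixtures follow
  # (alpha, beta), so the band is 0.02 percentage points
  for (q in IMD) {
    m <- distribution_summary(england_book$prevalence[[q]])$mean
    expect_lt(abs(100 * m - t1$prevalence[[q]]$mean_pct), 0.02)
  }
  # lognormal rows print the median (exp(lm)); lm itself is printed to
  # 2 dp, so the reconstructed median can drift by up to exp(0.005) ~ 0.5%
  for (b in names(t1$rr_death_svn)) {
    med <- distribution_summary(
      england_book$mortality_rr$rr_death_svn[[b]])$median
    expect_equal(med, t1$rr_death_svn[[b]]$mean, tolerance = 0.006)
  }
  for (q in c("IMD1", "IMD2", "IMD3", "IMD4")) {
    med <- distribution_summary(england_book$disease_rr[[q]])$median
    expect_equal(round(med, 2), t1$rr_disease[[q]]$mean, tolerance = 0.005)
    med <- distribution_summary(england_book$effectiveness$rr_quit[[q]])$median
    if (q != "IMD1")
      expect_equal(round(med, 2), t1$rr_quit[[q]]$mean, tolerance = 0.005)
  }
  expect_equal(
    round(distribution_summary(england_book$effectiveness$quit_varenicline)$mean, 2),
    0.19)
  expect_equal(
    round(distribution_summary(england_book$effectiveness$quit_ecigarette)$mean, 2),
    0.13)
  # uptake means follow the printed (alpha, beta); the printed percentage
  # for IMD2 (6.48) is inconsistent with its own (93, 1349) at the second
  # decimal, so the check is against alpha/(alpha+beta)
  for (q in IMD) {
    ab <- t1$uptake[[q]]
    m <- distribution_summary(england_book$uptake[[q]])$mean
    expect_equal(m, ab$shape1 / (ab$shape1 + ab$shape2))
  }
})

test_that("local-authority books inherit England inputs but use printed prevalence CIs", {
  york <- fixture_parameter_book("york")
  shef <- fixture_parameter_book("sheffield")
  t2 <- table2_constants()
  for (q in IMD) {
    s <- distribution_summary(york$prevalence[[q]])
    expect_equal(100 * s$mean, t2$york[[q]][["mean"]], tolerance = 1e-8)
    width <- t2$york[[q]][["hi"]] - t2$york[[q]][["lo"]]
    expect_equal(100 * s$sd, width / (2 * qnorm(0.975)), tolerance = 1e-8)
  }
  s <- distribution_summary(shef$prevalence$IMD1)
  expect_equal(round(100 * s$mean, 2), 22.27)
  # everything else inherited
  expect_equal(shef$effectiveness, england_book$effectiveness)
  expect_equal(shef$costs, england_book$costs)
  expect_equal(york$settings$population, 207000)
  expect_equal(shef$settings$population, 574000)
  expect_false(all(york$settings$quintile_shares == 0.2))
})

test_that("reference levels are fixed and never sampled", {
  expect_equal(england_book$effectiveness$rr_quit$IMD1$family, "fixed")
  expect_equal(england_book$disease_rr$IMD5$family, "fixed")
  set.seed(5)
  for (i in 1:5) {
    s <- draw_sample(england_book)
    expect_identical(s$rr_quit[["IMD1"]], 1)
    expect_identical(s$rr_disease[["IMD5"]], 1)
  }
})

test_that("sampling is reproducible and seeds differentiate draws", {
  s1 <- draw_sample_seeded(england_book, 123)
  s2 <- draw_sample_seeded(england_book, 123)
  s3 <- draw_sample_seeded(england_book, 124)
  expect_identical(s1[names(s1) != "settings"], s2[names(s2) != "settings"])
  expect_false(identical(s1$prevalence, s3$prevalence))
})

test_that("an all-fixed book resolves to its means exactly", {
  s <- draw_sample_seeded(flat_book, 9)
  expect_identical(unname(s$prevalence), rep(887 / (887 + 5406), 5))
  expect_identical(unname(s$rr_quit), rep(1, 5))
  expect_identical(unname(s$hrqol[c("imd2", "imd3", "imd4", "imd5")]),
                   rep(0, 4))
})

test_that("sample values respect probability and relative-risk domains", {
  for (seed in 1:20) {
    s <- draw_sample_seeded(england_book, seed)
    expect_true(all(s$prevalence >= 0 & s$prevalence <= 1))
    expect_true(all(s$uptake >= 0 & s$uptake <= 1))
    expect_true(all(s$quit_rate >= 0 & s$quit_rate <= 1))
    expect_true(all(s$rr_quit > 0), all(s$rr_disease > 0))
    expect_true(all(s$rr_death_svn > 0) && s$rr_death_svf > 0)
    expect_true(all(s$cost_disease > 0) && all(s$disutility > 0))
  }
})

test_that("beta sample mean is close to alpha/(alpha+beta)", {
  spec <- dist_spec("beta", shape1 = 6, shape2 = 25)
  set.seed(31)
  draws <- replicate(1e4, dceasmoke:::draw_dist(spec))
  s <- distribution_summary(spec)
  expect_lt(abs(mean(draws) - 6 / 31), 3 * s$sd / sqrt(1e4))
})

test_that("base_case_sample returns analytic means", {
  bc <- base_case_sample(england_book)
  expect_equal(unname(bc$prevalence["IMD1"]), 2441 / (2441 + 11775))
  expect_equal(unname(bc$quit_rate["varenicline"]), 6 / 31)
  expect_equal(unname(bc$rr_death_svf), exp(0.09 + 0.02^2 / 2))
  expect_equal(unname(bc$cost_intervention["varenicline"]), 163,
               tolerance = 1e-9)
})

test_that("flattened samples follow the group layout and omit fixed inputs", {
  groups <- parameter_groups(england_book)
  s <- draw_sample_seeded(england_book, 2)
  v <- flatten_parameter_sample(s, england_book)
  expect_identical(names(v), unlist(groups, use.names = FALSE))
  expect_false("rr_quit_IMD1" %in% names(v))
  expect_false("rr_disease_IMD5" %in% names(v))
  expect_equal(unname(v["prevalence_IMD2"]), unname(s$prevalence["IMD2"]))
  expect_equal(unname(v["hrqol_constant"]), unname(s$hrqol["constant"]))
  # flat book: quintile gradients are fixed, so those groups vanish
  gf <- parameter_groups(flat_book)
  expect_false(any(c("prevalence", "rr_quit", "uptake") %in% names(gf)))
  expect_true(all(c("quit_rates", "costs", "disutilities") %in% names(gf)))
})

test_that("parameter book YAML round trip is exact", {
  path <- tempfile(fileext = ".yaml")
  write_parameter_book(england_book, path)
  back <- read_parameter_book(path)
  expect_equal(back$prevalence, england_book$prevalence)
  expect_equal(back$hrqol$params$sigma, england_book$hrqol$params$sigma)
  expect_equal(back$settings$quintile_shares,
               england_book$settings$quintile_shares)
  expect_equal(back$costs, england_book$costs)
  s1 <- draw_sample_seeded(back, 55)
  s2 <- draw_sample_seeded(england_book, 55)
  expect_identical(s1$hrqol, s2$hrqol)
})
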