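#' Smoking-cessation cohort model
#'
#' Three-state (smoker, former smoker, dead) annual-cycle Markov cohort
#' model.  The full cohort enters as smokers; in each cycle smokers may
#' quit (intervention quit rate in the first cycle of an active arm,
#' background rate of 2%/year thereafter and in the no-intervention arm,
#' both scaled by the quintile's relative risk of quitting), then each
#' state is exposed to state-specific mortality.  There is no relapse.
#' Smokers and former smokers accrue expected events of six
#' smoking-related diseases (lung cancer, coronary heart disease, COPD,
#' myocardial infarction, stroke, asthma exacerbation), each carrying a
#' one-cycle cost and utility decrement.  QALYs and costs are discounted
#' at the settings' rate with factor (1+r)^-t for cycle t = 0, 1, ...;
#' accruals use start-of-cycle occupancy with no half-cycle correction.
#' Survivors at the age cap are censored.
#'
#' @name markov_model
NULL

ARMS <- c("none", "varenicline", "ecigarette")

# index into 18..100 age grids
age_idx <- function(age) pmin(pmax(age, 18L), 100L) - 17L

rr_band_svn <- function(age) {
  # under-35s use the youngest published band
  cut(pmin(pmax(age, 35), 75), c(34, 44, 54, 64, 74, Inf),
      labels = AGE_BANDS_RR)
}

hrqol_age_term <- function(age, hrqol) {
  band <- cut(age, c(-Inf, 24, 34, 44, 54, 64, 74, Inf),
              labels = c("ref", "age_25_34", "age_35_44", "age_45_54",
                         "age_55_64", "age_65_74", "age_75plus"))
  out <- numeric(length(age))
  nz <- band != "ref"
  out[nz] <- hrqol[as.character(band[nz])]
  out
}

#' Annual mortality rate for smokers from all-cause mortality
#'
#' Decomposes the all-cause rate so that the population-weighted average
#' of the smoker, former-smoker and nonsmoker rates reproduces it:
#' `m_s = all_cause / (p_s + p_f / rr_svf + p_n / rr_svn)`, with the
#' former-smoker rate `m_s / rr_svf` and nonsmoker rate `m_s / rr_svn`.
#' With relative risks above 1 the smoker rate exceeds the all-cause
#' rate, as it must.
#'
#' @param all_cause Annual all-cause mortality rate in \[0, 1).
#' @param p_smoker,p_former,p_non Population smoking-status proportions
#'   (non-negative, summing to 1).
#' @param rr_svf Relative risk of death, smokers v. former smokers.
#' @param rr_svn Relative risk of death, smokers v. nonsmokers.
#' @return Annual mortality rate for smokers (vectorised over age).
#' @examples
#' smoker_mortality_rate(0.01, 0.2, 0.3, 0.5, 1.11, 2.0)
#' @export
smoker_mortality_rate <- function(all_cause, p_smoker, p_former, p_non,
                                  rr_svf, rr_svn) {
  stopifnot(all(all_cause >= 0), all(all_cause < 1),
            all(p_smoker >= 0), all(p_former >= 0), all(p_non >= 0),
            all(abs(p_smoker + p_former + p_non - 1) < 1e-9),
            all(rr_svf > 0), all(rr_svn > 0))
  denom <- p_smoker + p_former / rr_svf + p_non / rr_svn
  if (any(denom <= 0)) stop("non-positive denominator in mortality decomposition")
  all_cause / denom
}

#' Annual quit probability for a cycle
#'
#' First cycle of an active arm: the intervention quit rate times the
#' quintile's relative risk of quitting.  All later cycles, and every
#' cycle of the no-intervention arm, use the background quit rate times
#' the same relative risk.  Results above 1 are clamped with a warning.
#'
#' @param base_quit Intervention quit rate (active arms) in \[0, 1\].
#' @param rr_quit_q Quintile relative risk of quitting (>= 0).
#' @param is_first_cycle Logical.
#' @param arm One of `"none"`, `"varenicline"`, `"ecigarette"`.
#' @param background_quit Background annual quit rate (default 0.02).
#' @return Probability in \[0, 1\].
#' @examples
#' annual_quit_probability(0.19, 1.0, TRUE, "varenicline")
#' annual_quit_probability(0.19, 1.36, FALSE, "varenicline")  # 0.02 * 1.36
#' @export
annual_quit_probability <- function(base_quit, rr_quit_q, is_first_cycle, arm,
                                    background_quit = 0.02) {
  arm <- match.arg(arm, ARMS)
  stopifnot(base_quit >= 0, base_quit <= 1, rr_quit_q >= 0)
  q <- if (is_first_cycle && arm != "none") base_quit * rr_quit_q
       else background_quit * rr_quit_q
  if (q > 1) {
    warning("quit probability ", signif(q, 4), " clamped to 1")
    q <- 1
  }
  q
}

# Per-quintile age-indexed inputs shared by all arms: mortality by state,
# utility by state, per-disease incidence, and the per-cycle expected
# event cost / disutility rates they imply.
precompute_quintile <- function(sample, ext, quintile,
                                disease_rr_mode = c("imd3_normalised", "raw")) {
  disease_rr_mode <- match.arg(disease_rr_mode)
  q <- match(quintile, IMD)
  if (is.na(q)) stop("unknown quintile: ", quintile)
  ages <- ext$ages
  all_cause <- ext$mortality[, q]
  props <- ext$status_props[, q, ]
  rr_svn <- sample$rr_death_svn[as.character(rr_band_svn(ages))]
  m_s <- smoker_mortality_rate(all_cause, props[, "smoker"], props[, "former"],
                               props[, "non"], sample$rr_death_svf, rr_svn)
  m_s <- pmin(m_s, 1)
  m_f <- pmin(m_s / sample$rr_death_svf, 1)

  rr_q <- sample$rr_disease[q]
  scale <- if (disease_rr_mode == "imd3_normalised")
    rr_q / sample$rr_disease[["IMD3"]] else rr_q
  inc <- ext$incidence * scale            # age x status x disease

  uloss_s <- as.numeric(inc[, "smoker", ] %*% sample$disutility)
  uloss_f <- as.numeric(inc[, "former", ] %*% sample$disutility)
  crate_s <- as.numeric(inc[, "smoker", ] %*% sample$cost_disease)
  crate_f <- as.numeric(inc[, "former", ] %*% sample$cost_disease)

  hr <- sample$hrqol
  imd_term <- if (q == 1) 0 else hr[[paste0("imd", q)]]
  base_u <- hr[["constant"]] + hrqol_age_term(ages, hr) + imd_term
  util_s <- base_u + hr[["smoker"]]
  util_f <- base_u
  if (any(util_s < -1 | util_s > 1 | util_f < -1 | util_f > 1))
    warning("HRQoL utility outside [-1, 1] for quintile ", quintile,
            "; values retained")

  list(ages = ages, m_s = m_s, m_f = m_f,
       util_s = util_s, util_f = util_f,
       uloss_s = uloss_s, uloss_f = uloss_f,
       crate_s = crate_s, crate_f = crate_f,
       incidence = inc)
}

arm_quit_first <- function(sample, arm) {
  switch(arm,
    none = sample$settings$background_quit,
    varenicline = sample$quit_rate[["varenicline"]],
    ecigarette = sample$quit_rate[["ecigarette"]])
}

arm_unit_cost <- function(sample, arm) {
  switch(arm, none = 0,
    varenicline = sample$cost_intervention[["varenicline"]],
    ecigarette = sample$cost_intervention[["ecigarette"]])
}

#' Run the cohort trace for one entry age
#'
#' Reference implementation for a single cohort: explicit per-cycle loop
#' recording state occupancy, expected disease events, and discounted
#' QALY and cost accruals.  The fast path used by the PSA
#' ([per_smoker_lifetime_outcomes()]) is vectorised over entry ages and
#' is cross-checked against this trace in the test suite.
#'
#' @param sample A `parameter_sample`.
#' @param ext An `external_inputs` bundle.
#' @param quintile `"IMD1"` .. `"IMD5"`.
#' @param arm `"none"`, `"varenicline"` or `"ecigarette"`.
#' @param entry_age Entry age (within the settings' entrant range).
#' @param disease_rr_mode `"imd3_normalised"` (incidence represents IMD3;
#'   quintile relative risks are rescaled so IMD3 reproduces the base) or
#'   `"raw"`.
#' @return An object of class `cohort_trace`: data frame `trace` with
#'   per-cycle occupancies, accruals and per-disease events, and `totals`
#'   (discounted QALYs and costs per entering smoker).
#' @export
run_cohort_trace <- function(sample, ext, quintile, arm = "none",
                             entry_age = 40,
                             disease_rr_mode = c("imd3_normalised", "raw")) {
  arm <- match.arg(arm, ARMS)
  st <- sample$settings
  stopifnot(entry_age >= min(st$entry_ages), entry_age <= max(st$entry_ages))
  pre <- precompute_quintile(sample, ext, quintile, disease_rr_mode)
  r <- st$discount_rate
  q0 <- st$background_quit
  rrq <- sample$rr_quit[[quintile]]
  quit_first <- arm_quit_first(sample, arm)

  n_cyc <- st$age_cap - entry_age
  S <- 1; Fo <- 0; D <- 0
  rows <- vector("list", n_cyc)
  ev <- matrix(0, n_cyc, 6, dimnames = list(NULL, DISEASES))
  tot_qaly <- 0; tot_cost <- 0
  for (t in 0:(n_cyc - 1)) {
    age <- entry_age + t
    i <- age_idx(age)
    df <- (1 + r)^(-t)
    q_t <- annual_quit_probability(quit_first, rrq, t == 0, arm, q0)
    events <- S * pre$incidence[i, "smoker", ] + Fo * pre$incidence[i, "former", ]
    qaly <- df * (S * (pre$util_s[i] - pre$uloss_s[i]) +
                  Fo * (pre$util_f[i] - pre$uloss_f[i]))
    cost <- df * (S * pre$crate_s[i] + Fo * pre$crate_f[i])
    if (t == 0) cost <- cost + df * arm_unit_cost(sample, arm)
    ev[t + 1, ] <- events
    rows[[t + 1]] <- data.frame(cycle = t, age = age, smoker = S, former = Fo,
                                dead = D, qaly = qaly, cost = cost)
    tot_qaly <- tot_qaly + qaly; tot_cost <- tot_cost + cost
    S_new <- S * (1 - q_t) * (1 - pre$m_s[i])
    F_new <- (Fo + S * q_t) * (1 - pre$m_f[i])
    D <- D + S * (1 - q_t) * pre$m_s[i] + (Fo + S * q_t) * pre$m_f[i]
    S <- S_new; Fo <- F_new
  }
  trace <- do.call(rbind, rows)
  trace <- cbind(trace, ev)
  structure(list(trace = trace, quintile = quintile, arm = arm,
                 entry_age = entry_age,
                 totals = c(qaly = unname(tot_qaly), cost = unname(tot_cost))),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("<cohort_trace: %s, %s, entry age %d, %d cycles>\n",
              x$quintile, x$arm, x$entry_age, nrow(x$trace)))
  cat(sprintf("  discounted per smoker: %.4f QALYs, £%.2f\n",
              x$totals[["qaly"]], x$totals[["cost"]]))
  invisible(x)
}

#' Export a cohort trace as a tidy CSV
#'
#' Long format with columns `cycle`, `state`, `occupancy`, `disease`,
#' `events`, `cost`, `qaly` (state rows carry occupancy; disease rows
#' carry events; accruals repeat on the first state row of the cycle).
#'
#' @param x A `cohort_trace`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_trace <- function(x, path) {
  tr <- x$trace
  state_rows <- do.call(rbind, lapply(c("smoker", "former", "dead"), function(s)
    data.frame(cycle = tr$cycle, state = s, occupancy = tr[[s]],
               disease = NA, events = NA,
               cost = ifelse(s == "smoker", tr$cost, NA),
               qaly = ifelse(s == "smoker", tr$qaly, NA))))
  dis_rows <- do.call(rbind, lapply(DISEASES, function(d)
    data.frame(cycle = tr$cycle, state = NA, occupancy = NA,
               disease = d, events = tr[[d]], cost = NA, qaly = NA)))
  out <- rbind(state_rows, dis_rows)
  out <- out[order(out$cycle), ]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

# Vectorised engine: discounted (QALY, cost) per entering smoker for every
# entry age at once.  Exactly the per-age loop of run_cohort_trace, with
# entry ages as a vector dimension.
cohort_engine_all_ages <- function(pre, sample, arm, quintile) {
  st <- sample$settings
  entry <- st$entry_ages
  r <- st$discount_rate
  rrq <- sample$rr_quit[[quintile]]
  q_first <- min(arm_quit_first(sample, arm) * rrq, 1)
  q_later <- min(st$background_quit * rrq, 1)
  if (arm == "none") q_first <- q_later
  c_int <- arm_unit_cost(sample, arm)

  nE <- length(entry)
  S <- rep(1, nE); Fo <- rep(0, nE)
  qaly <- numeric(nE); cost <- numeric(nE)
  max_t <- st$age_cap - min(entry)
  for (t in 0:(max_t - 1)) {
    age <- entry + t
    alive <- age < st$age_cap
    if (!any(alive)) break
    i <- age_idx(age)
    df <- (1 + r)^(-t)
    q_t <- if (t == 0) q_first else q_later
    gs <- (pre$util_s[i] - pre$uloss_s[i]); gf <- (pre$util_f[i] - pre$uloss_f[i])
    qaly <- qaly + df * alive * (S * gs + Fo * gf)
    cost <- cost + df * alive * (S * pre$crate_s[i] + Fo * pre$crate_f[i])
    if (t == 0) cost <- cost + df * c_int
    S_new <- S * (1 - q_t) * (1 - pre$m_s[i])
    F_new <- (Fo + S * q_t) * (1 - pre$m_f[i])
    S <- ifelse(alive, S_new, S)
    Fo <- ifelse(alive, F_new, Fo)
  }
  list(qaly = qaly, cost = cost)
}

entry_age_weights <- function(settings) {
  w <- settings$entry_age_weights
  if (is.null(w)) w <- rep(1, length(settings$entry_ages))
  if (length(w) != length(settings$entry_ages))
    stop("entry_age_weights must match entry_ages in length")
  if (sum(w) <= 0) stop("entrant age distribution is empty")
  w / sum(w)
}

#' Discounted lifetime outcomes per entering smoker
#'
#' Entrant-age-distribution-weighted average (uniform over 18-75 by
#' default) of per-entry-age discounted QALY and cost totals.
#'
#' @inheritParams run_cohort_trace
#' @return Named numeric: `qaly`, `cost`.
#' @export
per_smoker_lifetime_outcomes <- function(sample, ext, quintile, arm = "none",
                                         disease_rr_mode = c("imd3_normalised",
                                                             "raw")) {
  arm <- match.arg(arm, ARMS)
  pre <- precompute_quintile(sample, ext, quintile, disease_rr_mode)
  out <- cohort_engine_all_ages(pre, sample, arm, quintile)
  w <- entry_age_weights(sample$settings)
  c(qaly = sum(w * out$qaly), cost = sum(w * out$cost))
}

#' Per-smoker outcomes for every quintile and arm
#'
#' Shared precomputation across the three arms of one parameter sample;
#' used by the PSA loop.
#'
#' @inheritParams run_cohort_trace
#' @return A 5 x 3 x 2 array (quintile x arm x \{qaly, cost\}).
#' @export
per_smoker_outcomes_all <- function(sample, ext,
                                    disease_rr_mode = c("imd3_normalised",
                                                        "raw")) {
  disease_rr_mode <- match.arg(disease_rr_mode)
  w <- entry_age_weights(sample$settings)
  out <- array(NA_real_, dim = c(5, 3, 2),
               dimnames = list(quintile = IMD, arm = ARMS,
                               outcome = c("qaly", "cost")))
  for (q in IMD) {
    pre <- precompute_quintile(sample, ext, q, disease_rr_mode)
    for (arm in ARMS) {
      res <- cohort_engine_all_ages(pre, sample, arm, q)
      out[q, arm, "qaly"] <- sum(w * res$qaly)
      out[q, arm, "cost"] <- sum(w * res$cost)
    }
  }
  out
}

#' Population-scaled outcomes for one arm
#'
#' The number of smokers in quintile q is `N w_q pi_q`; in an active arm
#' the treated count is additionally scaled by the quintile uptake rate,
#' and only the treated incur the intervention's incremental per-smoker
#' outcomes (non-uptakers contribute the no-intervention outcome and no
#' intervention cost).
#'
#' @inheritParams run_cohort_trace
#' @param per_smoker Optional precomputed [per_smoker_outcomes_all()] array.
#' @return An object of class `arm_outcome`: per-quintile population
#'   discounted QALYs and costs plus smoker and treated counts.
#' @export
population_arm_outcomes <- function(sample, ext, arm = "none",
                                    per_smoker = NULL,
                                    disease_rr_mode = c("imd3_normalised",
                                                        "raw")) {
  arm <- match.arg(arm, ARMS)
  st <- sample$settings
  if (abs(sum(st$quintile_shares) - 1) > 1e-9)
    stop("quintile shares must sum to 1")
  if (is.null(per_smoker))
    per_smoker <- per_smoker_outcomes_all(sample, ext, disease_rr_mode)
  smokers <- st$population * st$quintile_shares * sample$prevalence
  if (arm == "none") {
    treated <- rep(0, 5)
    qalys <- smokers * per_smoker[, "none", "qaly"]
    costs <- smokers * per_smoker[, "none", "cost"]
  } else {
    treated <- smokers * sample$uptake
    qalys <- smokers * per_smoker[, "none", "qaly"] +
      treated * (per_smoker[, arm, "qaly"] - per_smoker[, "none", "qaly"])
    costs <- smokers * per_smoker[, "none", "cost"] +
      treated * (per_smoker[, arm, "cost"] - per_smoker[, "none", "cost"])
  }
  structure(list(arm = arm, qalys = stats::setNames(qalys, IMD),
                 costs = stats::setNames(costs, IMD),
                 smokers = stats::setNames(smokers, IMD),
                 treated = stats::setNames(treated, IMD)),
            class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("<arm_outcome: %s>\n", x$arm))
  print(data.frame(quintile = IMD, qalys = x$qalys, costs = x$costs,
                   row.names = NULL))
  invisible(x)
}
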