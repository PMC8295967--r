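#' Synthetic external input tables
#'
#' The cohort model consumes several inputs that the published tables do
#' not print: all-cause mortality by age and deprivation quintile,
#' smoking-status proportions by age and quintile, smoking-related
#' disease incidence by age and smoking status, baseline
#' quality-adjusted life expectancy (QALE) per quintile, the quintile
#' shares of health opportunity costs, the Atkinson inequality-aversion
#' parameter, and the HRQoL coefficient covariance.  This generator
#' emulates them with documented, deterministic constructions so the
#' whole pipeline runs offline; every table is flagged synthetic.
#'
#' Construction: mortality follows a Gompertz curve with a multiplicative
#' deprivation gradient (most deprived highest), mildly jittered by the
#' seed and made monotone in age by a running maximum; smoking-status
#' proportions scale the national prevalence gradient with an age profile
#' in which current smoking declines and former smoking rises after
#' midlife; disease incidence is exponential in age per disease with
#' former smokers at half the smoker rate; opportunity-cost shares fall
#' from the most to the least deprived quintile; baseline QALE rises from
#' the most to the least deprived quintile.
#'
#' Scenarios: `"default"` as above; `"flat"` removes every quintile
#' gradient (equal mortality, proportions, shares and QALE across
#' quintiles) and is used by symmetry tests; `"steep_gradient"` widens
#' the gradients.
#'
#' @param seed Integer seed; the tables are deterministic given the seed.
#' @param scenario `"default"`, `"flat"` or `"steep_gradient"`.
#' @return An object of class `external_inputs`: list with elements
#'   `ages` (18:100), `mortality` (age x quintile matrix of annual
#'   rates), `status_props` (age x quintile x status array over
#'   smoker/former/non), `incidence` (age x status x disease array,
#'   statuses smoker/former), `qale` (per-person baseline QALE by
#'   quintile), `opp_cost_shares`, `epsilon`, `scenario`, `seed`, and a
#'   `provenance` flag.
#' @examples
#' ext <- generate_external_inputs(seed = 1)
#' ext$opp_cost_shares
#' @export
generate_external_inputs <- function(seed = 1L,
                                     scenario = c("default", "flat",
                                                  "steep_gradient")) {
  scenario <- match.arg(scenario)
  ages <- 18:100
  n_age <- length(ages)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  q_mult <- switch(scenario,
    default = c(1.35, 1.15, 1.00, 0.90, 0.80),
    flat = rep(1, 5),
    steep_gradient = c(1.80, 1.35, 1.00, 0.75, 0.55))

  # Gompertz-like all-cause mortality with mild seeded jitter, monotone in
  # age by construction.
  base_mort <- 3e-5 * exp(0.090 * (ages - 18) + 1.62)
  jitter <- exp(stats::rnorm(n_age, 0, 0.02))
  mortality <- vapply(q_mult, function(m) {
    r <- pmin(base_mort * jitter * m, 0.95)
    cummax(r)
  }, numeric(n_age))
  dimnames(mortality) <- list(age = ages, quintile = IMD)

  # Smoking-status proportions (current / former / never): prevalence
  # gradient from the printed national table, age profile declining in
  # current smoking and rising in former smoking.
  prev_mean <- vapply(table1_constants()$prevalence,
                      function(p) p$shape1 / (p$shape1 + p$shape2), numeric(1))
  prev_q <- switch(scenario,
    default = prev_mean,
    flat = rep(prev_mean[["IMD3"]], 5),
    steep_gradient = prev_mean * c(1.4, 1.2, 1.0, 0.85, 0.7))
  age_shape_s <- ifelse(ages <= 60, 1, pmax(0.4, 1 - 0.012 * (ages - 60)))
  age_shape_f <- pmin(0.15 + 0.004 * (ages - 18), 0.5)
  status_props <- array(0, dim = c(n_age, 5, 3),
                        dimnames = list(age = ages, quintile = IMD,
                                        status = c("smoker", "former", "non")))
  for (q in 1:5) {
    ps <- prev_q[q] * age_shape_s
    pf <- age_shape_f
    status_props[, q, "smoker"] <- ps
    status_props[, q, "former"] <- pf
    status_props[, q, "non"] <- 1 - ps - pf
  }

  # Disease incidence for smokers; former smokers at half the rate.
  inc_base <- c(lung_cancer = 2e-4, chd = 1e-3, copd = 8e-4,
                mi = 6e-4, stroke = 5e-4, asthma_ex = 2e-3)
  inc_slope <- c(lung_cancer = 0.07, chd = 0.05, copd = 0.06,
                 mi = 0.05, stroke = 0.06, asthma_ex = 0.00)
  incidence <- array(0, dim = c(n_age, 2, 6),
                     dimnames = list(age = ages, status = c("smoker", "former"),
                                     disease = DISEASES))
  inc_jitter <- exp(stats::rnorm(6, 0, 0.05))
  for (d in seq_along(DISEASES)) {
    r <- pmin(inc_base[d] * inc_jitter[d] * exp(inc_slope[d] * (ages - 40)), 0.3)
    incidence[, "smoker", d] <- r
    incidence[, "former", d] <- 0.5 * r
  }

  qale <- switch(scenario,
    default = c(62, 65, 68, 71, 74),
    flat = rep(68, 5),
    steep_gradient = c(55, 61, 67, 73, 79))
  names(qale) <- IMD

  shares <- switch(scenario,
    default = c(0.30, 0.25, 0.20, 0.15, 0.10),
    flat = rep(0.2, 5),
    steep_gradient = c(0.40, 0.25, 0.15, 0.12, 0.08))
  names(shares) <- IMD

  structure(list(
    ages = ages,
    mortality = mortality,
    status_props = status_props,
    incidence = incidence,
    qale = qale,
    opp_cost_shares = shares,
    epsilon = 10.95,
    scenario = scenario,
    seed = seed,
    provenance = "synthetic"
  ), class = "external_inputs")
}

#' @export
print.external_inputs <- function(x, ...) {
  cat(sprintf("<external_inputs: scenario %s, seed %d, ages %d-%d (synthetic)>\n",
              x$scenario, x$seed, min(x$ages), max(x$ages)))
  invisible(x)
}

#' Export the synthetic external tables as CSV files plus a manifest
#'
#' Writes one CSV per table (`mortality.csv`, `status_props.csv`,
#' `incidence.csv`, `quintile_summary.csv`) and a `manifest.yaml`
#' recording seed, scenario and the synthetic provenance flag.
#'
#' @param ext An [generate_external_inputs()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_external_inputs <- function(ext, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mort <- as.data.frame.table(ext$mortality, responseName = "rate")
  utils::write.csv(mort, file.path(dir, "mortality.csv"), row.names = FALSE)
  sp <- as.data.frame.table(ext$status_props, responseName = "proportion")
  utils::write.csv(sp, file.path(dir, "status_props.csv"), row.names = FALSE)
  inc <- as.data.frame.table(ext$incidence, responseName = "incidence")
  utils::write.csv(inc, file.path(dir, "incidence.csv"), row.names = FALSE)
  qs <- data.frame(quintile = IMD, qale = ext$qale,
                   opp_cost_share = ext$opp_cost_shares)
  utils::write.csv(qs, file.path(dir, "quintile_summary.csv"), row.names = FALSE)
  writeLines(yaml::as.yaml(list(seed = ext$seed, scenario = ext$scenario,
                                epsilon = ext$epsilon,
                                provenance = ext$provenance)),
             file.path(dir, "manifest.yaml"))
  invisible(dir)
}
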