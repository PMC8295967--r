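#' Assemble a parameter book from the shipped fixture tables
#'
#' A parameter book holds every uncertain model input as a [dist_spec()]
#' plus the fixed analysis settings (discount rate, background quit rate,
#' cost-effectiveness threshold, population size and quintile shares).
#'
#' `region = "england"` uses the printed national table verbatim.  For
#' `"york"` and `"sheffield"` the smoking prevalence comes from the
#' printed local-authority means and 95% confidence intervals, converted
#' to Beta distributions by moment matching with a normal-approximation
#' standard error; all other inputs are inherited from England.
#'
#' `scenario = "flat"` removes every cross-quintile gradient: prevalence
#' and uptake are fixed at their IMD3 values for all quintiles, the
#' relative risks of disease and of quitting are fixed at 1, the HRQoL
#' deprivation coefficients have mean 0 and zero variance, and quintile
#' shares are equal.  With no gradient in either the book or the external
#' tables, the inequality impact iEDE - iNHB is identically zero, which
#' the test suite exploits.
#'
#' @param region `"england"`, `"york"` or `"sheffield"`.
#' @param scenario `"default"` or `"flat"`.
#' @param hrqol_rho Exchangeable correlation used to construct the
#'   synthetic HRQoL coefficient covariance (see [hrqol_covariance()]).
#' @return An object of class `parameter_book`.
#' @examples
#' book <- fixture_parameter_book("england")
#' distribution_summary(book$prevalence$IMD1)$mean
#' @export
fixture_parameter_book <- function(region = c("england", "york", "sheffield"),
                                   scenario = c("default", "flat"),
                                   hrqol_rho = 0.2) {
  region <- match.arg(region)
  scenario <- match.arg(scenario)
  t1 <- table1_constants()
  costs <- synthetic_cost_constants()

  prevalence <- lapply(t1$prevalence, function(p)
    dist_spec("beta", shape1 = p$shape1, shape2 = p$shape2))
  if (region != "england") {
    t2 <- table2_constants()[[region]]
    prevalence <- lapply(t2, function(row) {
      m <- row[["mean"]] / 100
      se <- (row[["hi"]] - row[["lo"]]) / 100 / (2 * stats::qnorm(0.975))
      beta_from_mean_se(m, se)
    })
  }

  rr_death_svn <- lapply(t1$rr_death_svn, function(p)
    dist_spec("lognormal", lm = p$lm, lv = p$lv))
  rr_death_svf <- dist_spec("lognormal", lm = t1$rr_death_svf$lm,
                            lv = t1$rr_death_svf$lv)
  rr_disease <- lapply(t1$rr_disease, function(p) {
    if (is.null(p$lm)) dist_spec("fixed", value = p$mean)
    else dist_spec("lognormal", lm = p$lm, lv = p$lv)
  })
  rr_quit <- lapply(t1$rr_quit, function(p) {
    if (is.null(p$lm)) dist_spec("fixed", value = p$mean)
    else dist_spec("lognormal", lm = p$lm, lv = p$lv)
  })
  uptake <- lapply(t1$uptake, function(p)
    dist_spec("beta", shape1 = p$shape1, shape2 = p$shape2))

  hrqol_mean <- t1$hrqol_coef
  hrqol <- dist_spec("mvnormal", mean = hrqol_mean,
                     sigma = hrqol_covariance(hrqol_mean, rho = hrqol_rho))

  quintile_shares <- region_quintile_shares(region)

  if (scenario == "flat") {
    m3 <- distribution_summary(prevalence$IMD3)$mean
    prevalence <- stats::setNames(
      rep(list(dist_spec("fixed", value = m3)), 5), IMD)
    u3 <- distribution_summary(uptake$IMD3)$mean
    uptake <- stats::setNames(rep(list(dist_spec("fixed", value = u3)), 5), IMD)
    rr_disease <- stats::setNames(
      rep(list(dist_spec("fixed", value = 1)), 5), IMD)
    rr_quit <- stats::setNames(rep(list(dist_spec("fixed", value = 1)), 5), IMD)
    hrqol_mean[c("imd2", "imd3", "imd4", "imd5")] <- 0
    se <- hrqol_se(hrqol_mean)
    se[c("imd2", "imd3", "imd4", "imd5")] <- 0
    hrqol <- dist_spec("mvnormal", mean = hrqol_mean,
                       sigma = hrqol_covariance(hrqol_mean, rho = hrqol_rho,
                                                se = se))
    quintile_shares <- stats::setNames(rep(0.2, 5), IMD)
  }

  book <- structure(list(
    settings = list(
      region = region,
      scenario = scenario,
      discount_rate = 0.035,
      background_quit = 0.02,
      threshold = 20000,
      population = region_population(region),
      quintile_shares = quintile_shares,
      entry_ages = 18:75,
      age_cap = 100
    ),
    prevalence = prevalence,
    mortality_rr = c(rr_death_svn = list(rr_death_svn),
                     rr_death_svf = list(rr_death_svf)),
    disease_rr = rr_disease,
    hrqol = hrqol,
    effectiveness = list(
      quit_varenicline = dist_spec("beta", shape1 = t1$quit_varenicline$shape1,
                                   shape2 = t1$quit_varenicline$shape2),
      quit_ecigarette = dist_spec("beta", shape1 = t1$quit_ecigarette$shape1,
                                  shape2 = t1$quit_ecigarette$shape2),
      rr_quit = rr_quit
    ),
    uptake = uptake,
    costs = list(
      intervention = lapply(costs$cost_intervention, function(m)
        gamma_from_mean_se(m, 0.1 * m)),
      disease = lapply(costs$cost_disease, function(m)
        gamma_from_mean_se(m, 0.1 * m))
    ),
    disutilities = lapply(costs$disutility, function(m)
      gamma_from_mean_se(m, 0.1 * m)),
    meta = list(cost_provenance = "synthetic",
                prevalence_provenance =
                  if (region == "england") "printed" else "printed-ci")
  ), class = "parameter_book")
  validate_parameter_book(book)
  book
}

# Synthetic HRQoL coefficient standard errors: 10% of |coefficient| with a
# floor of 0.005 (the published variance-covariance matrix is not printed).
hrqol_se <- function(coef) pmax(0.1 * abs(coef), 0.005)

#' Synthetic covariance for the HRQoL regression coefficients
#'
#' The published regression's variance-covariance matrix is not printed,
#' but correlated draws via its Cholesky factor are part of the method.
#' This builds a positive-semidefinite stand-in as `D R D`: `D` holds
#' coefficient standard errors of 10% of the absolute coefficient (floor
#' 0.005, overridable) and `R` is an exchangeable correlation matrix.
#'
#' @param coef Named coefficient vector.
#' @param rho Exchangeable correlation in (-1/(p-1), 1).
#' @param se Optional vector of standard errors overriding the default.
#' @return A symmetric PSD matrix with dimnames from `coef`.
#' @export
hrqol_covariance <- function(coef, rho = 0.2, se = NULL) {
  p <- length(coef)
  if (is.null(se)) se <- hrqol_se(coef)
  stopifnot(length(se) == p, all(se >= 0), rho > -1 / (p - 1), rho < 1)
  R <- matrix(rho, p, p); diag(R) <- 1
  sigma <- diag(se, p) %*% R %*% diag(se, p)
  dimnames(sigma) <- list(names(coef), names(coef))
  sigma
}

validate_parameter_book <- function(book) {
  s <- book$settings
  if (abs(sum(s$quintile_shares) - 1) > 1e-9)
    stop("quintile shares must sum to 1")
  stopifnot(s$discount_rate >= 0, s$discount_rate < 1,
            s$threshold > 0, s$population > 0,
            all(s$entry_ages >= 18), all(s$entry_ages <= 75),
            s$age_cap > 75)
  need <- function(x, nm) {
    if (!all(nm %in% names(x)))
      stop("parameter book missing entries: ",
           paste(setdiff(nm, names(x)), collapse = ", "))
  }
  need(book$prevalence, IMD); need(book$disease_rr, IMD)
  need(book$effectiveness$rr_quit, IMD); need(book$uptake, IMD)
  need(book$mortality_rr$rr_death_svn, AGE_BANDS_RR)
  # reference levels are fixed, never sampled
  if (book$effectiveness$rr_quit$IMD1$family != "fixed")
    stop("rr_quit IMD1 must be a fixed reference")
  if (book$disease_rr$IMD5$family != "fixed")
    stop("disease_rr IMD5 must be a fixed reference")
  invisible(book)
}

#' @export
print.parameter_book <- function(x, ...) {
  s <- x$settings
  cat(sprintf("<parameter_book: %s, scenario %s>\n", s$region, s$scenario))
  cat(sprintf("  population %s, threshold £%s/QALY, discount %.1f%%\n",
              format(s$population, big.mark = ","),
              format(s$threshold, big.mark = ","), 100 * s$discount_rate))
  invisible(x)
}

# --- sampling -------------------------------------------------------------

clamp_track <- function(x, lo, hi, counter_env, what) {
  out <- pmin(pmax(x, lo), hi)
  n_clamped <- sum(out != x)
  if (n_clamped > 0) {
    counter_env$n <- counter_env$n + n_clamped
    counter_env$where <- c(counter_env$where, what)
  }
  out
}

#' Draw one joint parameter sample from a book
#'
#' Every uncertain quantity is drawn independently from its assigned
#' family, except the HRQoL regression coefficients, which are drawn
#' jointly via a Cholesky-type factor of their covariance.  Sampled
#' probabilities are truncated to \[0, 1\] and relative risks to
#' (0, Inf); truncation events are counted in the `truncations`
#' attribute.  Reproducible: set the RNG seed before calling.
#'
#' @param book A [fixture_parameter_book()] or compatible book.
#' @return An object of class `parameter_sample`: named numeric vectors
#'   per block plus the book's settings.
#' @examples
#' set.seed(1)
#' s <- draw_sample(fixture_parameter_book("england"))
#' s$prevalence
#' @export
draw_sample <- function(book) {
  stopifnot(inherits(book, "parameter_book"))
  cnt <- new.env(); cnt$n <- 0L; cnt$where <- character()
  dr <- function(spec) draw_dist(spec)
  drawv <- function(specs) vapply(specs, dr, numeric(1))

  prevalence <- clamp_track(drawv(book$prevalence), 0, 1, cnt, "prevalence")
  rr_death_svn <- clamp_track(drawv(book$mortality_rr$rr_death_svn),
                              .Machine$double.xmin, Inf, cnt, "rr_death_svn")
  rr_death_svf <- clamp_track(dr(book$mortality_rr$rr_death_svf),
                              .Machine$double.xmin, Inf, cnt, "rr_death_svf")
  rr_disease <- clamp_track(drawv(book$disease_rr),
                            .Machine$double.xmin, Inf, cnt, "rr_disease")
  hrqol <- stats::setNames(dr(book$hrqol), names(book$hrqol$params$mean))
  quit <- clamp_track(
    c(varenicline = dr(book$effectiveness$quit_varenicline),
      ecigarette = dr(book$effectiveness$quit_ecigarette)),
    0, 1, cnt, "quit_rate")
  rr_quit <- clamp_track(drawv(book$effectiveness$rr_quit),
                         .Machine$double.xmin, Inf, cnt, "rr_quit")
  uptake <- clamp_track(drawv(book$uptake), 0, 1, cnt, "uptake")
  cost_intervention <- drawv(book$costs$intervention)
  cost_disease <- drawv(book$costs$disease)
  disutility <- drawv(book$disutilities)

  structure(list(
    prevalence = prevalence,
    rr_death_svn = rr_death_svn,
    rr_death_svf = rr_death_svf,
    rr_disease = rr_disease,
    hrqol = hrqol,
    quit_rate = quit,
    rr_quit = rr_quit,
    uptake = uptake,
    cost_intervention = cost_intervention,
    cost_disease = cost_disease,
    disutility = disutility,
    settings = book$settings
  ), class = "parameter_sample",
     truncations = list(n = cnt$n, where = unique(cnt$where)))
}

#' Resolve a book to its expected values (deterministic base case)
#'
#' Every distribution is replaced by its analytic mean (the HRQoL block by
#' its mean vector), giving the deterministic base-case input set.
#'
#' @inheritParams draw_sample
#' @return A `parameter_sample` with all values at their means.
#' @export
base_case_sample <- function(book) {
  stopifnot(inherits(book, "parameter_book"))
  m <- function(spec) distribution_summary(spec)$mean
  mv <- function(specs) vapply(specs, m, numeric(1))
  structure(list(
    prevalence = mv(book$prevalence),
    rr_death_svn = mv(book$mortality_rr$rr_death_svn),
    rr_death_svf = m(book$mortality_rr$rr_death_svf),
    rr_disease = mv(book$disease_rr),
    hrqol = stats::setNames(m(book$hrqol), names(book$hrqol$params$mean)),
    quit_rate = c(varenicline = m(book$effectiveness$quit_varenicline),
                  ecigarette = m(book$effectiveness$quit_ecigarette)),
    rr_quit = mv(book$effectiveness$rr_quit),
    uptake = mv(book$uptake),
    cost_intervention = mv(book$costs$intervention),
    cost_disease = mv(book$costs$disease),
    disutility = mv(book$disutilities),
    settings = book$settings
  ), class = "parameter_sample", truncations = list(n = 0L, where = character()))
}

# Column names of the sampled scalars, by variance-decomposition group.
# Fixed references and zero-variance coordinates are excluded.
#' Parameter-group layout of the sampled inputs
#'
#' Returns the named list of input-matrix column names per parameter
#' group.  The groups mirror the variance-decomposition axis of the
#' published sensitivity analysis: smoking prevalence, RR of death, RR of
#' disease, HRQoL coefficients, average quit rates, RR of quitting by
#' IMD, uptake rates by IMD, costs, and disutilities.
#'
#' @param book A `parameter_book`.
#' @return Named list of character vectors of column names.
#' @export
parameter_groups <- function(book) {
  nonfixed <- function(specs, prefix) {
    keep <- vapply(specs, function(s) s$family != "fixed", logical(1))
    if (!any(keep)) return(character(0))
    paste0(prefix, names(specs)[keep])
  }
  hr_sd <- sqrt(diag(book$hrqol$params$sigma))
  groups <- list(
    prevalence   = nonfixed(book$prevalence, "prevalence_"),
    rr_death     = c(nonfixed(book$mortality_rr$rr_death_svn, "rr_death_svn_"),
                     "rr_death_svf"),
    rr_disease   = nonfixed(book$disease_rr, "rr_disease_"),
    hrqol        = paste0("hrqol_", names(book$hrqol$params$mean)[hr_sd > 0]),
    quit_rates   = c("quit_varenicline", "quit_ecigarette"),
    rr_quit      = nonfixed(book$effectiveness$rr_quit, "rr_quit_"),
    uptake       = nonfixed(book$uptake, "uptake_"),
    costs        = c(paste0("cost_int_", names(book$costs$intervention)),
                     paste0("cost_", names(book$costs$disease))),
    disutilities = paste0("disutil_", names(book$disutilities))
  )
  groups[vapply(groups, length, integer(1)) > 0]
}

#' Flatten a parameter sample to a named numeric vector
#'
#' One scalar per sampled input, in the column layout of
#' [parameter_groups()]; this is the row format of the PSA input matrix
#' consumed by the value-of-information and ANCOVA stages.
#'
#' @param sample A `parameter_sample`.
#' @param book The book it was drawn from (defines which inputs are sampled).
#' @return Named numeric vector.
#' @export
flatten_parameter_sample <- function(sample, book) {
  vals <- c(
    stats::setNames(sample$prevalence, paste0("prevalence_", names(sample$prevalence))),
    stats::setNames(sample$rr_death_svn, paste0("rr_death_svn_", names(sample$rr_death_svn))),
    rr_death_svf = unname(sample$rr_death_svf),
    stats::setNames(sample$rr_disease, paste0("rr_disease_", names(sample$rr_disease))),
    stats::setNames(sample$hrqol, paste0("hrqol_", names(sample$hrqol))),
    quit_varenicline = unname(sample$quit_rate[["varenicline"]]),
    quit_ecigarette = unname(sample$quit_rate[["ecigarette"]]),
    stats::setNames(sample$rr_quit, paste0("rr_quit_", names(sample$rr_quit))),
    stats::setNames(sample$uptake, paste0("uptake_", names(sample$uptake))),
    stats::setNames(sample$cost_intervention,
                    paste0("cost_int_", names(sample$cost_intervention))),
    stats::setNames(sample$cost_disease, paste0("cost_", names(sample$cost_disease))),
    stats::setNames(sample$disutility, paste0("disutil_", names(sample$disutility)))
  )
  keep <- unlist(parameter_groups(book), use.names = FALSE)
  vals[keep]
}

# --- book file round trip -------------------------------------------------

spec_to_list <- function(spec) {
  p <- spec$params
  if (spec$family == "mvnormal")
    p <- list(mean = as.list(p$mean),
              sigma = apply(unname(p$sigma), 1, as.list, simplify = FALSE))
  c(list(family = spec$family), p)
}

list_to_spec <- function(x) {
  if (x$family == "mvnormal") {
    mean <- unlist(x$mean)
    sigma <- do.call(rbind, lapply(x$sigma, unlist))
    dimnames(sigma) <- list(names(mean), names(mean))
    return(dist_spec("mvnormal", mean = mean, sigma = sigma))
  }
  do.call(dist_spec, c(list(family = x$family), x[setdiff(names(x), "family")]))
}

#' Write / read a parameter book as a YAML file
#'
#' The file has sections `settings`, `prevalence`, `mortality_rr`,
#' `disease_rr`, `hrqol`, `effectiveness`, `uptake`, `costs`,
#' `disutilities` and `meta`; each uncertain entry is
#' `{family, <family parameters>}`.  Numbers are written with 17
#' significant digits so the round trip is exact.
#'
#' @param book A `parameter_book`.
#' @param path File path.
#' @return `write_parameter_book` returns `path` invisibly;
#'   `read_parameter_book` returns a `parameter_book`.
#' @export
write_parameter_book <- function(book, path) {
  as_plain <- function(x) {
    if (inherits(x, "dist_spec")) return(spec_to_list(x))
    if (is.list(x)) return(lapply(x, as_plain))
    x
  }
  obj <- as_plain(unclass(book))
  obj$settings$entry_ages <- as.integer(obj$settings$entry_ages)
  obj$settings$quintile_shares <- as.list(obj$settings$quintile_shares)
  handlers <- list(numeric = function(x) {
    r <- formatC(x, format = "e", digits = 17)   # YAML-parsable float syntax
    class(r) <- "verbatim"
    r
  })
  writeLines(yaml::as.yaml(obj, handlers = handlers), path)
  invisible(path)
}

#' @rdname write_parameter_book
#' @export
read_parameter_book <- function(path) {
  obj <- yaml::read_yaml(path)
  from_plain <- function(x) {
    if (is.list(x) && !is.null(x$family)) return(list_to_spec(x))
    if (is.list(x)) return(lapply(x, from_plain))
    x
  }
  book <- lapply(obj, from_plain)
  book$settings$quintile_shares <- unlist(book$settings$quintile_shares)
  book$settings$entry_ages <- as.integer(unlist(book$settings$entry_ages))
  class(book) <- "parameter_book"
  validate_parameter_book(book)
  book
}
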