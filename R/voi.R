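#' Payoff matrices for value-of-information analysis
#'
#' A payoff matrix holds, per PSA iteration, the payoff of each decision
#' option on a common scale (here monetised £ at the threshold).  Two
#' framings are built from a pairwise comparison: the *health* framing
#' pays `{0, k * iNHB}` (the value of choosing the first-named arm over
#' the comparator in overall health), and the *equity* framing pays
#' `{0, k * (iEDE - iNHB)}` (the value in inequality reduction).  The
#' builder is deliberately a small, swappable function: any
#' iteration-by-decision matrix on a common scale works.
#'
#' @param psa A `psa_result`.
#' @param comparison One of the PSA's comparisons.
#' @param framing `"health"` or `"equity"`.
#' @return An object of class `payoff_matrix`: numeric matrix
#'   (iterations x decisions) with a `framing` attribute.
#' @export
payoff_matrix <- function(psa, comparison = "varenicline vs ecigarette",
                          framing = c("health", "equity")) {
  framing <- match.arg(framing)
  stopifnot(inherits(psa, "psa_result"), comparison %in% psa$comparisons)
  k <- psa$settings$threshold
  metric <- if (framing == "health") "inhb" else "delta"
  x <- k * psa$outputs[, comparison, metric]
  ab <- strsplit(comparison, " vs ", fixed = TRUE)[[1]]
  m <- cbind(0, x)
  colnames(m) <- c(ab[2], ab[1])
  structure(m, class = c("payoff_matrix", class(m)), framing = framing)
}

as_payoff_matrix <- function(payoffs) {
  m <- unclass(payoffs)
  stopifnot(is.matrix(m), is.numeric(m), ncol(m) >= 2, all(is.finite(m)))
  m
}

#' Expected value of perfect information
#'
#' `EVPI = mean_i max_d payoff(i, d) - max_d mean_i payoff(i, d)`: the
#' expected gain from learning the true parameter values before choosing
#' a decision option.  Always non-negative.
#'
#' @param payoffs A [payoff_matrix()] or plain iterations-x-decisions
#'   numeric matrix (>= 2 decisions).
#' @return EVPI on the payoff scale.
#' @examples
#' evpi_from_payoffs(rbind(c(0, -1), c(0, 3)))  # 0.5
#' @export
evpi_from_payoffs <- function(payoffs) {
  m <- as_payoff_matrix(payoffs)
  if (nrow(m) < 2) stop("EVPI needs at least 2 iterations")
  mean(apply(m, 1, max)) - max(colMeans(m))
}

#' Regression-based expected value of partial perfect information
#'
#' Estimates EVPPI for a subset of parameters by regressing each
#' decision's payoff on the subset's sampled values with a flexible
#' smooth model, then applying the EVPI identity to the fitted values:
#' `EVPPI = mean_i max_d g_d(x_i) - max_d mean_i g_d(x_i)`, clipped into
#' `[0, EVPI]` (the information ordering, enforced against the same
#' payoff sample).
#' For subsets of up to 4 columns an additive smoothing-spline GAM is
#' used; for 5 or more columns a Gaussian-process regression (the
#' approach popularised by the SAVI platform).  Constant and duplicated
#' columns are pruned with a warning.
#'
#' @param payoffs A [payoff_matrix()] or numeric matrix.
#' @param inputs Iteration-by-parameter numeric matrix with column names
#'   (the PSA input sheet).
#' @param subset Character vector of column names (a parameter group), or
#'   a group name from `groups`.
#' @param groups Optional named list of column-name vectors (e.g.
#'   [parameter_groups()]), letting `subset` name a group.
#' @param k_basis Basis dimension per smooth term (default 4).
#' @return EVPPI estimate (>= 0) with attributes `se` (a fitted-model
#'   standard-error heuristic: residual-based MC error of the fitted
#'   maxima) and `method`.
#' @export
evppi_regression <- function(payoffs, inputs, subset, groups = NULL,
                             k_basis = 4) {
  m <- as_payoff_matrix(payoffs)
  stopifnot(is.matrix(inputs), nrow(inputs) == nrow(m))
  if (!is.null(groups) && length(subset) == 1 && subset %in% names(groups))
    subset <- groups[[subset]]
  if (length(subset) == 0) stop("subset must be nonempty")
  missing_cols <- setdiff(subset, colnames(inputs))
  if (length(missing_cols))
    stop("unknown input columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(m) < 100)
    warning("fewer than 100 PSA iterations; EVPPI regression is unreliable")

  X <- inputs[, subset, drop = FALSE]
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping constant input columns: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  X <- X[, !duplicated(t(X)), drop = FALSE]
  if (ncol(X) == 0) stop("subset has no varying columns")

  # payoffs are identical up to a column of zeros in the two-decision
  # case, but fit every non-constant decision column for generality
  fitted_payoff <- matrix(0, nrow(m), ncol(m))
  resid_var <- 0
  method <- if (ncol(X) <= 4) "gam" else "gp"
  for (d in seq_len(ncol(m))) {
    y <- m[, d]
    if (stats::sd(y) == 0) { fitted_payoff[, d] <- y; next }
    df <- data.frame(y = y, X)
    kk <- max(3, min(k_basis, nrow(m) - 2))
    terms <- paste0("s(", colnames(X), ", k = ", kk, ")")
    fml <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    gam_fit <- mgcv::gam(fml, data = df)
    if (method == "gam") {
      fitted_payoff[, d] <- stats::fitted(gam_fit)
      resid_var <- resid_var + stats::var(stats::residuals(gam_fit))
    } else {
      # GP with its noise level (nugget, on the unit-variance scale of the
      # standardised response) anchored to the additive pilot fit, so the
      # GP captures interactions without interpolating Monte Carlo noise
      nugget <- max(1e-3, stats::var(stats::residuals(gam_fit)) / stats::var(y))
      fit <- kernlab::gausspr(x = X, y = y, var = nugget)
      fitted_payoff[, d] <- as.numeric(kernlab::predict(fit, X))
      resid_var <- resid_var + stats::var(y - fitted_payoff[, d])
    }
  }
  ev <- mean(apply(fitted_payoff, 1, max)) - max(colMeans(fitted_payoff))
  # information ordering: 0 <= EVPPI <= EVPI, enforced against the same
  # payoff sample (regression noise can otherwise push the estimate past
  # either bound by a percent or two)
  ev <- min(max(ev, 0), evpi_from_payoffs(m))
  se <- sqrt(resid_var / nrow(m))
  structure(ev, se = se, method = method)
}

#' Scale a per-run value to a monetised population figure
#'
#' Pure scaling: multiplies a QALY-denominated value by the threshold k
#' (£/QALY) and an optional population/time factor when the payoffs were
#' per person.
#'
#' @param value Value in QALYs.
#' @param k Threshold in £/QALY (> 0).
#' @param population_factor Multiplier (default 1; the pipeline's payoffs
#'   are already population-level).
#' @return Value in £.
#' @examples
#' population_scale_monetize(10, 20000)  # 200000
#' @export
population_scale_monetize <- function(value, k, population_factor = 1) {
  stopifnot(k > 0)
  value * k * population_factor
}

#' Toy two-decision problem with normally distributed incremental payoff
#'
#' Draws `n` incremental payoffs from Normal(mu, sigma) and returns the
#' two-decision payoff matrix `{0, x}` together with the analytic EVPI
#' `sigma * phi(mu/sigma) - |mu| * Phi(-|mu|/sigma)` (the unit normal
#' loss integral) attached as the `analytic_evpi` attribute.  Used as
#' the independent oracle for the EVPI estimator.
#'
#' @param mu Mean incremental payoff.
#' @param sigma Standard deviation (> 0).
#' @param n Number of draws.
#' @param seed Seed.
#' @return A `payoff_matrix` with attribute `analytic_evpi`.
#' @export
toy_normal_decision_problem <- function(mu, sigma, n = 1e5, seed = 1) {
  stopifnot(sigma > 0, n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  x <- stats::rnorm(n, mu, sigma)
  analytic <- sigma * stats::dnorm(mu / sigma) -
    abs(mu) * stats::pnorm(-abs(mu) / sigma)
  m <- cbind(comparator = 0, intervention = x)
  structure(m, class = c("payoff_matrix", class(m)),
            framing = "toy", analytic_evpi = analytic)
}

#' VOI report over parameter groups
#'
#' EVPI plus per-group EVPPI for one comparison in both framings,
#' matching the grouping used by the ANCOVA report so the two are
#' comparable.
#'
#' @param psa A `psa_result`.
#' @param book The `parameter_book` the PSA was run from.
#' @param comparison Comparison to analyse.
#' @param framings Character vector among `"health"`, `"equity"`.
#' @return Data frame: framing, group (`"ALL"` for EVPI), value (£), se.
#' @export
voi_report <- function(psa, book, comparison = "varenicline vs ecigarette",
                       framings = c("health", "equity")) {
  groups <- parameter_groups(book)
  rows <- list()
  for (fr in framings) {
    pm <- payoff_matrix(psa, comparison, fr)
    evpi <- evpi_from_payoffs(pm)
    rows[[length(rows) + 1]] <- data.frame(
      framing = fr, group = "ALL", value = evpi, se = NA_real_)
    for (g in names(groups)) {
      cols <- intersect(groups[[g]], colnames(psa$inputs))
      if (!length(cols)) next
      ev <- evppi_regression(pm, psa$inputs, cols)
      rows[[length(rows) + 1]] <- data.frame(
        framing = fr, group = g, value = as.numeric(ev),
        se = attr(ev, "se"))
    }
  }
  do.call(rbind, rows)
}
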