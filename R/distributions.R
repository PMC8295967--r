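#' Distribution specification for an uncertain model input
#'
#' A `dist_spec` records the assumed sampling distribution of one model
#' input for probabilistic sensitivity analysis.  Supported families are
#' those used for the national parameter table: `beta` (proportions),
#' `gamma` (costs and disutilities), `lognormal` (relative risks, with
#' `lm` the mean and `lv` the standard deviation of the log-transformed
#' value), `mvnormal` (the correlated HRQoL regression coefficients) and
#' `fixed` (no uncertainty).
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"mvnormal"`,
#'   `"fixed"`.
#' @param ... Family parameters: `shape1`/`shape2` (beta), `shape`/`scale`
#'   (gamma), `lm`/`lv` (lognormal), `mean`/`sigma` (mvnormal, where
#'   `sigma` is a symmetric positive-semidefinite covariance matrix),
#'   `value` (fixed).
#'
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("beta", shape1 = 2441, shape2 = 11775)
#' dist_spec("lognormal", lm = 0.297, lv = 0.168)
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal", "mvnormal", "fixed"),
                      ...) {
  family <- match.arg(family)
  p <- list(...)
  switch(family,
    beta = {
      stopifnot(is.numeric(p$shape1), is.numeric(p$shape2))
      if (p$shape1 <= 0 || p$shape2 <= 0)
        stop("beta dist_spec requires shape1 > 0 and shape2 > 0")
    },
    gamma = {
      stopifnot(is.numeric(p$shape), is.numeric(p$scale))
      if (p$shape <= 0 || p$scale <= 0)
        stop("gamma dist_spec requires shape > 0 and scale > 0")
    },
    lognormal = {
      stopifnot(is.numeric(p$lm), is.numeric(p$lv))
      if (p$lv <= 0) stop("lognormal dist_spec requires lv > 0")
    },
    mvnormal = {
      stopifnot(is.numeric(p$mean), is.matrix(p$sigma))
      d <- length(p$mean)
      if (!all(dim(p$sigma) == c(d, d)))
        stop("mvnormal sigma must be ", d, " x ", d)
      if (max(abs(p$sigma - t(p$sigma))) > 1e-8)
        stop("mvnormal sigma must be symmetric")
      ev <- eigen(p$sigma, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8 * max(abs(ev), 1))
        stop("mvnormal sigma must be positive-semidefinite")
    },
    fixed = {
      stopifnot(is.numeric(p$value))
    }
  )
  structure(list(family = family, params = p), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  ps <- x$params
  if (x$family == "mvnormal") {
    cat(sprintf("<dist_spec mvnormal, dim %d>\n", length(ps$mean)))
  } else {
    cat(sprintf("<dist_spec %s(%s)>\n", x$family,
                paste(sprintf("%s = %g", names(ps), unlist(ps)), collapse = ", ")))
  }
  invisible(x)
}

#' Moment-matching Beta distribution from a mean and standard error
#'
#' Returns the Beta distribution with exactly the given mean and variance,
#' via `nu = mean (1 - mean) / se^2 - 1`, `shape1 = mean nu`,
#' `shape2 = (1 - mean) nu`.  This is the construction used to assign
#' uncertainty to service uptake rates ("standard error of 10% of mean
#' value") and to convert local-authority prevalence confidence intervals
#' to Beta parameters.
#'
#' @param mean Proportion in (0, 1).
#' @param se Standard error; must satisfy `se^2 < mean (1 - mean)`.
#' @return A `dist_spec` of family `beta`.
#' @examples
#' beta_from_mean_se(0.0403, 0.00403)  # ~ Beta(96, 2284)
#' @export
beta_from_mean_se <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (mean <= 0 || mean >= 1) stop("mean must lie strictly in (0, 1)")
  if (se <= 0) stop("se must be positive")
  if (se^2 >= mean * (1 - mean))
    stop("infeasible variance: se^2 must be < mean * (1 - mean)")
  nu <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Moment-matching Gamma distribution from a mean and standard error
#'
#' `shape = (mean/se)^2`, `scale = se^2/mean`; the returned distribution
#' reproduces both moments.  Used for costs and disutilities, which are
#' assigned gamma distributions with a standard error of 10% of the mean.
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#' @return A `dist_spec` of family `gamma`.
#' @examples
#' gamma_from_mean_se(100, 10)  # Gamma(shape = 100, scale = 1)
#' @export
gamma_from_mean_se <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1, length(se) == 1)
  if (mean <= 0 || se <= 0) stop("mean and se must be positive")
  dist_spec("gamma", shape = (mean / se)^2, scale = se^2 / mean)
}

#' Analytic summary of a distribution specification
#'
#' @param spec A [dist_spec()].
#' @return A list with `mean`, `sd` and `quantile` (the family's inverse
#'   CDF, a function of `p`).  For `mvnormal` the mean is the mean vector,
#'   `sd` the vector of marginal standard deviations, and `quantile`
#'   returns marginal normal quantiles (a matrix with one column per
#'   coordinate).
#' @examples
#' distribution_summary(dist_spec("beta", shape1 = 2441, shape2 = 11775))$mean
#' @export
distribution_summary <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    beta = {
      a <- p$shape1; b <- p$shape2
      list(mean = a / (a + b),
           sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
           quantile = function(q) stats::qbeta(q, a, b))
    },
    gamma = {
      list(mean = p$shape * p$scale,
           sd = sqrt(p$shape) * p$scale,
           quantile = function(q) stats::qgamma(q, shape = p$shape, scale = p$scale))
    },
    lognormal = {
      m <- exp(p$lm + p$lv^2 / 2)
      list(mean = m,
           sd = m * sqrt(exp(p$lv^2) - 1),
           median = exp(p$lm),
           quantile = function(q) stats::qlnorm(q, meanlog = p$lm, sdlog = p$lv))
    },
    mvnormal = {
      s <- sqrt(diag(p$sigma))
      list(mean = p$mean, sd = s,
           quantile = function(q) {
             out <- outer(stats::qnorm(q), s) +
               matrix(p$mean, length(q), length(p$mean), byrow = TRUE)
             colnames(out) <- names(p$mean)
             out
           })
    },
    fixed = {
      list(mean = p$value, sd = 0 * p$value,
           quantile = function(q) {
             if (length(p$value) == 1) rep(p$value, length(q))
             else matrix(p$value, length(q), length(p$value), byrow = TRUE)
           })
    }
  )
}

# One random draw from a dist_spec.  mvnormal uses the Cholesky-type
# factor mean + L z; for covariances built as D R D with a strictly
# positive-definite correlation R, L = D chol(R)' remains valid when some
# standard deviations are exactly zero (the flat scenario), where plain
# chol() would fail.
draw_dist <- function(spec) {
  p <- spec$params
  switch(spec$family,
    beta = stats::rbeta(1, p$shape1, p$shape2),
    gamma = stats::rgamma(1, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(1, meanlog = p$lm, sdlog = p$lv),
    mvnormal = {
      L <- mvn_factor(spec)
      as.numeric(p$mean + L %*% stats::rnorm(length(p$mean)))
    },
    fixed = p$value
  )
}

# Lower-triangular factor L with L L' = sigma.  Prefers chol(); falls back
# to an eigendecomposition square root for semidefinite matrices.  A
# clearly indefinite covariance is an error naming the offending block.
mvn_factor <- function(spec, label = "mvnormal") {
  sigma <- spec$params$sigma
  L <- tryCatch(t(chol(sigma)), error = function(e) NULL)
  if (!is.null(L)) return(L)
  ee <- eigen(sigma, symmetric = TRUE)
  if (min(ee$values) < -1e-8 * max(abs(ee$values), 1))
    stop("covariance for block '", label, "' is not positive-semidefinite; ",
         "Cholesky-type factorisation failed")
  ee$values[ee$values < 0] <- 0
  ee$vectors %*% diag(sqrt(ee$values), nrow = length(ee$values))
}
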