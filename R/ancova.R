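#' ANCOVA variance decomposition of PSA outputs
#'
#' Attributes the variance of a PSA output (e.g. population iNHB or the
#' inequality impact) to groups of input parameters by linear-model
#' sum-of-squares decomposition.  Inputs are standardised (mean 0, sd 1)
#' and a single main-effects linear model on all grouped columns is
#' fitted.  Each group's share of the output's total sum of squares is,
#' by default, its marginal (drop-one-group) increment in explained SS —
#' appropriate because PSA inputs are sampled independently, which makes
#' order dependence negligible; a sequential (type-I) mode is available
#' for comparison.
#'
#' @param outputs Numeric iteration vector (one PSA output).
#' @param inputs Iteration-by-parameter numeric matrix with column names.
#' @param groups Named list of column-name vectors partitioning (a subset
#'   of) the input columns.
#' @param ss_type `"marginal"` (default) or `"sequential"`.
#' @return An object of class `ancova_report`: data frame `shares`
#'   (group, share), plus `r_squared` and `residual` (= 1 - R^2).
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("a", "b")))
#' y <- 2 * x[, 1] + x[, 2]
#' ancova_decompose(y, x, list(g1 = "a", g2 = "b"))  # shares ~ (0.8, 0.2)
#' @export
ancova_decompose <- function(outputs, inputs, groups,
                             ss_type = c("marginal", "sequential")) {
  ss_type <- match.arg(ss_type)
  stopifnot(is.numeric(outputs), is.matrix(inputs),
            length(outputs) == nrow(inputs), is.list(groups),
            length(groups) >= 1, !is.null(names(groups)))
  cols <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(cols))
    stop("groups must not share columns")
  missing_cols <- setdiff(cols, colnames(inputs))
  if (length(missing_cols))
    stop("unknown input columns: ", paste(missing_cols, collapse = ", "))
  if (length(outputs) <= length(cols) + 10)
    stop("need n > number of grouped columns + 10")

  X <- inputs[, cols, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  X <- scale(X[, keep, drop = FALSE])
  groups_kept <- lapply(groups, function(g) intersect(g, colnames(X)))

  ss_tot <- sum((outputs - mean(outputs))^2)
  if (ss_tot == 0) {
    warning("constant output: all shares 0")
    return(structure(list(
      shares = data.frame(group = names(groups), share = 0),
      r_squared = 0, residual = 1, ss_type = ss_type),
      class = "ancova_report"))
  }

  rss <- function(Xsub) {
    if (ncol(Xsub) == 0) return(ss_tot)
    fit <- stats::lm.fit(cbind(1, Xsub), outputs)
    sum(fit$residuals^2)
  }
  rss_full <- rss(X)
  r2 <- 1 - rss_full / ss_tot

  share <- numeric(length(groups))
  if (ss_type == "marginal") {
    for (g in seq_along(groups)) {
      drop_cols <- setdiff(colnames(X), groups_kept[[g]])
      share[g] <- (rss(X[, drop_cols, drop = FALSE]) - rss_full) / ss_tot
    }
  } else {
    prev_rss <- ss_tot
    sofar <- character()
    for (g in seq_along(groups)) {
      sofar <- c(sofar, groups_kept[[g]])
      cur_rss <- rss(X[, sofar, drop = FALSE])
      share[g] <- (prev_rss - cur_rss) / ss_tot
      prev_rss <- cur_rss
    }
  }
  share <- pmax(share, 0)

  structure(list(shares = data.frame(group = names(groups), share = share,
                                     row.names = NULL),
                 r_squared = r2, residual = 1 - r2, ss_type = ss_type),
            class = "ancova_report")
}

#' @export
print.ancova_report <- function(x, ...) {
  cat(sprintf("<ancova_report: %s SS, R^2 = %.3f>\n", x$ss_type, x$r_squared))
  print(x$shares)
  invisible(x)
}

#' ANCOVA report for all PSA outputs and comparisons
#'
#' Runs [ancova_decompose()] for the iNHB and inequality-impact outputs
#' of every comparison in a PSA, over the standard parameter groups.
#'
#' @param psa A `psa_result`.
#' @param book The `parameter_book` the PSA was run from.
#' @param ss_type Passed to [ancova_decompose()].
#' @return Data frame: output, comparison, group, share, r_squared.
#' @export
ancova_report_all <- function(psa, book, ss_type = "marginal") {
  groups <- parameter_groups(book)
  groups <- lapply(groups, intersect, colnames(psa$inputs))
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  rows <- list()
  for (cmp in psa$comparisons) {
    for (metric in c("inhb", "delta")) {
      rep <- ancova_decompose(psa$outputs[, cmp, metric], psa$inputs,
                              groups, ss_type)
      rows[[length(rows) + 1]] <- data.frame(
        output = metric, comparison = cmp, group = rep$shares$group,
        share = rep$shares$share, r_squared = rep$r_squared)
    }
  }
  do.call(rbind, rows)
}
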