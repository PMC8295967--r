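#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of the parameter book's uncertainty through
#' the cohort model and equity metrics.  Each iteration draws one joint
#' parameter sample (common random inputs across all three arms),
#' computes population arm outcomes, and records iNHB, iEDE and the
#' inequality impact for every requested pairwise comparison, alongside
#' the flattened input vector.  Per-iteration seeds are spawned from the
#' root seed up front, so results are reproducible and independent of
#' evaluation order.
#'
#' @param book A `parameter_book`.
#' @param ext An `external_inputs` bundle.
#' @param comparisons Character vector of pairwise comparisons, subset of
#'   `"varenicline vs none"`, `"ecigarette vs none"`,
#'   `"varenicline vs ecigarette"`.
#' @param n Number of iterations (published analysis: 1,000).
#' @param seed Root seed.
#' @param epsilon Optional override of the Atkinson aversion parameter.
#' @param disease_rr_mode See [run_cohort_trace()].
#' @return An object of class `psa_result`: `inputs` (n x p matrix of
#'   sampled scalars), `outputs` (n x comparison x metric array with
#'   metrics `inhb`, `iede`, `delta`), `base_case` (the deterministic
#'   means-based result per comparison), `seed`, `n`, `truncations`.
#' @examples
#' \donttest{
#' book <- fixture_parameter_book("england")
#' ext <- generate_external_inputs(seed = 1)
#' psa <- run_psa(book, ext, n = 50, seed = 42)
#' decision_probabilities(psa)
#' }
#' @export
run_psa <- function(book, ext,
                    comparisons = c("varenicline vs none",
                                    "ecigarette vs none",
                                    "varenicline vs ecigarette"),
                    n = 1000, seed = 42, epsilon = NULL,
                    disease_rr_mode = c("imd3_normalised", "raw")) {
  stopifnot(n >= 1)
  disease_rr_mode <- match.arg(disease_rr_mode)
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  eq <- equity_settings_from(book, ext, epsilon = epsilon)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)

  p_names <- unlist(parameter_groups(book), use.names = FALSE)
  inputs <- matrix(NA_real_, n, length(p_names),
                   dimnames = list(NULL, p_names))
  outputs <- array(NA_real_, dim = c(n, length(comparisons), 3),
                   dimnames = list(NULL, comparison = comparisons,
                                   metric = c("inhb", "iede", "delta")))
  trunc_total <- 0L

  one_iteration <- function(s) {
    set.seed(s)
    smp <- draw_sample(book)
    per_smoker <- per_smoker_outcomes_all(smp, ext, disease_rr_mode)
    arms <- lapply(stats::setNames(ARMS, ARMS), function(a)
      population_arm_outcomes(smp, ext, a, per_smoker = per_smoker))
    res <- lapply(comparisons, function(cmp) {
      ab <- strsplit(cmp, " vs ", fixed = TRUE)[[1]]
      compare_arms(arms[[ab[1]]], arms[[ab[2]]], eq)
    })
    list(inputs = flatten_parameter_sample(smp, book),
         out = t(vapply(res, function(r) c(r$inhb, r$iede, r$delta),
                        numeric(3))),
         trunc = attr(smp, "truncations")$n)
  }

  for (i in seq_len(n)) {
    it <- tryCatch(one_iteration(iter_seeds[i]), error = function(e)
      stop("PSA iteration ", i, " (seed ", iter_seeds[i], ") failed: ",
           conditionMessage(e)))
    inputs[i, ] <- it$inputs
    outputs[i, , ] <- it$out
    trunc_total <- trunc_total + it$trunc
  }

  base <- base_case_results(book, ext, comparisons, epsilon = epsilon,
                            disease_rr_mode = disease_rr_mode)

  structure(list(inputs = inputs, outputs = outputs, base_case = base,
                 comparisons = comparisons, seed = seed, n = n,
                 settings = eq, truncations = trunc_total),
            class = "psa_result")
}

#' Deterministic base-case comparison results at the parameter means
#'
#' @inheritParams run_psa
#' @return A list of `comparison_result` objects, one per comparison.
#' @export
base_case_results <- function(book, ext,
                              comparisons = c("varenicline vs none",
                                              "ecigarette vs none",
                                              "varenicline vs ecigarette"),
                              epsilon = NULL,
                              disease_rr_mode = c("imd3_normalised", "raw")) {
  comparisons <- match.arg(comparisons, several.ok = TRUE)
  eq <- equity_settings_from(book, ext, epsilon = epsilon)
  smp <- base_case_sample(book)
  per_smoker <- per_smoker_outcomes_all(smp, ext, disease_rr_mode)
  arms <- lapply(stats::setNames(ARMS, ARMS), function(a)
    population_arm_outcomes(smp, ext, a, per_smoker = per_smoker))
  stats::setNames(lapply(comparisons, function(cmp) {
    ab <- strsplit(cmp, " vs ", fixed = TRUE)[[1]]
    compare_arms(arms[[ab[1]]], arms[[ab[2]]], eq)
  }), comparisons)
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result: %d iterations, seed %d, %d inputs>\n",
              x$n, x$seed, ncol(x$inputs)))
  print(psa_summary_table(x))
  invisible(x)
}

#' Decision probabilities from a PSA
#'
#' Empirical probability that the first-named arm increases overall
#' health (iNHB > 0) and that it reduces inequality (iEDE > iNHB), per
#' comparison, with binomial Monte Carlo standard errors.
#'
#' @param psa A `psa_result`.
#' @return Data frame: comparison, `p_inhb_pos`, `p_delta_pos` and their
#'   standard errors (proportions in \[0, 1\]).
#' @export
decision_probabilities <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  n <- psa$n
  p1 <- colMeans(psa$outputs[, , "inhb", drop = FALSE] > 0)
  p2 <- colMeans(psa$outputs[, , "delta", drop = FALSE] > 0)
  data.frame(comparison = psa$comparisons,
             p_inhb_pos = as.numeric(p1),
             se_inhb = sqrt(as.numeric(p1) * (1 - as.numeric(p1)) / n),
             p_delta_pos = as.numeric(p2),
             se_delta = sqrt(as.numeric(p2) * (1 - as.numeric(p2)) / n),
             row.names = NULL)
}

#' PSA summary in the layout of the published results table
#'
#' Per comparison: mean iNHB and mean inequality impact (iEDE - iNHB)
#' with 2.5/97.5 percentile intervals, and the decision probabilities in
#' percent (2 dp).
#'
#' @param psa A `psa_result`.
#' @return Data frame, one row per comparison.
#' @export
psa_summary_table <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  qs <- function(v) stats::quantile(v, c(0.025, 0.975), names = FALSE)
  rows <- lapply(seq_along(psa$comparisons), function(j) {
    inhb <- psa$outputs[, j, "inhb"]; delta <- psa$outputs[, j, "delta"]
    data.frame(comparison = psa$comparisons[j],
               mean_inhb = mean(inhb),
               inhb_lo = qs(inhb)[1], inhb_hi = qs(inhb)[2],
               mean_delta = mean(delta),
               delta_lo = qs(delta)[1], delta_hi = qs(delta)[2],
               p_inhb_pos_pct = round(100 * mean(inhb > 0), 2),
               p_delta_pos_pct = round(100 * mean(delta > 0), 2))
  })
  do.call(rbind, rows)
}

#' Export a PSA result as CSV files
#'
#' Writes `inputs.csv` (one row per iteration, one column per sampled
#' scalar — the layout consumed by the VOI and ANCOVA stages),
#' `outputs.csv` (iteration, comparison, inhb, iede, delta),
#' `summary.csv` and `scatter.csv` (equity-impact-plane coordinates:
#' iteration, comparison, delta, inhb).
#'
#' @param psa A `psa_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_psa_csv <- function(psa, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(psa$inputs), file.path(dir, "inputs.csv"),
                   row.names = FALSE)
  long <- do.call(rbind, lapply(seq_along(psa$comparisons), function(j)
    data.frame(iteration = seq_len(psa$n), comparison = psa$comparisons[j],
               inhb = psa$outputs[, j, "inhb"],
               iede = psa$outputs[, j, "iede"],
               delta = psa$outputs[, j, "delta"])))
  utils::write.csv(long, file.path(dir, "outputs.csv"), row.names = FALSE)
  utils::write.csv(psa_summary_table(psa), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  utils::write.csv(long[, c("iteration", "comparison", "delta", "inhb")],
                   file.path(dir, "scatter.csv"), row.names = FALSE)
  invisible(dir)
}
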