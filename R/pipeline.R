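#' Load and validate a run configuration
#'
#' The YAML run config drives one end-to-end analysis.  Recognised keys:
#' `region` (england/york/sheffield, required), `scenario` (default,
#' flat or steep_gradient externals preset), `externals_seed`, `n`
#' (PSA iterations), `seed` (PSA root seed), `epsilon` (optional
#' aversion override), `comparisons`, `out_dir`, and `reports` (logical
#' toggles `psa`, `voi`, `ancova`).  Unknown keys are rejected;
#' defaults: `n = 1000`, `seed = 42`, `externals_seed = 1`,
#' `scenario = "default"`, all reports on.
#'
#' @param path Path to a YAML file, or a named list with the same keys.
#' @return An object of class `run_config` with all defaults resolved.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  stopifnot(is.list(cfg))
  known <- c("region", "scenario", "externals_seed", "n", "seed", "epsilon",
             "comparisons", "out_dir", "reports")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown run-config keys: ", paste(bad, collapse = ", "))
  if (is.null(cfg$region)) stop("run config must name a region")
  cfg$region <- match.arg(cfg$region, c("england", "york", "sheffield"))
  cfg$scenario <- if (is.null(cfg$scenario)) "default"
    else match.arg(cfg$scenario, c("default", "flat", "steep_gradient"))
  cfg$externals_seed <- if (is.null(cfg$externals_seed)) 1L
    else as.integer(cfg$externals_seed)
  cfg$n <- if (is.null(cfg$n)) 1000L else as.integer(cfg$n)
  if (cfg$n < 1) stop("n must be >= 1")
  cfg$seed <- if (is.null(cfg$seed)) 42L else as.integer(cfg$seed)
  if (is.null(cfg$comparisons))
    cfg$comparisons <- c("varenicline vs none", "ecigarette vs none",
                         "varenicline vs ecigarette")
  reports <- list(psa = TRUE, voi = TRUE, ancova = TRUE)
  for (nm in names(cfg$reports)) {
    if (!nm %in% names(reports)) stop("unknown report toggle: ", nm)
    reports[[nm]] <- isTRUE(cfg$reports[[nm]])
  }
  cfg$reports <- reports
  structure(cfg, class = "run_config")
}

#' Run the full analysis pipeline from a configuration
#'
#' Builds the region's parameter book and synthetic externals, runs the
#' PSA, and writes `summary.csv`, `scatter.csv`, `inputs.csv`,
#' `outputs.csv`, `base_case.csv` (per-quintile comparison results),
#' plus `voi.csv` and `ancova.csv` when enabled, and a `manifest.yaml`
#' recording seeds, sizes, truncation counts and file checksums.
#'
#' @param config A `run_config` (or path / list accepted by
#'   [load_run_config()]).
#' @return Invisibly, a list with `book`, `ext`, `psa`, `voi`, `ancova`
#'   and the output directory.
#' @export
run_full_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- load_run_config(config)
  out_dir <- if (is.null(config$out_dir)) tempfile("dcea_run_") else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  # on any stage failure, keep partial outputs and record the stage
  stage <- "setup"
  on.exit({
    if (!is.null(stage))
      writeLines(yaml::as.yaml(list(failed_stage = stage,
                                    region = config$region,
                                    scenario = config$scenario)),
                 file.path(out_dir, "manifest.yaml"))
  }, add = TRUE)

  book_scenario <- if (config$scenario == "flat") "flat" else "default"
  book <- fixture_parameter_book(config$region, scenario = book_scenario)
  ext <- generate_external_inputs(seed = config$externals_seed,
                                  scenario = config$scenario)

  stage <- "psa"
  psa <- run_psa(book, ext, comparisons = config$comparisons,
                 n = config$n, seed = config$seed, epsilon = config$epsilon)
  if (isTRUE(config$reports$psa)) write_psa_csv(psa, out_dir)

  bc <- psa$base_case
  base_rows <- do.call(rbind, lapply(bc, function(r)
    data.frame(comparison = r$comparison, quintile = IMD,
               inhb_q = as.numeric(r$inhb_q), inhb = r$inhb, iede = r$iede,
               delta = r$delta, quadrant = r$quadrant)))
  utils::write.csv(base_rows, file.path(out_dir, "base_case.csv"),
                   row.names = FALSE)

  stage <- "voi"
  voi <- NULL
  if (isTRUE(config$reports$voi) &&
      "varenicline vs ecigarette" %in% psa$comparisons) {
    voi <- voi_report(psa, book)
    utils::write.csv(voi, file.path(out_dir, "voi.csv"), row.names = FALSE)
  }
  stage <- "ancova"
  anc <- NULL
  if (isTRUE(config$reports$ancova)) {
    anc <- ancova_report_all(psa, book)
    utils::write.csv(anc, file.path(out_dir, "ancova.csv"), row.names = FALSE)
  }

  stage <- NULL   # all stages completed
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  manifest <- list(
    region = config$region, scenario = config$scenario,
    externals_seed = config$externals_seed, psa_seed = config$seed,
    n_iterations = config$n,
    epsilon = psa$settings$epsilon,
    truncation_count = psa$truncations,
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "manifest.yaml"))

  invisible(list(book = book, ext = ext, psa = psa, voi = voi, ancova = anc,
                 out_dir = out_dir))
}
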