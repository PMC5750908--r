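#' Configuration for an end-to-end pipeline run
#'
#' Every threshold of the analysis is configurable, with the standard
#' arsenic defaults: exposure bands at 1/5/10 ug/L, PCV 10 ug/L, hazard
#' rank cut-points 10%/5%/1%, LOD 0.02 ug/L.
#'
#' Exactly one input source must be given: `input` (a samples CSV),
#' `sim` (a [sim_config()]; the default when neither is given is
#' [default_sim_config()] at `seed`), or `params` (a model-parameter
#' JSON path or named list of [lognormal_model()]s — "skip-fitting"
#' mode, which reproduces predictions without sample data and skips the
#' sample-based stages).
#'
#' @param input optional path to a samples CSV.
#' @param sim optional [sim_config()].
#' @param params optional model-parameter JSON path or named model list.
#' @param lod limit of detection, ug/L.
#' @param boundaries three strictly increasing band edges, ug/L.
#' @param pcv prescribed concentration value, ug/L; must equal the top
#'   boundary.
#' @param rank_thresholds three strictly decreasing rank cut-points.
#' @param min_n minimum stratum size for transformation selection.
#' @param alpha significance level used throughout.
#' @param n_dwellings dwelling totals for prediction (single value
#'   recycled over strata, or a named vector).
#' @param seed integer seed for any simulation.
#' @param output_dir directory for output artifacts.
#' @return an object of class `run_config`.
#' @export
run_config <- function(input = NULL, sim = NULL, params = NULL,
                       lod = 0.02, boundaries = c(1, 5, 10), pcv = 10,
                       rank_thresholds = c(0.10, 0.05, 0.01),
                       min_n = 30, alpha = 0.05, n_dwellings = 200,
                       seed = 1L, output_dir = "pwshazard_out") {
  if (any(diff(boundaries) <= 0) || length(boundaries) != 3) {
    stop("boundaries must be three strictly increasing values",
         call. = FALSE)
  }
  if (pcv != boundaries[3]) {
    stop("pcv must equal the top exposure-band boundary", call. = FALSE)
  }
  if (length(rank_thresholds) != 3 || any(diff(rank_thresholds) >= 0)) {
    stop("rank_thresholds must be strictly decreasing", call. = FALSE)
  }
  n_sources <- sum(!is.null(input), !is.null(sim), !is.null(params))
  if (n_sources > 1) {
    stop("give at most one of input, sim, params", call. = FALSE)
  }
  if (n_sources == 0) sim <- default_sim_config(seed = seed)
  structure(list(input = input, sim = sim, params = params, lod = lod,
                 boundaries = boundaries, pcv = pcv,
                 rank_thresholds = rank_thresholds, min_n = min_n,
                 alpha = alpha, n_dwellings = n_dwellings,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full hazard-assessment pipeline
#'
#' Executes the stages in order and writes their artifacts to
#' `config$output_dir`:
#'
#' 1. `resolved_samples.csv` — records after worst-case resolution;
#' 2. `stratum_summary.csv` — per-stratum descriptive statistics;
#' 3. `transformation_report.csv` — ladder-of-powers selection;
#' 4. `comparison_report.json` — homoscedasticity gate and final test;
#' 5. `model_params.json` + `hazard_table.csv` — fitted models, band
#'    percentages, hazard ranks, predicted counts;
#' 6. `region_prediction.json` — region-wide exceedance totals;
#'
#' plus `manifest.json` recording the configuration, seed and package
#' version.  Identical configuration and seed give identical outputs.
#' In skip-fitting mode (`config$params`) the sample-based stages 1-4
#' are skipped.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage messages.
#' @return a list of the in-memory artifacts (invisibly): `samples`,
#'   `summary`, `ladder`, `comparison`, `models`, `hazard`, `region`,
#'   `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- list(files = character(0))
  emit <- function(name) {
    path <- file.path(config$output_dir, name)
    out$files <<- c(out$files, path)
    path
  }

  if (is.null(config$params)) {
    samples <- run_stage("input", {
      if (!is.null(config$input)) {
        read_samples(config$input, lod = config$lod)
      } else {
        generate_study(config$sim)
      }
    })
    say(sprintf("input: %d records, %d strata", nrow(samples),
                length(unique(samples$sbgc))))
    samples <- run_stage("resolve", resolve_records(samples))
    write_samples(samples, emit("resolved_samples.csv"))
    out$samples <- samples

    out$summary <- run_stage("summarise",
                             summarise_study(samples, config$boundaries))
    write_summary_table(out$summary, emit("stratum_summary.csv"))

    out$ladder <- run_stage("ladder",
                            ladder_report(samples, min_n = config$min_n,
                                          alpha = config$alpha))
    utils::write.csv(out$ladder, emit("transformation_report.csv"),
                     row.names = FALSE, quote = FALSE)

    out$comparison <- run_stage("compare",
                                compare_strata(samples, alpha = config$alpha))
    write_comparison_report(out$comparison, emit("comparison_report.json"))
    say(sprintf("comparison: homoscedastic=%s, %s p=%.3g",
                out$comparison$homoscedastic, out$comparison$final_test,
                out$comparison$final_p))

    out$models <- run_stage("fit", {
      labels <- unique(samples$sbgc)
      stats::setNames(lapply(labels, function(lbl) {
        fit_lognormal(samples$arsenic_ugL[samples$sbgc == lbl])
      }), labels)
    })
  } else {
    out$models <- run_stage("params", {
      if (is.character(config$params)) read_model_params(config$params)
      else lapply(config$params, as_lognormal_model)
    })
    say(sprintf("skip-fitting mode: %d stratum models", length(out$models)))
  }
  write_model_params(out$models, emit("model_params.json"))

  out$hazard <- run_stage("rank",
    hazard_table(out$models, config$n_dwellings, config$boundaries,
                 config$rank_thresholds))
  write_hazard_table(out$hazard, emit("hazard_table.csv"))

  out$region <- run_stage("predict",
    predict_region(out$models, config$n_dwellings, config$boundaries,
                   config$rank_thresholds))
  jsonlite::write_json(list(
    total_expected_exceedances = out$region$total_expected_exceedances,
    total_rounded = out$region$total_rounded,
    per_stratum_share = as.list(out$region$per_stratum_share)
  ), emit("region_prediction.json"), auto_unbox = TRUE, digits = NA)
  say(sprintf("region: %.2f expected PCV exceedances (rounded %d)",
              out$region$total_expected_exceedances,
              out$region$total_rounded))

  manifest <- list(
    package = "pwshazard",
    version = as.character(utils::packageVersion("pwshazard")),
    seed = config$seed,
    lod = config$lod,
    boundaries = config$boundaries,
    pcv = config$pcv,
    rank_thresholds = config$rank_thresholds,
    min_n = config$min_n,
    alpha = config$alpha,
    n_dwellings = config$n_dwellings,
    input = if (is.null(config$input)) NA else config$input,
    skip_fitting = !is.null(config$params),
    files = out$files
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out)
}
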