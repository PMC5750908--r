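#' Simulation parameters for one stratum
#'
#' @param sbgc stratum label.
#' @param gm geometric mean concentration, ug/L, > 0.
#' @param sigma_log SD of natural-log concentrations, >= 0.
#' @param n_dwellings number of dwellings to simulate, >= 1.
#' @param shared_supply_fraction fraction of dwellings on supplies shared
#'   between several dwellings (default 0: one supply per dwelling).
#' @param mean_dwellings_per_shared_supply mean size of a shared supply,
#'   >= 2.
#' @return an object of class `stratum_sim_params`.
#' @export
stratum_sim_params <- function(sbgc, gm, sigma_log, n_dwellings,
                               shared_supply_fraction = 0,
                               mean_dwellings_per_shared_supply = 2) {
  if (!nzchar(sbgc)) stop("sbgc label must be non-empty", call. = FALSE)
  if (!is.finite(gm) || gm <= 0) stop("gm must be > 0", call. = FALSE)
  if (!is.finite(sigma_log) || sigma_log < 0) {
    stop("sigma_log must be >= 0", call. = FALSE)
  }
  if (n_dwellings < 1 || n_dwellings != round(n_dwellings)) {
    stop("n_dwellings must be a positive integer", call. = FALSE)
  }
  if (shared_supply_fraction < 0 || shared_supply_fraction > 1) {
    stop("shared_supply_fraction must be in [0, 1]", call. = FALSE)
  }
  if (mean_dwellings_per_shared_supply < 2) {
    stop("mean_dwellings_per_shared_supply must be >= 2", call. = FALSE)
  }
  structure(list(sbgc = sbgc, gm = gm, sigma_log = sigma_log,
                 n_dwellings = as.integer(n_dwellings),
                 shared_supply_fraction = shared_supply_fraction,
                 mean_dwellings_per_shared_supply =
                   mean_dwellings_per_shared_supply),
            class = "stratum_sim_params")
}

#' Simulation configuration for a whole survey
#'
#' @param strata list of [stratum_sim_params()] with unique labels.
#' @param lod limit of detection, ug/L (> 0); draws below it are
#'   substituted at the LOD and flagged censored.
#' @param seed master integer seed.
#' @return an object of class `sim_config`.
#' @seealso [default_sim_config()] for the packaged Cornwall-like setup.
#' @export
sim_config <- function(strata, lod = 0.02, seed = 1L) {
  stopifnot(is.list(strata), length(strata) > 0)
  ok <- vapply(strata, inherits, logical(1), "stratum_sim_params")
  if (!all(ok)) stop("strata must be stratum_sim_params objects",
                     call. = FALSE)
  labels <- vapply(strata, `[[`, character(1), "sbgc")
  if (anyDuplicated(labels)) {
    stop("duplicate stratum labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.finite(lod) || lod <= 0) stop("lod must be > 0", call. = FALSE)
  structure(list(strata = stats::setNames(strata, labels),
                 lod = lod, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default simulation configuration: the Cornwall-like study
#'
#' Ten strata with the packaged per-SBGC log-normal parameters
#' ([cornwall_sbgc_params()]) at the published per-stratum sample sizes
#' (140, 93, 11, 19, 73, 69, 66, 3, 18, 16; 508 dwellings in total),
#' LOD 0.02 ug/L, no shared supplies.
#'
#' @param seed master integer seed.
#' @param shared_supply_fraction fraction of dwellings on shared
#'   supplies, applied to every stratum (default 0).
#' @return a [sim_config()].
#' @export
default_sim_config <- function(seed = 1L, shared_supply_fraction = 0) {
  models <- cornwall_sbgc_params()
  strata <- Map(function(lbl, m) {
    stratum_sim_params(lbl, m$gm, m$sigma_log, m$n,
                       shared_supply_fraction = shared_supply_fraction)
  }, names(models), models)
  sim_config(strata, lod = 0.02, seed = seed)
}

# Stable sub-seed for stratum `index` under master `seed`, so that adding
# a stratum to a config never perturbs the draws of earlier strata.
# Linear-congruential style mix, kept below 2^31 - 1.
derive_subseed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 30269) %% 2147483647)
}

#' Simulate one stratum of dwelling-level arsenic records
#'
#' Draws `ln(concentration) ~ Normal(ln(gm), sigma_log^2)`, one value per
#' supply; draws below the LOD are substituted at the LOD with
#' `below_lod = TRUE`.  When `shared_supply_fraction > 0`, the chosen
#' fraction of dwellings is grouped onto multi-dwelling supplies whose
#' single draw is carried by every member dwelling (as a real survey
#' ascribes a shared supply's measurement to all households on it).
#'
#' @param params a [stratum_sim_params()].
#' @param lod limit of detection, ug/L.
#' @param seed integer seed; identical seeds give identical output.
#' @return a sample `data.frame` with `params$n_dwellings` rows (see
#'   [read_samples()] for the columns).
#' @export
generate_stratum <- function(params, lod = 0.02, seed = 1L) {
  stopifnot(inherits(params, "stratum_sim_params"))
  if (!is.finite(lod) || lod <= 0) stop("lod must be > 0", call. = FALSE)
  n <- params$n_dwellings
  old <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  # assign dwellings to supplies
  supply_of <- seq_len(n)
  n_shared <- floor(params$shared_supply_fraction * n)
  if (n_shared >= 2) {
    size <- max(2L, round(params$mean_dwellings_per_shared_supply))
    grouped <- seq_len(n_shared)
    supply_of[grouped] <- (grouped - 1L) %/% size + 1L
    # singleton supplies continue the numbering after the shared ones
    n_groups <- max(supply_of[grouped])
    rest <- setdiff(seq_len(n), grouped)
    supply_of[rest] <- n_groups + seq_along(rest)
  }
  supplies <- unique(supply_of)
  draw <- if (params$sigma_log == 0) {
    rep(params$gm, length(supplies))
  } else {
    exp(stats::rnorm(length(supplies), mean = log(params$gm),
                     sd = params$sigma_log))
  }
  conc <- draw[match(supply_of, supplies)]
  below <- conc < lod
  conc[below] <- lod
  data.frame(
    dwelling_id = sprintf("%s-d%04d", params$sbgc, seq_len(n)),
    supply_id = sprintf("%s-s%04d", params$sbgc, supply_of),
    sbgc = params$sbgc,
    arsenic_ugL = conc,
    below_lod = below,
    water_type = "drinking_water",
    treated = NA,
    stringsAsFactors = FALSE
  )
}

#' Simulate a whole multi-stratum survey
#'
#' Concatenates per-stratum simulations; each stratum uses an
#' independent sub-seed derived deterministically from the master seed
#' and the stratum's position, so extending the configuration leaves
#' earlier strata unchanged.
#'
#' @param config a [sim_config()]; [default_sim_config()] reproduces the
#'   Cornwall-like 508-dwelling study.
#' @return a sample `data.frame` (see [read_samples()] for columns).
#' @examples
#' study <- generate_study(default_sim_config(seed = 7))
#' nrow(study)  # 508
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  parts <- Map(function(params, i) {
    generate_stratum(params, lod = config$lod,
                     seed = derive_subseed(config$seed, i))
  }, config$strata, seq_along(config$strata))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
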