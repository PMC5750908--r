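#' Read dwelling-level arsenic sample records
#'
#' Reads a CSV of private-water-supply arsenic measurements, one row per
#' dwelling.  Required columns: `dwelling_id`, `supply_id`, `sbgc`,
#' `arsenic_ugL`.  Optional columns: `below_lod` (logical), `water_type`
#' (`"drinking_water"` or `"groundwater"`), `treated` (logical).
#'
#' Censored measurements may be encoded either as the literal marker
#' `"<LOD"` in `arsenic_ugL` or as a numeric value with `below_lod = TRUE`;
#' both are normalised to the configured LOD with the flag set.
#'
#' @param path path to a CSV file.
#' @param lod limit of detection in ug/L; values below it (and `"<LOD"`
#'   markers) are substituted at this value with `below_lod = TRUE`.
#' @return a `data.frame` with columns `dwelling_id`, `supply_id`, `sbgc`,
#'   `arsenic_ugL`, `below_lod`, `water_type`, `treated`, row order as in
#'   the file.
#' @seealso [resolve_records()], [write_samples()]
#' @export
read_samples <- function(path, lod = 0.02) {
  if (!file.exists(path)) {
    stop("sample file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  required <- c("dwelling_id", "supply_id", "sbgc", "arsenic_ugL")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  conc_chr <- trimws(raw[["arsenic_ugL"]])
  is_marker <- toupper(conc_chr) %in% c("<LOD", "BDL", "ND")
  conc <- suppressWarnings(as.numeric(conc_chr))
  bad <- !is_marker & (is.na(conc) | conc <= 0)
  if (any(bad)) {
    stop("non-positive or unparseable arsenic_ugL at row(s): ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  below <- if ("below_lod" %in% names(raw)) {
    parse_logical(raw[["below_lod"]])
  } else {
    rep(FALSE, n)
  }
  below <- below | is_marker | (!is.na(conc) & conc < lod)
  conc[below] <- lod

  sbgc <- trimws(raw[["sbgc"]])
  if (any(!nzchar(sbgc))) {
    stop("empty sbgc label at row(s): ",
         paste(which(!nzchar(sbgc)), collapse = ", "), call. = FALSE)
  }
  water <- if ("water_type" %in% names(raw)) raw[["water_type"]]
           else rep("drinking_water", n)
  ok_water <- water %in% c("drinking_water", "groundwater")
  if (any(!ok_water)) {
    stop("invalid water_type at row(s): ",
         paste(which(!ok_water), collapse = ", "), call. = FALSE)
  }
  treated <- if ("treated" %in% names(raw)) parse_logical(raw[["treated"]])
             else rep(NA, n)
  data.frame(
    dwelling_id = raw[["dwelling_id"]],
    supply_id = raw[["supply_id"]],
    sbgc = sbgc,
    arsenic_ugL = conc,
    below_lod = below,
    water_type = water,
    treated = treated,
    stringsAsFactors = FALSE
  )
}

parse_logical <- function(x) {
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO", "")] <- FALSE
  out
}

#' Write sample records to CSV
#'
#' @param samples a sample `data.frame` as produced by [read_samples()] or
#'   [generate_study()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  check_samples(samples)
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve repeat measurements and shared supplies
#'
#' Applies the worst-case record-resolution rules used before any
#' statistics: where a supply was measured more than once, the highest
#' concentration is retained; that single retained value is then carried
#' by every dwelling sharing the supply.  The number of dwellings is
#' unchanged.  The retained row is flagged censored only if all
#' measurements of the supply were censored.
#'
#' @param samples a sample `data.frame` (see [read_samples()]).
#' @return a `data.frame` with the same rows (dwellings), each carrying
#'   its supply's maximum measured concentration.
#' @export
resolve_records <- function(samples) {
  check_samples(samples)
  if (anyDuplicated(samples$dwelling_id)) {
    dup <- unique(samples$dwelling_id[duplicated(samples$dwelling_id)])
    stop("duplicate dwelling_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  out <- samples
  for (sid in unique(samples$supply_id)) {
    idx <- which(samples$supply_id == sid)
    mx <- max(samples$arsenic_ugL[idx])
    out$arsenic_ugL[idx] <- mx
    out$below_lod[idx] <- all(samples$below_lod[idx])
  }
  out
}

check_samples <- function(samples) {
  stopifnot(is.data.frame(samples))
  required <- c("dwelling_id", "supply_id", "sbgc", "arsenic_ugL", "below_lod")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stop("samples missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(samples$arsenic_ugL) | samples$arsenic_ugL <= 0)) {
    stop("all arsenic_ugL values must be positive and finite", call. = FALSE)
  }
  invisible(samples)
}

#' Write a hazard table to CSV
#'
#' Writes one row per stratum with fixed column order: `sbgc`, `n`, `gm`,
#' `sigma_log`, `pct_lt1`, `pct_1_5`, `pct_5_10`, `pct_ge10`, `rank`,
#' `n_dwellings`, `exp_lt1`, `exp_1_5`, `exp_5_10`, `exp_ge10`.
#'
#' @param rows a hazard table `data.frame` from [hazard_table()] or the
#'   `rows` element of [predict_region()].
#' @param path output file path.
#' @param digits significant figures used for numeric columns (default 3).
#' @return `path`, invisibly.
#' @export
write_hazard_table <- function(rows, path, digits = 3) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    stop("hazard table must be a non-empty data.frame", call. = FALSE)
  }
  cols <- c("sbgc", "n", "gm", "sigma_log",
            "pct_lt1", "pct_1_5", "pct_5_10", "pct_ge10",
            "rank", "n_dwellings",
            "exp_lt1", "exp_1_5", "exp_5_10", "exp_ge10")
  missing <- setdiff(cols, names(rows))
  if (length(missing) > 0) {
    stop("hazard table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- rows[, cols]
  num <- vapply(out, is.numeric, logical(1)) &
    !(names(out) %in% c("rank", "n", "n_dwellings"))
  out[num] <- lapply(out[num], signif, digits = digits)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hazard table written by [write_hazard_table()]
#'
#' @param path CSV path.
#' @return a `data.frame`.
#' @export
read_hazard_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(sbgc = "character"))
}

#' Write per-stratum log-normal model parameters to JSON
#'
#' The JSON layout is `{"schema_version": 1, "strata": {"<sbgc>":
#' {"gm": ..., "sigma_log": ..., "n": ...}}}` with `gm` in ug/L and
#' `sigma_log` the SD of natural-log concentrations.
#'
#' @param models a named list of [lognormal_model()] objects, names are
#'   stratum labels.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(models, path) {
  stopifnot(is.list(models), length(models) > 0, !is.null(names(models)))
  strata <- lapply(models, function(m) {
    m <- as_lognormal_model(m)
    if (is.na(m$n)) list(gm = m$gm, sigma_log = m$sigma_log)
    else list(gm = m$gm, sigma_log = m$sigma_log, n = m$n)
  })
  jsonlite::write_json(list(schema_version = 1L, strata = strata), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read per-stratum log-normal model parameters from JSON
#'
#' @param path JSON path in the layout written by [write_model_params()].
#' @return a named list of [lognormal_model()] objects.
#' @export
read_model_params <- function(path) {
  if (!file.exists(path)) {
    stop("model-parameter file not found: ", path, call. = FALSE)
  }
  obj <- jsonlite::read_json(path)
  if (is.null(obj$strata)) {
    stop("model-parameter file has no 'strata' field: ", path, call. = FALSE)
  }
  lapply(obj$strata, function(s) {
    lognormal_model(gm = s$gm, sigma_log = s$sigma_log,
                    n = if (is.null(s$n)) NA_integer_ else s$n)
  })
}
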