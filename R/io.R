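#' Read a batch-culture time course from CSV
#'
#' Expects a comma-separated file with a header row: a mandatory `time`
#' column (h), a biomass column named either `od600` or `biomass` (gDW/L),
#' and any number of metabolite columns (mM). Empty cells are missing values.
#' OD600 readings are converted to gDW/L with the strain-specific conversion
#' factor.
#'
#' @param path CSV file path.
#' @param od_to_gdw Conversion factor in gDW per OD600 unit (default 0.37).
#' @return A tibble with `time`, `biomass` (gDW/L) and metabolite columns;
#'   attributes `biomass_unit` (the unit found in the file) and `od_to_gdw`.
#' @export
read_timecourse <- function(path, od_to_gdw = 0.37) {
  stopifnot(is.numeric(od_to_gdw), od_to_gdw > 0)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (anyDuplicated(names(raw))) {
    stop("duplicate columns in ", path, ": ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "), call. = FALSE)
  }
  if (!"time" %in% names(raw)) stop("missing required column `time` in ", path, call. = FALSE)
  unit_col <- intersect(c("od600", "biomass"), names(raw))
  if (length(unit_col) == 0) {
    stop("need a biomass column named `od600` or `biomass` in ", path, call. = FALSE)
  }
  if (length(unit_col) > 1) stop("at most one biomass column allowed in ", path, call. = FALSE)

  out <- raw
  for (col in names(raw)) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(vals))
    if (length(bad) > 0) {
      stop("non-numeric value in ", path, ", column `", col, "`, data row ",
           bad[1], ": \"", raw[[col]][bad[1]], "\"", call. = FALSE)
    }
    out[[col]] <- vals
  }
  if (any(is.na(out$time))) stop("missing values in `time` column of ", path, call. = FALSE)
  out <- dplyr::arrange(out, .data$time)
  check_times(out$time)

  if (unit_col == "od600") {
    out$biomass <- out$od600 * od_to_gdw
    out$od600 <- NULL
  }
  out <- dplyr::relocate(out, "time", "biomass")
  attr(out, "biomass_unit") <- if (unit_col == "od600") "od600" else "gdw_per_l"
  attr(out, "od_to_gdw") <- od_to_gdw
  out
}

#' Write a time course to CSV
#'
#' Values are written with full double precision so that write/read round
#' trips are lossless.
#'
#' @param data A time-course tibble (`time`, `biomass`, metabolites).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

#' Aggregate parameter estimates across replicate experiments
#'
#' Computes the per-parameter sample mean and standard deviation (n - 1
#' denominator) across replicate fits, e.g. biological triplicates. This is
#' distinct from the within-fit parametric-bootstrap precision of
#' [estimate_precision()] and is labeled accordingly.
#'
#' @param fits A list of `flux_fit` objects (>= 2) with identical parameter
#'   sets.
#' @return A tibble with `term`, `mean`, `sd`, `n`, `unit` and
#'   `basis = "replicate aggregation"`.
#' @examples
#' \dontrun{
#' fits <- lapply(1:3, function(s)
#'   fit_timecourse(generate_culture(seed = s)$timecourse,
#'                  fit_config(fix_k = c(DHA = 0.0086))))
#' aggregate_replicates(fits)
#' }
#' @export
aggregate_replicates <- function(fits) {
  if (!is.list(fits) || length(fits) < 2) {
    stop("need a list of at least 2 fits", call. = FALSE)
  }
  if (!all(vapply(fits, inherits, TRUE, "flux_fit"))) {
    stop("all elements must be flux_fit objects", call. = FALSE)
  }
  terms <- names(fits[[1]]$par)
  same <- vapply(fits, function(f) identical(names(f$par), terms), TRUE)
  if (!all(same)) stop("fits have mismatched parameter sets", call. = FALSE)
  mat <- do.call(rbind, lapply(fits, function(f) f$par[terms]))
  tibble::tibble(
    term = terms,
    mean = unname(colMeans(mat)),
    sd = unname(apply(mat, 2, stats::sd)),
    n = length(fits),
    unit = term_unit(terms),
    basis = "replicate aggregation"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `od_to_gdw`, `carbon_counts` (name: integer),
#' `degradation_constants` (name: 1/h), `fit` (passed to [fit_config()]),
#' `generator` (passed to [generate_culture()]), `fba` (see
#' [fba_model_spec()]). Missing keys fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg$od_to_gdw <- cfg$od_to_gdw %||% 0.37
  if (cfg$od_to_gdw <= 0) stop("od_to_gdw must be > 0", call. = FALSE)
  cfg$carbon_counts <- unlist(cfg$carbon_counts) %||% carbon_counts()
  cfg$degradation_constants <- unlist(cfg$degradation_constants)
  structure(cfg, class = "run_config")
}

#' Write a provenance record for a run
#'
#' Emits a small JSON file recording the package version, a hash of the
#' effective configuration, the seed, and a timestamp, so results can be
#' traced to the exact settings that produced them.
#'
#' @param path Output JSON path.
#' @param config The configuration object used (any list).
#' @param seed The seed used, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, config, seed = NULL) {
  rec <- list(
    package = "batchflux",
    version = as.character(utils::packageVersion("batchflux")),
    config_hash = rlang::hash(config),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
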