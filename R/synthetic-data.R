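#' Default measurement-noise model
#'
#' Additive Gaussian noise with a per-point standard deviation
#' `max(rel * |value|, floor)`. Defaults: 5% relative on biomass with a floor
#' of 0.002 gDW/L, and 2% relative on metabolite concentrations with a floor
#' of 0.05 mM. Noise is unclipped: small negative concentrations can occur
#' near depletion, as they do in real quantification.
#'
#' @param biomass_rel,biomass_floor Relative SD and absolute floor for biomass.
#' @param metabolite_rel,metabolite_floor Same for metabolite concentrations.
#' @return A list of class `noise_config`.
#' @export
noise_config <- function(biomass_rel = 0.05, biomass_floor = 0.002,
                         metabolite_rel = 0.02, metabolite_floor = 0.05) {
  vals <- c(biomass_rel, biomass_floor, metabolite_rel, metabolite_floor)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("noise parameters must be finite and >= 0", call. = FALSE)
  }
  structure(list(biomass_rel = biomass_rel, biomass_floor = biomass_floor,
                 metabolite_rel = metabolite_rel, metabolite_floor = metabolite_floor),
            class = "noise_config")
}

noise_sd <- function(values, rel, floor) pmax(rel * abs(values), floor)

#' Ground-truth parameter presets
#'
#' `"wildtype_dha"`: E. coli growing on 15 mM dihydroxyacetone (DHA), seeded
#' at OD600 0.05 (0.0185 gDW/L at 0.37 gDW per OD unit), growth rate
#' 0.15 1/h, DHA uptake 5.2 mmol/gDW/h and abiotic DHA decay 0.0086 1/h.
#'
#' @param preset Preset name.
#' @return A [kinetic_params()] object.
#' @export
culture_preset <- function(preset = "wildtype_dha") {
  switch(preset,
    wildtype_dha = kinetic_params(
      x0 = 0.05 * 0.37, mu = 0.15,
      metabolites = tibble::tibble(name = "DHA", m0 = 15, q = -5.2, k = 0.0086)
    ),
    stop("unknown preset `", preset, "`; available: wildtype_dha", call. = FALSE)
  )
}

#' Abiotic decay-rate presets
#'
#' `"abiotic_lowsalt"` is the 5x-diluted-salt condition (k = 0.0086 1/h);
#' `"abiotic_highsalt"` is the full-salt condition, with k chosen so that 82%
#' of the substrate degrades within 48 h, i.e. k = -log(0.18)/48.
#'
#' @param preset Preset name.
#' @return The first-order decay constant in 1/h.
#' @export
abiotic_preset <- function(preset = "abiotic_lowsalt") {
  switch(preset,
    abiotic_lowsalt = 0.0086,
    abiotic_highsalt = -log(0.18) / 48,
    stop("unknown preset `", preset,
         "`; available: abiotic_lowsalt, abiotic_highsalt", call. = FALSE)
  )
}

#' Time at which a consumed substrate is exhausted
#'
#' First root of the noiseless concentration trajectory, found numerically.
#'
#' @param params A [kinetic_params()] object.
#' @param name Metabolite name; its modeled concentration must become
#'   nonpositive within `horizon`.
#' @param horizon Upper bound of the root search (h).
#' @return Exhaustion time in hours.
#' @export
exhaustion_time <- function(params, name, horizon = 1000) {
  f <- function(t) simulate_metabolite(params, name, t)
  if (f(horizon) > 0) {
    stop("`", name, "` is not exhausted within ", horizon, " h", call. = FALSE)
  }
  stats::uniroot(f, lower = 0, upper = horizon, tol = 1e-10)$root
}

#' Generate a synthetic batch-culture time course with known ground truth
#'
#' Noiseless trajectories come from the analytical model, sampling is
#' truncated just before the substrate-exhaustion time (every emitted point
#' has positive noiseless substrate), then additive Gaussian noise is applied.
#'
#' @param params A [kinetic_params()] object or a preset name for
#'   [culture_preset()]. Default is the wild-type DHA preset.
#' @param times Sampling times (h); default every 2 h over 48 h.
#' @param noise A [noise_config()]; pass `NULL` for noiseless output.
#' @param seed Integer seed; mandatory when noise is applied.
#' @param biomass_unit `"gdw_per_l"` (default) or `"od600"` (divides by
#'   `od_to_gdw` before noise).
#' @param od_to_gdw OD600-to-dry-weight conversion factor (gDW per OD unit).
#' @return A list with `timecourse` (tibble: `time`, `biomass`, metabolites)
#'   and `truth` (the generating [kinetic_params()], in gDW/L units).
#' @examples
#' sim <- generate_culture(seed = 1)
#' head(sim$timecourse)
#' @export
generate_culture <- function(params = "wildtype_dha",
                             times = seq(0, 48, by = 2),
                             noise = noise_config(),
                             seed = NULL,
                             biomass_unit = c("gdw_per_l", "od600"),
                             od_to_gdw = 0.37) {
  if (is.character(params)) params <- culture_preset(params)
  stopifnot(inherits(params, "kinetic_params"))
  biomass_unit <- match.arg(biomass_unit)
  check_times(times)

  # truncate at exhaustion of the first consumed substrate (if any runs out)
  consumed <- params$metabolites$name[params$metabolites$q < 0]
  for (nm in consumed) {
    final <- simulate_metabolite(params, nm, max(times))
    if (final <= 0) {
      t_ex <- exhaustion_time(params, nm, horizon = max(times))
      times <- times[times < t_ex]
    }
  }
  if (length(times) < 2) stop("fewer than 2 sampling times before exhaustion", call. = FALSE)

  clean <- simulate_timecourse(params, times)
  out <- clean
  if (biomass_unit == "od600") out$biomass <- out$biomass / od_to_gdw

  noisy <- !is.null(noise)
  if (noisy) {
    stopifnot(inherits(noise, "noise_config"))
    if (is.null(seed)) stop("`seed` is mandatory when noise is applied", call. = FALSE)
    withr::with_seed(seed, {
      out$biomass <- out$biomass +
        stats::rnorm(nrow(out), 0, noise_sd(out$biomass, noise$biomass_rel, noise$biomass_floor))
      for (nm in params$metabolites$name) {
        out[[nm]] <- out[[nm]] +
          stats::rnorm(nrow(out), 0, noise_sd(clean[[nm]], noise$metabolite_rel, noise$metabolite_floor))
      }
    })
  }
  attr(out, "biomass_unit") <- biomass_unit
  list(timecourse = out, truth = params)
}

#' Generate a synthetic abiotic (noninoculated) decay curve
#'
#' The substrate decays as `m0 * exp(-k t)`; each degradation product
#' accumulates as `yield * m0 * (1 - exp(-k t))`.
#'
#' @param k First-order decay constant (1/h) or an [abiotic_preset()] name.
#' @param m0 Initial substrate concentration (mM).
#' @param yields Named numeric vector of molar product yields (see
#'   [dha_yields()]); `NULL` for substrate-only output.
#' @param times Sampling times (h); the default matches the noninoculated
#'   incubation design (samples at 0, 24 and 48 h).
#' @param noise A [noise_config()] (its metabolite settings apply to every
#'   column) or `NULL` for noiseless output.
#' @param seed Integer seed; mandatory when noise is applied.
#' @param substrate Column name for the decaying species.
#' @return A tibble with `time`, the substrate column, and one column per
#'   product.
#' @export
generate_abiotic <- function(k = "abiotic_lowsalt", m0 = 15, yields = dha_yields(),
                             times = c(0, 24, 48), noise = noise_config(),
                             seed = NULL, substrate = "DHA") {
  if (is.character(k)) k <- abiotic_preset(k)
  stopifnot(is.numeric(k), length(k) == 1, k >= 0, is.numeric(m0), m0 >= 0)
  check_times(times)
  if (!is.null(yields)) check_yields(yields)

  out <- tibble::tibble(time = as.numeric(times))
  out[[substrate]] <- m0 * exp(-k * times)
  for (nm in names(yields)) {
    out[[nm]] <- yields[[nm]] * m0 * (1 - exp(-k * times))
  }

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_config"))
    if (is.null(seed)) stop("`seed` is mandatory when noise is applied", call. = FALSE)
    withr::with_seed(seed, {
      for (nm in setdiff(names(out), "time")) {
        out[[nm]] <- out[[nm]] +
          stats::rnorm(nrow(out), 0, noise_sd(out[[nm]], noise$metabolite_rel, noise$metabolite_floor))
      }
    })
  }
  out
}
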