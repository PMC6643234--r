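#' Analytical biomass trajectory of a batch culture
#'
#' Exponential growth with an optional lag: `X(t) = x0` for `t <= t_lag` and
#' `X(t) = x0 * exp(mu * (t - t_lag))` afterwards.
#'
#' @param params A [kinetic_params()] object.
#' @param times Strictly increasing, nonnegative sampling times in hours.
#' @return Numeric vector of biomass concentrations (gDW/L), one per time.
#' @examples
#' p <- kinetic_params(x0 = 1, mu = 0.1)
#' simulate_biomass(p, times = log(2) / 0.1) # one doubling time -> 2
#' @export
simulate_biomass <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  check_times(times)
  s <- pmax(times - params$t_lag, 0)
  params$x0 * exp(params$mu * s)
}

# Tolerance below which mu + k is treated as exactly zero (the analytical
# solution divides by mu + k).
MU_PLUS_K_TOL <- 1e-9

#' Analytical concentration trajectory of one extracellular metabolite
#'
#' Solves d(M)/dt = -k*M + q*X(t) for exponential (or lagged-exponential)
#' biomass. Without a lag,
#' `M(t) = q*x0/(mu + k) * (exp(mu*t) - exp(-k*t)) + m0 * exp(-k*t)`.
#' With a lag, abiotic degradation acts from t = 0 while the biological
#' exchange term starts at `t_lag` (growth time `s = t - t_lag`). In the
#' degenerate limit `mu + k ~ 0` (both rates zero) the linear limit
#' `M(t) = m0 + q*x0*t` is used.
#'
#' @inheritParams simulate_biomass
#' @param name Name of the metabolite (must exist in `params`).
#' @return Numeric vector of concentrations (mM). Values are not clamped at
#'   zero; depletion handling belongs to the data generator.
#' @examples
#' p <- kinetic_params(
#'   x0 = 0.0185, mu = 0.15,
#'   metabolites = tibble::tibble(name = "DHA", m0 = 15, q = -5.2, k = 0.0086)
#' )
#' simulate_metabolite(p, "DHA", times = c(0, 10, 20))
#' @export
simulate_metabolite <- function(params, name, times) {
  stopifnot(inherits(params, "kinetic_params"))
  check_times(times)
  row <- met_row(params, name)
  metabolite_curve(times, x0 = params$x0, mu = params$mu, t_lag = params$t_lag,
                   m0 = row$m0, q = row$q, k = row$k)
}

# Core closed form, shared by the simulator and the fit model function.
# Vectorized over `times`; parameters are scalars.
metabolite_curve <- function(times, x0, mu, t_lag, m0, q, k) {
  s <- pmax(times - t_lag, 0)
  decay <- exp(-k * times)
  # Degradation acts from t = 0, exchange from t_lag:
  #   t <= t_lag: M = m0 * exp(-k t)
  #   t >  t_lag: M = q x0/(mu+k) * (e^{mu s} - e^{-k s}) + m0 e^{-k t}
  # (s = 0 makes the exchange term vanish, so one expression covers both).
  # Rearranged as e^{-k s} * expm1((mu+k) s) / (mu+k) for numerical stability;
  # below the tolerance the series limit q x0 e^{-k s} s is used (mu = k = 0
  # gives the linear form m0 + q x0 t).
  if (abs(mu + k) < MU_PLUS_K_TOL) {
    exchange <- q * x0 * exp(-k * s) * s
  } else {
    exchange <- q * x0 * exp(-k * s) * expm1((mu + k) * s) / (mu + k)
  }
  exchange + m0 * decay
}

#' Analytical trajectories for biomass and all metabolites
#'
#' @inheritParams simulate_biomass
#' @return A tibble with columns `time`, `biomass`, and one column per
#'   metabolite (mM).
#' @export
simulate_timecourse <- function(params, times) {
  stopifnot(inherits(params, "kinetic_params"))
  check_times(times)
  out <- tibble::tibble(time = as.numeric(times),
                        biomass = simulate_biomass(params, times))
  for (nm in params$metabolites$name) {
    out[[nm]] <- simulate_metabolite(params, nm, times)
  }
  out
}

#' Numerical (ODE) trajectories of the batch-culture model
#'
#' Integrates dX/dt = mu * X (X frozen at `x0` during the lag) and
#' dM_i/dt = -k_i * M_i + q_i * X(t) with `deSolve::lsoda()`. Serves as an
#' independent check of the analytical solutions.
#'
#' @inheritParams simulate_biomass
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @return A tibble shaped like [simulate_timecourse()].
#' @export
simulate_ode <- function(params, times, rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(params, "kinetic_params"))
  check_times(times)
  mets <- params$metabolites
  t_out <- unique(sort(c(0, params$t_lag, times)))
  state <- c(X = params$x0, stats::setNames(mets$m0, mets$name))

  deriv <- function(t, y, parms) {
    growing <- t >= parms$t_lag
    # exchange is inactive during lag; biomass constant there
    dX <- if (growing) parms$mu * y[["X"]] else 0
    dM <- -parms$k * y[-1] + (if (growing) parms$q * y[["X"]] else 0 * parms$q)
    list(c(dX, dM))
  }

  sol <- deSolve::lsoda(
    y = state, times = t_out, func = deriv,
    parms = list(mu = params$mu, t_lag = params$t_lag, q = mets$q, k = mets$k),
    rtol = rtol, atol = atol
  )
  istate <- attr(sol, "istate")[1]
  if (!is.null(istate) && istate < 0) {
    stop("ODE integration failed (lsoda istate = ", istate,
         "); try looser tolerances or check parameter magnitudes", call. = FALSE)
  }
  sol <- tibble::as_tibble(as.data.frame(sol))
  sol <- sol[match(times, sol$time), ]
  names(sol)[names(sol) == "X"] <- "biomass"
  tibble::as_tibble(sol)
}
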