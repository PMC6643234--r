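#' Molar branch yields of nonenzymatic DHA degradation
#'
#' Default conversion yields of dihydroxyacetone in (5x-diluted-salt) M9
#' medium: formate 36%, glycolate 26%, acetate 1.3% per mole of DHA degraded.
#' The yields are read as molar fractions; they deliberately do not sum to 1 —
#' the remainder is attributed to unidentified products.
#'
#' @return Named numeric vector of molar yields.
#' @export
dha_yields <- function() {
  c(formate = 0.36, glycolate = 0.26, acetate = 0.013)
}

check_yields <- function(yields) {
  if (!is.numeric(yields) || is.null(names(yields)) || any(names(yields) == "")) {
    stop("`yields` must be a named numeric vector", call. = FALSE)
  }
  if (any(!is.finite(yields)) || any(yields < 0)) {
    stop("yields must be finite and >= 0", call. = FALSE)
  }
  if (sum(yields) > 1 + 1e-12) {
    stop("yields sum to ", signif(sum(yields), 4), " > 1; at most one mole of ",
         "product pool per mole of substrate degraded", call. = FALSE)
  }
  invisible(yields)
}

#' Fit first-order decay kinetics to a noninoculated (abiotic) curve
#'
#' Fits `M(t) = m0 * exp(-k t)` by nonlinear least squares, initialized by
#' log-linear regression. Reports the rate constant with its asymptotic
#' standard error, the reciprocal time constant 1/k, the true exponential
#' half-life ln(2)/k, and the Pearson correlation between observed and fitted
#' values.
#'
#' @param times Sampling times (h), at least 3.
#' @param concentrations Observed concentrations (mM), positive for the
#'   log-linear initialization.
#' @param sigma Optional per-point measurement SD used as weights; default
#'   unweighted.
#' @return An object of class `degradation_fit` with elements `k`, `k_sd`,
#'   `m0`, `characteristic_time` (1/k), `half_life` (ln 2/k), `pearson_r`,
#'   `fitted` (tibble of time/observed/fitted/residual) and `k_clamped`
#'   (TRUE when an increasing series drove k to its lower bound 0).
#' @examples
#' t <- seq(0, 48, by = 3)
#' fit_degradation(t, 15 * exp(-0.0086 * t))
#' @export
fit_degradation <- function(times, concentrations, sigma = NULL) {
  check_times(times)
  if (length(times) < 3) stop("need at least 3 points to fit decay kinetics", call. = FALSE)
  if (length(concentrations) != length(times)) {
    stop("`concentrations` must match `times` in length", call. = FALSE)
  }
  if (any(!is.finite(concentrations))) stop("concentrations must be finite", call. = FALSE)
  if (is.null(sigma)) sigma <- rep(1, length(times))
  if (any(sigma <= 0)) stop("`sigma` must be positive", call. = FALSE)

  # log-linear initialization (requires positive concentrations)
  pos <- concentrations > 0
  if (sum(pos) < 2) stop("need >= 2 positive concentrations for initialization", call. = FALSE)
  init <- stats::lm(log(concentrations[pos]) ~ times[pos])
  k0 <- max(-unname(stats::coef(init)[2]), 0)
  m00 <- exp(unname(stats::coef(init)[1]))

  resid_fn <- function(par) (concentrations - par[["m0"]] * exp(-par[["k"]] * times)) / sigma
  fit <- minpack.lm::nls.lm(
    par = c(m0 = m00, k = k0),
    lower = c(m0 = 0, k = 0), upper = c(m0 = Inf, k = Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  k <- unname(fit$par[["k"]])
  m0 <- unname(fit$par[["m0"]])
  k_clamped <- k <= 0
  if (k_clamped) warning("concentrations do not decrease; k clamped at 0", call. = FALSE)

  # asymptotic SE from the Jacobian (NA when k sits on the bound or df = 0)
  k_sd <- NA_real_
  dof <- length(times) - 2
  if (!k_clamped && dof > 0) {
    covm <- tryCatch(solve(fit$hessian) * fit$deviance / dof, error = function(e) NULL)
    if (!is.null(covm) && covm[2, 2] >= 0) k_sd <- sqrt(covm[2, 2])
  }

  fitted_vals <- m0 * exp(-k * times)
  r <- if (stats::sd(concentrations) == 0 || stats::sd(fitted_vals) == 0) NA_real_
       else stats::cor(concentrations, fitted_vals)

  structure(list(
    k = k, k_sd = k_sd, m0 = m0,
    characteristic_time = if (k > 0) 1 / k else Inf,
    half_life = if (k > 0) log(2) / k else Inf,
    pearson_r = r,
    k_clamped = k_clamped,
    converged = fit$info %in% 1:4,
    fitted = tibble::tibble(time = as.numeric(times),
                            observed = as.numeric(concentrations),
                            fitted = fitted_vals,
                            residual = as.numeric(concentrations) - fitted_vals)
  ), class = "degradation_fit")
}

#' @export
print.degradation_fit <- function(x, ...) {
  cat("<degradation_fit>\n")
  cat(sprintf("  k                  : %.5g 1/h (SD %.3g)%s\n", x$k, x$k_sd,
              if (x$k_clamped) " [clamped at 0]" else ""))
  cat(sprintf("  reciprocal 1/k     : %.4g h\n", x$characteristic_time))
  cat(sprintf("  half-life ln(2)/k  : %.4g h\n", x$half_life))
  cat(sprintf("  Pearson r          : %.5f\n", x$pearson_r))
  invisible(x)
}

#' @method tidy degradation_fit
#' @export
tidy.degradation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("k", "m0"),
    estimate = c(x$k, x$m0),
    std.error = c(x$k_sd, NA_real_),
    unit = c("1/h", "mM")
  )
}

#' @method glance degradation_fit
#' @export
glance.degradation_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, k_sd = x$k_sd,
    characteristic_time = x$characteristic_time, half_life = x$half_life,
    pearson_r = x$pearson_r, n = nrow(x$fitted),
    converged = x$converged, k_clamped = x$k_clamped
  )
}

#' @rdname plot_degradation
#' @method autoplot degradation_fit
#' @export
autoplot.degradation_fit <- function(object, ...) {
  df <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "time (h)", y = "concentration (mM)",
                  title = sprintf("first-order decay: k = %.4g 1/h, r = %.4f",
                                  object$k, object$pearson_r))
}

#' Plot an abiotic degradation fit
#'
#' Observed points with the fitted first-order decay curve.
#'
#' @param object A `degradation_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_degradation <- function(object, ...) autoplot.degradation_fit(object, ...)

#' Fraction of substrate degraded after a given time
#'
#' For first-order decay, `1 - exp(-k t)`.
#'
#' @param k Decay constant (1/h), >= 0. Vectorized.
#' @param t Elapsed time (h), >= 0. Vectorized.
#' @return Fraction in `[0, 1)`.
#' @examples
#' degraded_fraction(0.0086, 48) # ~0.34
#' @export
degraded_fraction <- function(k, t) {
  if (any(!is.finite(k)) || any(k < 0)) stop("`k` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(t)) || any(t < 0)) stop("`t` must be finite and >= 0", call. = FALSE)
  1 - exp(-k * t)
}

#' Characteristic times of first-order decay
#'
#' Returns both the reciprocal time constant 1/k and the exponential
#' half-life ln(2)/k, explicitly labeled — the two are sometimes conflated in
#' the literature (1/k is ln(2)/k * 1.44, i.e. the time to decay to 1/e).
#'
#' @param k Decay constant (1/h), > 0 for finite results; k = 0 yields
#'   unbounded times flagged in the output.
#' @return A tibble with columns `quantity` (`"reciprocal_time"`,
#'   `"half_life"`), `hours`, and `unbounded`.
#' @examples
#' characteristic_times(0.0086) # 1/k = 116 h, ln(2)/k = 80.6 h
#' @export
characteristic_times <- function(k) {
  stopifnot(is.numeric(k), length(k) == 1)
  if (!is.finite(k) || k < 0) stop("`k` must be finite and >= 0", call. = FALSE)
  unbounded <- k == 0
  tibble::tibble(
    quantity = c("reciprocal_time", "half_life"),
    hours = if (unbounded) c(Inf, Inf) else c(1 / k, log(2) / k),
    unbounded = unbounded
  )
}

#' Partition a degraded amount among products by molar yields
#'
#' @param amount_degraded Moles (or mmol) of substrate degraded, >= 0.
#' @param yields Named molar yields, see [dha_yields()]; must sum to <= 1.
#' @return A tibble with `product` and `amount`; the last row,
#'   `"unidentified"`, carries the remainder so that the total equals
#'   `amount_degraded` exactly.
#' @examples
#' apply_yields(10) # formate 3.6, glycolate 2.6, acetate 0.13, rest unidentified
#' @export
apply_yields <- function(amount_degraded, yields = dha_yields()) {
  stopifnot(is.numeric(amount_degraded), length(amount_degraded) == 1)
  if (!is.finite(amount_degraded) || amount_degraded < 0) {
    stop("`amount_degraded` must be finite and >= 0", call. = FALSE)
  }
  check_yields(yields)
  amounts <- unname(yields) * amount_degraded
  tibble::tibble(
    product = c(names(yields), "unidentified"),
    amount = c(amounts, amount_degraded - sum(amounts))
  )
}

#' Specific co-consumption fluxes of abiotic degradation products
#'
#' In inoculated cultures the degradation products do not accumulate, so
#' their consumption must balance their abiotic production. Under that
#' quasi-steady assumption the specific uptake flux of product P is
#' `q_P(t) = yield_P * k * M(t) / X(t)`, where M is the substrate and X the
#' biomass concentration. The time average over the supplied window is
#' reported. This balance is a construction of this package, not a fitted
#' quantity, and is labeled as such in outputs.
#'
#' @param k Substrate decay constant (1/h).
#' @param yields Named molar yields per mole of substrate degraded.
#' @param substrate Substrate concentration series (mM), aligned with
#'   `biomass`.
#' @param biomass Biomass series (gDW/L), strictly positive.
#' @return A tibble with `product`, `flux` (mmol/gDW/h, uptake reported
#'   positive) and `basis = "quasi-steady balance"`.
#' @examples
#' coconsumption_fluxes(0.0086, dha_yields(), substrate = 15, biomass = 0.04)
#' @export
coconsumption_fluxes <- function(k, yields, substrate, biomass) {
  stopifnot(is.numeric(k), length(k) == 1, k >= 0)
  check_yields(yields)
  if (length(substrate) != length(biomass)) {
    stop("`substrate` and `biomass` must be aligned series", call. = FALSE)
  }
  if (any(!is.finite(biomass)) || any(biomass <= 0)) {
    stop("`biomass` must be positive everywhere in the window", call. = FALSE)
  }
  if (any(!is.finite(substrate)) || any(substrate < 0)) {
    stop("`substrate` must be finite and >= 0", call. = FALSE)
  }
  per_time <- k * substrate / biomass
  tibble::tibble(
    product = names(yields),
    flux = unname(yields) * mean(per_time),
    basis = "quasi-steady balance"
  )
}
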