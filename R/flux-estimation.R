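#' Configuration for flux estimation
#'
#' @param estimate_lag Estimate a lag phase `t_lag`? Default `FALSE`.
#' @param fix_k Named numeric vector of first-order degradation constants
#'   (1/h) per metabolite, typically taken from abiotic-control fits via
#'   [fit_degradation()]. Metabolites not listed get k = 0. Ignored for
#'   metabolites being co-estimated.
#' @param co_estimate_k Co-estimate k alongside the fluxes instead of fixing
#'   it? Default `FALSE` (fixing k from noninoculated controls is the
#'   recommended workflow).
#' @param weights Measurement-error model used both to weight the residuals
#'   and as the parametric-bootstrap noise model: either a [noise_config()]
#'   (relative SD with absolute floor, the default) or a named numeric vector
#'   of absolute per-series SDs (names `biomass` and metabolite names).
#' @param bounds Optional named list overriding the default box bounds
#'   (`x0` \[1e-6, 10\] gDW/L, `mu` \[1e-4, 2\] 1/h, `t_lag` \[0, 24\] h,
#'   `q` \[-50, 50\] mmol/gDW/h, `m0` \[0, 2 max(obs)\] mM, `k` \[0, 2\] 1/h);
#'   each element a length-2 `c(lower, upper)`.
#' @param mc_iterations Number of parametric-bootstrap replicates used by
#'   [estimate_precision()]. Default 100.
#' @param seed Integer seed for the bootstrap; mandatory there.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(estimate_lag = FALSE, fix_k = NULL, co_estimate_k = FALSE,
                       weights = noise_config(), bounds = NULL,
                       mc_iterations = 100, seed = NULL) {
  if (!is.null(fix_k)) {
    if (!is.numeric(fix_k) || is.null(names(fix_k))) {
      stop("`fix_k` must be a named numeric vector", call. = FALSE)
    }
    if (any(!is.finite(fix_k)) || any(fix_k < 0)) {
      stop("all fixed k must be finite and >= 0", call. = FALSE)
    }
  }
  if (!inherits(weights, "noise_config")) {
    if (!is.numeric(weights) || is.null(names(weights)) || any(weights <= 0)) {
      stop("`weights` must be a noise_config or a named vector of positive SDs", call. = FALSE)
    }
  }
  if (!is.numeric(mc_iterations) || mc_iterations < 1) {
    stop("`mc_iterations` must be >= 1", call. = FALSE)
  }
  if (!is.null(bounds)) {
    ok <- vapply(bounds, function(b) is.numeric(b) && length(b) == 2 && b[1] < b[2], TRUE)
    if (!all(ok)) stop("each bounds entry must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  structure(list(estimate_lag = isTRUE(estimate_lag), fix_k = fix_k,
                 co_estimate_k = isTRUE(co_estimate_k), weights = weights,
                 bounds = bounds, mc_iterations = as.integer(mc_iterations),
                 seed = seed),
            class = "fit_config")
}

# per-point measurement SD for one series under the configured error model
series_sigma <- function(values, series, weights) {
  if (inherits(weights, "noise_config")) {
    if (series == "biomass") {
      sd <- noise_sd(values, weights$biomass_rel, weights$biomass_floor)
    } else {
      sd <- noise_sd(values, weights$metabolite_rel, weights$metabolite_floor)
    }
  } else {
    if (!series %in% names(weights)) {
      stop("no weight configured for series `", series, "`", call. = FALSE)
    }
    sd <- rep(weights[[series]], length(values))
  }
  pmax(sd, 1e-12) # keep weighting finite for (near-)noiseless data
}

default_bound <- function(what, config, data_max = NULL) {
  user <- config$bounds[[what]]
  if (!is.null(user)) return(user)
  switch(what,
    x0 = c(1e-6, 10),
    mu = c(1e-4, 2),
    t_lag = c(0, 24),
    q = c(-50, 50),
    m0 = c(0, 2 * data_max),
    k = c(0, 2)
  )
}

clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

# Assemble the parameter vector, bounds and an unpacking closure for a
# given dataset + configuration.
build_parameterization <- function(data, config) {
  met_names <- setdiff(names(data), c("time", "biomass"))
  t <- data$time
  x <- data$biomass

  # initialization: log-linear regression of biomass vs time
  pos <- !is.na(x) & x > 0
  if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(x[pos]) ~ t[pos]))
    x0_init <- exp(unname(cf[1])); mu_init <- unname(cf[2])
  } else {
    x0_init <- max(x, 1e-3, na.rm = TRUE); mu_init <- 0.1
  }

  b_x0 <- default_bound("x0", config)
  b_mu <- default_bound("mu", config)
  par <- c(x0 = clamp(x0_init, b_x0), mu = clamp(mu_init, b_mu))
  lower <- c(x0 = b_x0[1], mu = b_mu[1])
  upper <- c(x0 = b_x0[2], mu = b_mu[2])

  if (config$estimate_lag) {
    b_lag <- default_bound("t_lag", config)
    par <- c(par, t_lag = clamp(0, b_lag))
    lower <- c(lower, t_lag = b_lag[1]); upper <- c(upper, t_lag = b_lag[2])
  }

  # trapezoid of observed biomass, for the q initial guess
  xi <- x; xi[is.na(xi)] <- stats::approx(t[!is.na(x)], x[!is.na(x)], t, rule = 2)$y[is.na(x)]
  int_x <- sum(diff(t) * (utils::head(xi, -1) + utils::tail(xi, -1)) / 2)

  fixed_k <- stats::setNames(rep(0, length(met_names)), met_names)
  if (!is.null(config$fix_k)) {
    known <- intersect(names(config$fix_k), met_names)
    fixed_k[known] <- config$fix_k[known]
  }

  for (nm in met_names) {
    m <- data[[nm]]
    ok <- !is.na(m)
    m_first <- m[ok][1]; m_last <- rev(m[ok])[1]
    k_nm <- fixed_k[[nm]]
    b_m0 <- default_bound("m0", config, data_max = max(abs(m[ok]), 1e-6))
    b_q <- default_bound("q", config)
    q_init <- ((m_last - m_first) + k_nm * mean(m[ok]) * (max(t[ok]) - min(t[ok]))) /
      max(int_x, 1e-12)
    par <- c(par, stats::setNames(clamp(max(m_first, 0), b_m0), paste0("m0_", nm)),
             stats::setNames(clamp(q_init, b_q), paste0("q_", nm)))
    lower <- c(lower, stats::setNames(b_m0[1], paste0("m0_", nm)),
               stats::setNames(b_q[1], paste0("q_", nm)))
    upper <- c(upper, stats::setNames(b_m0[2], paste0("m0_", nm)),
               stats::setNames(b_q[2], paste0("q_", nm)))
    if (config$co_estimate_k) {
      b_k <- default_bound("k", config)
      par <- c(par, stats::setNames(clamp(k_nm, b_k), paste0("k_", nm)))
      lower <- c(lower, stats::setNames(b_k[1], paste0("k_", nm)))
      upper <- c(upper, stats::setNames(b_k[2], paste0("k_", nm)))
    }
  }

  unpack <- function(p) {
    mets <- tibble::tibble(
      name = met_names,
      m0 = unname(p[paste0("m0_", met_names)]),
      q = unname(p[paste0("q_", met_names)]),
      k = if (config$co_estimate_k) unname(p[paste0("k_", met_names)])
          else unname(fixed_k[met_names])
    )
    kinetic_params(x0 = unname(p[["x0"]]), mu = unname(p[["mu"]]),
                   t_lag = if (config$estimate_lag) unname(p[["t_lag"]]) else 0,
                   metabolites = if (length(met_names) > 0) mets else NULL)
  }

  list(par = par, lower = lower, upper = upper, unpack = unpack,
       met_names = met_names, fixed_k = fixed_k)
}

# long table of observations with per-point sigma
observation_table <- function(data, weights) {
  met_names <- setdiff(names(data), c("time", "biomass"))
  long <- tidyr::pivot_longer(data, cols = dplyr::all_of(c("biomass", met_names)),
                              names_to = "series", values_to = "observed")
  long <- dplyr::filter(long, !is.na(.data$observed))
  long <- dplyr::group_by(long, .data$series)
  long <- dplyr::mutate(long, sigma = series_sigma(.data$observed, .data$series[1], weights))
  dplyr::ungroup(long)
}

# times within one series are strictly increasing (data is arranged by time)
predict_series <- function(params, series, times) {
  if (series == "biomass") simulate_biomass(params, times)
  else simulate_metabolite(params, series, times)
}

#' Fit growth rate and exchange fluxes to a batch-culture time course
#'
#' Joint weighted nonlinear least-squares estimation of the initial biomass
#' `x0`, growth rate `mu`, optionally a lag `t_lag`, and per-metabolite
#' initial concentration `m0` and exchange flux `q`, using the analytical
#' batch model with first-order abiotic degradation (constants fixed from
#' noninoculated controls, or co-estimated). The objective is
#' `sum(((obs - model)/sigma)^2)` over all series, minimized by box-bounded
#' Levenberg–Marquardt.
#'
#' @param data A data frame with columns `time` (h), `biomass` (gDW/L) and
#'   one column per metabolite (mM). At least 4 biomass observations and 3
#'   per metabolite series; empty cells may be `NA`.
#' @param config A [fit_config()].
#' @param window Optional `c(t_min, t_max)` restricting the fit to a time
#'   window (e.g. the exponential phase); by default all observations are
#'   used.
#' @return An object of class `flux_fit`; see [tidy.flux_fit()],
#'   [glance.flux_fit()], [estimate_precision()], [goodness_of_fit()].
#' @examples
#' sim <- generate_culture(seed = 1)
#' fit <- fit_timecourse(sim$timecourse, fit_config(fix_k = c(DHA = 0.0086)))
#' tidy(fit)
#' @export
fit_timecourse <- function(data, config = fit_config(), window = NULL) {
  stopifnot(inherits(config, "fit_config"))
  data <- tibble::as_tibble(data)
  if (!"time" %in% names(data) || !"biomass" %in% names(data)) {
    stop("`data` needs `time` and `biomass` columns", call. = FALSE)
  }
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 2)
    data <- dplyr::filter(data, .data$time >= window[1], .data$time <= window[2])
  }
  data <- dplyr::arrange(data, .data$time)
  check_times(data$time)
  if (sum(!is.na(data$biomass)) < 4) {
    stop("need at least 4 biomass observations", call. = FALSE)
  }
  met_names <- setdiff(names(data), c("time", "biomass"))
  for (nm in met_names) {
    if (sum(!is.na(data[[nm]])) < 3) {
      stop("metabolite series `", nm, "` needs at least 3 observations", call. = FALSE)
    }
  }

  parm <- build_parameterization(data, config)
  obs <- observation_table(data, config$weights)

  resid_fn <- function(p) {
    p <- stats::setNames(p, names(parm$par))
    params <- parm$unpack(p)
    pred <- numeric(nrow(obs))
    for (ser in unique(obs$series)) {
      idx <- obs$series == ser
      pred[idx] <- predict_series(params, ser, obs$time[idx])
    }
    (obs$observed - pred) / obs$sigma
  }

  fit <- minpack.lm::nls.lm(
    par = parm$par, lower = parm$lower, upper = parm$upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("optimizer did not converge (info = ", fit$info, "): ", fit$message,
            call. = FALSE)
  }

  est <- parm$unpack(stats::setNames(fit$par, names(parm$par)))
  pred <- numeric(nrow(obs))
  for (ser in unique(obs$series)) {
    idx <- obs$series == ser
    pred[idx] <- predict_series(est, ser, obs$time[idx])
  }
  residuals <- dplyr::mutate(obs, fitted = pred,
                             residual = .data$observed - .data$fitted)

  out <- structure(list(
    estimates = est,
    par = stats::setNames(as.numeric(fit$par), names(parm$par)),
    lower = parm$lower, upper = parm$upper,
    objective = fit$deviance,
    rsstrace = fit$rsstrace,
    converged = converged,
    optim_info = fit$info, optim_message = fit$message,
    residuals = residuals,
    data = data, config = config,
    boot = NULL
  ), class = "flux_fit")
  out$pearson <- goodness_of_fit(out)
  out
}

#' Pearson goodness of fit of a flux estimation
#'
#' Correlation between observed and fitted values, per series and pooled over
#' all series. A constant observed series has no defined correlation and is
#' reported as `NA` with `note = "constant series"`.
#'
#' @param fit A `flux_fit`.
#' @return A tibble with `series` (including `"pooled"`), `pearson_r`, `n`,
#'   and `note`.
#' @export
goodness_of_fit <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  res <- fit$residuals
  one <- function(df, label) {
    constant <- stats::sd(df$observed) == 0
    tibble::tibble(
      series = label,
      pearson_r = if (constant) NA_real_ else stats::cor(df$observed, df$fitted),
      n = nrow(df),
      note = if (constant) "constant series" else NA_character_
    )
  }
  per <- dplyr::bind_rows(lapply(split(res, res$series), function(d) one(d, d$series[1])))
  dplyr::bind_rows(per, one(res, "pooled"))
}

#' Parametric-bootstrap precision of fitted parameters
#'
#' Simulates `mc_iterations` replicate datasets from the fitted parameters
#' plus the configured measurement-error model, refits each, and reports the
#' per-parameter standard deviation and 2.5/97.5 percentile interval.
#' Deterministic given the seed. Non-converged replicates are excluded and
#' counted; more than 20% failures raises a warning.
#'
#' @param fit A converged `flux_fit`.
#' @param mc_iterations,seed Optional overrides of the values in the fit's
#'   config.
#' @return The `flux_fit` with a `boot` element (`sd`, `ci`, `draws`,
#'   `n_fail`); see [tidy.flux_fit()].
#' @export
estimate_precision <- function(fit, mc_iterations = NULL, seed = NULL) {
  stopifnot(inherits(fit, "flux_fit"))
  if (!fit$converged) stop("cannot bootstrap a non-converged fit", call. = FALSE)
  B <- mc_iterations %||% fit$config$mc_iterations
  seed <- seed %||% fit$config$seed
  if (is.null(seed)) stop("a seed is required for the bootstrap", call. = FALSE)

  data <- fit$data
  met_names <- setdiff(names(data), c("time", "biomass"))
  clean <- simulate_timecourse(fit$estimates, data$time)
  weights <- fit$config$weights

  draws <- matrix(NA_real_, nrow = B, ncol = length(fit$par),
                  dimnames = list(NULL, names(fit$par)))
  n_fail <- 0
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      rep_data <- data
      for (ser in c("biomass", met_names)) {
        ok <- !is.na(data[[ser]])
        sd_b <- series_sigma(clean[[ser]][ok], ser, weights)
        rep_data[[ser]][ok] <- clean[[ser]][ok] + stats::rnorm(sum(ok), 0, sd_b)
      }
      rep_fit <- tryCatch(
        suppressWarnings(fit_timecourse(rep_data, fit$config)),
        error = function(e) NULL
      )
      if (is.null(rep_fit) || !rep_fit$converged) {
        n_fail <- n_fail + 1
      } else {
        draws[b, ] <- rep_fit$par[colnames(draws)]
      }
    }
  })
  if (n_fail > 0.2 * B) {
    warning(n_fail, " of ", B, " bootstrap replicates failed to converge", call. = FALSE)
  }
  kept <- draws[stats::complete.cases(draws), , drop = FALSE]
  if (nrow(kept) < 2) stop("too few converged bootstrap replicates", call. = FALSE)

  fit$boot <- list(
    sd = apply(kept, 2, stats::sd),
    ci = tibble::tibble(
      term = colnames(kept),
      conf.low = apply(kept, 2, stats::quantile, probs = 0.025, names = FALSE),
      conf.high = apply(kept, 2, stats::quantile, probs = 0.975, names = FALSE)
    ),
    mc_iterations = B, n_fail = n_fail, seed = seed,
    method = "parametric bootstrap"
  )
  fit
}

term_unit <- function(term) {
  dplyr::case_when(
    term == "x0" ~ "gDW/L",
    term == "mu" ~ "1/h",
    term == "t_lag" ~ "h",
    startsWith(term, "m0_") ~ "mM",
    startsWith(term, "q_") ~ "mmol/gDW/h",
    startsWith(term, "k_") ~ "1/h",
    TRUE ~ ""
  )
}

#' @method tidy flux_fit
#' @export
tidy.flux_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$par), estimate = unname(x$par),
                        unit = term_unit(names(x$par)))
  if (!is.null(x$boot)) {
    out$std.error <- unname(x$boot$sd[out$term])
    out <- dplyr::left_join(out, x$boot$ci, by = "term")
    out <- out[c("term", "estimate", "std.error", "conf.low", "conf.high", "unit")]
  }
  out
}

#' @method glance flux_fit
#' @export
glance.flux_fit <- function(x, ...) {
  pooled <- x$pearson$pearson_r[x$pearson$series == "pooled"]
  tibble::tibble(
    objective = x$objective,
    converged = x$converged,
    n_obs = nrow(x$residuals),
    n_par = length(x$par),
    pooled_r = pooled,
    mc_iterations = if (is.null(x$boot)) NA_integer_ else x$boot$mc_iterations
  )
}

#' @export
print.flux_fit <- function(x, ...) {
  cat("<flux_fit>", if (x$converged) "(converged)" else "(NOT converged)", "\n")
  cat(sprintf("  weighted SSR: %.6g over %d observations\n",
              x$objective, nrow(x$residuals)))
  print(tidy(x))
  invisible(x)
}

#' Exchange rates in the uptake-positive reporting convention
#'
#' The model's sign convention is production-positive (`q > 0` = net
#' secretion). Field reports print uptake rates as positive numbers; this
#' helper relabels each flux accordingly.
#'
#' @param fit A `flux_fit`.
#' @return A tibble with `name`, `q` (model sign), `direction` and `rate`
#'   (= `abs(q)`, mmol/gDW/h).
#' @export
exchange_rates <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  mets <- fit$estimates$metabolites
  tibble::tibble(
    name = mets$name,
    q = mets$q,
    direction = ifelse(mets$q < 0, "uptake", "production"),
    rate = abs(mets$q)
  )
}

#' @rdname plot_fit
#' @method autoplot flux_fit
#' @export
autoplot.flux_fit <- function(object, ...) {
  res <- object$residuals
  grid <- seq(min(res$time), max(res$time), length.out = 200)
  curves <- simulate_timecourse(object$estimates, grid)
  curves <- tidyr::pivot_longer(curves, -"time",
                                names_to = "series", values_to = "fitted")
  ggplot2::ggplot(res, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), colour = "grey30") +
    ggplot2::geom_line(data = curves, ggplot2::aes(y = .data$fitted),
                       colour = "firebrick") +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "concentration",
                  title = "observed vs fitted batch time course")
}

#' Plot a flux fit
#'
#' Observed points and fitted model curves, one panel per series.
#'
#' @param object A `flux_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_fit <- function(object, ...) autoplot.flux_fit(object, ...)
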