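test_that("noiseless data returns the generating parameters to high precision", {
  sim <- generate_culture(noise = NULL)
  fit <- fit_timecourse(sim$timecourse, wt_config())
  expect_true(fit$converged)
  expect_equal(fit$par[["mu"]], 0.15, tolerance = 1e-6)
  expect_equal(fit$par[["q_DHA"]], -5.2, tolerance = 1e-6)
  expect_equal(fit$par[["x0"]], 0.0185, tolerance = 1e-6)
  expect_equal(fit$par[["m0_DHA"]], 15, tolerance = 1e-6)
})

test_that("noisy recovery lands within 3 bootstrap SDs of the truth", {
  sim <- generate_culture(seed = 42)
  fit <- fit_timecourse(sim$timecourse, wt_config(seed = 42, mc_iterations = 100))
  fit <- estimate_precision(fit)
  sd <- fit$boot$sd
  expect_lt(abs(fit$par[["mu"]] - 0.15), 3 * sd[["mu"]])
  expect_lt(abs(fit$par[["q_DHA"]] - (-5.2)), 3 * sd[["q_DHA"]])
  # precision on the wild-type preset is of the order the method reports
  expect_gt(sd[["mu"]], 0.0001)
  expect_lt(sd[["mu"]], 0.1)
  expect_gt(sd[["q_DHA"]], 0.001)
  expect_lt(sd[["q_DHA"]], 1)
})

test_that("a metabolite generated with zero flux is recovered as null", {
  params <- kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = "S", m0 = 10, q = 0, k = 0.0086)
  )
  sim <- generate_culture(params, seed = 3)
  fit <- fit_timecourse(sim$timecourse, fit_config(fix_k = c(S = 0.0086),
                                                   seed = 3, mc_iterations = 80))
  fit <- estimate_precision(fit)
  expect_lt(abs(fit$par[["q_S"]]), 2 * fit$boot$sd[["q_S"]])
})

test_that("optimizer objective never increases across iterations", {
  sim <- generate_culture(seed = 5)
  fit <- fit_timecourse(sim$timecourse, wt_config())
  expect_true(all(diff(fit$rsstrace) <= 1e-10))
})

test_that("estimates are invariant to metabolite column order", {
  params <- kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = c("DHA", "glycerol"),
                                 m0 = c(15, 0), q = c(-5.2, 0.4), k = c(0.0086, 0))
  )
  sim <- generate_culture(params, seed = 9)
  cfg <- fit_config(fix_k = c(DHA = 0.0086))
  fit1 <- fit_timecourse(sim$timecourse, cfg)
  shuffled <- sim$timecourse[, c("time", "glycerol", "biomass", "DHA")]
  fit2 <- fit_timecourse(shuffled, cfg)
  for (term in names(fit1$par)) {
    expect_equal(fit2$par[[term]], fit1$par[[term]], tolerance = 1e-5)
  }
})

test_that("rescaling a series together with its sigma leaves the fit invariant", {
  sim <- generate_culture(seed = 13)
  w1 <- c(biomass = 0.005, DHA = 0.3)
  fit1 <- fit_timecourse(sim$timecourse, fit_config(fix_k = c(DHA = 0.0086), weights = w1))
  scaled <- sim$timecourse
  scaled$DHA <- scaled$DHA * 10
  w2 <- c(biomass = 0.005, DHA = 3)
  fit2 <- fit_timecourse(scaled, fit_config(fix_k = c(DHA = 0.0086), weights = w2,
                                            bounds = list(q = c(-500, 500))))
  expect_equal(fit2$par[["mu"]], fit1$par[["mu"]], tolerance = 1e-6)
  expect_equal(fit2$par[["q_DHA"]], 10 * fit1$par[["q_DHA"]], tolerance = 1e-6)
  expect_equal(fit2$par[["m0_DHA"]], 10 * fit1$par[["m0_DHA"]], tolerance = 1e-6)
  expect_equal(fit2$objective, fit1$objective, tolerance = 1e-6)
})

test_that("ignoring degradation biases the uptake flux upward in magnitude", {
  sim <- generate_culture(noise = NULL) # truth: q = -5.2, k = 0.0086
  fit_no_k <- fit_timecourse(sim$timecourse, fit_config(fix_k = c(DHA = 0)))
  expect_gt(abs(fit_no_k$par[["q_DHA"]]), 5.2)
})

test_that("bootstrap SDs collapse for a noiseless error model and scale with noise", {
  sim <- generate_culture(noise = NULL)
  silent <- noise_config(0, 1e-12, 0, 1e-12)
  fit <- fit_timecourse(sim$timecourse, fit_config(fix_k = c(DHA = 0.0086), weights = silent))
  fit <- estimate_precision(fit, mc_iterations = 20, seed = 1)
  expect_true(all(fit$boot$sd < 1e-6))

  # halving the measurement SD about halves every parameter SD
  full <- noise_config(0.05, 0.002, 0.02, 0.05)
  half <- noise_config(0.025, 0.001, 0.01, 0.025)
  base <- fit_timecourse(generate_culture(seed = 21)$timecourse,
                         fit_config(fix_k = c(DHA = 0.0086)))
  sd_full <- estimate_precision(
    structure(modifyList(base, list(config = fit_config(fix_k = c(DHA = 0.0086), weights = full))),
              class = "flux_fit"),
    mc_iterations = 200, seed = 2)$boot$sd
  sd_half <- estimate_precision(
    structure(modifyList(base, list(config = fit_config(fix_k = c(DHA = 0.0086), weights = half))),
              class = "flux_fit"),
    mc_iterations = 200, seed = 2)$boot$sd
  for (term in c("mu", "q_DHA")) {
    expect_gt(sd_full[[term]] / sd_half[[term]], 1.6)
    expect_lt(sd_full[[term]] / sd_half[[term]], 2.4)
  }
})

test_that("parameter recovery and bootstrap coverage hold over replicates", {
  n_rep <- 50
  mu_hat <- q_hat <- numeric(n_rep)
  cover_mu <- cover_q <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    sim <- generate_culture(seed = 1000 + i)
    fit <- fit_timecourse(sim$timecourse, wt_config())
    mu_hat[i] <- fit$par[["mu"]]
    q_hat[i] <- fit$par[["q_DHA"]]
    fit <- estimate_precision(fit, mc_iterations = 80, seed = 2000 + i)
    ci <- fit$boot$ci
    cover_mu[i] <- ci$conf.low[ci$term == "mu"] <= 0.15 &&
      0.15 <= ci$conf.high[ci$term == "mu"]
    cover_q[i] <- ci$conf.low[ci$term == "q_DHA"] <= -5.2 &&
      -5.2 <= ci$conf.high[ci$term == "q_DHA"]
  }
  expect_lt(stats::median(abs(mu_hat - 0.15) / 0.15), 0.05)
  expect_lt(stats::median(abs(q_hat - (-5.2)) / 5.2), 0.05)
  expect_gte(mean(cover_mu), 0.85)
  expect_gte(mean(cover_q), 0.85)
})

test_that("goodness of fit reports per-series and pooled correlations", {
  sim <- generate_culture(seed = 7)
  fit <- fit_timecourse(sim$timecourse, wt_config())
  gof <- goodness_of_fit(fit)
  expect_setequal(gof$series, c("biomass", "DHA", "pooled"))
  expect_true(all(gof$pearson_r >= -1 & gof$pearson_r <= 1))
  expect_gt(gof$pearson_r[gof$series == "pooled"], 0.99)

  # a constant observed series has no defined correlation
  inert <- kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = "S", m0 = 4, q = 0, k = 0)
  )
  sim0 <- generate_culture(inert, noise = NULL)
  fit0 <- fit_timecourse(sim0$timecourse, fit_config())
  gof0 <- goodness_of_fit(fit0)
  srow <- gof0[gof0$series == "S", ]
  expect_true(is.na(srow$pearson_r))
  expect_identical(srow$note, "constant series")
})

test_that("insufficient observations are rejected with a clear error", {
  sim <- generate_culture(noise = NULL)
  expect_error(fit_timecourse(sim$timecourse[1:3, ], wt_config()), "at least 4")
  few <- sim$timecourse
  few$DHA[-(1:2)] <- NA
  expect_error(fit_timecourse(few, wt_config()), "at least 3")
})
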