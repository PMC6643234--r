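test_that("exact first-order decay is recovered from three points", {
  t <- c(0, 24, 48)
  fit <- fit_degradation(t, 15 * exp(-0.0086 * t))
  expect_equal(fit$k, 0.0086, tolerance = 1e-6)
  expect_equal(fit$m0, 15, tolerance = 1e-6)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-8)
})

test_that("a constant series clamps k at zero with unbounded times", {
  expect_warning(fit <- fit_degradation(c(0, 10, 20, 30), rep(12, 4)), "clamped")
  expect_equal(fit$k, 0)
  expect_true(fit$k_clamped)
  expect_identical(fit$half_life, Inf)
  expect_identical(fit$characteristic_time, Inf)
})

test_that("noisy decay data recover k within its reported uncertainty", {
  curve <- generate_abiotic(k = 0.0086, m0 = 15, yields = NULL,
                            times = seq(0, 48, by = 3), seed = 1)
  fit <- fit_degradation(curve$time, curve$DHA)
  expect_lt(abs(fit$k - 0.0086), 2 * fit$k_sd)
  expect_gt(fit$pearson_r, 0.97)
})

test_that("k estimation is nearly unbiased at 2% noise over many replicates", {
  k_hat <- vapply(1:200, function(s) {
    curve <- generate_abiotic(k = 0.0086, m0 = 15, yields = NULL,
                              noise = noise_config(metabolite_rel = 0.02,
                                                   metabolite_floor = 0),
                              times = seq(0, 48, by = 3), seed = s)
    fit_degradation(curve$time, curve$DHA)$k
  }, numeric(1))
  expect_lt(abs(mean(k_hat) - 0.0086) / 0.0086, 0.02)
})

test_that("degraded fraction follows 1 - exp(-kt) and is monotone", {
  expect_equal(round(degraded_fraction(0.0086, 48), 2), 0.34)
  expect_equal(degraded_fraction(0, 100), 0)
  expect_equal(degraded_fraction(0.0086, 39), 1 - exp(-0.3354), tolerance = 1e-6)
  # increasing in both arguments, bounded in [0, 1)
  ks <- seq(0.001, 2, length.out = 25)
  ts <- seq(0.5, 48, length.out = 25)
  expect_true(all(diff(degraded_fraction(ks, 10)) > 0))
  expect_true(all(diff(degraded_fraction(0.1, ts)) > 0))
  f <- degraded_fraction(ks, 10)
  expect_true(all(f >= 0 & f < 1))
  expect_error(degraded_fraction(-0.1, 1), ">= 0")
  expect_error(degraded_fraction(0.1, -1), ">= 0")
})

test_that("both characteristic times are reported and ordered", {
  ct <- characteristic_times(0.0086)
  expect_equal(round(ct$hours[ct$quantity == "reciprocal_time"]), 116)
  expect_equal(ct$hours[ct$quantity == "half_life"], log(2) / 0.0086, tolerance = 1e-9)
  expect_equal(characteristic_times(log(2))$hours[2], 1)
  # 1/k > ln2/k always
  for (k in c(0.001, 0.0086, 0.5, 3)) {
    ct <- characteristic_times(k)
    expect_gt(ct$hours[1], ct$hours[2])
  }
  ct0 <- characteristic_times(0)
  expect_true(all(ct0$unbounded))
  expect_true(all(is.infinite(ct0$hours)))
})

test_that("yield partition reproduces the branch stoichiometry and conserves moles", {
  out <- apply_yields(10)
  expect_equal(out$amount[out$product == "formate"], 3.6)
  expect_equal(out$amount[out$product == "glycolate"], 2.6)
  expect_equal(out$amount[out$product == "acetate"], 0.13)
  expect_equal(sum(out$amount), 10, tolerance = 1e-12)

  expect_equal(apply_yields(0)$amount, rep(0, 4))
  full <- apply_yields(5, yields = c(p = 1))
  expect_equal(full$amount[full$product == "p"], 5)
  expect_equal(full$amount[full$product == "unidentified"], 0)

  # conservation holds for arbitrary yield vectors
  set.seed(4)
  for (i in 1:20) {
    y <- stats::runif(3)
    y <- y / sum(y) * stats::runif(1)
    names(y) <- c("a", "b", "c")
    amount <- stats::runif(1, 0, 100)
    expect_equal(sum(apply_yields(amount, y)$amount), amount, tolerance = 1e-12)
  }
  expect_error(apply_yields(1, c(a = 0.7, b = 0.5)), "> 1")
})

test_that("co-consumption fluxes follow the quasi-steady balance", {
  out <- coconsumption_fluxes(0.0086, dha_yields(), substrate = 15, biomass = 0.04)
  expect_equal(out$flux[out$product == "formate"], 0.36 * 0.0086 * 15 / 0.04,
               tolerance = 1e-12)
  # zero yield gives zero flux
  zero <- coconsumption_fluxes(0.0086, c(p = 0), substrate = 15, biomass = 0.04)
  expect_equal(zero$flux, 0)
  # doubling biomass at fixed substrate halves the specific flux
  twice <- coconsumption_fluxes(0.0086, dha_yields(), substrate = 15, biomass = 0.08)
  expect_equal(out$flux, 2 * twice$flux, tolerance = 1e-12)
  expect_error(coconsumption_fluxes(0.0086, dha_yields(), 15, 0), "positive")
})
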