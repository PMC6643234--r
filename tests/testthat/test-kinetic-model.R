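test_that("biomass trajectory is exponential with the expected lag behaviour", {
  expect_equal(simulate_biomass(kinetic_params(x0 = 1, mu = 0.1), log(2) / 0.1), 2)
  expect_equal(simulate_biomass(kinetic_params(x0 = 0.0185, mu = 0.15), 0), 0.0185)
  lagged <- kinetic_params(x0 = 1, mu = 0.5, t_lag = 5)
  expect_equal(simulate_biomass(lagged, 5), 1) # growth has not started yet
  expect_equal(simulate_biomass(lagged, 7), exp(0.5 * 2))

  expect_error(simulate_biomass(lagged, c(2, 1)), "increasing")
  expect_error(simulate_biomass(lagged, -1), "nonnegative")
})

test_that("metabolite closed form matches its scalar special cases", {
  # q = 0: pure exponential decay
  decay_only <- kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = "DHA", m0 = 15, q = 0, k = 0.0086)
  )
  expect_equal(simulate_metabolite(decay_only, "DHA", 48), 15 * exp(-0.0086 * 48),
               tolerance = 1e-12)

  # k = 0: M0 + q X0 (e^{mu t} - 1)/mu
  no_decay <- kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = "DHA", m0 = 15, q = -5.2, k = 0)
  )
  expect_equal(simulate_metabolite(no_decay, "DHA", 10),
               15 + (-5.2) * 0.0185 * (exp(0.15 * 10) - 1) / 0.15,
               tolerance = 1e-12)

  # full model at the wild-type preset
  expect_equal(simulate_metabolite(wt_params(), "DHA", 10), 11.602, tolerance = 1e-4)

  expect_error(simulate_metabolite(wt_params(), "glucose", 1), "unknown metabolite")
})

test_that("analytic and ODE solutions agree over a parameter grid", {
  set.seed(11)
  times <- seq(0, 48, by = 2)
  for (rep in 1:12) {
    params <- kinetic_params(
      x0 = stats::runif(1, 0.01, 1),
      mu = stats::runif(1, 0, 2),
      t_lag = sample(c(0, 0, 3), 1),
      metabolites = tibble::tibble(
        name = c("S", "P"),
        m0 = stats::runif(2, 0, 20),
        q = stats::runif(2, -5, 5),
        k = stats::runif(2, 0, 2)
      )
    )
    analytic <- simulate_timecourse(params, times)
    ode <- simulate_ode(params, times)
    for (col in c("biomass", "S", "P")) {
      scale <- max(abs(analytic[[col]]), 1)
      expect_lt(max(abs(analytic[[col]] - ode[[col]])) / scale, 1e-6)
    }
  }
})

test_that("ODE oracle reproduces the constant-biomass (mu = 0) closed form", {
  params <- kinetic_params(
    x0 = 0.5, mu = 0,
    metabolites = tibble::tibble(name = "S", m0 = 2, q = 1.3, k = 0.4)
  )
  times <- seq(0, 10, by = 0.5)
  ode <- simulate_ode(params, times)
  expect_equal(ode$biomass, rep(0.5, length(times)), tolerance = 1e-8)
  # constant source into first-order decay: q X0/k (1 - e^{-kt}) + M0 e^{-kt}
  closed <- 1.3 * 0.5 / 0.4 * (1 - exp(-0.4 * times)) + 2 * exp(-0.4 * times)
  expect_equal(ode$S, closed, tolerance = 1e-7)
})

test_that("trajectories are monotone in the expected directions", {
  times <- seq(0, 20, by = 0.25)
  x <- simulate_biomass(wt_params(), times)
  expect_true(all(diff(x) >= 0))
  m <- simulate_metabolite(wt_params(), "DHA", times)
  positive <- m > 0
  expect_true(all(diff(m[positive]) < 0)) # uptake + decay: strictly falling
  # q = 0, k = 0 gives a constant series
  inert <- kinetic_params(
    x0 = 0.0185, mu = 0.15,
    metabolites = tibble::tibble(name = "S", m0 = 3, q = 0, k = 0)
  )
  expect_equal(simulate_metabolite(inert, "S", times), rep(3, length(times)))
})

test_that("the degenerate mu + k limit is continuous across the switch", {
  times <- seq(0, 8, by = 0.5)
  curve_at <- function(mu, k) {
    params <- kinetic_params(
      x0 = 0.0185, mu = mu,
      metabolites = tibble::tibble(name = "S", m0 = 15, q = -5.2, k = k)
    )
    simulate_metabolite(params, "S", times)
  }
  above <- curve_at(mu = 1.5e-9, k = 0)
  below <- curve_at(mu = 0.5e-9, k = 0)
  expect_lt(max(abs(above - below)), 1e-8)
  # exact zero matches the linear limit
  expect_equal(curve_at(0, 0), 15 - 5.2 * 0.0185 * times, tolerance = 1e-12)
})
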