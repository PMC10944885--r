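final_params <- pk_params(ka = 0.58, tlag = 0.35, v = 26.21, v2 = 26.60,
                          cl = 1.07, cl2 = 0.75)

test_that("no drug appears before the absorption lag has elapsed", {
  pr <- predict_concentration(final_params, data.frame(time = 0, amt = 100),
                              times = c(0, 0.1, 0.2, 0.34, 0.36, 1))
  expect_equal(pr$conc[1:4], rep(0, 4))
  expect_gt(pr$conc[6], 0)
})

test_that("closed form matches a high-accuracy ODE integration", {
  skip_if_not_installed("deSolve")
  times <- c(1, 2, 4, 6, 8, 12, 24, 48, 72, 96)
  cf <- predict_concentration(final_params, data.frame(time = 0, amt = 100),
                              times)$conc
  ode <- ode_conc_oracle(final_params, 0, 100, times)
  expect_equal(cf, ode, tolerance = 1e-6)
})

test_that("closed form agrees with the ODE oracle for random parameters and dosing", {
  skip_if_not_installed("deSolve")
  set.seed(31)
  for (rep in 1:8) {
    p <- pk_params(ka = runif(1, 0.2, 3), tlag = runif(1, 0, 0.5),
                   v = runif(1, 10, 60), v2 = runif(1, 10, 80),
                   cl = runif(1, 0.3, 5), cl2 = runif(1, 0.2, 4))
    nd <- sample(1:3, 1)
    dt <- sort(runif(nd, 0, 48))
    da <- runif(nd, 50, 900)
    times <- seq(0.5, 96, by = 3.7)
    # keep prediction times away from each absorption onset so the
    # closed form's narrow onset taper is numerically inactive
    onset <- rep(dt + p[["tlag"]], each = length(times))
    ok <- apply(abs(outer(times, dt + p[["tlag"]], "-")), 1, min) > 0.3
    times <- times[ok]
    cf <- predict_concentration(p, data.frame(time = dt, amt = da), times)$conc
    ode <- ode_conc_oracle(p, dt, da, times)
    expect_equal(cf, ode, tolerance = 1e-6)
  }
})

test_that("dose superposition is exactly linear", {
  times <- c(1, 4, 12, 36, 90)
  c100 <- predict_concentration(final_params, data.frame(time = 0, amt = 100),
                                times)$conc
  c900 <- predict_concentration(final_params, data.frame(time = 0, amt = 900),
                                times)$conc
  expect_equal(c900, 9 * c100, tolerance = 1e-12)
})

test_that("disposition constants satisfy their defining identities", {
  d <- disposition_constants(final_params)
  expect_equal(d$k10, 1.07 / 26.21, tolerance = 1e-12)
  expect_equal(round(d$k10, 5), 0.04082)
  set.seed(7)
  for (rep in 1:20) {
    p <- pk_params(ka = runif(1, 0.1, 3), tlag = 0.3, v = runif(1, 5, 80),
                   v2 = runif(1, 5, 80), cl = runif(1, 0.1, 8),
                   cl2 = runif(1, 0.1, 8))
    d <- disposition_constants(p)
    expect_equal(d$alpha * d$beta, d$k10 * d$k21, tolerance = 1e-12)
    expect_equal(d$alpha + d$beta, d$k10 + d$k12 + d$k21, tolerance = 1e-12)
    expect_true(d$alpha > d$beta && d$beta > 0)
  }
  # one-compartment limit: with vanishing distribution clearance the larger
  # hybrid constant tends to the elimination constant and the smaller to zero
  d1 <- disposition_constants(pk_params(0.6, 0.3, 26, 26, 1.1, 1e-7))
  expect_equal(d1$alpha, 1.1 / 26, tolerance = 1e-4)
  expect_lt(d1$beta, 1e-7)
})

test_that("steady-state AUC equals dose over clearance, for any parameters", {
  expect_equal(steady_state_metrics(final_params, 900, 24)$auc,
               1000 * 900 / 1.07, tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:10) {
    p <- pk_params(ka = runif(1, 0.2, 2), tlag = runif(1, 0, 0.5),
                   v = runif(1, 10, 60), v2 = runif(1, 10, 60),
                   cl = runif(1, 0.3, 4), cl2 = runif(1, 0.2, 3))
    dose <- runif(1, 50, 900)
    expect_equal(steady_state_metrics(p, dose, 24)$auc, 1000 * dose / p[["cl"]],
                 tolerance = 1e-12)
  }
})

test_that("steady-state trough and peak match day-21 superposition", {
  # 22 daily doses put the profile within 0.5% of steady state
  dose_t <- seq(0, 21 * 24, by = 24)
  ssm <- steady_state_metrics(final_params, 900, 24)
  t21 <- 21 * 24
  trough <- predict_concentration(final_params,
                                  data.frame(time = dose_t, amt = 900),
                                  t21 + 24)$conc
  expect_equal(ssm$cmin, trough, tolerance = 5e-3)
  grid <- t21 + seq(0, 24, by = 0.05)
  peak <- max(predict_concentration(final_params,
                                    data.frame(time = dose_t, amt = 900),
                                    grid)$conc)
  expect_equal(ssm$cmax, peak, tolerance = 5e-3)
})

test_that("trough vanishes as the dosing interval grows", {
  expect_lt(steady_state_metrics(final_params, 900, 5000)$cmin, 1e-3)
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_params(0, 0.3, 26, 26, 1, 0.7), "positive")
  expect_error(steady_state_metrics(final_params, -900, 24), "dose")
  expect_error(steady_state_metrics(final_params, 900, 0), "tau")
})
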