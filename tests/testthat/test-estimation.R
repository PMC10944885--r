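test_that("with no IIV the objective is the exact weighted least-squares -2LL", {
  truth <- small_model(omega = NULL, sigma_prop = 0.15)
  ds <- small_trial(n_per_arm = 3, truth = truth, seed = 2)
  ofv <- as.numeric(foce_ofv(truth, ds))
  # direct computation, additive form of the same quantity
  sub <- orinpk:::subject_data(ds)
  direct <- 0
  for (s in sub) {
    p <- individual_typical_params(truth, s$covariates)
    f <- predict_concentration(p, data.frame(time = s$dose_time, amt = s$dose_amt),
                               s$times)$conc
    v <- (0.15 * pmax(f, 1e-3))^2
    direct <- direct + sum(log(2 * pi * v) + (s$y - f)^2 / v)
  }
  expect_equal(ofv, direct, tolerance = 1e-10)
})

test_that("FOCE matches adaptive quadrature on one- and two-eta problems", {
  # one eta on clearance
  m1 <- small_model(omega = c(cl = 0.08), sigma_prop = 0.12)
  ds1 <- small_trial(n_per_arm = 2, times = c(1, 4, 12, 48), truth = m1, seed = 4)
  ofv_foce <- as.numeric(foce_ofv(m1, ds1))
  ofv_quad <- quadrature_ofv(m1, ds1, n_nodes = 80)
  expect_equal(ofv_foce, ofv_quad, tolerance = 5e-3)
  # two etas (clearance and volume)
  m2 <- small_model(omega = c(cl = 0.08, v = 0.05), sigma_prop = 0.12)
  ds2 <- small_trial(n_per_arm = 2, times = c(1, 2, 6, 24, 72), truth = m2, seed = 5)
  expect_equal(as.numeric(foce_ofv(m2, ds2)),
               quadrature_ofv(m2, ds2, n_nodes = 50), tolerance = 5e-3)
})

test_that("the objective is additive, order-invariant and scale-consistent", {
  m <- small_model()
  ds <- small_trial(n_per_arm = 3, truth = m, seed = 6)
  ofv <- as.numeric(foce_ofv(m, ds))
  # duplicating every subject doubles the OFV
  ds2 <- ds
  clone <- function(df) { d <- df; d$id <- paste0(d$id, "_dup"); d }
  ds2$subjects <- rbind(ds$subjects, clone(ds$subjects))
  ds2$doses <- rbind(ds$doses, clone(ds$doses))
  ds2$obs <- rbind(ds$obs, clone(ds$obs))
  expect_equal(as.numeric(foce_ofv(ds = ds2, m = m)), 2 * ofv, tolerance = 1e-9)
  # subject order is irrelevant
  perm <- rev(seq_len(nrow(ds$subjects)))
  ds3 <- ds
  ds3$subjects <- ds$subjects[perm, ]
  expect_equal(as.numeric(foce_ofv(m, ds3)), ofv, tolerance = 1e-9)
  # rescaling dose together with volumes and clearances leaves predictions,
  # hence the likelihood, unchanged
  k <- 3.7
  m4 <- m
  m4$typical[c("v", "v2", "cl", "cl2")] <- k * m4$typical[c("v", "v2", "cl", "cl2")]
  ds4 <- ds
  ds4$doses$amt <- k * ds4$doses$amt
  ds4$subjects$dose_mg <- k * ds4$subjects$dose_mg
  expect_equal(as.numeric(foce_ofv(m4, ds4)), ofv, tolerance = 1e-8)
})

test_that("fitting noise-free data drives the residual variance to its floor", {
  truth <- small_model(omega = NULL, sigma_prop = 0.1)
  design <- trial_design(arms = data.frame(dose = c(100, 400), n = c(3, 3)),
                         single_times = c(1, 2, 4, 6, 8, 12, 24, 48, 72, 96),
                         day21_times = numeric(0), dose_times = 0, dropout = 0)
  ds <- generate_trial(design, truth, seed = 1)
  # replace the observations with exact model predictions
  sub <- orinpk:::subject_data(ds)
  for (s in sub) {
    f <- predict_concentration(individual_typical_params(truth, s$covariates),
                               data.frame(time = s$dose_time, amt = s$dose_amt),
                               s$times)$conc
    ds$obs$dv[ds$obs$id == s$id & !ds$obs$blq] <- f
  }
  fit <- fit_poppk(truth, ds, control = fit_control(se = FALSE))
  expect_lt(fit$model$sigma$prop, 0.01)
  expect_equal(fit$model$typical[["cl"]], truth$typical[["cl"]], tolerance = 0.02)
})

test_that("information criteria follow their definitions and SEs are reported", {
  m <- small_model()
  ds <- small_trial(n_per_arm = 3, truth = m, seed = 8)
  fit <- suppressWarnings(
    fit_poppk(m, ds, control = fit_control(se = TRUE, reltol = 1e-5)))
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_params)
  expect_equal(fit$bic, fit$ofv + fit$n_params * log(fit$n_obs))
  expect_equal(fit$n_params, 9)  # 6 typical + 2 omega + 1 sigma
  expect_true(all(is.finite(fit$estimates$estimate)))
  expect_true(all(fit$estimates$estimate > 0 |
                    startsWith(fit$estimates$parameter, "beta_")))
  # RSEs from the Hessian exist and are positive for most parameters
  expect_gt(mean(is.finite(fit$estimates$rse)), 0.7)
  expect_true(all(fit$estimates$rse[is.finite(fit$estimates$rse)] > 0))
})

test_that("nested-model comparison applies the chi-squared thresholds", {
  expect_true(compare_fits(100, 88.25)$accept)          # drop 11.75 > 3.84
  expect_false(compare_fits(100, 100)$accept)           # no drop
  expect_false(compare_fits(100, 96.5)$accept)          # 3.5 < 3.84
  d <- compare_fits(100, 88.25)
  expect_equal(d$delta_ofv, 11.75)
  expect_lt(d$p_value, 0.001)
  # the conventional thresholds are the chi-squared(1) quantiles
  expect_equal(qchisq(0.95, 1), 3.84, tolerance = 1e-3)
  expect_equal(qchisq(0.99, 1), 6.64, tolerance = 1e-3)
})

test_that("eta warm starts never corrupt the objective value", {
  m <- small_model()
  ds <- small_trial(n_per_arm = 3, truth = m, seed = 9)
  cold <- foce_ofv(m, ds)
  warm <- foce_ofv(m, ds, eta_start = attr(cold, "etas"))
  expect_equal(as.numeric(warm), as.numeric(cold), tolerance = 1e-8)
})
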