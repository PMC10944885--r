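make_fit_at <- function(m, ds, control = fit_control()) {
  # a fit object frozen at the given model (no optimization): empirical-Bayes
  # etas are recomputed internally by the diagnostics
  sub <- orinpk:::subject_data(ds)
  det <- orinpk:::foce_ofv_sub(m, sub, control, detail = TRUE)
  structure(list(model = m, control = control, etas = det$etas,
                 ofv = det$ofv, fix = character(0)),
            class = "poppk_fit")
}

test_that("near-noise-free data make IPRED track DV and CWRES standardized", {
  truth <- small_model(omega = c(cl = 0.04, v = 0.04), sigma_prop = 1e-3)
  ds <- small_trial(n_per_arm = 4, truth = truth, seed = 14)
  fit <- make_fit_at(truth, ds)
  g <- gof_table(fit, ds)
  expect_equal(g$ipred, g$dv, tolerance = 2e-2)
  expect_true(all(is.finite(g$cwres)))
})

test_that("CWRES are calibrated when the model is the truth", {
  truth <- small_model(omega = c(cl = 0.06, v = 0.05), sigma_prop = 0.15)
  ds <- small_trial(n_per_arm = 6, truth = truth, seed = 16)
  g <- gof_table(make_fit_at(truth, ds), ds)
  expect_lt(abs(mean(g$cwres)), 0.2)
  expect_gt(mean(abs(g$cwres) < 2), 0.9)
  expect_gt(sd(g$cwres), 0.6)
  expect_lt(sd(g$cwres), 1.4)
})

test_that("with a single observation and no IIV, CWRES is the scalar z-score", {
  m <- small_model(omega = NULL, sigma_prop = 0.2)
  subj <- data.frame(id = "A", dose_mg = 100)
  p <- individual_typical_params(m, c(dose_mg = 100))
  pred <- predict_concentration(p, data.frame(time = 0, amt = 100), 6)$conc
  ds <- pk_trial(subj, data.frame(id = "A", time = 0, amt = 100),
                 data.frame(id = "A", time = 6, dv = 1.3 * pred))
  g <- gof_table(make_fit_at(m, ds), ds)
  expect_equal(g$cwres, (1.3 * pred - pred) / (0.2 * pred), tolerance = 1e-9)
})

test_that("the NPDE decorrelation equals a hand Cholesky solve", {
  m <- small_model(omega = c(cl = 0.05), sigma_prop = 0.1)
  subj <- data.frame(id = "A", dose_mg = 100)
  ds <- pk_trial(subj, data.frame(id = "A", time = 0, amt = 100),
                 data.frame(id = "A", time = c(2, 24), dv = c(2500, 1100)))
  nsim <- 400
  res <- npde(m, ds, nsim = nsim, seed = 77)
  h <- simulate_replicates(m, ds, nsim = nsim, seed = 77)
  mu <- colMeans(h$sim)
  V <- cov(h$sim) + diag(1e-8 * mean(diag(cov(h$sim))) + 1e-12, 2)
  L <- t(chol(V))
  ystar <- forwardsolve(L, c(2500, 1100) - mu)
  sstar <- t(forwardsolve(L, t(h$sim) - mu))
  pd <- pmin(pmax((colSums(t(t(sstar) < ystar)) + 0.5) / (nsim + 1),
                  1 / (2 * nsim)), 1 - 1 / (2 * nsim))
  expect_equal(res$npde$npde, qnorm(pd), tolerance = 1e-12)
  expect_error(npde(m, ds, nsim = 1), "at least 2")
})

test_that("NPDE is calibrated under the true model", {
  truth <- small_model(omega = c(cl = 0.06, v = 0.05), sigma_prop = 0.15)
  ds <- small_trial(n_per_arm = 6, truth = truth, seed = 18)
  res <- npde(truth, ds, nsim = 600, seed = 3)
  expect_lt(abs(res$mean), 0.25)
  expect_gt(res$variance, 0.6)
  expect_lt(res$variance, 1.5)
  expect_gt(res$p_shapiro, 0.001)
})

test_that("VPC bands cover the observed percentiles for the true model", {
  truth <- small_model(omega = c(cl = 0.06, v = 0.05), sigma_prop = 0.15)
  ds <- small_trial(n_per_arm = 8, truth = truth, seed = 19)
  v <- vpc(truth, ds, nsim = 400, seed = 4)
  cover <- orinpk:::vpc_coverage(v)
  expect_gt(mean(cover), 0.8)
  # a grossly misspecified model (clearance divided by 3) is detected
  bad <- truth
  bad$typical[["cl"]] <- truth$typical[["cl"]] / 3
  vb <- vpc(bad, ds, nsim = 400, seed = 4)
  tb <- vb$table
  miss <- tb$obs_p50 < tb$sim_p50_lo | tb$obs_p50 > tb$sim_p50_hi
  # low clearance inflates concentrations once elimination dominates:
  # bins past the absorption phase exclude the observed median
  expect_true(all(miss[tb$bin >= 12]))
  expect_gt(mean(miss), mean(!orinpk:::vpc_coverage(v)))
})

test_that("a single replicate gives a degenerate VPC band", {
  truth <- small_model()
  ds <- small_trial(n_per_arm = 2, truth = truth, seed = 20)
  v1 <- vpc(truth, ds, nsim = 1, seed = 5)
  expect_equal(v1$table$sim_p50_lo, v1$table$sim_p50_med)
  expect_equal(v1$table$sim_p50_hi, v1$table$sim_p50_med)
})

test_that("VPC and NPDE share one simulation harness", {
  truth <- small_model()
  ds <- small_trial(n_per_arm = 2, truth = truth, seed = 22)
  h1 <- simulate_replicates(truth, ds, nsim = 50, seed = 9)
  h2 <- simulate_replicates(truth, ds, nsim = 50, seed = 9)
  expect_identical(h1$sim, h2$sim)
  expect_equal(nrow(h1$index), sum(!ds$obs$blq))
})

test_that("bootstrap of a cloned-subject dataset has zero-width CIs", {
  truth <- small_model(omega = NULL, sigma_prop = 0.15)
  one <- small_trial(n_per_arm = 1, doses = 100, truth = truth, seed = 23)
  # clone the single subject 8 times
  clones <- lapply(1:8, function(k) {
    s <- one$subjects; s$id <- paste0("C", k)
    d <- one$doses; d$id <- paste0("C", k)
    o <- one$obs; o$id <- paste0("C", k)
    list(s = s, d = d, o = o)
  })
  ds <- pk_trial(do.call(rbind, lapply(clones, `[[`, "s")),
                 do.call(rbind, lapply(clones, `[[`, "d")),
                 do.call(rbind, lapply(clones, `[[`, "o")))
  fit <- fit_poppk(truth, ds, control = fit_control(se = FALSE))
  bt <- bootstrap_poppk(fit, ds, n = 5, seed = 1, stratify = FALSE,
                        control = fit_control(se = FALSE, reltol = 1e-6))
  width <- (bt$summary$ci_hi - bt$summary$ci_lo) / abs(bt$summary$median)
  expect_true(all(width < 1e-6))
})

test_that("bootstrap is reproducible and consistent with the full-data fit", {
  truth <- small_model(omega = NULL, sigma_prop = 0.15)
  ds <- small_trial(n_per_arm = 5, truth = truth, seed = 24)
  fit <- fit_poppk(truth, ds, control = fit_control(se = FALSE))
  b1 <- bootstrap_poppk(fit, ds, n = 12, seed = 7)
  b2 <- bootstrap_poppk(fit, ds, n = 12, seed = 7)
  expect_identical(b1$estimates, b2$estimates)
  expect_equal(b1$n_success, 12)
  # bootstrap medians near the full-data estimates (within one bootstrap SE)
  full <- setNames(fit$estimates$estimate, fit$estimates$parameter)
  for (p in c("tv_cl", "tv_v")) {
    se <- sd(b1$estimates[, p])
    expect_lt(abs(b1$summary$median[b1$summary$parameter == p] - full[[p]]),
              3 * se + 1e-8)
  }
})
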