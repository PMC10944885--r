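# cheap deterministic "fitter" driven by a linear-model likelihood: lets the
# selection logic be exercised exactly, independently of FOCE runtime
lm_fitter <- function(response) {
  force(response)
  function(m, ds) {
    covs <- if (is.null(m$effects)) character(0) else unique(m$effects$covariate)
    X <- ds$subjects[covs]
    df <- cbind(data.frame(y = response), X)
    f <- stats::lm(y ~ ., data = df)
    list(ofv = -2 * as.numeric(stats::logLik(f)), model = m,
         n_params = length(stats::coef(f)) + 1)
  }
}

fake_base_fit <- function(m, ds, fitter) {
  f <- fitter(m, ds)
  structure(list(model = m, ofv = f$ofv, n_params = f$n_params),
            class = "poppk_fit")
}

test_that("duplicated covariates are caught by the pre-screen", {
  set.seed(1)
  cov_df <- data.frame(a = rnorm(25, 10), c = rnorm(25, 5))
  cov_df$b <- cov_df$a  # duplicate under another name
  sc <- covariate_prescreen(cov_df)
  expect_true(sum(c("a", "b") %in% sc$candidates) == 1)
  expect_true("c" %in% sc$candidates)
  expect_equal(abs(sc$excluded$r[1]), 1, tolerance = 1e-12)
})

test_that("independent covariates are flagged at roughly the nominal 5% rate", {
  set.seed(42)
  n_pairs <- 0; n_flag <- 0
  for (rep in 1:40) {
    cov_df <- as.data.frame(matrix(rnorm(25 * 5, 10), 25, 5))
    sc <- covariate_prescreen(cov_df)
    p <- sc$p_values[upper.tri(sc$p_values)]
    r <- sc$correlation[upper.tri(sc$correlation)]
    n_pairs <- n_pairs + length(p)
    n_flag <- n_flag + sum(p < 0.05 & abs(r) > 0.5)
  }
  rate <- n_flag / n_pairs
  expect_lt(rate, 0.10)   # |r| > 0.5 at n = 25 is rarer than p < 0.05 alone
  # p < 0.05 alone calibrates near 5%
  set.seed(43)
  n <- 0; k <- 0
  for (rep in 1:40) {
    sc <- covariate_prescreen(as.data.frame(matrix(rnorm(25 * 5, 10), 25, 5)))
    p <- sc$p_values[upper.tri(sc$p_values)]
    n <- n + length(p); k <- k + sum(p < 0.05)
  }
  expect_gt(k / n, 0.01)
  expect_lt(k / n, 0.12)
})

test_that("no retained pair stays collinear after the pre-screen", {
  # cohort-like covariate table: the weight family is strongly correlated
  cc <- generate_cohort_covariates(n = 25, seed = 13)
  cov_df <- cc[c("weight", "bmi", "bsa", "lbw", "ibw", "bf", "tbil", "dbil",
                 "ibil", "ldh", "bun", "alt", "ast", "alp", "clcr", "adj_clcr")]
  sc <- covariate_prescreen(cov_df)
  expect_lt(length(sc$candidates), ncol(cov_df))
  r <- sc$correlation[sc$candidates, sc$candidates, drop = FALSE]
  p <- sc$p_values[sc$candidates, sc$candidates, drop = FALSE]
  off <- upper.tri(r)
  expect_true(all(abs(r[off]) <= 0.5 | p[off] >= 0.05))
})

test_that("zero-variance covariates are excluded with a warning", {
  cov_df <- data.frame(a = rnorm(10, 5), flat = rep(2, 10))
  expect_warning(sc <- covariate_prescreen(cov_df), "zero-variance")
  expect_false("flat" %in% sc$candidates)
})

test_that("forward step adds the strongest passing extension, or nothing", {
  set.seed(7)
  n <- 40
  subjects <- data.frame(id = sprintf("S%02d", 1:n), dose_mg = 100,
                         good = rnorm(n, 10), noise1 = rnorm(n, 5),
                         noise2 = rnorm(n, 5))
  ds <- list(subjects = subjects)
  y <- 2 + 1.5 * subjects$good + rnorm(n, 0, 0.5)
  fitter <- lm_fitter(y)
  base <- population_model(pk_params(0.6, 0.3, 26, 27, 1.1, 0.8),
                           sigma = list(prop = 0.2))
  bf <- fake_base_fit(base, ds, fitter)
  st <- forward_step(bf, ds, c("good", "noise1", "noise2"),
                     parameters = "cl", fitter = fitter)
  expect_equal(st$entry$decision, "accepted")
  expect_equal(st$entry$covariate, "good")
  expect_lt(st$entry$delta_ofv, -3.84)
  # bookkeeping: delta equals after minus before
  expect_equal(st$entry$delta_ofv, st$entry$ofv_after - st$entry$ofv_before)
  # empty candidate list is a no-op
  st0 <- forward_step(bf, ds, character(0), parameters = "cl", fitter = fitter)
  expect_match(st0$entry$decision, "no-op")
  expect_identical(st0$fit$ofv, bf$ofv)
})

test_that("backward step removes effects by the published 6.64 rule", {
  # fitter with controllable OFV rises on deletion
  rig <- function(rises) {
    function(m, ds) {
      covs <- if (is.null(m$effects)) character(0) else m$effects$covariate
      missing <- setdiff(names(rises), covs)
      list(ofv = 1000 + sum(rises[missing]), model = m,
           n_params = 2 + length(covs))
    }
  }
  base <- population_model(
    pk_params(0.6, 0.3, 26, 27, 1.1, 0.8),
    effects = rbind(covariate_effect("cl", "a", 0.5, 10),
                    covariate_effect("cl", "b", 0.5, 10)),
    sigma = list(prop = 0.2))
  ds <- list(subjects = data.frame(id = "x", a = 1, b = 1))
  # removal of a raises OFV by 4.19 (< 6.64): a is removed first
  fitter <- rig(c(a = 4.19, b = 100))
  bf <- structure(list(model = base, ofv = 1000, n_params = 4),
                  class = "poppk_fit")
  st <- backward_step(bf, ds, fitter = fitter)
  expect_equal(st$entry$decision, "removed")
  expect_equal(st$entry$covariate, "a")
  expect_equal(st$entry$delta_ofv, 4.19)
  # 5.88 is also below the threshold and removed
  st2 <- backward_step(bf, ds, fitter = rig(c(a = 5.88, b = 100)))
  expect_equal(st2$entry$decision, "removed")
  # a 100-point rise retains the effect
  st3 <- backward_step(structure(list(model = st$fit$model, ofv = st$fit$ofv,
                                      n_params = 3), class = "poppk_fit"),
                       ds, fitter = rig(c(a = 4.19, b = 100)))
  expect_match(st3$entry$decision, "no-op")
})

test_that("stepwise selection recovers a real effect among noise and stops", {
  set.seed(15)
  n <- 40
  subjects <- data.frame(id = sprintf("S%02d", 1:n), dose_mg = 100,
                         lbw = exp(rnorm(n, log(45), 0.2)),
                         noise1 = rnorm(n, 8), noise2 = rnorm(n, 8))
  ds <- list(subjects = subjects)
  y <- 1 + 1.1 * log(subjects$lbw) + rnorm(n, 0, 0.25)
  fitter <- lm_fitter(y)
  base <- population_model(pk_params(0.6, 0.3, 26, 27, 1.1, 0.8),
                           sigma = list(prop = 0.2))
  bf <- fake_base_fit(base, ds, fitter)
  res <- run_stepwise(bf, ds, c("lbw", "noise1", "noise2"),
                      parameters = "cl", fitter = fitter)
  expect_true(has_effect <- any(res$model$effects$covariate == "lbw"))
  tr <- res$trace
  # accepted forward steps decrease the OFV monotonically
  acc <- tr[tr$action == "add" & tr$decision == "accepted", ]
  expect_true(all(acc$delta_ofv < -3.84))
  expect_true(all(diff(c(acc$ofv_before[1], acc$ofv_after)) < 0))
  # trace arithmetic is internally consistent
  expect_equal(tr$delta_ofv, tr$ofv_after - tr$ofv_before)
  # no candidates: final model equals base
  res0 <- run_stepwise(bf, ds, character(0), parameters = "cl", fitter = fitter)
  expect_null(res0$model$effects)
})

test_that("stepwise selection works end to end on a small FOCE problem", {
  # truth carries one LBW effect on clearance; one noise covariate competes
  truth <- population_model(
    pk_params(0.6, 0.3, 26, 27, 1.1, 0.8),
    effects = covariate_effect("cl", "lbw", 1.1, 45),
    omega = c(cl = 0.05), sigma = list(prop = 0.12))
  design <- trial_design(arms = data.frame(dose = c(100, 400), n = c(6, 6)),
                         single_times = c(1, 2, 4, 8, 12, 24, 48, 96),
                         day21_times = numeric(0), dose_times = 0, dropout = 0)
  ds <- generate_trial(design, truth, seed = 33)
  set.seed(33)
  ds$subjects$noise <- exp(rnorm(12, log(20), 0.3))
  base <- truth
  base$effects <- NULL
  ctrl <- fit_control(se = FALSE, reltol = 1e-5, maxit = 200)
  bf <- fit_poppk(base, ds, control = ctrl)
  res <- run_stepwise(bf, ds, c("lbw", "noise"), parameters = "cl",
                      fitter = function(m, d) fit_poppk(m, d, control = ctrl))
  expect_true(any(res$model$effects$covariate == "lbw"))
  expect_false(isTRUE(any(res$model$effects$covariate == "noise")))
  lbw_hat <- res$model$effects$exponent[res$model$effects$covariate == "lbw"]
  expect_equal(lbw_hat, 1.1, tolerance = 0.5)
})
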