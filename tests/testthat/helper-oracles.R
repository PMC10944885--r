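# Independent numerical oracles used across the suite.

# High-accuracy ODE solution of the 3-state absorption system
# (gut -> central <-> peripheral, central elimination); doses enter the gut
# at dose time + lag. Returns ng/mL at `times`.
ode_conc_oracle <- function(p, dose_time, dose_amt, times, rtol = 1e-10) {
  stopifnot(requireNamespace("deSolve", quietly = TRUE))
  p <- unclass(p)
  k10 <- p[["cl"]] / p[["v"]]
  k12 <- p[["cl2"]] / p[["v"]]
  k21 <- p[["cl2"]] / p[["v2"]]
  ka <- p[["ka"]]
  rhs <- function(t, A, parms) {
    list(c(-ka * A[1],
           ka * A[1] - (k10 + k12) * A[2] + k21 * A[3],
           k12 * A[2] - k21 * A[3]))
  }
  ev_t <- dose_time + p[["tlag"]]
  events <- data.frame(var = "gut", time = ev_t, value = dose_amt,
                       method = "add")
  tout <- sort(unique(c(0, ev_t, times)))
  sol <- deSolve::lsoda(c(gut = 0, a1 = 0, a2 = 0), tout, rhs, parms = NULL,
                        rtol = rtol, atol = 1e-12,
                        events = list(data = events))
  1000 * sol[match(times, tout), "a1"] / p[["v"]]
}

# Gauss-Hermite nodes/weights by Golub-Welsch
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  b <- sqrt(i / 2)
  A <- matrix(0, n, n)
  A[cbind(i, i + 1)] <- b
  A[cbind(i + 1, i)] <- b
  e <- eigen(A, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Exact (quadrature) -2 log marginal likelihood for a model with IIV on
# one or two parameters, matching the package's residual-variance floor.
quadrature_ofv <- function(m, ds, n_nodes = 80) {
  sub <- orinpk:::subject_data(ds)
  gh <- gauss_hermite(n_nodes)
  omega <- m$omega
  q <- nrow(omega)
  stopifnot(q %in% 1:2)
  L <- t(chol(omega))
  cond_lik <- function(s, eta) {
    names(eta) <- rownames(omega)
    p <- individual_params(m, s$covariates, eta)
    f <- predict_concentration(p, data.frame(time = s$dose_time, amt = s$dose_amt),
                               s$times)$conc
    v <- pmax((m$sigma$prop * pmax(f, 1e-3))^2 + m$sigma$add^2, 1e-10)
    exp(sum(stats::dnorm(s$y, f, sqrt(v), log = TRUE)))
  }
  ofv <- 0
  for (s in sub) {
    if (q == 1) {
      lik <- sum(gh$w / sqrt(pi) *
                   vapply(gh$x, function(x) cond_lik(s, sqrt(2) * L[1, 1] * x),
                          numeric(1)))
    } else {
      lik <- 0
      for (i in seq_len(n_nodes)) for (j in seq_len(n_nodes)) {
        z <- sqrt(2) * c(gh$x[i], gh$x[j])
        lik <- lik + gh$w[i] * gh$w[j] / pi * cond_lik(s, as.numeric(L %*% z))
      }
    }
    ofv <- ofv - 2 * log(lik)
  }
  ofv
}

# small two-arm rich-sampling design for fast estimation tests
small_trial <- function(n_per_arm = 6, doses = c(100, 400),
                        times = c(1, 2, 4, 8, 12, 24, 48, 96),
                        truth = small_model(), seed = 1) {
  design <- trial_design(
    arms = data.frame(dose = doses, n = rep(n_per_arm, length(doses))),
    single_times = times, day21_times = numeric(0),
    dose_times = 0, dropout = 0)
  generate_trial(design, truth, seed = seed)
}

# base-style model without covariates; moderate IIV unless removed
small_model <- function(omega = c(cl = 0.05, v = 0.04), sigma_prop = 0.15) {
  population_model(
    typical = pk_params(ka = 0.6, tlag = 0.3, v = 26, v2 = 27, cl = 1.1,
                        cl2 = 0.8),
    omega = omega, sigma = list(prop = sigma_prop, add = 0))
}
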