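#' Simulate replicate datasets at the observed design
#'
#' The shared Monte-Carlo harness behind the VPC and the NPDE: for each
#' replicate, fresh inter-individual random effects and residual errors
#' are drawn while every subject keeps their own doses, covariates and
#' (non-BLQ) observation times. Simulated concentrations are truncated at
#' zero.
#'
#' @param m A `poppk_model`.
#' @param ds A [pk_trial()] dataset.
#' @param nsim Number of replicate datasets.
#' @param seed Seed.
#' @return List: `sim` (matrix `nsim` x n_obs), `index` (data frame with
#'   id, time, time-after-dose, dv for each observation column).
#' @export
simulate_replicates <- function(m, ds, nsim = 1000, seed = 1) {
  if (nsim < 1) stop("nsim must be >= 1")
  set.seed(seed)
  sub <- subject_data(ds)
  q <- if (is.null(m$omega)) 0L else nrow(m$omega)
  Lw <- if (q) t(chol(m$omega))
  index <- do.call(rbind, lapply(sub, function(s) {
    tad <- vapply(s$times, function(t) {
      dt <- s$dose_time[s$dose_time <= t]
      if (length(dt)) t - max(dt) else t
    }, numeric(1))
    data.frame(id = s$id, time = s$times, tad = tad, dv = s$y,
               stringsAsFactors = FALSE)
  }))
  n_obs <- nrow(index)
  sim <- matrix(NA_real_, nsim, n_obs)
  col0 <- 0L
  for (s in sub) {
    ni <- length(s$y)
    cols <- col0 + seq_len(ni)
    p_typ <- individual_typical_params(m, s$covariates)
    for (r in seq_len(nsim)) {
      p <- if (q) {
        eta <- stats::setNames(as.numeric(Lw %*% stats::rnorm(q)), rownames(m$omega))
        individual_params(m, s$covariates, eta)
      } else p_typ
      f <- conc_at(p, s$dose_time, s$dose_amt, s$times)
      sim[r, cols] <- pmax(f * (1 + m$sigma$prop * stats::rnorm(ni)) +
                             m$sigma$add * stats::rnorm(ni), 0)
    }
    col0 <- col0 + ni
  }
  list(sim = sim, index = index)
}

#' Visual predictive check
#'
#' Simulates `nsim` replicates of the dataset under the model and compares
#' the observed 5th/50th/95th concentration percentiles per time bin with
#' the corresponding simulation-based 95% confidence bands. Bins are the
#' nominal sampling times (the design is nominal-time sparse sampling),
#' either on absolute time or on time after the most recent dose.
#'
#' @inheritParams simulate_replicates
#' @param probs Percentiles compared (default 5th, 50th, 95th).
#' @param ci Confidence level of the simulated percentile bands.
#' @param view `"time"` (time since first dose) or `"tad"` (time after
#'   dose).
#' @return An object of class `poppk_vpc`: per-bin table with observed
#'   percentiles and simulated percentile confidence bands.
#' @export
vpc <- function(m, ds, nsim = 1000, seed = 1, probs = c(0.05, 0.5, 0.95),
                ci = 0.95, view = c("time", "tad")) {
  view <- match.arg(view)
  h <- simulate_replicates(m, ds, nsim, seed)
  key <- if (view == "time") h$index$time else h$index$tad
  bins <- sort(unique(key))
  a <- (1 - ci) / 2
  rows <- lapply(bins, function(b) {
    cols <- which(key == b)
    obs_q <- stats::quantile(h$index$dv[cols], probs, names = FALSE)
    # percentile of each replicate, then CI across replicates
    rep_q <- apply(h$sim[, cols, drop = FALSE], 1, stats::quantile,
                   probs = probs, names = FALSE)
    rep_q <- matrix(rep_q, nrow = length(probs))
    out <- data.frame(bin = b, n = length(cols))
    for (i in seq_along(probs)) {
      pc <- paste0("p", round(100 * probs[i]))
      out[[paste0("obs_", pc)]] <- obs_q[i]
      out[[paste0("sim_", pc, "_lo")]] <- stats::quantile(rep_q[i, ], a, names = FALSE)
      out[[paste0("sim_", pc, "_med")]] <- stats::median(rep_q[i, ])
      out[[paste0("sim_", pc, "_hi")]] <- stats::quantile(rep_q[i, ], 1 - a, names = FALSE)
    }
    out
  })
  structure(list(table = do.call(rbind, rows), probs = probs, ci = ci,
                 nsim = nsim, seed = seed, view = view),
            class = "poppk_vpc")
}

#' @export
print.poppk_vpc <- function(x, ...) {
  cat(sprintf("VPC (%d replicates, %s bins, %g%% CI)\n", x$nsim, x$view,
              100 * x$ci))
  inside <- vpc_coverage(x)
  cat(sprintf("observed percentiles inside simulated CI: %d / %d\n",
              sum(inside), length(inside)))
  invisible(x)
}

# logical vector: is each observed percentile inside its simulated band
vpc_coverage <- function(v) {
  tb <- v$table
  unlist(lapply(round(100 * v$probs), function(pc) {
    tb[[paste0("obs_p", pc)]] >= tb[[paste0("sim_p", pc, "_lo")]] &
      tb[[paste0("obs_p", pc)]] <= tb[[paste0("sim_p", pc, "_hi")]]
  }))
}

#' Normalized prediction distribution errors
#'
#' Simulates the dataset `nsim` times, decorrelates each subject's
#' observed and simulated vectors with the empirical mean and covariance
#' of that subject's simulated ensemble (Cholesky), computes rank-based
#' probabilities of the decorrelated observations within the decorrelated
#' ensemble, and maps them through the standard-normal quantile function.
#' Probabilities are clipped to `[1/(2 nsim), 1 - 1/(2 nsim)]` so no
#' quantile is infinite. Under a correct model the NPDE are standard
#' normal: a t-test of mean 0, a Fisher chi-squared test of variance 1
#' and a Shapiro-Wilk normality test summarize the check.
#'
#' @inheritParams simulate_replicates
#' @return An object of class `poppk_npde`: per-observation `npde` values
#'   (with id/time), `mean`, `variance` and the three test p-values.
#' @export
npde <- function(m, ds, nsim = 1000, seed = 1) {
  if (nsim < 2) stop("NPDE needs at least 2 simulation replicates")
  h <- simulate_replicates(m, ds, nsim, seed)
  ids <- unique(h$index$id)
  val <- rep(NA_real_, nrow(h$index))
  for (id in ids) {
    cols <- which(h$index$id == id)
    S <- h$sim[, cols, drop = FALSE]
    mu <- colMeans(S)
    V <- stats::cov(S)
    V <- V + diag(1e-8 * mean(diag(V)) + 1e-12, ncol(V))
    L <- t(chol(V))
    ystar <- forwardsolve(L, h$index$dv[cols] - mu)
    sstar <- t(forwardsolve(L, t(S) - mu))
    pd <- (colSums(t(t(sstar) < ystar)) + 0.5) / (nsim + 1)
    pd <- pmin(pmax(pd, 1 / (2 * nsim)), 1 - 1 / (2 * nsim))
    val[cols] <- stats::qnorm(pd)
  }
  n <- length(val)
  s2 <- stats::var(val)
  chi <- (n - 1) * s2 / 1
  p_var <- 2 * min(stats::pchisq(chi, n - 1), stats::pchisq(chi, n - 1, lower.tail = FALSE))
  structure(list(npde = data.frame(h$index[c("id", "time", "tad")], npde = val),
                 mean = mean(val), variance = s2,
                 p_t = stats::t.test(val)$p.value,
                 p_var = min(p_var, 1),
                 p_shapiro = if (n >= 3 && n <= 5000)
                   stats::shapiro.test(val)$p.value else NA_real_,
                 nsim = nsim, seed = seed),
            class = "poppk_npde")
}

#' @export
print.poppk_npde <- function(x, ...) {
  cat(sprintf("NPDE (%d replicates): mean %.3f, variance %.3f\n",
              x$nsim, x$mean, x$variance))
  cat(sprintf("t-test p = %.3f; variance test p = %.3f; Shapiro-Wilk p = %.3f\n",
              x$p_t, x$p_var, x$p_shapiro))
  invisible(x)
}

#' Goodness-of-fit table
#'
#' Per-observation diagnostics of a fit: population prediction PRED
#' (all random effects at zero), individual prediction IPRED (at the
#' empirical-Bayes eta mode), individual weighted residual IWRES, and
#' conditional weighted residuals CWRES from the FOCE linearization
#' (residuals around `IPRED - J eta*`, decorrelated by the Cholesky factor
#' of the model-implied covariance `J Omega J' + V`).
#'
#' @param fit A `poppk_fit`.
#' @param ds The dataset it was fitted to.
#' @return Data frame: `id`, `time`, `tad`, `dv`, `pred`, `ipred`,
#'   `iwres`, `cwres`.
#' @export
gof_table <- function(fit, ds) {
  m <- fit$model
  sub <- subject_data(ds)
  det <- foce_ofv_sub(m, sub, fit$control, eta_start = fit$etas, detail = TRUE)
  out <- vector("list", length(sub))
  q <- if (is.null(m$omega)) 0L else nrow(m$omega)
  for (j in seq_along(sub)) {
    s <- sub[[j]]
    dj <- det$subjects[[j]]
    p0 <- individual_typical_params(m, s$covariates)
    pred <- conc_at(p0, s$dose_time, s$dose_amt, s$times)
    tad <- vapply(s$times, function(t) {
      dt <- s$dose_time[s$dose_time <= t]
      if (length(dt)) t - max(dt) else t
    }, numeric(1))
    if (q > 0L) {
      ipred <- as.numeric(dj$ipred)
      J <- matrix(dj$J, ncol = q)
      V <- diag(as.numeric(dj$vres), length(s$y))
      C <- J %*% m$omega %*% t(J) + V
      L <- t(chol((C + t(C)) / 2))
      mean_lin <- ipred - as.numeric(J %*% as.numeric(dj$eta))
      cwres <- as.numeric(forwardsolve(L, s$y - mean_lin))
      iwres <- (s$y - ipred) / sqrt(as.numeric(dj$vres))
    } else {
      ipred <- pred
      vres <- residual_model(pred, m$sigma)$var
      cwres <- iwres <- (s$y - pred) / sqrt(pmax(vres, 1e-10))
    }
    out[[j]] <- data.frame(id = s$id, time = s$times, tad = tad, dv = s$y,
                           pred = pred, ipred = ipred, iwres = iwres,
                           cwres = cwres, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# dataset with subjects resampled (with replacement) within dose arm
resample_dataset <- function(ds, stratify = TRUE) {
  ids <- ds$subjects$id
  groups <- if (stratify) split(ids, ds$subjects$dose_mg) else list(ids)
  picked <- unlist(lapply(groups, function(g) sample(g, length(g), replace = TRUE)))
  subjects <- ds$subjects[match(picked, ds$subjects$id), , drop = FALSE]
  new_id <- sprintf("B%03d", seq_along(picked))
  doses <- do.call(rbind, lapply(seq_along(picked), function(k) {
    d <- ds$doses[ds$doses$id == picked[k], , drop = FALSE]
    d$id <- new_id[k]
    d
  }))
  obs <- do.call(rbind, lapply(seq_along(picked), function(k) {
    o <- ds$obs[ds$obs$id == picked[k], , drop = FALSE]
    o$id <- new_id[k]
    o
  }))
  subjects$id <- new_id
  pk_trial(subjects, doses, obs, lloq = ds$lloq,
           meta = c(ds$meta, list(resampled = TRUE)))
}

#' Non-parametric bootstrap of a population PK fit
#'
#' Resamples subjects with replacement (stratified by dose arm so every
#' resample spans the dose range), refits the model on each resampled
#' dataset starting from the original estimates, and summarizes each
#' parameter by the median, RSE% and the 2.5th/97.5th percentile
#' confidence interval across successful refits. Bit-reproducible given
#' the seed.
#'
#' @param fit A fitted `poppk_fit` (its model is the refit start).
#' @param ds The original dataset.
#' @param n Number of bootstrap resamples.
#' @param seed Seed.
#' @param stratify Stratify resampling by dose arm (default TRUE).
#' @param control [fit_control()] for the refits (standard errors are
#'   never needed).
#' @return An object of class `poppk_boot`: `summary` table (median,
#'   rse, ci_lo, ci_hi per parameter), raw `estimates`, `n_success`,
#'   `n_failed` and metadata.
#' @export
bootstrap_poppk <- function(fit, ds, n = 1000, seed = 1, stratify = TRUE,
                            control = fit_control(se = FALSE)) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  est <- vector("list", n)
  failed <- 0L
  for (b in seq_len(n)) {
    db <- resample_dataset(ds, stratify)
    fb <- try(fit_poppk(fit$model, db, control = control, fix = fit$fix),
              silent = TRUE)
    if (inherits(fb, "try-error") || !is.finite(fb$ofv)) {
      failed <- failed + 1L
      next
    }
    est[[b]] <- stats::setNames(fb$estimates$estimate, fb$estimates$parameter)
  }
  est <- do.call(rbind, est[!vapply(est, is.null, logical(1))])
  if (is.null(est) || !nrow(est)) stop("all bootstrap refits failed")
  summ <- data.frame(
    parameter = colnames(est),
    median = apply(est, 2, stats::median),
    rse = 100 * apply(est, 2, stats::sd) / abs(apply(est, 2, stats::median)),
    ci_lo = apply(est, 2, stats::quantile, 0.025),
    ci_hi = apply(est, 2, stats::quantile, 0.975),
    row.names = NULL)
  structure(list(summary = summ, estimates = est,
                 n_success = nrow(est), n_failed = failed,
                 stratified = stratify, seed = seed),
            class = "poppk_boot")
}

#' @export
print.poppk_boot <- function(x, ...) {
  cat(sprintf("Bootstrap: %d successful refits (%d failed)%s\n", x$n_success,
              x$n_failed, if (x$stratified) ", stratified by dose arm" else ""))
  s <- x$summary
  s$median <- signif(s$median, 4)
  s$rse <- sprintf("%.1f%%", s$rse)
  s$ci_lo <- signif(s$ci_lo, 4); s$ci_hi <- signif(s$ci_hi, 4)
  print(s, row.names = FALSE)
  invisible(x)
}
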