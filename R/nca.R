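#' Non-compartmental analysis of one concentration profile
#'
#' Model-free exposure metrics: Cmax/Tmax straight from the observed
#' points, AUC by the linear-up/log-down trapezoid, terminal slope
#' lambda_z by log-linear regression over the best adjusted-r-squared
#' window of the last 3 to 6 points after (and excluding) Tmax,
#' `t1/2 = ln 2 / lambda_z`, `AUC0-inf = AUC0-t + Clast/lambda_z`,
#' `CL/F = 1000 * dose / AUC0-inf` (L/h for dose in mg and AUC in
#' ng*h/mL) and `Vz/F = CL/F / lambda_z`.
#'
#' When no credible terminal phase exists (fewer than 3 usable points or
#' best r-squared < 0.8) the extrapolated quantities are `NA`.
#'
#' @param times Sampling times (h), increasing.
#' @param conc Concentrations (ng/mL).
#' @param dose Dose (mg) administered at the profile's time origin.
#' @return A one-row data frame: `cmax`, `tmax`, `auc_t`, `auc_inf`,
#'   `lambda_z`, `t_half`, `cl_f`, `vz_f`, `r2_terminal`, `n_terminal`.
#' @export
nca_profile <- function(times, conc, dose) {
  keep <- is.finite(conc) & is.finite(times)
  times <- times[keep]; conc <- conc[keep]
  if (is.unsorted(times, strictly = TRUE)) stop("times must be strictly increasing")
  if (sum(conc > 0) < 3) stop("need at least 3 positive concentrations")
  if (dose <= 0) stop("dose must be positive")
  i_max <- which.max(conc)
  cmax <- conc[i_max]; tmax <- times[i_max]
  auc_t <- auc_lin_up_log_down(times, conc)

  # terminal slope: log-linear fit over trailing windows of 3..6 points,
  # positive concentrations after Tmax, Tmax itself excluded
  cand <- which(seq_along(conc) > i_max & conc > 0)
  lz <- r2 <- NA_real_; n_term <- 0L
  if (length(cand) >= 3) {
    best_adj <- -Inf
    for (k in 3:min(6, length(cand))) {
      idx <- utils::tail(cand, k)
      x <- times[idx]; z <- log(conc[idx])
      sxx <- sum((x - mean(x))^2)
      slope <- -sum((x - mean(x)) * (z - mean(z))) / sxx
      if (slope <= 0) next
      rss <- sum((z - mean(z) + slope * (x - mean(x)))^2)
      tss <- sum((z - mean(z))^2)
      r2k <- if (tss > 0) 1 - rss / tss else 1
      adj <- 1 - (1 - r2k) * (k - 1) / (k - 2)
      if (adj > best_adj) {
        best_adj <- adj; lz <- slope; r2 <- r2k; n_term <- k
      }
    }
  }
  if (!is.na(r2) && r2 < 0.8) { lz <- r2 <- NA_real_; n_term <- 0L }
  clast <- conc[max(which(conc > 0))]
  auc_inf <- if (is.na(lz)) NA_real_ else auc_t + clast / lz
  cl_f <- if (is.na(auc_inf)) NA_real_ else 1000 * dose / auc_inf
  data.frame(cmax = cmax, tmax = tmax, auc_t = auc_t, auc_inf = auc_inf,
             lambda_z = lz, t_half = log(2) / lz, cl_f = cl_f,
             vz_f = cl_f / lz, r2_terminal = r2, n_terminal = n_term)
}

# linear trapezoid on rising/flat segments, log trapezoid on declining
# segments with both endpoints positive
auc_lin_up_log_down <- function(times, conc) {
  dt <- diff(times)
  c1 <- utils::head(conc, -1)
  c2 <- utils::tail(conc, -1)
  seg <- ifelse(c2 < c1 & c2 > 0 & c1 > 0,
                (c1 - c2) * dt / log(c1 / c2),
                (c1 + c2) * dt / 2)
  sum(seg)
}

#' Per-subject NCA over a trial dataset
#'
#' Applies [nca_profile()] to each subject's single-dose period
#' (observations in 0-96 h, dose at t = 0) or to the day-21 interval of
#' the multiple-dose period (observations in 576-600 h, re-anchored to the
#' 576 h dose; the 24 h interval AUC plays the role of AUC0-t).
#'
#' @param ds A [pk_trial()] dataset.
#' @param period `"single"` or `"multiple"`.
#' @param include_blq Include BLQ records (as their recorded values);
#'   default drops them.
#' @return Data frame with `id`, `dose_mg` and the [nca_profile()] columns;
#'   subjects with too few usable points are skipped.
#' @export
nca_dataset <- function(ds, period = c("single", "multiple"), include_blq = FALSE) {
  period <- match.arg(period)
  out <- list()
  for (j in seq_len(nrow(ds$subjects))) {
    id <- ds$subjects$id[j]
    obs <- ds$obs[ds$obs$id == id, ]
    if (!include_blq) obs <- obs[!obs$blq, ]
    obs <- obs[order(obs$time), ]
    if (period == "single") {
      obs <- obs[obs$time <= 96, ]
      t0 <- 0
    } else {
      obs <- obs[obs$time >= 576 & obs$time <= 600, ]
      t0 <- 576
    }
    if (sum(obs$dv > 0) < 3) next
    r <- try(nca_profile(obs$time - t0, obs$dv, ds$subjects$dose_mg[j]),
             silent = TRUE)
    if (inherits(r, "try-error")) next
    out[[id]] <- cbind(data.frame(id = id, dose_mg = ds$subjects$dose_mg[j],
                                  stringsAsFactors = FALSE), r)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Dose-proportionality assessment
#'
#' Regression of mean exposure against dose across arms, summarized by the
#' Pearson correlation coefficient R (linearity is conventionally claimed
#' at R >= 0.99). The log-log slope-based R is reported alongside.
#'
#' @param doses Dose levels (mg).
#' @param mean_exposure Mean exposure per dose level (same order).
#' @return List with `r` (Pearson R, rounded to 2 decimals), `r_raw`,
#'   `p_value`, `r_loglog`, `n_levels`, and `proportional` (R >= 0.99).
#' @examples
#' dose_proportionality(c(100, 200, 400), c(1000, 2100, 3900))
#' @export
dose_proportionality <- function(doses, mean_exposure) {
  if (length(doses) != length(mean_exposure)) stop("length mismatch")
  if (length(doses) < 3) stop("need at least 3 dose levels")
  ct <- stats::cor.test(doses, mean_exposure)
  r_ll <- stats::cor(log(doses), log(mean_exposure))
  r <- round(unname(ct$estimate), 2)
  list(r = r, r_raw = unname(ct$estimate), p_value = ct$p.value,
       r_loglog = r_ll, n_levels = length(doses), proportional = r >= 0.99)
}

#' Published NCA exposure summary of the phase I trial
#'
#' Arm-level mean exposures of oral ORIN1001 reported from the phase I
#' dose-escalation study (non-compartmental analysis): mean Cmax and mean
#' AUC0-t per dose arm for the single-dose period (AUC to 100 h) and the
#' day-21 multiple-dose interval (AUC over 24 h). These published summary
#' values are the inputs of the dose-proportionality assessment.
#'
#' @return Data frame with `period`, `dose`, `n`, `cmax_mean` (ng/mL),
#'   `auc_t_mean` (ng*h/mL).
#' @export
orin_exposure_summary <- function() {
  rbind(
    data.frame(period = "single", dose = c(100, 200, 300, 400, 500, 650, 900),
               n = c(3, 3, 4, 3, 3, 5, 4),
               cmax_mean = c(3820, 5590, 9360, 13446.67, 14866.67, 18300, 31225),
               auc_t_mean = c(68788.93, 131728.83, 228262.75, 368183.33,
                              378935.33, 522604.40, 1043135)),
    data.frame(period = "multiple", dose = c(100, 200, 300, 400, 500, 650, 900),
               n = c(3, 3, 3, 3, 3, 2, 2),
               cmax_mean = c(4846.67, 10633.33, 14700, 21466.67, 33533.33,
                             39400, 58650),
               auc_t_mean = c(66065, 171946.67, 239481.67, 371281.67, 579450,
                              661975, 1022700))
  )
}
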