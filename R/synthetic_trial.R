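#' Phase I trial design for the synthetic generator
#'
#' Default design emulating the dose-escalation study: 25 subjects over
#' seven once-daily arms (100-900 mg), a single dose at t = 0 observed for
#' 96 h, then 21 daily doses from 96 h to 576 h, with sparse sampling at
#' the nominal times (pre-dose and 1, 2, 4, 6, 8, 12, 24, 48, 72, 96 h
#' after the single dose; pre-dose and 1, 2, 4, 6, 8, 12, 24 h after the
#' day-21 dose at 576 h) - 19 nominal samples per subject, 475 in total.
#'
#' @param arms Data frame with `dose` (mg) and `n` per arm.
#' @param single_times Sampling times (h) in the single-dose period.
#' @param day21_times Sampling times (h) around the day-21 dose.
#' @param dose_times Dosing times (h); default single dose at 0 then daily
#'   from 96 h to 576 h.
#' @param dropout Fraction of observation records removed at random
#'   (missed samples), in `[0, 0.5)`. The default removes 4 of 475.
#' @return A list of class `trial_design`.
#' @export
trial_design <- function(arms = data.frame(dose = c(100, 200, 300, 400, 500, 650, 900),
                                           n = c(3, 3, 4, 3, 3, 5, 4)),
                         single_times = c(0, 1, 2, 4, 6, 8, 12, 24, 48, 72, 96),
                         day21_times = 576 + c(0, 1, 2, 4, 6, 8, 12, 24),
                         dose_times = c(0, seq(96, 576, by = 24)),
                         dropout = 4 / 475) {
  if (dropout < 0 || dropout >= 0.5)
    stop("dropout fraction must be in [0, 0.5)")
  structure(list(arms = arms, single_times = single_times,
                 day21_times = day21_times, dose_times = dose_times,
                 dropout = dropout),
            class = "trial_design")
}

# inverse-CDF truncated normal / lognormal draws
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}
rtlnorm <- function(n, median, iqr_lo, iqr_hi, lo, hi) {
  sdlog <- log(iqr_hi / iqr_lo) / (2 * stats::qnorm(0.75))
  exp(rtnorm(n, log(median), sdlog, log(lo), log(hi)))
}

#' Covariate distribution of the synthetic cohort
#'
#' Sampling specification emulating the modeling cohort's baseline
#' characteristics: sex, age, height and body-mass index are drawn from
#' truncated (log)normals calibrated to the cohort's medians, IQRs and
#' ranges (weight and every body-size covariate - LBW, BSA, IBW, BF%,
#' adjusted weight - then follow deterministically through
#' [derive_covariates()]); laboratory covariates are independent truncated
#' lognormals matched to median/IQR and truncated to the observed range.
#'
#' @return A list of class `covariate_distribution` with per-covariate
#'   sampling parameters.
#' @export
covariate_distribution <- function() {
  structure(list(
    sex_male_frac = 13 / 25,
    age = list(mean = 57, sd = 9.5, lo = 37, hi = 72),
    height = list(male = c(mean = 171, sd = 5.5, lo = 158, hi = 178),
                  female = c(mean = 156, sd = 5.5, lo = 150, hi = 172)),
    bmi = list(mean = 22.6, sd = 4.2, lo = 18.67, hi = 28.72),
    height_bmi_corr = 0.7,
    weight_range = c(42, 80),
    labs = list(
      tbil = list(median = 10.30, iqr = c(8.35, 13.35), range = c(4.80, 23.20)),
      ldh  = list(median = 214,   iqr = c(180.50, 279), range = c(98, 1268)),
      bun  = list(median = 8.94,  iqr = c(7.12, 11.09), range = c(3.70, 16.28)),
      cr   = list(median = 58,    iqr = c(50.45, 70),   range = c(31, 89)),
      alt  = list(median = 18.7,  iqr = c(10.75, 25.55), range = c(3, 37)),
      ast  = list(median = 22,    iqr = c(16.50, 28.50), range = c(10, 77)),
      alp  = list(median = 85,    iqr = c(58, 147.45),  range = c(31, 304))
    ),
    dbil_frac = list(mean = 0.30, sd = 0.07, lo = 0.10, hi = 0.60)
  ), class = "covariate_distribution")
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` internally consistent subjects from a
#' [covariate_distribution()]: anthropometrics are generated from
#' (sex, height, BMI) and pushed through [derive_covariates()], so derived
#' covariates always honor their formulas; labs are drawn independently.
#'
#' @param dist A [covariate_distribution()].
#' @param n Number of subjects.
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Data frame with one row per subject: `sex`, `age`, `height`,
#'   `weight`, all labs, and the derived covariates.
#' @export
generate_cohort_covariates <- function(dist = covariate_distribution(), n,
                                       seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_male <- round(n * dist$sex_male_frac)
  sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
  age <- round(rtnorm(n, dist$age$mean, dist$age$sd, dist$age$lo, dist$age$hi))
  # height and BMI share a Gaussian copula so LBW reproduces the cohort's
  # spread; each margin is a truncated normal
  rho <- dist$height_bmi_corr
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  tq <- function(u, mean, sd, lo, hi) {
    plo <- stats::pnorm(lo, mean, sd)
    phi <- stats::pnorm(hi, mean, sd)
    stats::qnorm(plo + u * (phi - plo), mean, sd)
  }
  height <- numeric(n)
  for (sx in c("male", "female")) {
    h <- dist$height[[sx]]
    k <- sex == sx
    height[k] <- tq(stats::pnorm(z1[k]), h[["mean"]], h[["sd"]], h[["lo"]], h[["hi"]])
  }
  bmi <- tq(stats::pnorm(z2), dist$bmi$mean, dist$bmi$sd, dist$bmi$lo, dist$bmi$hi)
  weight <- pmin(pmax(bmi * (height / 100)^2, dist$weight_range[1]),
                 dist$weight_range[2])
  labs <- lapply(dist$labs, function(l)
    rtlnorm(n, l$median, l$iqr[1], l$iqr[2], l$range[1], l$range[2]))
  dbil <- labs$tbil * rtnorm(n, dist$dbil_frac$mean, dist$dbil_frac$sd,
                             dist$dbil_frac$lo, dist$dbil_frac$hi)
  der <- derive_covariates(sex, age, height, weight, labs$cr)
  out <- data.frame(sex = sex, age = age, height = height, weight = weight,
                    stringsAsFactors = FALSE)
  for (nm in names(labs)) out[[nm]] <- labs[[nm]]
  out$dbil <- dbil
  out$ibil <- labs$tbil - dbil
  cbind(out, der)
}

#' Generate a synthetic PK trial
#'
#' Full forward simulation of the study: covariates from
#' [generate_cohort_covariates()], individual parameters from the truth
#' model (covariate effects and lognormal IIV), concentrations from the
#' closed-form structural model with proportional residual error
#' (truncated at zero), BLQ flagging below the assay LLOQ of 50 ng/mL,
#' and uniform random removal of a `dropout` fraction of observation
#' records (dose events are never dropped). Reproducible given the seed.
#'
#' @param design A [trial_design()].
#' @param truth A complete `poppk_model` used as the data-generating truth.
#' @param seed Integer seed.
#' @param dist A [covariate_distribution()].
#' @return A [pk_trial()] dataset with provenance in `$meta`.
#' @examples
#' ds <- generate_trial(trial_design(), orin_final_model(), seed = 1)
#' ds
#' @export
generate_trial <- function(design = trial_design(), truth = orin_final_model(),
                           seed = 1, dist = covariate_distribution()) {
  set.seed(seed)
  n <- sum(design$arms$n)
  cov <- generate_cohort_covariates(dist, n)
  ids <- sprintf("S%02d", seq_len(n))
  dose_mg <- rep(design$arms$dose, design$arms$n)
  subjects <- cbind(data.frame(id = ids, dose_mg = dose_mg,
                               stringsAsFactors = FALSE), cov)
  q <- if (is.null(truth$omega)) 0L else nrow(truth$omega)
  Lw <- if (q) t(chol(truth$omega))
  obs_times <- sort(unique(c(design$single_times, design$day21_times)))
  doses <- obs <- vector("list", n)
  for (j in seq_len(n)) {
    covs <- unlist(cov[j, setdiff(names(cov), "sex")])
    p <- if (q) {
      eta <- stats::setNames(as.numeric(Lw %*% stats::rnorm(q)),
                             rownames(truth$omega))
      individual_params(truth, covs, eta)
    } else individual_typical_params(truth, covs)
    f <- conc_at(p, design$dose_times, rep(dose_mg[j], length(design$dose_times)),
                 obs_times)
    eps <- stats::rnorm(length(f))
    dv <- pmax(f * (1 + truth$sigma$prop * eps) +
                 truth$sigma$add * stats::rnorm(length(f)), 0)
    doses[[j]] <- data.frame(id = ids[j], time = design$dose_times,
                             amt = dose_mg[j], stringsAsFactors = FALSE)
    obs[[j]] <- data.frame(id = ids[j], time = obs_times, dv = dv,
                           stringsAsFactors = FALSE)
  }
  obs <- do.call(rbind, obs)
  n_drop <- round(design$dropout * nrow(obs))
  if (n_drop > 0) obs <- obs[-sample(nrow(obs), n_drop), ]
  pk_trial(subjects = subjects, doses = do.call(rbind, doses),
           observations = obs, lloq = 50,
           meta = list(seed = seed, generator = "orinpk synthetic_trial",
                       version = as.character(utils::packageVersion("orinpk"))))
}
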