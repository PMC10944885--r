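#' Pearson collinearity pre-screen of candidate covariates
#'
#' Pairwise Pearson correlation with two-sided p-values over a numeric
#' covariate table. When a pair has `|r| > r_threshold` and
#' `p < p_threshold`, only one member is kept: pairs are resolved in
#' decreasing `|r|`, retaining the member with the higher univariate
#' `score` (by convention the OFV drop when the covariate is tested alone
#' on CL/F); without scores, ties fall back to column order. Zero-variance
#' columns are excluded with a warning.
#'
#' @param cov_df Data frame of numeric covariates (one row per subject,
#'   at least 3 rows).
#' @param r_threshold Absolute-correlation threshold (default 0.5).
#' @param p_threshold Significance threshold for the correlation test.
#' @param score Optional named numeric vector of univariate scores
#'   (larger = retained preferentially).
#' @return An object of class `covariate_screen`: correlation and p-value
#'   matrices, an `excluded` table (covariate, kept partner, r, p) and
#'   the retained `candidates`.
#' @export
covariate_prescreen <- function(cov_df, r_threshold = 0.5, p_threshold = 0.05,
                                score = NULL) {
  cov_df <- as.data.frame(cov_df)
  num <- vapply(cov_df, is.numeric, logical(1))
  cov_df <- cov_df[num]
  if (nrow(cov_df) < 3) stop("need at least 3 subjects")
  sds <- vapply(cov_df, stats::sd, numeric(1))
  if (any(sds == 0)) {
    warning("zero-variance covariate(s) excluded: ",
            paste(names(cov_df)[sds == 0], collapse = ", "))
    cov_df <- cov_df[sds > 0]
  }
  nm <- names(cov_df)
  k <- length(nm)
  r_mat <- p_mat <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r_mat) <- 1; diag(p_mat) <- 0
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ct <- stats::cor.test(cov_df[[i]], cov_df[[j]])
    r_mat[i, j] <- r_mat[j, i] <- unname(ct$estimate)
    p_mat[i, j] <- p_mat[j, i] <- ct$p.value
    if (abs(ct$estimate) > r_threshold && ct$p.value < p_threshold)
      pairs[[length(pairs) + 1]] <- list(a = nm[i], b = nm[j],
                                         r = unname(ct$estimate), p = ct$p.value)
  }
  rank_of <- function(x) {
    if (!is.null(score) && x %in% names(score)) score[[x]] else -match(x, nm)
  }
  alive <- nm
  excluded <- data.frame(covariate = character(), kept = character(),
                         r = numeric(), p = numeric(), stringsAsFactors = FALSE)
  if (length(pairs)) {
    ord <- order(-abs(vapply(pairs, function(p) p$r, numeric(1))))
    for (pr in pairs[ord]) {
      if (!(pr$a %in% alive) || !(pr$b %in% alive)) next
      drop <- if (rank_of(pr$a) >= rank_of(pr$b)) pr$b else pr$a
      keep <- setdiff(c(pr$a, pr$b), drop)
      alive <- setdiff(alive, drop)
      excluded <- rbind(excluded, data.frame(covariate = drop, kept = keep,
                                             r = pr$r, p = pr$p,
                                             stringsAsFactors = FALSE))
    }
  }
  structure(list(correlation = r_mat, p_values = p_mat, excluded = excluded,
                 candidates = alive, r_threshold = r_threshold,
                 p_threshold = p_threshold),
            class = "covariate_screen")
}

#' @export
print.covariate_screen <- function(x, ...) {
  cat(sprintf("Covariate pre-screen (|r| > %g, p < %g): %d candidates retained\n",
              x$r_threshold, x$p_threshold, length(x$candidates)))
  cat("  candidates:", paste(x$candidates, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat("  excluded (collinear):\n")
    print(x$excluded, row.names = FALSE)
  }
  invisible(x)
}

default_fitter <- function(control) {
  force(control)
  function(m, ds) fit_poppk(m, ds, control = control)
}

add_effect <- function(m, parameter, covariate, ds, exponent = 0) {
  ref <- stats::median(ds$subjects[[covariate]])
  m$effects <- rbind(m$effects,
                     covariate_effect(parameter, covariate, exponent, ref))
  m
}

has_effect <- function(m, parameter, covariate) {
  !is.null(m$effects) && any(m$effects$parameter == parameter &
                               m$effects$covariate == covariate)
}

#' Univariate covariate scores on clearance
#'
#' OFV drop when each candidate is tested alone on CL/F against the base
#' model; used to resolve collinear pairs in [covariate_prescreen()].
#'
#' @param base_fit A fitted `poppk_fit` for the base model.
#' @param ds Dataset.
#' @param candidates Covariate names present in `ds$subjects`.
#' @param fitter Fitting function `function(model, ds)`; defaults to
#'   [fit_poppk()] without standard errors.
#' @return Named numeric vector of OFV drops.
#' @export
univariate_scores <- function(base_fit, ds, candidates,
                              fitter = default_fitter(fit_control(se = FALSE))) {
  vapply(candidates, function(cv) {
    f <- try(fitter(add_effect(base_fit$model, "cl", cv, ds), ds), silent = TRUE)
    if (inherits(f, "try-error")) return(-Inf)
    base_fit$ofv - f$ofv
  }, numeric(1))
}

step_entry <- function(action, parameter, covariate, ofv_before, ofv_after,
                       threshold, decision) {
  data.frame(action = action, parameter = parameter, covariate = covariate,
             ofv_before = ofv_before, ofv_after = ofv_after,
             delta_ofv = ofv_after - ofv_before, threshold = threshold,
             decision = decision, stringsAsFactors = FALSE)
}

#' One forward-inclusion step
#'
#' Fits every remaining candidate parameter-covariate extension of the
#' current model and adds the extension with the largest OFV drop,
#' provided the drop exceeds `threshold` (3.84, chi-squared 0.05 with
#' 1 df). Returns a no-op entry when nothing passes.
#'
#' @param fit Current fitted `poppk_fit`.
#' @param ds Dataset.
#' @param candidates Candidate covariate names.
#' @param parameters Structural parameters searched
#'   (default CL/F, V/F, V2/F, CL2/F).
#' @param threshold OFV-decrease threshold for inclusion.
#' @param fitter Fitting function `function(model, ds) -> poppk_fit`.
#' @return List: `entry` (one [step_entry] row for the accepted addition,
#'   or a no-op row), `fit` (updated fit or the input), `tested` (all
#'   tested extensions with their OFV drops).
#' @export
forward_step <- function(fit, ds, candidates,
                         parameters = c("cl", "v", "v2", "cl2"),
                         threshold = 3.84,
                         fitter = default_fitter(fit_control(se = FALSE))) {
  tested <- list()
  for (cv in candidates) for (pp in parameters) {
    if (has_effect(fit$model, pp, cv)) next
    f <- try(fitter(add_effect(fit$model, pp, cv, ds), ds), silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$ofv)) next
    tested[[paste(pp, cv, sep = "~")]] <- list(parameter = pp, covariate = cv,
                                               fit = f, drop = fit$ofv - f$ofv)
  }
  if (!length(tested))
    return(list(entry = step_entry("add", NA, NA, fit$ofv, fit$ofv, threshold,
                                   "no-op (no candidates)"),
                fit = fit, tested = NULL))
  drops <- vapply(tested, function(t) t$drop, numeric(1))
  best <- tested[[which.max(drops)]]
  tested_df <- data.frame(parameter = vapply(tested, `[[`, "", "parameter"),
                          covariate = vapply(tested, `[[`, "", "covariate"),
                          delta_ofv = -drops, row.names = NULL)
  if (best$drop > threshold)
    list(entry = step_entry("add", best$parameter, best$covariate,
                            fit$ofv, best$fit$ofv, threshold, "accepted"),
         fit = best$fit, tested = tested_df)
  else
    list(entry = step_entry("add", NA, NA, fit$ofv, fit$ofv, threshold,
                            "no-op (no extension passed)"),
         fit = fit, tested = tested_df)
}

#' One backward-elimination step
#'
#' Refits the model with each covariate effect deleted in turn and removes
#' the effect whose deletion raises the OFV least, provided that rise does
#' not exceed `threshold` (6.64, chi-squared 0.01 with 1 df); otherwise
#' every effect is retained and the step is a no-op.
#'
#' @inheritParams forward_step
#' @param threshold OFV-increase threshold above which an effect is kept.
#' @return List as in [forward_step()] with action `"remove"`.
#' @export
backward_step <- function(fit, ds, threshold = 6.64,
                          fitter = default_fitter(fit_control(se = FALSE))) {
  eff <- fit$model$effects
  if (is.null(eff) || !nrow(eff))
    return(list(entry = step_entry("remove", NA, NA, fit$ofv, fit$ofv,
                                   threshold, "no-op (no effects)"),
                fit = fit, tested = NULL))
  tested <- list()
  for (i in seq_len(nrow(eff))) {
    m2 <- fit$model
    m2$effects <- eff[-i, , drop = FALSE]
    if (!nrow(m2$effects)) m2$effects <- NULL
    f <- try(fitter(m2, ds), silent = TRUE)
    if (inherits(f, "try-error") || !is.finite(f$ofv)) next
    tested[[paste(eff$parameter[i], eff$covariate[i], sep = "~")]] <-
      list(parameter = eff$parameter[i], covariate = eff$covariate[i],
           fit = f, rise = f$ofv - fit$ofv)
  }
  if (!length(tested))
    return(list(entry = step_entry("remove", NA, NA, fit$ofv, fit$ofv,
                                   threshold, "no-op (all refits failed)"),
                fit = fit, tested = NULL))
  rises <- vapply(tested, function(t) t$rise, numeric(1))
  best <- tested[[which.min(rises)]]
  tested_df <- data.frame(parameter = vapply(tested, `[[`, "", "parameter"),
                          covariate = vapply(tested, `[[`, "", "covariate"),
                          delta_ofv = rises, row.names = NULL)
  if (best$rise <= threshold)
    list(entry = step_entry("remove", best$parameter, best$covariate,
                            fit$ofv, best$fit$ofv, threshold, "removed"),
         fit = best$fit, tested = tested_df)
  else
    list(entry = step_entry("remove", NA, NA, fit$ofv, fit$ofv, threshold,
                            "no-op (all effects retained)"),
         fit = fit, tested = tested_df)
}

#' Stepwise covariate selection
#'
#' The full workflow: forward inclusion (adding the best passing
#' parameter-covariate extension until none passes the 3.84 OFV-drop
#' threshold), then backward elimination (removing the weakest effect
#' while its deletion raises the OFV by at most 6.64). Returns the final
#' fit and a step trace mirroring the conventional stepwise table.
#'
#' @param base_fit Fitted base model (`poppk_fit`).
#' @param ds Dataset.
#' @param candidates Candidate covariates (e.g. from
#'   [covariate_prescreen()]).
#' @param parameters Structural parameters searched.
#' @param forward_threshold,backward_threshold Chi-squared decision
#'   thresholds (defaults 3.84 and 6.64).
#' @param fitter Fitting function used for every candidate fit.
#' @param max_steps Safety cap on total steps.
#' @return List with `fit` (final), `trace` (step table) and `model`.
#' @export
run_stepwise <- function(base_fit, ds, candidates,
                         parameters = c("cl", "v", "v2", "cl2"),
                         forward_threshold = 3.84, backward_threshold = 6.64,
                         fitter = default_fitter(fit_control(se = FALSE)),
                         max_steps = 30) {
  trace <- list()
  fit <- base_fit
  for (s in seq_len(max_steps)) {
    st <- forward_step(fit, ds, candidates, parameters, forward_threshold, fitter)
    trace[[length(trace) + 1]] <- st$entry
    if (st$entry$decision != "accepted") break
    fit <- st$fit
  }
  for (s in seq_len(max_steps)) {
    st <- backward_step(fit, ds, backward_threshold, fitter)
    trace[[length(trace) + 1]] <- st$entry
    if (st$entry$decision != "removed") break
    fit <- st$fit
  }
  trace <- do.call(rbind, trace)
  trace$step <- seq_len(nrow(trace))
  list(fit = fit, model = fit$model,
       trace = trace[, c("step", "action", "parameter", "covariate",
                         "ofv_before", "ofv_after", "delta_ofv",
                         "threshold", "decision")])
}
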