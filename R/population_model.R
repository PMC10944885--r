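#' Power-of-median covariate effect
#'
#' One multiplicative covariate effect on a structural parameter:
#' `effect = (cov / reference)^exponent`, the standard power model with
#' normalization at the cohort median, so a subject at the reference value
#' has effect exactly 1.
#'
#' @param parameter Structural parameter name, one of
#'   `"ka","tlag","v","v2","cl","cl2"`.
#' @param covariate Covariate name (continuous, positive).
#' @param exponent Power exponent (dimensionless fixed effect).
#' @param reference Reference (median) covariate value; must be positive.
#' @return One-row data frame describing the effect.
#' @export
covariate_effect <- function(parameter, covariate, exponent, reference) {
  parameter <- match.arg(parameter, c("ka", "tlag", "v", "v2", "cl", "cl2"))
  if (!is.finite(reference) || reference <= 0) stop("reference must be positive")
  data.frame(parameter = parameter, covariate = covariate,
             exponent = exponent, reference = reference,
             stringsAsFactors = FALSE)
}

#' Hierarchical population PK model
#'
#' Bundles the typical structural parameters, power-of-median covariate
#' effects, inter-individual variability (IIV) and the residual error
#' model. Individual parameters follow the exponential IIV model
#' `P_ij = TVP_i * prod_k (cov_jk / ref_k)^theta_k * exp(eta_ij)` with
#' `eta ~ N(0, omega)`; the residual model is proportional
#' (`var = (prop * pred)^2`), additive (`var = add^2`) or combined.
#'
#' @param typical Named vector of typical values (a [pk_params()] object or
#'   a named numeric with elements `ka, tlag, v, v2, cl, cl2`).
#' @param effects Data frame of covariate effects (rows from
#'   [covariate_effect()]), or `NULL` for none.
#' @param omega IIV variances (omega-squared): a named numeric vector for a
#'   diagonal matrix, or a full positive-semidefinite matrix with dimnames,
#'   over a subset of the structural parameters. `NULL` for no IIV.
#' @param sigma Residual error: `list(prop = , add = )`; either component
#'   may be 0 but not both.
#' @return An object of class `poppk_model`.
#' @examples
#' m <- population_model(
#'   typical = pk_params(0.58, 0.35, 26.21, 26.60, 1.07, 0.75),
#'   effects = covariate_effect("cl", "tbil", -0.46, 10.30),
#'   omega = c(cl = 0.067, v = 0.049),
#'   sigma = list(prop = 0.197)
#' )
#' @export
population_model <- function(typical, effects = NULL, omega = NULL,
                             sigma = list(prop = 0.2, add = 0)) {
  typical <- unclass(as_pk_params(typical))
  if (!is.null(effects)) {
    stopifnot(all(c("parameter", "covariate", "exponent", "reference") %in% names(effects)))
    if (!all(effects$parameter %in% names(typical)))
      stop("covariate effect references unknown parameter: ",
           paste(setdiff(effects$parameter, names(typical)), collapse = ", "))
    if (any(effects$reference <= 0)) stop("effect reference values must be positive")
    effects <- effects[, c("parameter", "covariate", "exponent", "reference")]
  }
  if (!is.null(omega)) {
    if (is.matrix(omega)) {
      if (is.null(rownames(omega))) stop("omega matrix needs dimnames")
      ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-10 * max(abs(ev))) stop("omega must be positive semidefinite")
    } else {
      if (is.null(names(omega))) stop("omega vector needs names")
      if (any(omega < 0)) stop("omega variances must be non-negative")
      omega <- diag(omega, nrow = length(omega)) |>
        (\(m) { dimnames(m) <- list(names(omega), names(omega)); m })()
    }
    if (!all(rownames(omega) %in% names(typical)))
      stop("omega names must be structural parameter names")
  }
  sigma <- list(prop = if (is.null(sigma$prop)) 0 else sigma$prop,
                add = if (is.null(sigma$add)) 0 else sigma$add)
  if (sigma$prop < 0 || sigma$add < 0 || (sigma$prop == 0 && sigma$add == 0))
    stop("residual model needs a positive proportional and/or additive component")
  structure(list(typical = typical, effects = effects, omega = omega, sigma = sigma),
            class = "poppk_model")
}

#' @export
print.poppk_model <- function(x, ...) {
  cat("Population PK model (two-compartment oral, lagged first-order absorption)\n")
  cat("Typical values:\n")
  print(round(x$typical, 4))
  if (!is.null(x$effects) && nrow(x$effects)) {
    cat("Covariate effects (power of covariate/reference):\n")
    print(x$effects, row.names = FALSE)
  }
  if (!is.null(x$omega)) {
    cat("IIV variances (omega^2):\n")
    print(round(diag(x$omega), 4))
  }
  cat(sprintf("Residual error: proportional %g, additive %g ng/mL\n",
              x$sigma$prop, x$sigma$add))
  invisible(x)
}

#' Published final model for oral ORIN1001
#'
#' The final population PK estimate set from the phase I dose-escalation
#' study in Chinese patients with advanced solid tumors: a two-compartment
#' model with lagged first-order absorption, total bilirubin (TBIL) and
#' lean body weight (LBW) effects on CL/F, an LBW effect on CL2/F, a
#' lactate dehydrogenase (LDH) effect on V2/F, diagonal IIV on
#' V/F, CL/F, Ka and Tlag, and proportional residual error. The reference
#' covariate values are the modeling-cohort medians (TBIL 10.30 umol/L,
#' LBW 45.13 kg, LDH 214 IU/L).
#'
#' @return A [population_model()] object.
#' @examples
#' m <- orin_final_model()
#' individual_typical_params(m, c(tbil = 10.30, lbw = 45.13, ldh = 214))
#' @export
orin_final_model <- function() {
  population_model(
    typical = pk_params(ka = 0.58, tlag = 0.35, v = 26.21, v2 = 26.60,
                        cl = 1.07, cl2 = 0.75),
    effects = rbind(
      covariate_effect("cl",  "tbil", -0.46, 10.30),
      covariate_effect("cl",  "lbw",   1.11, 45.13),
      covariate_effect("v2",  "ldh",   0.99, 214),
      covariate_effect("cl2", "lbw",   2.21, 45.13)
    ),
    omega = c(v = 0.049, cl = 0.067, ka = 0.534, tlag = 0.438),
    sigma = list(prop = 0.197, add = 0)
  )
}

#' Reference covariate values of a model
#'
#' The covariate map of the "reference patient": every covariate named by
#' the model's effects at its reference (median) value.
#'
#' @param m A `poppk_model`.
#' @return Named numeric vector.
#' @export
reference_covariates <- function(m) {
  if (is.null(m$effects) || !nrow(m$effects)) return(stats::setNames(numeric(0), character(0)))
  refs <- tapply(m$effects$reference, m$effects$covariate, `[`, 1)
  stats::setNames(as.numeric(refs), names(refs))
}

#' Covariate-adjusted typical parameters for one subject
#'
#' Applies every covariate effect multiplicatively:
#' `P_i = TVP_i * prod (cov/reference)^exponent`.
#'
#' @param m A `poppk_model`.
#' @param covariates Named numeric vector/list of the subject's covariates;
#'   must contain every covariate the model references.
#' @return A [pk_params()] object.
#' @export
individual_typical_params <- function(m, covariates) {
  p <- m$typical
  if (!is.null(m$effects) && nrow(m$effects)) {
    covariates <- unlist(covariates)
    miss <- setdiff(m$effects$covariate, names(covariates))
    if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
    for (i in seq_len(nrow(m$effects))) {
      e <- m$effects[i, ]
      p[[e$parameter]] <- p[[e$parameter]] *
        (covariates[[e$covariate]] / e$reference)^e$exponent
    }
  }
  as_pk_params(p)
}

#' Individual parameters with inter-individual variability
#'
#' Covariate-adjusted typical values times `exp(eta)` for the parameters
#' carrying IIV; parameters without IIV pass through unchanged.
#'
#' @inheritParams individual_typical_params
#' @param eta Named numeric vector of random effects (names must match
#'   omega's parameters), or unnamed in omega order.
#' @return A [pk_params()] object.
#' @export
individual_params <- function(m, covariates, eta) {
  p <- unclass(individual_typical_params(m, covariates))
  if (length(eta)) {
    nm <- names(eta)
    if (is.null(nm)) {
      if (is.null(m$omega) || length(eta) != nrow(m$omega))
        stop("unnamed eta must match omega dimension")
      nm <- rownames(m$omega)
    }
    p[nm] <- p[nm] * exp(as.numeric(eta))
  }
  as_pk_params(p)
}

#' Residual error model
#'
#' Mean and variance of one observation given its model prediction:
#' `var = (prop * pred)^2 + add^2`.
#'
#' @param pred Predicted concentration(s), ng/mL.
#' @param sigma Residual specification `list(prop=, add=)` or a
#'   `poppk_model`.
#' @return List with `mean` (= pred) and `var`.
#' @export
residual_model <- function(pred, sigma) {
  if (inherits(sigma, "poppk_model")) sigma <- sigma$sigma
  prop <- if (is.null(sigma$prop)) 0 else sigma$prop
  add <- if (is.null(sigma$add)) 0 else sigma$add
  if (any(pred < 0)) stop("pred must be non-negative")
  list(mean = pred, var = (prop * pred)^2 + add^2)
}

#' Derived body-size and renal covariates
#'
#' Standard derived covariates from basic demographics:
#' BMI (weight/height^2), BSA (DuBois), lean body weight (Janmahasatian),
#' ideal body weight (Devine), body-fat percentage (Deurenberg),
#' creatinine clearance (Cockcroft-Gault, creatinine converted from
#' umol/L to mg/dL), adjusted weight (IBW + 0.4*(weight - IBW), applied
#' only when BMI > 25 kg/m^2) and the adjusted-weight Cockcroft-Gault
#' clearance.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param age Age in years.
#' @param height Height in cm.
#' @param weight Weight in kg.
#' @param creatinine Serum creatinine in umol/L.
#' @return Data frame with columns `bmi` (kg/m^2), `bsa` (m^2), `lbw`
#'   (kg), `ibw` (kg), `bf` (%), `clcr` (mL/min), `adj_weight` (kg),
#'   `adj_clcr` (mL/min).
#' @examples
#' derive_covariates("female", age = 57, height = 165, weight = 64,
#'                   creatinine = 58)
#' @export
derive_covariates <- function(sex, age, height, weight, creatinine) {
  if (any(!sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (any(c(age, height, weight, creatinine) <= 0))
    stop("demographic inputs must be positive")
  male <- sex == "male"
  ht_m <- height / 100
  bmi <- weight / ht_m^2
  bsa <- 0.007184 * weight^0.425 * height^0.725
  lbw <- ifelse(male,
                9270 * weight / (6680 + 216 * bmi),
                9270 * weight / (8780 + 244 * bmi))
  ht_in <- height / 2.54
  ibw <- ifelse(male, 50, 45.5) + 2.3 * (ht_in - 60)
  bf <- 1.20 * bmi + 0.23 * age - 10.8 * male - 5.4
  cr_mgdl <- creatinine / 88.4
  cg <- function(wt) (140 - age) * wt / (72 * cr_mgdl) * ifelse(male, 1, 0.85)
  clcr <- cg(weight)
  adj_weight <- ifelse(bmi > 25, ibw + 0.4 * (weight - ibw), weight)
  data.frame(bmi = bmi, bsa = bsa, lbw = lbw, ibw = ibw, bf = bf,
             clcr = clcr, adj_weight = adj_weight, adj_clcr = cg(adj_weight))
}

#' Write / read a population model as JSON
#'
#' Plain-text round-trippable model specification: typical values, effect
#' table, omega matrix and residual components.
#'
#' @param m A `poppk_model`.
#' @param path File path.
#' @return `read_model_json` returns a `poppk_model`;
#'   `write_model_json` returns `path` invisibly.
#' @export
write_model_json <- function(m, path) {
  spec <- list(typical = as.list(m$typical),
               effects = m$effects,
               omega = if (is.null(m$omega)) NULL else
                 list(names = rownames(m$omega), matrix = unname(m$omega)),
               sigma = m$sigma)
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  omega <- NULL
  if (!is.null(spec$omega)) {
    omega <- as.matrix(spec$omega$matrix)
    dimnames(omega) <- list(spec$omega$names, spec$omega$names)
  }
  effects <- if (is.null(spec$effects) || !length(spec$effects)) NULL else
    as.data.frame(spec$effects)
  population_model(typical = unlist(spec$typical), effects = effects,
                   omega = omega, sigma = spec$sigma)
}
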