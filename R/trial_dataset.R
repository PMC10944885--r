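#' Longitudinal PK trial dataset
#'
#' Event-level container for a sparse-sampling oral dosing study:
#' a subject table (dose arm and covariates), a dose-event table and an
#' observation table. This is the substrate every other stage (estimation,
#' diagnostics, NCA, simulation) consumes.
#'
#' @param subjects Data frame with `id`, `dose_mg` and one column per
#'   covariate (all positive).
#' @param doses Data frame with `id`, `time` (h since first dose),
#'   `amt` (mg); times strictly increasing within subject.
#' @param observations Data frame with `id`, `time` (h), `dv`
#'   (concentration, ng/mL) and optionally `blq` (logical, below the
#'   assay's lower limit of quantification).
#' @param lloq Lower limit of quantification (ng/mL) used to flag `blq`
#'   when the column is absent. The assay's validated linear range starts
#'   at 50 ng/mL.
#' @param meta Optional provenance list (seed, generator, source file).
#' @return An object of class `pk_trial`.
#' @export
pk_trial <- function(subjects, doses, observations, lloq = 50, meta = list()) {
  subjects$id <- as.character(subjects$id)
  doses$id <- as.character(doses$id)
  observations$id <- as.character(observations$id)
  if (is.null(observations$blq)) observations$blq <- observations$dv < lloq
  ds <- structure(list(subjects = subjects, doses = doses,
                       obs = observations, lloq = lloq, meta = meta),
                  class = "pk_trial")
  validate_pk_trial(ds)
  ds
}

validate_pk_trial <- function(ds) {
  stopifnot(all(c("id", "dose_mg") %in% names(ds$subjects)),
            all(c("id", "time", "amt") %in% names(ds$doses)),
            all(c("id", "time", "dv") %in% names(ds$obs)))
  if (any(ds$subjects$dose_mg <= 0)) stop("dose_mg must be positive")
  unknown <- setdiff(c(ds$doses$id, ds$obs$id), ds$subjects$id)
  if (length(unknown))
    stop("records reference unknown subjects: ", paste(unique(unknown), collapse = ", "))
  if (any(ds$doses$time < 0) || any(ds$obs$time < 0))
    stop("event times must be non-negative")
  bad <- vapply(split(ds$doses$time, ds$doses$id),
                function(t) any(diff(t) <= 0), logical(1))
  if (any(bad))
    stop("non-monotone dose times for subject(s): ",
         paste(names(bad)[bad], collapse = ", "))
  dupobs <- vapply(split(ds$obs$time, ds$obs$id), anyDuplicated, integer(1))
  if (any(dupobs > 0))
    stop("duplicated observation times for subject(s): ",
         paste(names(dupobs)[dupobs > 0], collapse = ", "))
  if (any(!ds$obs$blq & ds$obs$dv < 0))
    stop("negative concentrations in non-BLQ records")
  invisible(ds)
}

#' @export
print.pk_trial <- function(x, ...) {
  cat(sprintf("PK trial: %d subjects, %d dose events, %d observations (%d BLQ)\n",
              nrow(x$subjects), nrow(x$doses), nrow(x$obs), sum(x$obs$blq)))
  cat("Dose arms (mg):", paste(sort(unique(x$subjects$dose_mg)), collapse = ", "), "\n")
  invisible(x)
}

covariate_columns <- function(ds) {
  setdiff(names(ds$subjects), c("id", "dose_mg", "sex"))
}

#' Read a NONMEM-style PK dataset from CSV
#'
#' Expects the conventional long layout: one row per event with columns
#' `ID`, `TIME`, `SEQ` (within-time ordering; observations before a
#' same-time dose carry a lower SEQ), `EVID` (1 = dose, 0 = observation),
#' `AMT`, `DV`, optional `MDV` and `BLQ`, plus one column per covariate
#' (constant within subject; taken from the subject's first row).
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector renaming non-standard
#'   columns, e.g. `c(ID = "subject")`.
#' @param lloq Lower limit of quantification (ng/mL).
#' @return A [pk_trial()] object.
#' @export
read_pk_dataset <- function(path, col_map = NULL, lloq = 50) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map))
    for (std in names(col_map)) names(raw)[names(raw) == col_map[[std]]] <- std
  required <- c("ID", "TIME", "AMT", "DV", "EVID")
  miss <- setdiff(required, names(raw))
  if (length(miss))
    stop("dataset is missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(raw$SEQ)) raw$SEQ <- seq_len(nrow(raw))
  raw <- raw[order(raw$ID, raw$TIME, raw$SEQ), ]
  covs <- setdiff(names(raw), c("ID", "TIME", "SEQ", "AMT", "DV", "EVID", "MDV", "BLQ"))
  first <- raw[!duplicated(raw$ID), , drop = FALSE]
  dsub <- raw[raw$EVID == 1, ]
  dose_mg <- vapply(split(dsub$AMT, dsub$ID), function(a) a[1], numeric(1))
  subjects <- data.frame(id = as.character(first$ID),
                         dose_mg = as.numeric(dose_mg[as.character(first$ID)]),
                         stringsAsFactors = FALSE)
  for (cv in covs) subjects[[cv]] <- first[[cv]]
  obs <- raw[raw$EVID == 0, ]
  observations <- data.frame(id = as.character(obs$ID), time = obs$TIME, dv = obs$DV,
                             stringsAsFactors = FALSE)
  if (!is.null(obs$BLQ)) observations$blq <- as.logical(obs$BLQ)
  pk_trial(subjects = subjects,
           doses = data.frame(id = as.character(dsub$ID), time = dsub$TIME,
                              amt = dsub$AMT, stringsAsFactors = FALSE),
           observations = observations, lloq = lloq,
           meta = list(source = path))
}

#' Write a PK dataset to NONMEM-style CSV
#'
#' Deterministic row order: by subject, then time, with same-time
#' observations before dose events (pre-dose samples), encoded through the
#' `SEQ` column rather than time jitter. Writing then reading reproduces
#' the dataset.
#'
#' @param ds A [pk_trial()] object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(ds, path) {
  covs <- setdiff(names(ds$subjects), c("id", "dose_mg"))
  rows_obs <- if (nrow(ds$obs)) data.frame(
    ID = ds$obs$id, TIME = ds$obs$time, EVID = 0L, AMT = 0,
    DV = ds$obs$dv, MDV = as.integer(ds$obs$blq), BLQ = as.integer(ds$obs$blq),
    ord = 0L, stringsAsFactors = FALSE) else NULL
  rows_dose <- if (nrow(ds$doses)) data.frame(
    ID = ds$doses$id, TIME = ds$doses$time, EVID = 1L, AMT = ds$doses$amt,
    DV = NA_real_, MDV = 1L, BLQ = 0L, ord = 1L, stringsAsFactors = FALSE) else NULL
  out <- rbind(rows_obs, rows_dose)
  if (is.null(out)) {
    out <- data.frame(ID = character(), TIME = numeric(), SEQ = integer(),
                      EVID = integer(), AMT = numeric(), DV = numeric(),
                      MDV = integer(), BLQ = integer())
    for (cv in covs) out[[cv]] <- numeric()
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  out <- out[order(out$ID, out$TIME, out$ord), ]
  out$SEQ <- stats::ave(seq_len(nrow(out)), out$ID, FUN = seq_along)
  idx <- match(out$ID, ds$subjects$id)
  for (cv in covs) out[[cv]] <- ds$subjects[[cv]][idx]
  out <- out[, c("ID", "TIME", "SEQ", "EVID", "AMT", "DV", "MDV", "BLQ", covs)]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
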