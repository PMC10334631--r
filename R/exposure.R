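## Past-1-year incident-user exposure classification (landmark design).
##
## Relative to study entry t0, two half-open windows at day resolution:
##   FAR  = [t0 - 548 d, t0 - 365 d)   ("1-1.5 years before entry")
##   NEAR = [t0 - 365 d, t0)           ("the past 1 year before entry")
## Any prescription in FAR makes the patient a prevalent user of that drug;
## otherwise any prescription in NEAR makes them an incident user; otherwise
## they are a nonuser. Prescriptions on/after t0 are ignored: exposure is
## defined wholly before the landmark, so no immortal time can accrue.

#' Exposure window definition
#'
#' @param lookback_far_days Days back from entry where the lookback starts
#'   (default 548, i.e. 1.5 years at 365 days/year, ceiling of 547.5).
#' @param lookback_near_days Days back from entry where the incident window
#'   starts (default 365).
#' @return A list of class `exposure_windows`.
#' @export
exposure_windows <- function(lookback_far_days = 548L,
                             lookback_near_days = 365L) {
  lookback_far_days <- as.integer(lookback_far_days)
  lookback_near_days <- as.integer(lookback_near_days)
  if (!(lookback_far_days > lookback_near_days && lookback_near_days > 0)) {
    stop("require lookback_far_days > lookback_near_days > 0", call. = FALSE)
  }
  structure(list(lookback_far_days = lookback_far_days,
                 lookback_near_days = lookback_near_days),
            class = "exposure_windows")
}

#' Truncate an ATC code to level 2 or level 4
#'
#' ATC level 2 is the 3-character therapeutic group (e.g. `"N07"`), level 4
#' the 5-character chemical subgroup (e.g. `"A02AA"`).
#'
#' @param code Character vector of ATC codes (full codes or prefixes).
#' @param level 2 or 4.
#' @return Character vector of truncated, uppercased codes.
#' @examples
#' truncate_atc("N07AA02", 2) # "N07"
#' truncate_atc("A02AA04", 4) # "A02AA"
#' @export
truncate_atc <- function(code, level) {
  if (!level %in% c(2L, 4L)) stop("ATC level must be 2 or 4", call. = FALSE)
  width <- if (level == 2L) 3L else 5L
  code <- toupper(code)
  bad <- !is_valid_atc(code) | nchar(code) < width
  if (any(bad)) {
    stop(sprintf("cannot truncate to ATC level %d: invalid or too-short code(s): %s",
                 level, paste(utils::head(unique(code[bad]), 5), collapse = ", ")),
         call. = FALSE)
  }
  substr(code, 1L, width)
}

#' Classify one patient-drug pair as incident user / prevalent user / nonuser
#'
#' @param dates `Date` vector of prescription dates for one patient and one
#'   (truncated) drug code. May be empty.
#' @param t0 Study entry date (`Date`).
#' @param windows An [exposure_windows()] object.
#' @return One of `"prevalent_user"`, `"incident_user"`, `"nonuser"`.
#'   Use in the far window takes precedence over use in the near window;
#'   prescriptions on or after `t0` are ignored.
#' @export
classify_exposure <- function(dates, t0, windows = exposure_windows()) {
  d <- as.integer(as.Date(t0) - as.Date(dates))
  # date in [t0-far, t0-near) <=> near < d <= far; in [t0-near, t0) <=> 0 < d <= near
  if (any(d > windows$lookback_near_days & d <= windows$lookback_far_days)) {
    "prevalent_user"
  } else if (any(d > 0L & d <= windows$lookback_near_days)) {
    "incident_user"
  } else {
    "nonuser"
  }
}

#' Build the patient x drug exposure matrix
#'
#' Drops prescriptions flagged anticancer (or matching
#' `anticancer_prefixes`), truncates the remaining codes to the requested
#' ATC level, pools each patient's prescription dates per truncated code,
#' and classifies every (cohort patient, drug) pair with
#' [classify_exposure()]. The drug list consists of the distinct truncated
#' codes with at least `min_users` incident users in the cohort.
#'
#' @param bundle A `claims_bundle`.
#' @param cohort Cohort data.frame with columns `patient_id` and
#'   `time_zero` (one row per patient; see [build_cohort()]).
#' @param level ATC level, 2 or 4.
#' @param windows An [exposure_windows()] object.
#' @param anticancer_prefixes Additional ATC prefixes to exclude beyond the
#'   bundle's `is_anticancer` flags.
#' @param min_users Minimum number of incident users for a drug to enter
#'   the matrix (default 1).
#' @return An `exposure_matrix`: a character matrix (patients x drugs,
#'   dimnames set) with entries in `nonuser`/`incident_user`/
#'   `prevalent_user`, plus attributes `atc_level` and `windows`.
#' @export
build_exposure_matrix <- function(bundle, cohort, level,
                                  windows = exposure_windows(),
                                  anticancer_prefixes = character(0),
                                  min_users = 1L) {
  if (!nrow(cohort)) stop("empty cohort", call. = FALSE)
  stopifnot(!anyDuplicated(cohort$patient_id))

  rx <- data.table::as.data.table(
    bundle$prescriptions[, c("patient_id", "date", "atc_code",
                             "is_anticancer")])
  rx <- rx[!rx$is_anticancer]
  if (length(anticancer_prefixes)) {
    rx <- rx[!has_atc_prefix(rx$atc_code, anticancer_prefixes)]
  }

  pid <- NULL; drug <- NULL; dback <- NULL; cls <- NULL # NSE bindings
  patients <- cohort$patient_id
  t0 <- as.Date(cohort$time_zero)

  if (nrow(rx)) {
    width <- if (level == 2L) 3L else 5L
    rx <- rx[nchar(rx$atc_code) >= width]
  }
  if (nrow(rx)) {
    rx[, drug := truncate_atc(atc_code, level)]
    cohort_dt <- data.table::data.table(patient_id = patients, t0 = t0,
                                        key = "patient_id")
    rx <- rx[cohort_dt, on = "patient_id", nomatch = NULL]
    rx[, dback := as.integer(t0 - date)]
    rx <- rx[dback > 0L & dback <= windows$lookback_far_days]
  }

  if (nrow(rx)) {
    pair <- rx[, list(
      cls = if (any(dback > windows$lookback_near_days)) "prevalent_user"
            else "incident_user"),
      by = c("patient_id", "drug")]
    inc_counts <- pair[pair$cls == "incident_user",
                       list(n_inc = .N), by = "drug"]
    keep <- sort(inc_counts$drug[inc_counts$n_inc >= min_users])
  } else {
    pair <- NULL
    keep <- character(0)
  }

  mat <- matrix("nonuser", nrow = length(patients), ncol = length(keep),
                dimnames = list(patients, keep))
  if (length(keep) && !is.null(pair)) {
    pair <- pair[pair$drug %in% keep]
    mat[cbind(match(pair$patient_id, patients), match(pair$drug, keep))] <-
      pair$cls
  }
  structure(mat, atc_level = as.integer(level), windows = windows,
            class = c("exposure_matrix", class(mat)))
}

#' @export
print.exposure_matrix <- function(x, ...) {
  tab <- table(factor(x, levels = exposure_class_levels()))
  cat(sprintf("exposure_matrix: %d patients x %d drugs (ATC level %d)\n",
              nrow(x), ncol(x), attr(x, "atc_level")))
  cat(sprintf("  incident pairs %d, prevalent pairs %d, nonuser pairs %d\n",
              tab[["incident_user"]], tab[["prevalent_user"]],
              tab[["nonuser"]]))
  invisible(x)
}
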