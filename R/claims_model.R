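## Closed enumerations shared across the pipeline ---------------------------

#' Enumerations used throughout the pipeline
#'
#' Closed category sets for patient sex, the six age bands, the six
#' treatment-based stage-proxy categories, the three Charlson Comorbidity
#' Index (CCI) bands, exposure classes and cohort split labels.
#'
#' @name enumerations
#' @keywords internal
NULL

#' @export
#' @rdname enumerations
sex_levels <- function() c("male", "female")

#' @export
#' @rdname enumerations
age_group_levels <- function() {
  c("15-39", "40-49", "50-59", "60-69", "70-79", ">79")
}

#' @export
#' @rdname enumerations
treatment_category_levels <- function() {
  c("colonoscopy_only", "operation_only", "operation_chemo",
    "operation_radio", "operation_both", "chemo_or_radio_without_operation")
}

#' @export
#' @rdname enumerations
cci_category_levels <- function() c("0", "1-2", "3+")

#' @export
#' @rdname enumerations
treatment_kind_levels <- function() {
  c("colonoscopy", "operation", "chemotherapy", "radiotherapy")
}

#' @export
#' @rdname enumerations
exposure_class_levels <- function() {
  c("nonuser", "incident_user", "prevalent_user")
}

#' @export
#' @rdname enumerations
death_cause_levels <- function() c("target_cancer", "other")

#' @export
#' @rdname enumerations
outcome_levels <- function() c("all_cause", "cancer_specific")

## ATC code syntax -----------------------------------------------------------

#' Check ATC code syntax
#'
#' A full ATC code is letter, two digits, letter, letter, two digits
#' (e.g. `"N07AA02"`). Shorter prefixes at the hierarchy's cut points
#' (1, 3, 4, 5 characters) are permitted on input.
#'
#' @param code Character vector of candidate codes.
#' @return Logical vector, `TRUE` where the code is a syntactically valid
#'   ATC code or prefix.
#' @examples
#' is_valid_atc(c("N07AA02", "A02AA", "N07", "x1", ""))
#' @export
is_valid_atc <- function(code) {
  !is.na(code) &
    grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", code)
}

## Bundle construction and validation ----------------------------------------

#' Construct a claims bundle
#'
#' Bundles the four linked claims tables (patients, diagnoses, treatments,
#' prescriptions) with the data coverage interval, and validates referential
#' integrity and field-level invariants.
#'
#' @param patients data.frame with columns `patient_id`, `sex`,
#'   `birth_year`, `death_date` (`Date`, `NA` if alive), `death_cause`
#'   (`"target_cancer"`/`"other"`, `NA` if alive).
#' @param diagnoses data.frame with columns `patient_id`, `date`, `code`.
#' @param treatments data.frame with columns `patient_id`, `date`, `kind`.
#' @param prescriptions data.frame with columns `patient_id`, `date`,
#'   `atc_code`, `is_anticancer`.
#' @param coverage_start,coverage_end `Date` bounds of data coverage; all
#'   event dates must fall inside them.
#' @return An object of class `claims_bundle`.
#' @export
claims_bundle <- function(patients, diagnoses, treatments, prescriptions,
                          coverage_start, coverage_end) {
  b <- structure(
    list(patients = as.data.frame(patients),
         diagnoses = as.data.frame(diagnoses),
         treatments = as.data.frame(treatments),
         prescriptions = as.data.frame(prescriptions),
         coverage_start = as.Date(coverage_start),
         coverage_end = as.Date(coverage_end)),
    class = "claims_bundle")
  validate_claims_bundle(b)
  b
}

#' @export
print.claims_bundle <- function(x, ...) {
  cat("claims_bundle:", nrow(x$patients), "patients,",
      nrow(x$diagnoses), "diagnoses,",
      nrow(x$treatments), "treatments,",
      nrow(x$prescriptions), "prescriptions\n")
  cat("coverage:", format(x$coverage_start), "to",
      format(x$coverage_end), "\n")
  invisible(x)
}

check_columns <- function(df, needed, table) {
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop(sprintf("schema error in '%s': missing column(s) %s",
                 table, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Validate a claims bundle
#'
#' Checks the invariants every downstream stage relies on: required columns,
#' referential integrity (no event row without its patient), valid category
#' values, ATC syntax, death cause present iff death date present, and all
#' event dates inside the coverage interval.
#'
#' @param bundle A `claims_bundle`.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_claims_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "claims_bundle"))
  p <- bundle$patients
  check_columns(p, c("patient_id", "sex", "birth_year",
                     "death_date", "death_cause"), "patients")
  check_columns(bundle$diagnoses, c("patient_id", "date", "code"),
                "diagnoses")
  check_columns(bundle$treatments, c("patient_id", "date", "kind"),
                "treatments")
  check_columns(bundle$prescriptions,
                c("patient_id", "date", "atc_code", "is_anticancer"),
                "prescriptions")

  if (anyDuplicated(p$patient_id)) {
    stop("duplicate patient_id in patients table", call. = FALSE)
  }
  if (any(!is.na(p$sex) & !p$sex %in% sex_levels())) {
    stop("invalid sex value in patients table", call. = FALSE)
  }
  has_date <- !is.na(p$death_date)
  has_cause <- !is.na(p$death_cause)
  if (any(has_date != has_cause)) {
    stop("death_cause must be present iff death_date is present",
         call. = FALSE)
  }
  if (!all(p$death_cause[has_cause] %in% death_cause_levels())) {
    stop("death_cause must be 'target_cancer' or 'other'", call. = FALSE)
  }
  if (any(p$death_date[has_date] < bundle$coverage_start) ||
      any(p$death_date[has_date] > bundle$coverage_end)) {
    stop("death_date outside the data coverage interval", call. = FALSE)
  }
  if (any(!bundle$treatments$kind %in% treatment_kind_levels())) {
    stop("treatment kind outside {colonoscopy, operation, chemotherapy, radiotherapy}",
         call. = FALSE)
  }
  bad_atc <- !is_valid_atc(toupper(bundle$prescriptions$atc_code))
  if (any(bad_atc)) {
    stop(sprintf("invalid ATC code(s): %s",
                 paste(utils::head(unique(
                   bundle$prescriptions$atc_code[bad_atc]), 5),
                   collapse = ", ")), call. = FALSE)
  }

  for (tab in c("diagnoses", "treatments", "prescriptions")) {
    df <- bundle[[tab]]
    orphans <- setdiff(df$patient_id, p$patient_id)
    if (length(orphans)) {
      stop(sprintf(
        "referential-integrity error: %s rows reference unknown patient_id(s): %s",
        tab, paste(utils::head(orphans, 10), collapse = ", ")),
        call. = FALSE)
    }
    if (nrow(df) && any(df$date < bundle$coverage_start |
                          df$date > bundle$coverage_end)) {
      stop(sprintf("%s has event dates outside the coverage interval", tab),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

## Readers / writers ---------------------------------------------------------

parse_dates <- function(x, table, allow_na = FALSE) {
  x <- as.character(x)
  blank <- is.na(x) | x == ""
  d <- as.Date(rep(NA_character_, length(x)))
  d[!blank] <- as.Date(x[!blank], format = "%Y-%m-%d")
  bad <- !blank & is.na(d)
  if (any(bad)) {
    stop(sprintf("unparseable date(s) in '%s' at row(s): %s", table,
                 paste(utils::head(which(bad), 10), collapse = ", ")),
         call. = FALSE)
  }
  if (!allow_na && any(blank)) {
    stop(sprintf("missing date(s) in '%s' at row(s): %s", table,
                 paste(utils::head(which(blank), 10), collapse = ", ")),
         call. = FALSE)
  }
  d
}

read_claims_table <- function(path) {
  utils::read.csv(path, colClasses = "character", na.strings = NULL,
                  check.names = FALSE)
}

#' Read a claims bundle from delimited tables
#'
#' Reads `patients.csv`, `diagnoses.csv`, `treatments.csv`,
#' `prescriptions.csv` and the `bundle_meta.json` sidecar from a directory
#' (or from explicitly named paths). Dates are ISO 8601; empty strings mark
#' absent death dates/causes. The anticancer flag on each prescription is
#' resolved at ingestion against the `anticancer_atc_prefixes` of the
#' sidecar. When no sidecar is present the coverage interval is the min/max
#' event date and the anticancer prefix list is empty.
#'
#' @param dir Directory holding the four tables and sidecar; alternatively
#'   supply the four file paths via `paths`.
#' @param paths Optional named list/vector with entries `patients`,
#'   `diagnoses`, `treatments`, `prescriptions`, and optionally `meta`.
#' @return A validated `claims_bundle`.
#' @seealso [write_claims_bundle()]
#' @export
read_claims_bundle <- function(dir = NULL, paths = NULL) {
  if (is.null(paths)) {
    stopifnot(!is.null(dir))
    paths <- list(patients = file.path(dir, "patients.csv"),
                  diagnoses = file.path(dir, "diagnoses.csv"),
                  treatments = file.path(dir, "treatments.csv"),
                  prescriptions = file.path(dir, "prescriptions.csv"),
                  meta = file.path(dir, "bundle_meta.json"))
  }
  for (nm in c("patients", "diagnoses", "treatments", "prescriptions")) {
    if (!file.exists(paths[[nm]])) {
      stop(sprintf("missing input file for table '%s': %s", nm, paths[[nm]]),
           call. = FALSE)
    }
  }

  pat <- read_claims_table(paths$patients)
  check_columns(pat, c("patient_id", "sex", "birth_year",
                       "death_date", "death_cause"), "patients")
  pat$birth_year <- as.integer(pat$birth_year)
  pat$death_date <- parse_dates(pat$death_date, "patients", allow_na = TRUE)
  pat$death_cause[pat$death_cause == ""] <- NA_character_

  dx <- read_claims_table(paths$diagnoses)
  check_columns(dx, c("patient_id", "date", "code"), "diagnoses")
  dx$date <- parse_dates(dx$date, "diagnoses")

  tr <- read_claims_table(paths$treatments)
  check_columns(tr, c("patient_id", "date", "kind"), "treatments")
  tr$date <- parse_dates(tr$date, "treatments")

  rx <- read_claims_table(paths$prescriptions)
  check_columns(rx, c("patient_id", "date", "atc_code"), "prescriptions")
  rx$date <- parse_dates(rx$date, "prescriptions")
  rx$atc_code <- toupper(rx$atc_code)

  meta_path <- paths$meta
  anticancer <- character(0)
  if (!is.null(meta_path) && file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    coverage_start <- as.Date(meta$coverage_start)
    coverage_end <- as.Date(meta$coverage_end)
    anticancer <- as.character(meta$anticancer_atc_prefixes %||% character(0))
  } else {
    all_dates <- c(dx$date, tr$date, rx$date,
                   pat$death_date[!is.na(pat$death_date)])
    if (!length(all_dates)) {
      stop("no sidecar metadata and no event dates to infer coverage from",
           call. = FALSE)
    }
    coverage_start <- min(all_dates)
    coverage_end <- max(all_dates)
  }
  rx$is_anticancer <- has_atc_prefix(rx$atc_code, anticancer)

  claims_bundle(pat, dx, tr, rx, coverage_start, coverage_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Match ATC codes against a set of prefixes
#' @param codes Character vector of ATC codes.
#' @param prefixes Character vector of ATC prefixes (may be empty).
#' @return Logical vector, `TRUE` where a code starts with any prefix.
#' @keywords internal
has_atc_prefix <- function(codes, prefixes) {
  out <- rep(FALSE, length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out
}

#' Write a claims bundle to delimited tables
#'
#' Inverse of [read_claims_bundle()]: writes the four tables plus the
#' `bundle_meta.json` sidecar so that reading the written directory
#' reproduces the bundle field-for-field.
#'
#' @param bundle A valid `claims_bundle`.
#' @param dir Output directory (created if needed).
#' @param anticancer_atc_prefixes Prefix list recorded in the sidecar; the
#'   reader uses it to re-derive `is_anticancer`. Defaults to the distinct
#'   full codes currently flagged, which round-trips any flag assignment.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_claims_bundle <- function(bundle, dir, anticancer_atc_prefixes = NULL) {
  validate_claims_bundle(bundle)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  }
  if (is.null(anticancer_atc_prefixes)) {
    anticancer_atc_prefixes <-
      sort(unique(bundle$prescriptions$atc_code[
        bundle$prescriptions$is_anticancer]))
  } else {
    derived <- has_atc_prefix(bundle$prescriptions$atc_code,
                              anticancer_atc_prefixes)
    if (!identical(derived, bundle$prescriptions$is_anticancer)) {
      stop("anticancer_atc_prefixes inconsistent with is_anticancer flags",
           call. = FALSE)
    }
  }

  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  pat <- bundle$patients
  pat_out <- data.frame(patient_id = pat$patient_id, sex = pat$sex,
                        birth_year = pat$birth_year,
                        death_date = fmt_date(pat$death_date),
                        death_cause = ifelse(is.na(pat$death_cause), "",
                                             pat$death_cause))
  dx <- bundle$diagnoses
  dx_out <- data.frame(patient_id = dx$patient_id,
                       date = fmt_date(dx$date), code = dx$code)
  tr <- bundle$treatments
  tr_out <- data.frame(patient_id = tr$patient_id,
                       date = fmt_date(tr$date), kind = tr$kind)
  rx <- bundle$prescriptions
  rx_out <- data.frame(patient_id = rx$patient_id,
                       date = fmt_date(rx$date), atc_code = rx$atc_code)

  paths <- c(patients = file.path(dir, "patients.csv"),
             diagnoses = file.path(dir, "diagnoses.csv"),
             treatments = file.path(dir, "treatments.csv"),
             prescriptions = file.path(dir, "prescriptions.csv"),
             meta = file.path(dir, "bundle_meta.json"))
  utils::write.csv(pat_out, paths["patients"], row.names = FALSE, quote = FALSE)
  utils::write.csv(dx_out, paths["diagnoses"], row.names = FALSE, quote = FALSE)
  utils::write.csv(tr_out, paths["treatments"], row.names = FALSE, quote = FALSE)
  utils::write.csv(rx_out, paths["prescriptions"], row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(
    list(coverage_start = format(bundle$coverage_start, "%Y-%m-%d"),
         coverage_end = format(bundle$coverage_end, "%Y-%m-%d"),
         anticancer_atc_prefixes = as.character(anticancer_atc_prefixes)),
    paths["meta"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
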