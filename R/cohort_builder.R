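## Cohort construction: treatment-evidenced cancer cases, washout, time zero
## at first treatment, treatment-category stage proxy, per-outcome survival.

#' Case definition
#'
#' A patient qualifies as a case iff they have at least one diagnosis whose
#' code starts with one of `diagnosis_prefixes` AND at least one treatment
#' record of a qualifying kind. Time zero is the earliest qualifying
#' treatment date.
#'
#' @param diagnosis_prefixes Diagnosis code prefixes (default the
#'   colorectal cancer family C18, C19, C20).
#' @param evidence_kinds Treatment kinds that qualify (default all four).
#' @return List of class `case_definition`.
#' @export
case_definition <- function(diagnosis_prefixes = c("C18", "C19", "C20"),
                            evidence_kinds = treatment_kind_levels()) {
  if (!length(diagnosis_prefixes) || !length(evidence_kinds)) {
    stop("case definition requires non-empty prefix and kind sets",
         call. = FALSE)
  }
  stopifnot(all(evidence_kinds %in% treatment_kind_levels()))
  structure(list(diagnosis_prefixes = diagnosis_prefixes,
                 evidence_kinds = evidence_kinds),
            class = "case_definition")
}

#' Washout policy
#'
#' Cases entering during the first `washout_years` calendar years of data
#' coverage are excluded, so only newly diagnosed (incident) cancer cases
#' remain.
#'
#' @param washout_years Non-negative integer (default 2).
#' @param data_start Start of data coverage (`Date`).
#' @return List of class `washout_policy`.
#' @export
washout_policy <- function(washout_years = 2L,
                           data_start = as.Date("2002-01-01")) {
  washout_years <- as.integer(washout_years)
  if (washout_years < 0) stop("washout_years must be >= 0", call. = FALSE)
  structure(list(washout_years = washout_years,
                 data_start = as.Date(data_start)),
            class = "washout_policy")
}

#' Identify treatment-evidenced cancer cases
#'
#' @param bundle A `claims_bundle`.
#' @param case_def A [case_definition()].
#' @return data.frame `patient_id`, `first_treatment_date`, sorted by
#'   `patient_id`. Patients lacking either a qualifying diagnosis or a
#'   qualifying treatment are absent.
#' @export
identify_cases <- function(bundle, case_def = case_definition()) {
  dx <- bundle$diagnoses
  has_dx <- unique(dx$patient_id[
    has_atc_prefix(toupper(dx$code), toupper(case_def$diagnosis_prefixes))])
  tr <- bundle$treatments
  tr <- tr[tr$kind %in% case_def$evidence_kinds & tr$patient_id %in% has_dx, ,
           drop = FALSE]
  if (!nrow(tr)) {
    return(data.frame(patient_id = character(0),
                      first_treatment_date = as.Date(character(0))))
  }
  first <- tapply(tr$date, tr$patient_id, min)
  out <- data.frame(patient_id = names(first),
                    first_treatment_date = as.Date(as.numeric(first),
                                                   origin = "1970-01-01"))
  out <- out[order(out$patient_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the washout period to identified cases
#'
#' Removes cases whose first treatment falls within the washout interval
#' `[data_start, data_start + washout_years)` (calendar years). Order is
#' preserved.
#'
#' @param cases Output of [identify_cases()].
#' @param policy A [washout_policy()].
#' @return The filtered case data.frame.
#' @export
apply_washout <- function(cases, policy = washout_policy()) {
  washout_end <- add_calendar_years(policy$data_start, policy$washout_years)
  drop <- cases$first_treatment_date >= policy$data_start &
    cases$first_treatment_date < washout_end
  out <- cases[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

add_calendar_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + as.integer(years)
  as.Date(lt)
}

#' Derive the treatment-category stage proxy
#'
#' Classifies a case into one of the six treatment categories used as a
#' proxy for cancer stage, from the set of treatment kinds recorded on or
#' after time zero (within an optional attribution window): surgery alone
#' marks early stage, chemo/radiotherapy without surgery marks advanced
#' stage, and colonoscopy only marks patients who received no cancer
#' treatment at all.
#'
#' @param bundle A `claims_bundle`.
#' @param patient_id One patient id.
#' @param t0 The patient's time zero (`Date`).
#' @param window_end Optional end of the attribution window (default: no
#'   bound, i.e. all records to end of coverage).
#' @return One of the six values of `treatment_category_levels()`.
#' @export
derive_treatment_category <- function(bundle, patient_id, t0,
                                      window_end = NULL) {
  tr <- bundle$treatments
  sel <- tr$patient_id == patient_id & tr$date >= as.Date(t0)
  if (!is.null(window_end)) sel <- sel & tr$date <= as.Date(window_end)
  kinds <- unique(tr$kind[sel])
  treatment_category_from_kinds(kinds)
}

#' Vectorised treatment-category derivation for a whole case list
#'
#' Same definition as [derive_treatment_category()], computed with one
#' grouped pass over the treatments table.
#'
#' @param bundle A `claims_bundle`.
#' @param patient_ids,t0 Parallel vectors of case ids and entry dates.
#' @inheritParams derive_treatment_category
#' @return Character vector of categories, parallel to `patient_ids`.
#' @export
derive_treatment_categories <- function(bundle, patient_ids, t0,
                                        window_end = NULL) {
  tr <- data.table::as.data.table(bundle$treatments)
  cases <- data.table::data.table(patient_id = patient_ids,
                                  t0 = as.Date(t0))
  tr <- tr[cases, on = "patient_id", nomatch = NULL]
  tr <- tr[tr$date >= tr$t0]
  if (!is.null(window_end)) tr <- tr[tr$date <= as.Date(window_end)]
  has <- function(k) {
    ids <- unique(tr$patient_id[tr$kind == k])
    patient_ids %in% ids
  }
  has_op <- has("operation"); has_ch <- has("chemotherapy")
  has_ra <- has("radiotherapy"); has_co <- has("colonoscopy")
  if (any(!(has_op | has_ch | has_ra | has_co))) {
    stop("case(s) without any treatment record on/after time zero",
         call. = FALSE)
  }
  ifelse(has_op,
         ifelse(has_ch & has_ra, "operation_both",
                ifelse(has_ch, "operation_chemo",
                       ifelse(has_ra, "operation_radio", "operation_only"))),
         ifelse(has_ch | has_ra, "chemo_or_radio_without_operation",
                "colonoscopy_only"))
}

#' Map a set of treatment kinds to the stage-proxy category
#' @param kinds Character vector drawn from `treatment_kind_levels()`.
#' @return One of `treatment_category_levels()`.
#' @export
treatment_category_from_kinds <- function(kinds) {
  if (!length(kinds)) {
    stop("no treatment records on/after time zero; not a valid case",
         call. = FALSE)
  }
  has_op <- "operation" %in% kinds
  has_chemo <- "chemotherapy" %in% kinds
  has_radio <- "radiotherapy" %in% kinds
  if (has_op) {
    if (has_chemo && has_radio) "operation_both"
    else if (has_chemo) "operation_chemo"
    else if (has_radio) "operation_radio"
    else "operation_only"
  } else if (has_chemo || has_radio) {
    "chemo_or_radio_without_operation"
  } else {
    "colonoscopy_only"
  }
}

#' Age band at study entry
#' @param birth_year Integer vector of birth years.
#' @param t0 `Date` vector of entry dates.
#' @return Character vector over `age_group_levels()`; `NA` (with a
#'   warning) for patients younger than 15 at entry.
#' @export
age_group_at <- function(birth_year, t0) {
  age <- as.integer(format(as.Date(t0), "%Y")) - as.integer(birth_year)
  out <- cut(age, breaks = c(15, 40, 50, 60, 70, 80, Inf),
             labels = age_group_levels(), right = FALSE)
  if (anyNA(out)) {
    warning(sprintf("%d patient(s) younger than 15 at entry; age_group NA",
                    sum(is.na(out))), call. = FALSE)
  }
  as.character(out)
}

#' Build one analysis-ready survival row
#'
#' Follow-up runs from time zero to death or the administrative end of
#' follow-up, whichever comes first. The all-cause event fires on any death
#' inside follow-up; the cancer-specific event additionally requires the
#' recorded cause to be the target cancer, so other-cause deaths censor the
#' cancer-specific outcome at the death date (cause-specific hazards).
#'
#' @param patient One row of the bundle's patients table.
#' @param t0 Entry date.
#' @param outcome_end_date Administrative end of follow-up (`Date`).
#' @return List with `followup_days`, `event_all_cause`,
#'   `event_cancer_specific`.
#' @export
build_survival_row <- function(patient, t0, outcome_end_date) {
  t0 <- as.Date(t0)
  end <- as.Date(outcome_end_date)
  death <- patient$death_date
  if (!is.na(death) && death < t0) {
    stop(sprintf("patient %s: death date precedes time zero",
                 patient$patient_id), call. = FALSE)
  }
  died <- !is.na(death) && death <= end
  stop_date <- if (died) death else end
  ev_all <- as.integer(died)
  ev_cancer <- as.integer(died && patient$death_cause == "target_cancer")
  list(followup_days = as.integer(stop_date - t0),
       event_all_cause = ev_all, event_cancer_specific = ev_cancer)
}

#' Build the analysis cohort from a claims bundle
#'
#' Runs case identification, washout, covariate derivation and survival-row
#' construction, producing one row per retained patient. The Charlson
#' comorbidity category is consumed precomputed via `cci` (the simulator
#' emits it; real-data users must supply their own mapping).
#'
#' @param bundle A `claims_bundle`.
#' @param cci data.frame `patient_id`, `cci_category` covering every case.
#' @param case_def A [case_definition()].
#' @param washout A [washout_policy()]; its `data_start` defaults to the
#'   bundle's coverage start.
#' @param outcome_end_date Administrative end of follow-up (default: the
#'   bundle's coverage end).
#' @param category_window_end Optional attribution bound passed to
#'   [derive_treatment_category()].
#' @return data.frame of cohort rows: `patient_id`, `time_zero`,
#'   `followup_days`, `event_all_cause`, `event_cancer_specific`, `sex`,
#'   `age_group`, `treatment_category`, `cci_category`, `split`
#'   (initialised to `"unassigned"`). Patients younger than 15 at entry are
#'   dropped with a warning.
#' @export
build_cohort <- function(bundle, cci,
                         case_def = case_definition(),
                         washout = NULL,
                         outcome_end_date = NULL,
                         category_window_end = NULL) {
  if (is.null(washout)) {
    washout <- washout_policy(data_start = bundle$coverage_start)
  }
  if (is.null(outcome_end_date)) outcome_end_date <- bundle$coverage_end
  cases <- apply_washout(identify_cases(bundle, case_def), washout)
  if (!nrow(cases)) {
    stop("no cases retained after washout", call. = FALSE)
  }
  pats <- bundle$patients[match(cases$patient_id,
                                bundle$patients$patient_id), , drop = FALSE]
  t0 <- cases$first_treatment_date

  if (anyNA(match(cases$patient_id, cci$patient_id))) {
    stop("cci table does not cover every case", call. = FALSE)
  }
  cci_cat <- cci$cci_category[match(cases$patient_id, cci$patient_id)]
  stopifnot(all(cci_cat %in% cci_category_levels()))

  age_group <- age_group_at(pats$birth_year, t0)

  ## vectorized survival rows (same definition as build_survival_row)
  end <- as.Date(outcome_end_date)
  death <- pats$death_date
  if (any(!is.na(death) & death < t0)) {
    stop("death date precedes time zero for some case(s)", call. = FALSE)
  }
  died <- !is.na(death) & death <= end
  stop_date <- as.Date(ifelse(died, death, end), origin = "1970-01-01")
  followup_days <- as.integer(stop_date - t0)

  trt <- derive_treatment_categories(bundle, cases$patient_id, t0,
                                     category_window_end)

  out <- data.frame(
    patient_id = cases$patient_id,
    time_zero = t0,
    followup_days = followup_days,
    event_all_cause = as.integer(died),
    event_cancer_specific = as.integer(died &
      !is.na(pats$death_cause) & pats$death_cause == "target_cancer"),
    sex = pats$sex,
    age_group = age_group,
    treatment_category = trt,
    cci_category = cci_cat,
    split = "unassigned")
  keep <- !is.na(out$age_group)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$event_cancer_specific <= out$event_all_cause),
            all(out$followup_days >= 0))
  out
}

#' Write a cohort table
#' @param cohort Cohort data.frame from [build_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort
  out$time_zero <- format(out$time_zero, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table written by [write_cohort()]
#' @param path CSV path.
#' @return Cohort data.frame with parsed dates.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, colClasses = "character")
  x$time_zero <- as.Date(x$time_zero)
  for (col in c("followup_days", "event_all_cause", "event_cancer_specific")) {
    x[[col]] <- as.integer(x[[col]])
  }
  x
}
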