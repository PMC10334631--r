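## Synthetic claims generator.
##
## Emits a claims_bundle with known ground truth: covariates drawn from the
## configured categorical distributions, per-drug usage patterns spanning the
## incident / prevalent / nonuser taxonomy, and cause-specific death times
## from Weibull proportional-hazards models with planted drug effects, so
## every downstream stage (cohort build, exposure classification, screen)
## can be checked against truth.

#' Specify one synthetic drug
#'
#' @param atc_code Full ATC code (7 characters).
#' @param p_incident Probability that a patient is an incident user.
#' @param p_prevalent Probability that a patient is a prevalent user.
#' @param log_hr_all_cause Planted log hazard ratio on the other-cause
#'   death hazard for incident users.
#' @param log_hr_cancer_specific Planted log hazard ratio on the cancer
#'   death hazard for incident users. When the two log-HRs are equal the
#'   all-cause hazard ratio equals them exactly.
#' @param rx_rate Mean prescriptions per exposed patient-year (> 0).
#' @return One-row data.frame.
#' @export
drug_spec <- function(atc_code, p_incident, p_prevalent = 0,
                      log_hr_all_cause = 0, log_hr_cancer_specific = 0,
                      rx_rate = 2) {
  stopifnot(is_valid_atc(toupper(atc_code)), nchar(atc_code) == 7,
            p_incident >= 0, p_prevalent >= 0,
            p_incident + p_prevalent <= 1, rx_rate > 0)
  data.frame(atc_code = toupper(atc_code), p_incident = p_incident,
             p_prevalent = p_prevalent,
             log_hr_all_cause = log_hr_all_cause,
             log_hr_cancer_specific = log_hr_cancer_specific,
             rx_rate = rx_rate)
}

#' Generate syntactically valid full ATC codes, distinct at level 4
#'
#' @param n Number of codes.
#' @return Character vector of 7-character codes whose 5-character prefixes
#'   are pairwise distinct and avoid the `L` (antineoplastics) group.
#' @export
synth_atc_codes <- function(n) {
  l1 <- setdiff(LETTERS[1:20], "L")
  # level-2 prefix (letter + digits) varies fastest, so small panels spread
  # across therapeutic groups instead of pooling into one level-2 code
  grid <- expand.grid(l1 = l1, d = sprintf("%02d", 1:20),
                      l3 = LETTERS[1:8], l4 = LETTERS[1:8],
                      stringsAsFactors = FALSE)
  if (n > nrow(grid)) stop("too many codes requested", call. = FALSE)
  if (n == 0) return(character(0))
  paste0(grid$l1[seq_len(n)], grid$d[seq_len(n)], grid$l3[seq_len(n)],
         grid$l4[seq_len(n)], "01")
}

#' A panel of identical-margin drugs (null by default)
#'
#' Convenience builder for screen simulations: `n_drugs` drugs with common
#' exposure probabilities and (by default zero) planted effects.
#'
#' @inheritParams drug_spec
#' @param n_drugs Number of drugs.
#' @return data.frame of stacked [drug_spec()] rows.
#' @export
drug_panel <- function(n_drugs, p_incident = 0.10, p_prevalent = 0.05,
                       log_hr_all_cause = 0, log_hr_cancer_specific = 0,
                       rx_rate = 2) {
  codes <- synth_atc_codes(n_drugs)
  if (!length(codes)) {
    return(data.frame(atc_code = character(0), p_incident = numeric(0),
                      p_prevalent = numeric(0),
                      log_hr_all_cause = numeric(0),
                      log_hr_cancer_specific = numeric(0),
                      rx_rate = numeric(0)))
  }
  do.call(rbind, lapply(codes, drug_spec, p_incident = p_incident,
                        p_prevalent = p_prevalent,
                        log_hr_all_cause = log_hr_all_cause,
                        log_hr_cancer_specific = log_hr_cancer_specific,
                        rx_rate = rx_rate))
}

#' Simulation configuration
#'
#' Assembles and validates every knob of the generator. Defaults follow the
#' marginal covariate distributions observed in the motivating national
#' claims cohort of colorectal cancer patients (about two thirds male,
#' age concentrated in the 60s, roughly 60% with a Charlson index of 3+),
#' with baseline Weibull hazards calibrated so mean follow-up is about
#' 54 months under administrative censoring at the end of 2015.
#'
#' @param n_patients Number of patients.
#' @param drugs data.frame of [drug_spec()] rows (may have zero rows).
#' @param seed Integer seed; the generator is deterministic given it.
#' @param coverage_start,coverage_end Data coverage interval.
#' @param entry_date_range Length-2 `Date` vector of possible study entry
#'   dates; must leave room for the washout and the 1.5-year lookback.
#' @param p_male Probability of male sex.
#' @param age_group_probs,treatment_category_probs,cci_probs Probability
#'   vectors over the 6 age bands, 6 treatment categories and 3 CCI bands.
#' @param covariate_log_hrs Named list of named numeric vectors (`sex`,
#'   `age_group`, `treatment_category`, `cci_category`) of log hazard
#'   ratios per level, applied to both cause-specific hazards.
#' @param baseline_hazard_cancer,baseline_hazard_other Length-2 numeric
#'   `c(shape, scale_days)` of the cause-specific Weibull baselines.
#' @param prevalent_continue If `TRUE` (default) half of the prevalent
#'   users also receive prescriptions inside the incident window, to
#'   exercise the classifier's far-window precedence rule.
#' @param p_post_entry Probability a patient receives a post-entry
#'   prescription (ignored by the exposure definition).
#' @param p_anticancer Probability a patient receives an anticancer
#'   prescription (excluded by the exposure builder).
#' @param anticancer_atc_prefixes ATC prefixes flagged anticancer.
#' @param anticancer_code Full code used for simulated anticancer scripts.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients,
                              drugs = drug_panel(0L),
                              seed = 1L,
                              coverage_start = as.Date("2002-01-01"),
                              coverage_end = as.Date("2015-12-31"),
                              entry_date_range = as.Date(c("2004-01-01",
                                                           "2015-12-31")),
                              p_male = 0.66,
                              age_group_probs =
                                c(48, 138, 299, 392, 345, 87) / 1309,
                              treatment_category_probs =
                                c(147, 254, 21, 343, 259, 285) / 1309,
                              cci_probs = c(100, 408, 801) / 1309,
                              covariate_log_hrs = default_covariate_log_hrs(),
                              baseline_hazard_cancer = c(shape = 0.9,
                                                         scale = 30000),
                              baseline_hazard_other = c(shape = 1.0,
                                                        scale = 70000),
                              prevalent_continue = TRUE,
                              p_post_entry = 0.10,
                              p_anticancer = 0.10,
                              anticancer_atc_prefixes = "L01",
                              anticancer_code = "L01XA01") {
  cfg <- structure(as.list(environment()), class = "simulation_config")
  validate_simulation_config(cfg)
  cfg
}

#' Default covariate log hazard ratios of the generator
#'
#' Modest, monotone-in-age effects applied to both cause-specific hazards;
#' reference levels (male, 15-39, operation only, CCI 0) carry 0.
#' Patients treated without operation or by colonoscopy only (the proxy for
#' advanced/terminal stage) carry the largest effects.
#' @return Named list of named numeric vectors.
#' @export
default_covariate_log_hrs <- function() {
  list(
    sex = c(male = 0, female = -0.10),
    age_group = stats::setNames(c(0, 0.10, 0.25, 0.45, 0.70, 1.00),
                                age_group_levels()),
    treatment_category = stats::setNames(c(0.90, 0, 0.30, 0.40, 0.50, 1.10),
                                         treatment_category_levels()),
    cci_category = stats::setNames(c(0, 0.15, 0.40), cci_category_levels())
  )
}

validate_probs <- function(p, n, what) {
  if (length(p) != n || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop(sprintf("%s must be a length-%d probability vector summing to 1",
                 what, n), call. = FALSE)
  }
}

#' Validate a simulation configuration
#' @param cfg A `simulation_config`.
#' @return Invisibly `TRUE`; stops on violation before any sampling.
#' @export
validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (cfg$n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  validate_probs(c(cfg$p_male, 1 - cfg$p_male), 2, "p_male")
  validate_probs(cfg$age_group_probs, 6, "age_group_probs")
  validate_probs(cfg$treatment_category_probs, 6, "treatment_category_probs")
  validate_probs(cfg$cci_probs, 3, "cci_probs")
  for (h in list(cfg$baseline_hazard_cancer, cfg$baseline_hazard_other)) {
    if (length(h) != 2 || any(h <= 0)) {
      stop("baseline hazards must be positive c(shape, scale)", call. = FALSE)
    }
  }
  d <- cfg$drugs
  if (nrow(d)) {
    stopifnot(all(is_valid_atc(d$atc_code)), all(nchar(d$atc_code) == 7),
              all(d$p_incident >= 0), all(d$p_prevalent >= 0),
              all(d$p_incident + d$p_prevalent <= 1), all(d$rx_rate > 0))
    if (anyDuplicated(d$atc_code)) {
      stop("duplicate atc_code in drugs", call. = FALSE)
    }
    if (any(has_atc_prefix(d$atc_code, cfg$anticancer_atc_prefixes))) {
      stop("drug panel overlaps the anticancer exclusion prefixes",
           call. = FALSE)
    }
  }
  if (cfg$entry_date_range[1] > cfg$entry_date_range[2]) {
    stop("entry_date_range reversed", call. = FALSE)
  }
  if (cfg$entry_date_range[1] - 548 < cfg$coverage_start ||
      cfg$entry_date_range[2] > cfg$coverage_end) {
    stop("entry_date_range must lie inside coverage with room for the 1.5-year lookback",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Draw Weibull survival times under a proportional-hazards multiplier
#'
#' Inverse-transform sampling from \eqn{S(t) = \exp(-m (t/\lambda)^k)}:
#' doubling the multiplier scales the median by \eqn{2^{-1/k}}.
#'
#' @param n Number of draws.
#' @param shape Weibull shape `k` (> 0).
#' @param scale Weibull scale `lambda` in days (> 0).
#' @param multiplier Positive hazard multiplier(s) `m` (length 1 or `n`).
#' @return Numeric vector of positive times in days.
#' @export
sample_survival_time <- function(n, shape, scale, multiplier = 1) {
  if (any(multiplier <= 0)) stop("multiplier must be > 0", call. = FALSE)
  if (shape <= 0 || scale <= 0) stop("shape and scale must be > 0",
                                     call. = FALSE)
  scale * (-log(stats::runif(n)) / multiplier)^(1 / shape)
}

## the generator -------------------------------------------------------------

category_kind_sets <- function(categories, rng_pick) {
  # rng_pick in [0,1): used only for chemo_or_radio_without_operation
  lapply(seq_along(categories), function(i) {
    switch(categories[i],
      colonoscopy_only = "colonoscopy",
      operation_only = "operation",
      operation_chemo = c("operation", "chemotherapy"),
      operation_radio = c("operation", "radiotherapy"),
      operation_both = c("operation", "chemotherapy", "radiotherapy"),
      chemo_or_radio_without_operation =
        if (rng_pick[i] < 0.4) "chemotherapy"
        else if (rng_pick[i] < 0.8) "radiotherapy"
        else c("chemotherapy", "radiotherapy"))
  })
}

age_band_bounds <- function() {
  list("15-39" = c(15, 39), "40-49" = c(40, 49), "50-59" = c(50, 59),
       "60-69" = c(60, 69), "70-79" = c(70, 79), ">79" = c(80, 94))
}

#' Simulate a claims bundle with known ground truth
#'
#' Deterministic given `config$seed`. For each patient, draws covariates
#' from the configured categorical distributions and an entry date `t0`;
#' emits one colorectal-cancer diagnosis (C18/C19/C20 family) at or shortly
#' before `t0` and treatment records realizing the drawn category with the
#' first treatment on `t0`; assigns each drug an exposure class and places
#' prescriptions accordingly (incident: only inside `[t0-365, t0)`;
#' prevalent: at least one in `[t0-548, t0-365)`; nonuser: none in the
#' lookback); draws two latent cause-specific Weibull death times scaled by
#' `exp(covariate log-HRs + planted drug log-HRs over incident exposures)`,
#' takes the earlier as death, and censors administratively at
#' `coverage_end`. Noise prescriptions after entry and anticancer scripts
#' are added to exercise the exposure filters; neither affects ground truth.
#'
#' @param config A [simulation_config()].
#' @return List of class `simulated_claims` with elements
#'   \describe{
#'     \item{bundle}{the `claims_bundle`}
#'     \item{covariates}{per-patient data.frame: `patient_id`, `sex`,
#'       `birth_year`, `age_group`, `treatment_category`, `cci_category`,
#'       `time_zero`}
#'     \item{ground_truth}{list: `exposure_class` (patient x drug character
#'       matrix, columns named by full ATC code), `survival` (per-patient
#'       true latent time/cause and observed follow-up/events), `drugs`
#'       (the spec table with planted log-HRs)}
#'   }
#' @export
simulate_bundle <- function(config) {
  validate_simulation_config(config)
  with_seed(config$seed, simulate_bundle_impl(config))
}

simulate_bundle_impl <- function(cfg) {
  n <- cfg$n_patients
  pid <- sprintf("P%06d", seq_len(n))

  sex <- ifelse(stats::runif(n) < cfg$p_male, "male", "female")
  age_group <- sample(age_group_levels(), n, TRUE, cfg$age_group_probs)
  trt_cat <- sample(treatment_category_levels(), n, TRUE,
                    cfg$treatment_category_probs)
  cci <- sample(cci_category_levels(), n, TRUE, cfg$cci_probs)

  entry_span <- as.integer(cfg$entry_date_range[2] - cfg$entry_date_range[1])
  t0 <- cfg$entry_date_range[1] +
    sample.int(entry_span + 1L, n, replace = TRUE) - 1L

  bounds <- age_band_bounds()
  lo <- vapply(bounds, `[`, numeric(1), 1)[age_group]
  hi <- vapply(bounds, `[`, numeric(1), 2)[age_group]
  age <- lo + floor(stats::runif(n) * (hi - lo + 1))
  birth_year <- as.integer(format(t0, "%Y")) - as.integer(age)

  ## diagnoses: one CRC code at or before t0
  dx_codes <- sample(c("C18", "C180", "C182", "C187", "C189",
                       "C19", "C20", "C20", "C209"), n, TRUE)
  dx_date <- t0 - sample.int(31L, n, replace = TRUE) + 1L  # 0..30 days before

  ## drug exposure classes and prescriptions
  drugs <- cfg$drugs
  n_drugs <- nrow(drugs)
  class_mat <- matrix("nonuser", nrow = n, ncol = n_drugs,
                      dimnames = list(pid, drugs$atc_code))
  acc <- list(); acc_n <- 0L
  push <- function(who, offsets, code) {
    acc_n <<- acc_n + 1L
    acc[[acc_n]] <<- list(who = who, off = offsets, code = code)
  }
  for (j in seq_len(n_drugs)) {
    u <- stats::runif(n)
    inc <- u < drugs$p_incident[j]
    prev <- !inc & u < drugs$p_incident[j] + drugs$p_prevalent[j]
    class_mat[inc, j] <- "incident_user"
    class_mat[prev, j] <- "prevalent_user"

    if (any(inc)) {
      k <- pmax(1L, stats::rpois(sum(inc), drugs$rx_rate[j]))
      push(rep(which(inc), k),
           sample.int(365L, sum(k), replace = TRUE),  # 1..365 days back
           drugs$atc_code[j])
    }
    if (any(prev)) {
      k <- pmax(1L, stats::rpois(sum(prev), drugs$rx_rate[j] * 0.5))
      push(rep(which(prev), k),
           365L + sample.int(183L, sum(k), replace = TRUE),  # 366..548 back
           drugs$atc_code[j])
      if (isTRUE(cfg$prevalent_continue)) {
        cont <- which(prev)[stats::runif(sum(prev)) < 0.5]
        if (length(cont)) {
          k2 <- pmax(1L, stats::rpois(length(cont), drugs$rx_rate[j]))
          push(rep(cont, k2), sample.int(365L, sum(k2), replace = TRUE),
               drugs$atc_code[j])
        }
      }
    }
  }
  rx_who <- unlist(lapply(acc, `[[`, "who"), use.names = FALSE)
  rx_off <- unlist(lapply(acc, `[[`, "off"), use.names = FALSE)
  rx_code <- unlist(lapply(acc, function(a) rep(a$code, length(a$who))),
                    use.names = FALSE)
  if (is.null(rx_who)) {
    rx_who <- integer(0); rx_off <- integer(0); rx_code <- character(0)
  }
  rx_pid <- pid[rx_who]
  rx_date <- t0[rx_who] - rx_off

  ## cause-specific survival with planted effects
  lhr <- cfg$covariate_log_hrs
  lp_cov <- lhr$sex[sex] + lhr$age_group[age_group] +
    lhr$treatment_category[trt_cat] + lhr$cci_category[cci]
  inc_mat <- class_mat == "incident_user"
  lp_cancer <- lp_cov
  lp_other <- lp_cov
  if (n_drugs) {
    lp_cancer <- lp_cancer +
      as.vector(inc_mat %*% drugs$log_hr_cancer_specific)
    lp_other <- lp_other + as.vector(inc_mat %*% drugs$log_hr_all_cause)
  }
  t_cancer <- sample_survival_time(n, cfg$baseline_hazard_cancer[1],
                                   cfg$baseline_hazard_cancer[2],
                                   exp(lp_cancer))
  t_other <- sample_survival_time(n, cfg$baseline_hazard_other[1],
                                  cfg$baseline_hazard_other[2],
                                  exp(lp_other))
  true_time <- pmin(t_cancer, t_other)
  true_cause <- ifelse(t_cancer <= t_other, "target_cancer", "other")
  death_days <- 1L + as.integer(floor(true_time))  # death strictly after t0
  death_date <- t0 + death_days
  censor_days <- as.integer(cfg$coverage_end - t0)
  died <- death_days <= censor_days
  followup_days <- ifelse(died, death_days, censor_days)
  death_date[!died] <- NA
  death_cause <- ifelse(died, true_cause, NA_character_)

  ## treatment records realizing the category; first treatment on t0
  pick <- stats::runif(n)
  kind_sets <- category_kind_sets(trt_cat, pick)
  add_scope <- stats::runif(n) < 0.3  # incidental colonoscopy post-entry
  n_kind <- lengths(kind_sets) + (add_scope & trt_cat != "colonoscopy_only")
  tr_pid <- rep(pid, n_kind)
  tr_kind <- unlist(lapply(seq_len(n), function(i) {
    ks <- kind_sets[[i]]
    anchor <- if ("operation" %in% ks) "operation" else ks[1]
    rest <- setdiff(ks, anchor)
    if (add_scope[i] && trt_cat[i] != "colonoscopy_only") {
      rest <- c(rest, "colonoscopy")
    }
    c(anchor, rest)
  }), use.names = FALSE)
  is_anchor <- unlist(lapply(n_kind, function(k) c(TRUE, rep(FALSE, k - 1L))),
                      use.names = FALSE)
  off_max <- pmin(60L, rep(followup_days, n_kind))
  offs <- as.integer(floor(stats::runif(length(tr_pid)) * (off_max + 1L)))
  offs[is_anchor] <- 0L
  tr_date <- rep(t0, n_kind) + offs

  ## post-entry and anticancer noise prescriptions
  if (n_drugs && cfg$p_post_entry > 0) {
    noisy <- which(stats::runif(n) < cfg$p_post_entry)
    if (length(noisy)) {
      jd <- sample.int(n_drugs, length(noisy), replace = TRUE)
      dts <- pmin(t0[noisy] + sample.int(181L, length(noisy),
                                         replace = TRUE) - 1L,
                  cfg$coverage_end)
      rx_pid <- c(rx_pid, pid[noisy]); rx_date <- c(rx_date, dts)
      rx_code <- c(rx_code, drugs$atc_code[jd])
    }
  }
  if (cfg$p_anticancer > 0) {
    acz <- which(stats::runif(n) < cfg$p_anticancer)
    if (length(acz)) {
      dts <- pmax(t0[acz] - sample.int(549L, length(acz), replace = TRUE) + 1L,
                  cfg$coverage_start)
      rx_pid <- c(rx_pid, pid[acz]); rx_date <- c(rx_date, dts)
      rx_code <- c(rx_code, rep(cfg$anticancer_code, length(acz)))
    }
  }

  patients <- data.frame(patient_id = pid, sex = sex,
                         birth_year = birth_year, death_date = death_date,
                         death_cause = death_cause)
  diagnoses <- data.frame(patient_id = pid, date = dx_date, code = dx_codes)
  treatments <- data.frame(patient_id = tr_pid, date = tr_date,
                           kind = tr_kind)
  prescriptions <- data.frame(
    patient_id = rx_pid, date = rx_date, atc_code = rx_code,
    is_anticancer = has_atc_prefix(rx_code, cfg$anticancer_atc_prefixes))

  bundle <- claims_bundle(patients, diagnoses, treatments, prescriptions,
                          cfg$coverage_start, cfg$coverage_end)
  covariates <- data.frame(patient_id = pid, sex = sex,
                           birth_year = birth_year, age_group = age_group,
                           treatment_category = trt_cat,
                           cci_category = cci, time_zero = t0)
  survival_truth <- data.frame(
    patient_id = pid, time_zero = t0, true_time_days = true_time,
    true_cause = true_cause, followup_days = followup_days,
    event_all_cause = as.integer(died),
    event_cancer_specific = as.integer(died & true_cause == "target_cancer"))
  structure(list(bundle = bundle, covariates = covariates,
                 ground_truth = list(exposure_class = class_mat,
                                     survival = survival_truth,
                                     drugs = drugs)),
            class = "simulated_claims")
}

#' Write simulator ground truth as delimited tables
#'
#' Emits `ground_truth.csv` (`patient_id, drug, class`, one row per
#' patient-drug pair) and `drug_truth.csv` (`atc_code, log_hr_all,
#' log_hr_cancer`).
#'
#' @param sim A `simulated_claims` object.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_ground_truth <- function(sim, dir) {
  stopifnot(inherits(sim, "simulated_claims"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- sim$ground_truth$exposure_class
  gt <- data.frame(patient_id = rep(rownames(cm), ncol(cm)),
                   drug = rep(colnames(cm), each = nrow(cm)),
                   class = as.vector(cm))
  p1 <- file.path(dir, "ground_truth.csv")
  p2 <- file.path(dir, "drug_truth.csv")
  utils::write.csv(gt, p1, row.names = FALSE, quote = FALSE)
  dt <- sim$ground_truth$drugs
  utils::write.csv(
    data.frame(atc_code = dt$atc_code, log_hr_all = dt$log_hr_all_cause,
               log_hr_cancer = dt$log_hr_cancer_specific),
    p2, row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}

## Scenario files ------------------------------------------------------------

#' Write a simulation scenario file
#'
#' Serialises a [simulation_config()] to YAML so a scenario can be shipped,
#' versioned and re-run. Dates become ISO strings; the drug table a list of
#' records.
#'
#' @param config A `simulation_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_scenario_config <- function(config, path) {
  validate_simulation_config(config)
  x <- unclass(config)
  for (f in c("coverage_start", "coverage_end")) x[[f]] <- format(x[[f]])
  x$entry_date_range <- format(x$entry_date_range)
  x$drugs <- if (nrow(config$drugs)) {
    lapply(seq_len(nrow(config$drugs)),
           function(i) as.list(config$drugs[i, ]))
  } else list()
  x$covariate_log_hrs <- lapply(x$covariate_log_hrs, as.list)
  x$baseline_hazard_cancer <- as.list(stats::setNames(
    as.numeric(x$baseline_hazard_cancer), c("shape", "scale")))
  x$baseline_hazard_other <- as.list(stats::setNames(
    as.numeric(x$baseline_hazard_other), c("shape", "scale")))
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' Read a simulation scenario file written by [write_scenario_config()]
#' @param path YAML scenario path.
#' @return A validated `simulation_config`.
#' @export
read_scenario_config <- function(path) {
  x <- yaml::read_yaml(path)
  drugs <- if (length(x$drugs)) {
    do.call(rbind, lapply(x$drugs, function(d) {
      drug_spec(d$atc_code, d$p_incident, d$p_prevalent,
                d$log_hr_all_cause, d$log_hr_cancer_specific, d$rx_rate)
    }))
  } else drug_panel(0L)
  simulation_config(
    n_patients = x$n_patients, drugs = drugs, seed = x$seed,
    coverage_start = as.Date(x$coverage_start),
    coverage_end = as.Date(x$coverage_end),
    entry_date_range = as.Date(unlist(x$entry_date_range)),
    p_male = x$p_male,
    age_group_probs = as.numeric(unlist(x$age_group_probs)),
    treatment_category_probs = as.numeric(unlist(x$treatment_category_probs)),
    cci_probs = as.numeric(unlist(x$cci_probs)),
    covariate_log_hrs = lapply(x$covariate_log_hrs,
                               function(v) unlist(v)),
    baseline_hazard_cancer = c(shape = x$baseline_hazard_cancer$shape,
                               scale = x$baseline_hazard_cancer$scale),
    baseline_hazard_other = c(shape = x$baseline_hazard_other$shape,
                              scale = x$baseline_hazard_other$scale),
    prevalent_continue = x$prevalent_continue,
    p_post_entry = x$p_post_entry, p_anticancer = x$p_anticancer,
    anticancer_atc_prefixes = unlist(x$anticancer_atc_prefixes),
    anticancer_code = x$anticancer_code)
}

#' The shipped demo scenario
#'
#' The default cohort-scale scenario: 2,618 patients (matching the size of
#' the motivating cohort before the 1:1 split), a 60-drug panel at
#' realistic exposure margins with four planted signals (two protective,
#' two detrimental at hazard ratio 2 or 1/2) among 56 nulls.
#'
#' @param seed Integer seed.
#' @return A `simulation_config`.
#' @export
demo_scenario <- function(seed = 20150101) {
  panel <- drug_panel(60, p_incident = 0.10, p_prevalent = 0.05,
                      rx_rate = 2)
  planted <- c(1, 2, 3, 4)
  effects <- log(c(0.5, 0.5, 2, 2))
  panel$log_hr_all_cause[planted] <- effects
  panel$log_hr_cancer_specific[planted] <- effects
  simulation_config(n_patients = 2618, drugs = panel, seed = seed,
                    baseline_hazard_cancer = c(shape = 0.9, scale = 10400),
                    baseline_hazard_other = c(shape = 1.0, scale = 36000))
}
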