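# Independent oracles used against the package's implementations.

# Brute-force window scan: checks each prescription date against the two
# exposure windows by explicit day-interval membership, then applies the
# far-window precedence rule.
oracle_classify_exposure <- function(dates, t0, far = 548L, near = 365L) {
  t0 <- as.Date(t0)
  in_far <- FALSE
  in_near <- FALSE
  for (d in as.list(as.Date(dates))) {
    if (d >= t0 - far && d < t0 - near) in_far <- TRUE
    if (d >= t0 - near && d < t0) in_near <- TRUE
  }
  if (in_far) "prevalent_user" else if (in_near) "incident_user" else "nonuser"
}

# Exhaustive step-up oracle: evaluates the rejection set for every candidate
# threshold k and computes adjusted values straight from the definition
# min(1, min_{j >= i} m * p_(j) / j), without any vectorised shortcut.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  reject_sorted <- seq_len(m) <= k
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * ps[j] / j, numeric(1))
    adj_sorted[i] <- min(1, min(vals))
  }
  reject <- logical(m)
  adj <- numeric(m)
  reject[o] <- reject_sorted
  adj[o] <- adj_sorted
  list(p_adjusted = adj, reject = reject)
}

# Scenario used by the screen-level simulation checks: hazards set so that
# roughly 60% of patients die inside follow-up, giving the event counts the
# per-drug Cox fits need.
screen_sim_config <- function(n_patients, drugs, seed, ...) {
  simulation_config(
    n_patients = n_patients, drugs = drugs, seed = seed,
    baseline_hazard_cancer = c(shape = 0.9, scale = 10400),
    baseline_hazard_other = c(shape = 1.0, scale = 36000), ...)
}

# Small fully deterministic bundle for claims-model tests.
tiny_bundle <- function() {
  patients <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    sex = c("male", "female", "male"),
    birth_year = c(1950L, 1940L, 1960L),
    death_date = as.Date(c("2010-06-01", NA, NA)),
    death_cause = c("target_cancer", NA, NA))
  diagnoses <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    date = as.Date(c("2005-03-01", "2006-01-10", "2007-07-07")),
    code = c("C189", "C20", "C50"))
  treatments <- data.frame(
    patient_id = c("P1", "P1", "P2"),
    date = as.Date(c("2005-03-15", "2005-04-01", "2006-02-01")),
    kind = c("operation", "chemotherapy", "colonoscopy"))
  prescriptions <- data.frame(
    patient_id = c("P1", "P2"),
    date = as.Date(c("2004-09-01", "2005-06-15")),
    atc_code = c("N07AA02", "B01AC06"),
    is_anticancer = c(FALSE, FALSE))
  claims_bundle(patients, diagnoses, treatments, prescriptions,
                as.Date("2002-01-01"), as.Date("2015-12-31"))
}
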