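test_that("the 1:1 split is exact, deterministic and label-complete", {
  cohort <- data.frame(patient_id = sprintf("P%04d", 1:2618),
                       split = "unassigned")
  s <- split_cohort(cohort, 0.5, seed = 13)
  expect_equal(sum(s$split == "discovery"), 1309)
  expect_equal(sum(s$split == "validation"), 1309)

  # half-up rounding: n = 5 gives discovery 3 / validation 2
  s5 <- split_cohort(cohort[1:5, ], 0.5, seed = 13)
  expect_equal(sum(s5$split == "discovery"), 3)
  expect_equal(sum(s5$split == "validation"), 2)

  expect_identical(split_cohort(cohort, 0.5, seed = 13)$split, s$split)
  expect_false(identical(split_cohort(cohort, 0.5, seed = 14)$split,
                         s$split))
  expect_error(split_cohort(cohort[1, , drop = FALSE]), "2 rows")
})

test_that("BH adjustment matches its worked example and p.adjust", {
  r <- bh_adjust(c(0.005, 0.01, 0.03, 0.04), q = 0.05)
  expect_equal(r$p_adjusted, c(0.02, 0.02, 0.04, 0.04))
  expect_true(all(r$reject))

  expect_equal(bh_adjust(rep(1, 6), 0.05)$p_adjusted, rep(1, 6))
  expect_false(any(bh_adjust(rep(1, 6), 0.05)$reject))

  r1 <- bh_adjust(0.04, 0.05)
  expect_equal(r1$p_adjusted, 0.04)
  expect_true(r1$reject)

  set.seed(1001)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p, 0.05)$p_adjusted, p.adjust(p, "BH"))
    expect_equal(bh_adjust(p, 0.05, method = "BY")$p_adjusted,
                 p.adjust(p, "BY"))
  }

  # NA entries are excluded from the family and never rejected
  rna <- bh_adjust(c(0.01, NA, 0.02), q = 0.05)
  expect_equal(rna$p_adjusted, c(0.02, NA, 0.02))
  expect_equal(rna$reject, c(TRUE, FALSE, TRUE))

  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH rejection sets are monotone in the FDR level", {
  set.seed(1002)
  for (i in 1:50) {
    p <- runif(sample(2:15, 1))
    qs <- sort(runif(3, 0.01, 0.3))
    rej <- lapply(qs, function(q) which(bh_adjust(p, q)$reject))
    expect_true(all(rej[[1]] %in% rej[[2]]))
    expect_true(all(rej[[2]] %in% rej[[3]]))
  }
})

make_screen_fixture <- function(n = 1200, n_drugs = 4, seed = 301,
                                log_hr = 0) {
  drugs <- drug_panel(n_drugs, p_incident = 0.15, p_prevalent = 0.05,
                      log_hr_all_cause = log_hr,
                      log_hr_cancer_specific = log_hr)
  sim <- simulate_bundle(screen_sim_config(n, drugs, seed))
  cohort <- split_cohort(build_cohort(sim$bundle, sim$covariates), 0.5,
                         seed = seed)
  mat <- build_exposure_matrix(sim$bundle, cohort, 4)
  list(sim = sim, cohort = cohort, mat = mat)
}

test_that("the Cox engine agrees with the formula interface oracle", {
  fx <- make_screen_fixture()
  cfg <- screen_config()
  rows <- fx$cohort[fx$cohort$split == "discovery", ]
  for (d in colnames(fx$mat)[1:3]) {
    cls <- fx$mat[match(rows$patient_id, rownames(fx$mat)), d]
    r <- fit_drug_model(rows, cls, "all_cause", cfg)
    keep <- cls != "prevalent_user"
    df <- rows[keep, ]
    df$exposed <- as.numeric(cls[keep] == "incident_user")
    df$sex <- factor(df$sex, sex_levels())
    df$age_group <- factor(df$age_group, age_group_levels())
    df$treatment_category <- factor(df$treatment_category,
                                    treatment_category_levels())
    df$cci_category <- factor(df$cci_category, cci_category_levels())
    f <- survival::coxph(
      survival::Surv(followup_days, event_all_cause) ~ exposed + sex +
        age_group + treatment_category + cci_category,
      data = df, ties = "efron")
    expect_equal(r$log_hr, unname(coef(f)["exposed"]), tolerance = 1e-10)
    expect_equal(r$p_raw,
                 2 * pnorm(-abs(coef(f)["exposed"] /
                                  sqrt(vcov(f)["exposed", "exposed"]))),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("recoding exposure 1<->0 inverts the hazard ratio exactly", {
  fx <- make_screen_fixture()
  cfg <- screen_config()
  rows <- fx$cohort[fx$cohort$split == "discovery", ]
  d <- colnames(fx$mat)[1]
  cls <- fx$mat[match(rows$patient_id, rownames(fx$mat)), d]
  r1 <- fit_drug_model(rows, cls, "all_cause", cfg)
  flipped <- ifelse(cls == "incident_user", "nonuser",
                    ifelse(cls == "nonuser", "incident_user", cls))
  # flipped arm sizes still clear the per-arm floor in this fixture
  r2 <- fit_drug_model(rows, flipped, "all_cause", cfg)
  expect_equal(r2$hr, 1 / r1$hr, tolerance = 1e-8)
  expect_equal(r2$p_raw, r1$p_raw, tolerance = 1e-8)
})

test_that("degenerate exposure vectors are reported, not thrown", {
  fx <- make_screen_fixture()
  rows <- fx$cohort[fx$cohort$split == "discovery", ]
  r0 <- fit_drug_model(rows, rep("nonuser", nrow(rows)), "all_cause",
                       screen_config())
  expect_false(r0$converged)
  expect_match(r0$reason, "degenerate")
  r1 <- fit_drug_model(rows, rep("incident_user", nrow(rows)), "all_cause",
                       screen_config())
  expect_false(r1$converged)
  expect_true(is.na(r1$hr))
})

test_that("patient order does not change any per-drug result", {
  fx <- make_screen_fixture(n = 800)
  cfg <- screen_config()
  rows <- fx$cohort[fx$cohort$split == "discovery", ]
  d <- colnames(fx$mat)[2]
  cls <- fx$mat[match(rows$patient_id, rownames(fx$mat)), d]
  r1 <- fit_drug_model(rows, cls, "cancer_specific", cfg)
  set.seed(1)
  perm <- sample(nrow(rows))
  r2 <- fit_drug_model(rows[perm, ], cls[perm], "cancer_specific", cfg)
  expect_equal(r1$log_hr, r2$log_hr, tolerance = 1e-9)
  expect_equal(r1$p_raw, r2$p_raw, tolerance = 1e-9)
  expect_equal(r1[c("n_users", "n_nonusers", "n_events")],
               r2[c("n_users", "n_nonusers", "n_events")])
})

test_that("two-group exponential data recovers the closed-form rate ratio", {
  # without covariates the Cox log-HR estimates the log event-rate ratio
  set.seed(1003)
  n <- 4000
  exposed <- rep(c(0, 1), each = n / 2)
  rate <- ifelse(exposed == 1, 2 / 1000, 1 / 1000)
  time <- rexp(n, rate)
  cens <- 1500
  event <- as.integer(time <= cens)
  rows <- data.frame(followup_days = pmin(time, cens),
                     event_all_cause = event,
                     event_cancer_specific = 0L)
  cls <- ifelse(exposed == 1, "incident_user", "nonuser")
  cfg <- screen_config(adjustment_set = character(0))
  r <- fit_drug_model(rows, cls, "all_cause", cfg)
  d1 <- sum(event[exposed == 1]); t1 <- sum(rows$followup_days[exposed == 1])
  d0 <- sum(event[exposed == 0]); t0 <- sum(rows$followup_days[exposed == 0])
  closed_form <- log((d1 / t1) / (d0 / t0))
  se <- sqrt(1 / d1 + 1 / d0)
  expect_lt(abs(r$log_hr - closed_form), 3 * se)
})

test_that("the two-stage screen separates a planted signal from nulls", {
  drugs <- drug_panel(8, p_incident = 0.15, p_prevalent = 0.05)
  drugs$log_hr_all_cause[1] <- log(3)
  drugs$log_hr_cancer_specific[1] <- log(3)
  sim <- simulate_bundle(screen_sim_config(3000, drugs, seed = 401))
  cohort <- split_cohort(build_cohort(sim$bundle, sim$covariates), 0.5,
                         seed = 401)
  mat <- build_exposure_matrix(sim$bundle, cohort, 4)
  rep <- run_two_stage_screen(cohort, mat,
                              screen_config(outcomes = "all_cause"))
  planted <- truncate_atc(drugs$atc_code[1], 4)
  expect_true(planted %in% rep$validated_signals$drug)
  expect_equal(rep$validated_signals$direction[
    rep$validated_signals$drug == planted], "detrimental")
  # validated signals are always a subset of discovery signals
  expect_true(all(rep$validated_signals$drug %in%
                    rep$discovery_signals$drug))
  # every discovery fit carries an FDR-adjusted p; validation rows do not
  res <- rep$results
  expect_true(all(!is.na(res$p_fdr_adjusted[res$stage == "discovery" &
                                              res$converged])))
  expect_true(all(is.na(res$p_fdr_adjusted[res$stage == "validation"])))
})

test_that("direction consistency is required for validation when configured", {
  fx <- make_screen_fixture(n = 1000, n_drugs = 3, seed = 402)
  rep1 <- run_two_stage_screen(fx$cohort, fx$mat,
                               screen_config(outcomes = "all_cause"))
  if (nrow(rep1$validated_signals)) {
    res <- rep1$results
    for (i in seq_len(nrow(rep1$validated_signals))) {
      sig <- rep1$validated_signals[i, ]
      ds <- res[res$drug == sig$drug & res$stage == "discovery" &
                  res$outcome == sig$outcome, ]
      expect_equal(sign(log(sig$hr)), sign(ds$log_hr))
    }
  }
  expect_s3_class(rep1, "screen_report")
})

test_that("an empty drug list yields an empty report with a warning", {
  fx <- make_screen_fixture(n = 600, n_drugs = 1, seed = 403)
  empty <- fx$mat[, 0, drop = FALSE]
  attr(empty, "atc_level") <- 4L
  class(empty) <- c("exposure_matrix", class(empty))
  expect_warning(rep <- run_two_stage_screen(fx$cohort, empty,
                                             screen_config()),
                 "no eligible")
  expect_equal(nrow(rep$results), 0)
  expect_equal(nrow(rep$validated_signals), 0)
})
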