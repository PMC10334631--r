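test_that("the generator is deterministic given its seed", {
  cfg <- simulation_config(n_patients = 80, drugs = drug_panel(5), seed = 3)
  s1 <- simulate_bundle(cfg)
  s2 <- simulate_bundle(cfg)
  expect_identical(s1, s2)
  s3 <- simulate_bundle(simulation_config(n_patients = 80,
                                          drugs = drug_panel(5), seed = 4))
  expect_false(identical(s1$bundle$prescriptions, s3$bundle$prescriptions))
})

test_that("configured exposure and sex margins are reproduced", {
  # all effects zero; per-drug incident fraction within 3 SE of p_incident
  p_inc <- 0.12
  cfg <- simulation_config(n_patients = 5000,
                           drugs = drug_panel(8, p_incident = p_inc),
                           seed = 21)
  sim <- simulate_bundle(cfg)
  inc_frac <- colMeans(sim$ground_truth$exposure_class == "incident_user")
  se <- sqrt(p_inc * (1 - p_inc) / 5000)
  expect_true(all(abs(inc_frac - p_inc) < 3 * se))

  # default p_male reproduces the male count of the motivating cohort
  sim2 <- simulate_bundle(simulation_config(n_patients = 1309, seed = 22))
  n_male <- sum(sim2$bundle$patients$sex == "male")
  se_male <- sqrt(1309 * 0.66 * 0.34)
  expect_lt(abs(n_male - 864), 3 * se_male)
})

test_that("zero drugs yields an empty prescriptions table (noise off)", {
  cfg <- simulation_config(n_patients = 40, seed = 5, p_anticancer = 0)
  sim <- simulate_bundle(cfg)
  expect_equal(nrow(sim$bundle$prescriptions), 0)
  expect_equal(ncol(sim$ground_truth$exposure_class), 0)
})

test_that("survival sampler follows the Weibull proportional-hazards form", {
  # doubling the hazard multiplier scales the median by 2^(-1/k)
  k <- 1.7; lam <- 900
  set.seed(31); t1 <- sample_survival_time(2e5, k, lam, 1)
  set.seed(31); t2 <- sample_survival_time(2e5, k, lam, 2)
  expect_equal(median(t2) / median(t1), 2^(-1 / k), tolerance = 0.02)

  # k = 1 is exponential with mean scale/multiplier
  set.seed(32); d <- sample_survival_time(1e5, 1, 1000, 1)
  expect_lt(abs(mean(d) - 1000), 3 * 1000 / sqrt(1e5))

  # identical rng state, identical draw
  set.seed(33); a <- sample_survival_time(5, 0.8, 500, 1.3)
  set.seed(33); b <- sample_survival_time(5, 0.8, 500, 1.3)
  expect_identical(a, b)

  expect_error(sample_survival_time(1, 1, 1000, 0), "multiplier")
})

test_that("all-cause survival under the null matches the baseline Weibull", {
  # Kaplan-Meier on 10^4 simulated patients with every effect zero vs the
  # closed-form two-cause survival function, sup-distance over follow-up
  zero_lhr <- lapply(default_covariate_log_hrs(), function(v) v * 0)
  cfg <- simulation_config(n_patients = 1e4, seed = 41,
                           covariate_log_hrs = zero_lhr,
                           baseline_hazard_cancer = c(0.9, 10400),
                           baseline_hazard_other = c(1.0, 36000))
  sim <- simulate_bundle(cfg)
  gt <- sim$ground_truth$survival
  km <- survival::survfit(survival::Surv(followup_days, event_all_cause) ~ 1,
                          data = gt)
  s_true <- exp(-(km$time / 10400)^0.9 - km$time / 36000)
  at_risk <- km$n.risk >= 100
  expect_lt(max(abs(km$surv[at_risk] - s_true[at_risk])), 0.02)
})

test_that("no event in the bundle postdates the coverage end", {
  sim <- simulate_bundle(simulation_config(
    n_patients = 400, drugs = drug_panel(6), seed = 51))
  b <- sim$bundle
  dates <- c(b$diagnoses$date, b$treatments$date, b$prescriptions$date,
             b$patients$death_date[!is.na(b$patients$death_date)])
  expect_true(all(dates <= b$coverage_end))
  expect_true(all(dates >= b$coverage_start))
})

test_that("invalid configurations are rejected before sampling", {
  expect_error(simulation_config(n_patients = 10,
                                 age_group_probs = rep(0.2, 6)),
               "age_group_probs")
  expect_error(simulation_config(n_patients = 10,
                                 baseline_hazard_other = c(1, -5)),
               "positive")
  bad <- drug_panel(1)
  bad$p_incident <- 0.8; bad$p_prevalent <- 0.4
  expect_error(simulation_config(n_patients = 10, drugs = bad))
  # drug under the anticancer exclusion prefix is refused
  overlap <- drug_panel(1)
  overlap$atc_code <- "L01AB01"
  expect_error(simulation_config(n_patients = 10, drugs = overlap),
               "anticancer")
})

test_that("scenario files round-trip the configuration", {
  cfg <- demo_scenario(seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario_config(cfg, path)
  cfg2 <- read_scenario_config(path)
  expect_equal(cfg2$n_patients, cfg$n_patients)
  expect_equal(cfg2$drugs, cfg$drugs, tolerance = 1e-12)
  expect_equal(cfg2$age_group_probs, cfg$age_group_probs, tolerance = 1e-12)
  expect_identical(cfg2$entry_date_range, cfg$entry_date_range)
})

test_that("ground truth is written as plain tables", {
  sim <- simulate_bundle(simulation_config(
    n_patients = 30, drugs = drug_panel(3), seed = 61))
  dir <- withr::local_tempdir()
  write_ground_truth(sim, dir)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 30 * 3)
  expect_setequal(unique(gt$class),
                  intersect(c("nonuser", "incident_user", "prevalent_user"),
                            unique(gt$class)))
  dt <- read.csv(file.path(dir, "drug_truth.csv"))
  expect_equal(dt$atc_code, sim$ground_truth$drugs$atc_code)
})
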