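test_that("ATC truncation returns the level-2 and level-4 prefixes", {
  expect_equal(truncate_atc("N07AA02", 2), "N07")
  expect_equal(truncate_atc("A02AA04", 4), "A02AA")
  expect_equal(truncate_atc("B01AC06", 4), "B01AC")
  expect_equal(truncate_atc("b01ac06", 4), "B01AC")
  expect_error(truncate_atc("N07", 4), "N07")
  expect_error(truncate_atc("N0", 2), "N0")
  expect_error(truncate_atc("N07AA02", 3), "level")
})

test_that("window classification follows the incident-user definition", {
  t0 <- as.Date("2010-06-01")
  w <- exposure_windows()
  expect_equal(classify_exposure(t0 - 100, t0, w), "incident_user")
  expect_equal(classify_exposure(t0 - 400, t0, w), "prevalent_user")
  expect_equal(classify_exposure(as.Date(character(0)), t0, w), "nonuser")
  # far-window use takes precedence over near-window use
  expect_equal(classify_exposure(c(t0 - 400, t0 - 30), t0, w),
               "prevalent_user")
  # boundaries: day 365 back is inside NEAR, day 366 inside FAR,
  # day 548 the last day of the lookback, day 549 outside; t0 itself ignored
  expect_equal(classify_exposure(t0 - 365, t0, w), "incident_user")
  expect_equal(classify_exposure(t0 - 366, t0, w), "prevalent_user")
  expect_equal(classify_exposure(t0 - 548, t0, w), "prevalent_user")
  expect_equal(classify_exposure(t0 - 549, t0, w), "nonuser")
  expect_equal(classify_exposure(t0, t0, w), "nonuser")
  expect_equal(classify_exposure(t0 + 10, t0, w), "nonuser")
})

test_that("classification agrees with the brute-force window-scan oracle", {
  set.seed(202)
  t0 <- as.Date("2010-01-01")
  for (i in 1:500) {
    n <- sample(0:6, 1)
    dates <- t0 + sample(-700:100, n, replace = TRUE)
    expect_identical(classify_exposure(dates, t0),
                     oracle_classify_exposure(dates, t0))
  }
})

test_that("adding a far-window prescription never moves a pair away from prevalent", {
  set.seed(203)
  t0 <- as.Date("2010-01-01")
  rank <- c(nonuser = 1, incident_user = 2, prevalent_user = 3)
  for (i in 1:200) {
    dates <- t0 + sample(-700:100, sample(0:4, 1), replace = TRUE)
    far_rx <- t0 - sample(366:548, 1)
    before <- classify_exposure(dates, t0)
    after <- classify_exposure(c(dates, far_rx), t0)
    expect_equal(after, "prevalent_user")
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("level-2 classification equals pooled level-4 classification", {
  set.seed(77)
  sim <- simulate_bundle(simulation_config(
    n_patients = 300, drugs = drug_panel(10), seed = 104))
  cohort <- build_cohort(sim$bundle, sim$covariates)
  m2 <- build_exposure_matrix(sim$bundle, cohort, 2)
  rx <- sim$bundle$prescriptions
  rx <- rx[!rx$is_anticancer, ]
  t0 <- cohort$time_zero[match(rx$patient_id, cohort$patient_id)]
  rx <- rx[!is.na(t0), ]
  t0 <- t0[!is.na(t0)]
  for (d in colnames(m2)) {
    for (p in sample(rownames(m2), 30)) {
      sel <- rx$patient_id == p & startsWith(rx$atc_code, d)
      expected <- classify_exposure(rx$date[sel],
                                    cohort$time_zero[cohort$patient_id == p])
      expect_identical(m2[p, d], expected)
    }
  }
})

test_that("exposure matrix reproduces ground truth and partitions classes", {
  sim <- simulate_bundle(simulation_config(
    n_patients = 500, drugs = drug_panel(12, p_incident = 0.1,
                                         p_prevalent = 0.08), seed = 105))
  cohort <- build_cohort(sim$bundle, sim$covariates)
  mat <- build_exposure_matrix(sim$bundle, cohort, 4)
  truth <- sim$ground_truth$exposure_class[cohort$patient_id, , drop = FALSE]
  colnames(truth) <- truncate_atc(colnames(truth), 4)
  expect_setequal(colnames(mat), colnames(truth))
  expect_true(all(mat[, colnames(mat)] == truth[, colnames(mat)]))
  # exactly one class per pair by construction of the matrix
  expect_true(all(mat %in% exposure_class_levels()))
})

test_that("post-entry prescriptions never leak into exposure", {
  sim <- simulate_bundle(simulation_config(
    n_patients = 400, drugs = drug_panel(6), seed = 106,
    p_post_entry = 0.5))
  cohort <- build_cohort(sim$bundle, sim$covariates)
  mat1 <- build_exposure_matrix(sim$bundle, cohort, 4)
  b2 <- sim$bundle
  t0 <- cohort$time_zero[match(b2$prescriptions$patient_id,
                               cohort$patient_id)]
  pre_entry <- !is.na(t0) & b2$prescriptions$date < t0
  b2$prescriptions <- b2$prescriptions[pre_entry, , drop = FALSE]
  mat2 <- build_exposure_matrix(b2, cohort, 4)
  expect_identical(unclass(mat1), unclass(mat2))
})

test_that("anticancer prescriptions are excluded before classification", {
  sim <- simulate_bundle(simulation_config(
    n_patients = 200, seed = 107, p_anticancer = 1))
  cohort <- build_cohort(sim$bundle, sim$covariates)
  mat <- build_exposure_matrix(sim$bundle, cohort, 4)
  expect_equal(ncol(mat), 0)
})

test_that("level-2 pooling merges codes sharing the 3-character prefix", {
  b <- tiny_bundle()
  b$prescriptions <- data.frame(
    patient_id = c("P1", "P1"),
    date = as.Date(c("2005-01-01", "2004-11-01")),
    atc_code = c("N07AA02", "N07AB01"),
    is_anticancer = FALSE)
  cohort <- data.frame(patient_id = "P1",
                       time_zero = as.Date("2005-03-15"))
  mat <- build_exposure_matrix(b, cohort, 2)
  expect_equal(colnames(mat), "N07")
  expect_equal(unname(mat["P1", "N07"]), "incident_user")
})

test_that("min_users filters the drug list", {
  sim <- simulate_bundle(simulation_config(
    n_patients = 300, drugs = drug_panel(8, p_incident = 0.05), seed = 108))
  cohort <- build_cohort(sim$bundle, sim$covariates)
  m1 <- build_exposure_matrix(sim$bundle, cohort, 4, min_users = 1)
  m10 <- build_exposure_matrix(sim$bundle, cohort, 4, min_users = 10)
  expect_true(all(colnames(m10) %in% colnames(m1)))
  inc <- colSums(m1 == "incident_user")
  expect_setequal(colnames(m10), names(inc)[inc >= 10])
})
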