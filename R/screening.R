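## The MWAS engine: discovery/validation split, per-drug covariate-adjusted
## Cox proportional-hazards fits, Benjamini-Hochberg FDR in discovery,
## replication at p < alpha in validation.

#' Screen configuration
#'
#' @param fdr_q Discovery-stage FDR level (default 0.05).
#' @param validation_alpha Validation-stage p threshold (default 0.05).
#' @param split_ratio Fraction assigned to the discovery set (default 0.5).
#' @param split_seed Seed of the random 1:1 split.
#' @param adjustment_set Covariate columns entered into every model
#'   (categoricals expanded against fixed reference levels).
#' @param outcomes Subset of `c("all_cause", "cancer_specific")`.
#' @param ties_method `"efron"` (default) or `"breslow"`.
#' @param require_direction_consistency If `TRUE` (default) a validated
#'   signal must have the same effect direction in both stages.
#' @param min_users_per_arm Minimum incident users and nonusers within a
#'   stage for a drug to be fit (default 10).
#' @param fdr_method `"BH"` (default, independence-valid step-up) or
#'   `"BY"` for the dependency-robust variant.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(fdr_q = 0.05, validation_alpha = 0.05,
                          split_ratio = 0.5, split_seed = 1L,
                          adjustment_set = c("sex", "age_group",
                                             "treatment_category",
                                             "cci_category"),
                          outcomes = c("all_cause", "cancer_specific"),
                          ties_method = c("efron", "breslow"),
                          require_direction_consistency = TRUE,
                          min_users_per_arm = 10L,
                          fdr_method = c("BH", "BY")) {
  stopifnot(fdr_q > 0, fdr_q < 1, split_ratio > 0, split_ratio < 1,
            validation_alpha > 0, validation_alpha <= 1,
            all(outcomes %in% outcome_levels()), min_users_per_arm >= 1)
  structure(list(fdr_q = fdr_q, validation_alpha = validation_alpha,
                 split_ratio = split_ratio,
                 split_seed = as.integer(split_seed),
                 adjustment_set = adjustment_set, outcomes = outcomes,
                 ties_method = match.arg(ties_method),
                 require_direction_consistency = require_direction_consistency,
                 min_users_per_arm = as.integer(min_users_per_arm),
                 fdr_method = match.arg(fdr_method)),
            class = "screen_config")
}

#' Randomly split a cohort into discovery and validation sets
#'
#' Simple random split without replacement; the discovery set receives
#' `floor(ratio * n + 0.5)` rows (half-up rounding, so a 1:1 split of an
#' even cohort is exactly equal). Deterministic given `seed`.
#'
#' @param cohort Cohort data.frame (>= 2 rows).
#' @param ratio Discovery fraction.
#' @param seed Integer seed.
#' @return The cohort with its `split` column set to
#'   `"discovery"`/`"validation"`.
#' @export
split_cohort <- function(cohort, ratio = 0.5, seed = 1L) {
  n <- nrow(cohort)
  if (n < 2) stop("need at least 2 rows to split", call. = FALSE)
  n_disc <- as.integer(floor(ratio * n + 0.5))
  idx <- with_seed(seed, sample.int(n, n_disc))
  cohort$split <- "validation"
  cohort$split[idx] <- "discovery"
  cohort
}

outcome_event_col <- function(outcome) {
  switch(outcome, all_cause = "event_all_cause",
         cancer_specific = "event_cancer_specific",
         stop(sprintf("unknown outcome '%s'", outcome), call. = FALSE))
}

#' Covariate design matrix for the adjustment set
#'
#' Expands the categorical adjustment covariates against fixed reference
#' levels (male; 15-39; operation only; CCI 0), without intercept column.
#'
#' @param rows Cohort rows.
#' @param adjustment_set Covariate names.
#' @return Numeric matrix with one row per cohort row.
#' @keywords internal
adjustment_matrix <- function(rows, adjustment_set) {
  levels_of <- list(sex = sex_levels(), age_group = age_group_levels(),
                    treatment_category = treatment_category_levels(),
                    cci_category = cci_category_levels())
  cols <- lapply(adjustment_set, function(v) {
    lv <- levels_of[[v]]
    if (is.null(lv)) lv <- sort(unique(rows[[v]]))
    f <- factor(rows[[v]], levels = lv)
    m <- outer(as.integer(f), 2:length(lv),
               function(i, j) as.numeric(i == j))
    colnames(m) <- paste0(v, lv[-1])
    m
  })
  do.call(cbind, cols)
}

empty_fit_result <- function(outcome, stage, n_users, n_nonusers, n_events,
                             reason) {
  data.frame(outcome = outcome, stage = stage, n_users = n_users,
             n_nonusers = n_nonusers, n_events = n_events,
             log_hr = NA_real_, hr = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, p_raw = NA_real_,
             p_fdr_adjusted = NA_real_, converged = FALSE, reason = reason)
}

#' Fit the per-drug proportional-hazards model
#'
#' Fits a Cox regression of the outcome on the binary incident-user
#' indicator plus the adjustment set, in one cohort split. Prevalent users
#' of the drug are excluded (new-user design: incident users vs nonusers).
#' A degenerate exposure vector or a failed/separated fit yields
#' `converged = FALSE` with the estimates absent; the screen continues.
#'
#' @param rows Cohort rows of one split.
#' @param exposure_class Character vector parallel to `rows` with the
#'   drug's exposure class per patient.
#' @param outcome `"all_cause"` or `"cancer_specific"`.
#' @param config A [screen_config()].
#' @param stage Stage label recorded in the result.
#' @param cov_matrix Optional precomputed [adjustment_matrix()] for `rows`.
#' @return One-row data.frame: counts, `log_hr`, `hr`, Wald 95% `ci_low`/
#'   `ci_high`, `p_raw`, `p_fdr_adjusted` (`NA` until [bh_adjust()]),
#'   `converged`, `reason`.
#' @export
fit_drug_model <- function(rows, exposure_class, outcome,
                           config = screen_config(), stage = "discovery",
                           cov_matrix = NULL) {
  stopifnot(length(exposure_class) == nrow(rows))
  keep <- exposure_class != "prevalent_user"
  exposed <- as.numeric(exposure_class[keep] == "incident_user")
  ev_col <- outcome_event_col(outcome)
  time <- rows$followup_days[keep]
  event <- rows[[ev_col]][keep]
  n_users <- sum(exposed == 1)
  n_nonusers <- sum(exposed == 0)
  n_events <- sum(event)

  if (n_users < config$min_users_per_arm ||
      n_nonusers < config$min_users_per_arm) {
    return(empty_fit_result(outcome, stage, n_users, n_nonusers, n_events,
                            "degenerate exposure"))
  }
  if (n_events == 0) {
    return(empty_fit_result(outcome, stage, n_users, n_nonusers, n_events,
                            "no events"))
  }

  if (is.null(cov_matrix)) {
    cov_matrix <- adjustment_matrix(rows, config$adjustment_set)
  }
  X <- cbind(exposed = exposed, cov_matrix[keep, , drop = FALSE])
  # drop constant columns (empty covariate levels) to keep the fit full rank
  const <- apply(X, 2, function(c) all(c == c[1]))
  const["exposed"] <- FALSE
  X <- X[, !const, drop = FALSE]

  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph.fit(x = X, y = survival::Surv(time, event),
                          strata = NULL, offset = NULL, init = NULL,
                          control = survival::coxph.control(),
                          weights = NULL, method = config$ties_method,
                          rownames = seq_along(time)),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)

  beta <- if (is.null(fit)) NA_real_ else unname(fit$coefficients["exposed"])
  se <- if (is.null(fit)) NA_real_ else sqrt(fit$var[1, 1])
  bad <- is.null(fit) || !is.finite(beta) || !is.finite(se) || se <= 0 ||
    abs(beta) > 15 || se > 15
  if (bad) {
    return(empty_fit_result(outcome, stage, n_users, n_nonusers, n_events,
                            "fit failed or separated"))
  }
  z <- beta / se
  ci_half <- stats::qnorm(0.975) * se
  data.frame(outcome = outcome, stage = stage, n_users = n_users,
             n_nonusers = n_nonusers, n_events = n_events, log_hr = beta,
             hr = exp(beta), ci_low = exp(beta - ci_half),
             ci_high = exp(beta + ci_half),
             p_raw = 2 * stats::pnorm(-abs(z)),
             p_fdr_adjusted = NA_real_, converged = TRUE, reason = "")
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Direct implementation of the step-up procedure: with order statistics
#' \eqn{p_{(1)} \le \dots \le p_{(m)}}, reject all \eqn{i \le k} where
#' \eqn{k = \max\{i : p_{(i)} \le i q / m\}}; the adjusted value is
#' \eqn{\min(1, \min_{j \ge i} m p_{(j)} / j)}. `NA` entries (unconverged
#' fits) are excluded from `m` and returned unadjusted (`NA`, not
#' rejected). `method = "BY"` inflates by \eqn{\sum_{i=1}^m 1/i} for the
#' dependency-robust variant.
#'
#' @param p Numeric vector of p values in `[0, 1]` (`NA` allowed).
#' @param q FDR level in (0, 1).
#' @param method `"BH"` or `"BY"`.
#' @return List with `p_adjusted` (same length/order as `p`) and `reject`
#'   (logical; `FALSE` where `p` is `NA`).
#' @export
bh_adjust <- function(p, q = 0.05, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(q > 0, q < 1)
  adj <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m > 0) {
    po <- p[ok]
    o <- order(po)
    cm <- if (method == "BY") sum(1 / seq_len(m)) else 1
    stepped <- cm * m * po[o] / seq_len(m)
    adj_sorted <- pmin(1, rev(cummin(rev(stepped))))
    adj_ok <- numeric(m)
    adj_ok[o] <- adj_sorted
    adj[ok] <- adj_ok
  }
  reject <- !is.na(adj) & adj <= q
  list(p_adjusted = adj, reject = reject)
}

#' Run the two-stage discovery/validation drug screen
#'
#' For every outcome and every supplied ATC-level exposure matrix: fits all
#' eligible drugs in the discovery set, applies [bh_adjust()] across that
#' family (one multiplicity family per outcome x level), refits the
#' discovery signals in the validation set, and validates those with
#' validation `p_raw < validation_alpha` (and, by default, a consistent
#' effect direction). Fully deterministic given the split.
#'
#' @param cohort Cohort with `split` already assigned (see
#'   [split_cohort()]).
#' @param exposure_matrices One `exposure_matrix` or a list of them (one
#'   per ATC level).
#' @param config A [screen_config()].
#' @return A `screen_report`: list with `results` (full per-drug table
#'   across stages), `discovery_signals`, `validated_signals` (both
#'   data.frames with direction labels), and `config`.
#' @export
run_two_stage_screen <- function(cohort, exposure_matrices,
                                 config = screen_config()) {
  if (inherits(exposure_matrices, "exposure_matrix")) {
    exposure_matrices <- list(exposure_matrices)
  }
  stopifnot(all(cohort$split %in% c("discovery", "validation")))
  disc <- cohort[cohort$split == "discovery", , drop = FALSE]
  val <- cohort[cohort$split == "validation", , drop = FALSE]

  cov_disc <- adjustment_matrix(disc, config$adjustment_set)
  cov_val <- adjustment_matrix(val, config$adjustment_set)

  all_res <- list()
  disc_sig <- list()
  val_sig <- list()
  for (mat in exposure_matrices) {
    level <- attr(mat, "atc_level")
    drugs <- colnames(mat)
    if (!length(drugs)) next
    cls_disc <- mat[match(disc$patient_id, rownames(mat)), , drop = FALSE]
    cls_val <- mat[match(val$patient_id, rownames(mat)), , drop = FALSE]
    for (outcome in config$outcomes) {
      res <- do.call(rbind, lapply(drugs, function(d) {
        r <- fit_drug_model(disc, cls_disc[, d], outcome, config,
                            stage = "discovery", cov_matrix = cov_disc)
        cbind(drug = d, level = level, r)
      }))
      bh <- bh_adjust(ifelse(res$converged, res$p_raw, NA_real_),
                      config$fdr_q, config$fdr_method)
      res$p_fdr_adjusted <- bh$p_adjusted
      res$validated <- NA
      sig <- res[bh$reject, , drop = FALSE]
      if (nrow(sig)) {
        sig$direction <- ifelse(sig$hr < 1, "protective", "detrimental")
        disc_sig[[length(disc_sig) + 1L]] <-
          sig[, c("drug", "level", "outcome", "hr", "p_raw",
                  "p_fdr_adjusted", "direction")]
      }
      vres <- NULL
      if (nrow(sig)) {
        vres <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
          d <- sig$drug[i]
          r <- fit_drug_model(val, cls_val[, d], outcome, config,
                              stage = "validation", cov_matrix = cov_val)
          r$validated <- r$converged &&
            !is.na(r$p_raw) && r$p_raw < config$validation_alpha &&
            (!config$require_direction_consistency ||
               sign(r$log_hr) == sign(sig$log_hr[i]))
          cbind(drug = d, level = level, r)
        }))
        vok <- vres[vres$validated %in% TRUE, , drop = FALSE]
        if (nrow(vok)) {
          vok$direction <- ifelse(vok$hr < 1, "protective", "detrimental")
          vok$p_fdr_discovery <-
            sig$p_fdr_adjusted[match(vok$drug, sig$drug)]
          vok$hr_discovery <- sig$hr[match(vok$drug, sig$drug)]
          val_sig[[length(val_sig) + 1L]] <-
            vok[, c("drug", "level", "outcome", "hr", "p_raw", "direction",
                    "hr_discovery", "p_fdr_discovery")]
        }
      }
      all_res[[length(all_res) + 1L]] <- rbind(res, vres)
    }
  }
  results <- if (length(all_res)) do.call(rbind, all_res) else
    empty_results_frame()
  if (!length(all_res)) {
    warning("no eligible drugs; empty screen report", call. = FALSE)
  }
  rownames(results) <- NULL
  structure(list(
    results = results,
    discovery_signals = rbind_or_empty(disc_sig, c(
      "drug", "level", "outcome", "hr", "p_raw", "p_fdr_adjusted",
      "direction")),
    validated_signals = rbind_or_empty(val_sig, c(
      "drug", "level", "outcome", "hr", "p_raw", "direction",
      "hr_discovery", "p_fdr_discovery")),
    config = config), class = "screen_report")
}

empty_results_frame <- function() {
  data.frame(drug = character(0), level = integer(0), outcome = character(0),
             stage = character(0), n_users = integer(0),
             n_nonusers = integer(0), n_events = integer(0),
             log_hr = numeric(0), hr = numeric(0), ci_low = numeric(0),
             ci_high = numeric(0), p_raw = numeric(0),
             p_fdr_adjusted = numeric(0), converged = logical(0),
             reason = character(0), validated = logical(0))
}

rbind_or_empty <- function(lst, cols) {
  if (length(lst)) {
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  } else {
    as.data.frame(stats::setNames(
      lapply(cols, function(x) character(0)), cols))
  }
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("screen_report: %d fits, %d discovery signal(s), %d validated signal(s)\n",
              nrow(x$results), nrow(x$discovery_signals),
              nrow(x$validated_signals)))
  if (nrow(x$validated_signals)) {
    print(x$validated_signals[, c("drug", "level", "outcome", "hr",
                                  "direction")])
  }
  invisible(x)
}
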