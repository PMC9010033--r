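test_that("prevalence filter is strict at the 15% boundary", {
  led <- exposure_ledger(data.frame(
    patient_id = c(sprintf("p%03d", 1:15), sprintf("p%03d", 1:16),
                   sprintf("p%03d", 1:100)),
    drug = c(rep("at_boundary", 15), rep("above", 16), rep("universal", 100)),
    day = 1))
  kept <- prevalence_filter(led, n_patients = 100)
  expect_false("at_boundary" %in% kept)   # 0.15 is not > 0.15
  expect_true(all(c("above", "universal") %in% kept))
  expect_error(prevalence_filter(led[0, ], 100), "empty")
})

test_that("cumulative covariate path matches the hand-constructed ledger", {
  # therapy days {2, 3, 5}, event day 6: covariate on intervals covering
  # days 1..6 must be 0,0,1,2,2,3
  led <- exposure_ledger(data.frame(patient_id = "A", drug = "cefepime",
                                    day = c(2, 3, 5)))
  events <- data.frame(patient_id = "A", event_day = 6)
  outc <- outcome_table(data.frame(patient_id = "A", recovery_day = 20,
                                   death_day = NA, infection_pre = FALSE,
                                   infection_post90 = FALSE))
  cp <- build_counting_process(led, events, outc, encoding = "cumulative")
  # expand back to day level for the check
  day_val <- unlist(lapply(seq_len(nrow(cp)), function(r)
    rep(cp$cefepime[r], cp$stop[r] - cp$start[r])))
  expect_equal(day_val, c(0, 0, 1, 2, 2, 3))
  expect_equal(cp$stop[nrow(cp)], 6)
  expect_true(cp$event[nrow(cp)])
  expect_equal(sum(cp$event), 1)
  # intervals are contiguous and non-overlapping per patient
  expect_equal(cp$start[-1], cp$stop[-nrow(cp)])

  # "any" encoding switches on the day after first exposure and stays on
  cp_any <- build_counting_process(led, events, outc, encoding = "any")
  day_any <- unlist(lapply(seq_len(nrow(cp_any)), function(r)
    rep(cp_any$cefepime[r], cp_any$stop[r] - cp_any$start[r])))
  expect_equal(day_any, c(0, 0, 1, 1, 1, 1))
})

test_that("never-exposed patients yield one zero row; degenerate events error", {
  led <- exposure_ledger(data.frame(patient_id = "B", drug = "cefepime", day = 1))
  outc <- outcome_table(data.frame(patient_id = c("A", "B"),
                                   recovery_day = c(10, 10),
                                   death_day = NA, infection_pre = FALSE,
                                   infection_post90 = FALSE))
  cp <- build_counting_process(led,
                               data.frame(patient_id = "A", event_day = NA),
                               outc)
  expect_equal(nrow(cp), 1)
  expect_equal(cp$cefepime, 0)
  expect_equal(c(cp$start, cp$stop), c(0, 10))

  expect_error(build_counting_process(
    led, data.frame(patient_id = "A", event_day = 0), outc), "day <= 0")
  expect_error(build_counting_process(
    led, data.frame(patient_id = "A", event_day = 12), outc),
    "after censoring")
})

test_that("zero-variation covariate is flagged as no-information", {
  cp <- hand_cp_table()
  cp$flat <- 0
  fit <- fit_cox_tv(cp, "flat")
  expect_equal(fit$log_hr, 0)
  expect_equal(fit$flag, "no_information")
  expect_false(is.finite(fit$se))
})

test_that("Newton solution matches brute-force partial-likelihood maximization", {
  cp <- hand_cp_table()
  fit <- fit_cox_tv(cp, "drug")
  brute <- stats::optimize(function(b) naive_cox_loglik(b, cp, "drug"),
                           interval = c(-5, 5), maximum = TRUE,
                           tol = 1e-10)
  expect_equal(fit$log_hr, brute$maximum, tolerance = 1e-6)
  expect_equal(fit$loglik[["fit"]], brute$objective, tolerance = 1e-9)
  expect_true(fit$converged)
  expect_equal(fit$n_events, 2)
})

test_that("a time-fixed binary covariate reproduces survival::coxph", {
  set.seed(71)
  n <- 120
  x <- rbinom(n, 1, 0.4)
  time <- round(rexp(n, 0.05 * exp(0.6 * x))) + 1
  status <- rbinom(n, 1, 0.7)
  cp <- data.frame(patient_id = sprintf("p%03d", 1:n), start = 0, stop = time,
                   event = status == 1, x = x)
  class(cp) <- c("counting_process", "data.frame")
  for (tie in c("breslow", "efron")) {
    fit <- fit_cox_tv(cp, "x", ties = tie)
    ref <- survival::coxph(survival::Surv(time, status) ~ x, ties = tie)
    expect_equal(fit$log_hr, unname(stats::coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, unname(sqrt(stats::vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("time-varying fit matches survival::coxph on counting-process data", {
  cfg <- sim_config(n_patients = 150, drug_log_hazards = c(drug = log(1.2)),
                    baseline_daily_hazard = 0.01,
                    exposure_pattern = "staggered",
                    recovery_day_range = c(20, 28), seed = 17)
  coh <- simulate_cohort(cfg, counts = FALSE)
  ev <- data.frame(patient_id = coh$truth$patient_id,
                   event_day = coh$truth$onset_day)
  cp <- build_counting_process(coh$exposures, ev, coh$outcomes,
                               encoding = "cumulative")
  fit <- fit_cox_tv(cp, "drug")
  ref <- survival::coxph(
    survival::Surv(start, stop, event) ~ drug, data = cp, ties = "breslow")
  expect_equal(fit$log_hr, unname(stats::coef(ref)), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(stats::vcov(ref)[1, 1])), tolerance = 1e-6)
})

test_that("partial likelihood is invariant to splitting rows with equal covariates", {
  cp <- hand_cp_table()
  fit1 <- fit_cox_tv(cp, "drug")
  # split patient D's single (0, 7] row into three sub-intervals
  d_row <- cp[cp$patient_id == "D", ]
  split_rows <- data.frame(patient_id = "D", start = c(0, 2, 5),
                           stop = c(2, 5, 7), event = FALSE, drug = 0)
  cp2 <- rbind(cp[cp$patient_id != "D", ], split_rows)
  class(cp2) <- c("counting_process", "data.frame")
  fit2 <- fit_cox_tv(cp2, "drug")
  expect_equal(fit1$log_hr, fit2$log_hr, tolerance = 1e-10)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-10)
})

test_that("shifting first exposure later never raises the cumulative covariate", {
  led1 <- exposure_ledger(data.frame(patient_id = "A", drug = "d",
                                     day = c(2, 3, 4, 5)))
  led2 <- exposure_ledger(data.frame(patient_id = "A", drug = "d",
                                     day = c(4, 5, 6, 7)))
  outc <- outcome_table(data.frame(patient_id = "A", recovery_day = 12,
                                   death_day = NA, infection_pre = FALSE,
                                   infection_post90 = FALSE))
  ev <- data.frame(patient_id = "A", event_day = NA)
  val_at <- function(cp, t) cp$d[cp$start < t & t <= cp$stop]
  cp1 <- build_counting_process(led1, ev, outc)
  cp2 <- build_counting_process(led2, ev, outc)
  for (t in 1:12) expect_lte(val_at(cp2, t), val_at(cp1, t))
})

test_that("the antibiotic panel runs per drug and encoding, surviving failures", {
  cfg <- sim_config(n_patients = 120, seed = 29)
  coh <- simulate_cohort(cfg, counts = FALSE)
  ev <- data.frame(patient_id = coh$truth$patient_id,
                   event_day = coh$truth$onset_day)
  panel <- run_antibiotic_panel(coh$exposures, ev, coh$outcomes,
                                n_patients = 120)
  drugs <- prevalence_filter(coh$exposures, 120)
  expect_equal(nrow(panel), 2 * length(drugs))
  expect_setequal(unique(panel$encoding), c("cumulative", "any"))
  # a drug below the prevalence filter never appears
  rare <- exposure_ledger(rbind(as.data.frame(coh$exposures),
                                data.frame(patient_id = "P001",
                                           drug = "rare_drug", day = 1)))
  panel2 <- run_antibiotic_panel(rare, ev, coh$outcomes, n_patients = 120)
  expect_false("rare_drug" %in% panel2$drug)
})

test_that("panel recovers the sign of each generating effect on large cohorts", {
  cfg <- sim_config(n_patients = 1200,
                    drug_log_hazards = c(harmful = log(1.3),
                                         protective = log(0.7)),
                    baseline_daily_hazard = 0.006,
                    exposure_pattern = "staggered",
                    recovery_day_range = c(25, 30), seed = 37)
  coh <- simulate_cohort(cfg, counts = FALSE)
  ev <- data.frame(patient_id = coh$truth$patient_id,
                   event_day = coh$truth$onset_day)
  panel <- run_antibiotic_panel(coh$exposures, ev, coh$outcomes,
                                n_patients = 1200,
                                encodings = "cumulative")
  expect_gt(panel$hr[panel$drug == "harmful"], 1)
  expect_lt(panel$hr[panel$drug == "protective"], 1)
})
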