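test_that("simulate_tree produces valid rooted trees deterministically", {
  t2 <- simulate_tree(2, seed = 1)
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$Nnode, 1)
  expect_true(all(t2$edge.length > 0))

  a <- ape::write.tree(simulate_tree(50, seed = 1))
  b <- ape::write.tree(simulate_tree(50, seed = 1))
  expect_identical(a, b)
  expect_false(identical(a, ape::write.tree(simulate_tree(50, seed = 2))))

  depths <- ape::node.depth.edgelength(simulate_tree(20, seed = 3))
  expect_true(all(is.finite(depths)) && sum(depths[1:20]) > 0)

  expect_error(simulate_tree(1), ">= 2")
})

test_that("zero hazard produces no coalescence events", {
  cfg <- sim_config(n_patients = 50, baseline_daily_hazard = 0,
                    drug_log_hazards = c(cefepime = 0), seed = 5)
  coh <- simulate_cohort(cfg, counts = FALSE)
  expect_false(any(coh$truth$coalesced))
  expect_true(all(is.na(coh$truth$onset_day)))
})

test_that("ground truth invariants hold across seeds", {
  for (seed in 1:3) {
    coh <- simulate_cohort(sim_config(n_patients = 60, seed = seed),
                           counts = FALSE)
    tr <- coh$truth
    expect_identical(is.na(tr$onset_day), !tr$coalesced)
    cens <- pmin(tr$recovery_day, tr$death_day, na.rm = TRUE)
    expect_true(all(tr$onset_day[tr$coalesced] < cens[tr$coalesced]))
    expect_true(all(tr$recovery_day >= 18 & tr$recovery_day <= 35))
  }
})

test_that("identical config implies byte-identical written cohorts", {
  cfg <- sim_config(n_patients = 8, seed = 123)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("written cohorts round-trip losslessly through the readers", {
  cfg <- sim_config(n_patients = 6, seed = 31)
  coh <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  paths <- write_cohort(coh, dir)
  expect_true(all(file.exists(paths)))
  expect_equal(length(paths), 7)
  back <- read_cohort(dir)
  expect_identical(back$table$counts, coh$table$counts)
  expect_identical(back$table$samples, coh$table$samples)
  expect_identical(as.data.frame(back$exposures), as.data.frame(coh$exposures))
  expect_identical(as.data.frame(back$outcomes), as.data.frame(coh$outcomes))
  expect_equal(ape::write.tree(back$tree), ape::write.tree(coh$tree))
  expect_equal(back$truth$coalesced, coh$truth$coalesced)
  expect_true(validate_cohort(back$table, back$tree, back$taxonomy,
                              back$exposures, back$outcomes))
  # row counts consistent with config
  expect_equal(length(unique(back$table$samples$patient_id)), 6)
})

test_that("daily onset incidence matches 1 - exp(-h) (hazard calibration)", {
  h0 <- 0.015
  cfg <- sim_config(n_patients = 400, baseline_daily_hazard = h0,
                    drug_log_hazards = c(cefepime = 0), death_prob = 0,
                    seed = 47)
  coh <- simulate_cohort(cfg, counts = FALSE)
  tr <- coh$truth
  # person-days at risk: days 1 .. min(onset, recovery - 1)
  risk_days <- ifelse(tr$coalesced, tr$onset_day, tr$recovery_day - 1L)
  n_days <- sum(risk_days)
  expect_gt(n_days, 5000)
  p_hat <- sum(tr$coalesced) / n_days
  p_true <- 1 - exp(-h0)
  mc_se <- sqrt(p_true * (1 - p_true) / n_days)
  expect_lt(abs(p_hat - p_true), 3 * mc_se)
})

test_that("coalesced fraction matches the analytic hazard integral", {
  beta <- log(1.12); h0 <- 0.005
  cfg <- sim_config(n_patients = 3000, baseline_daily_hazard = h0,
                    drug_log_hazards = c(drug = beta), death_prob = 0,
                    exposure_pattern = "staggered",
                    stagger_start_range = c(0, 10),
                    recovery_day_range = c(25, 30), seed = 53)
  coh <- simulate_cohort(cfg, counts = FALSE)
  # exact expectation over start day s ~ U{0..10} and recovery T ~ U{25..30}:
  # P(onset) = 1 - prod_{t=1}^{T-1} exp(-h0 exp(beta * max(0, t - s)))
  probs <- outer(0:10, 25:30, Vectorize(function(s, T) {
    t <- seq_len(T - 1)
    1 - exp(-sum(h0 * exp(beta * pmax(0, t - s))))
  }))
  p_true <- mean(probs)
  p_hat <- mean(coh$truth$coalesced)
  mc_se <- sqrt(p_true * (1 - p_true) / 3000)
  expect_lt(abs(p_hat - p_true), 3 * mc_se)
})

test_that("paired oral-stool distance decreases with time since onset; zero mixing stays flat", {
  paired_bc <- function(mix_rate, seed) {
    cfg <- sim_config(n_patients = 150, baseline_daily_hazard = 0.25,
                      coalescence_mix_rate = mix_rate, depth_mean = 800,
                      sampling_interval_days = 3,
                      recovery_day_range = c(20, 24), seed = seed)
    coh <- simulate_cohort(cfg)
    tr <- coh$truth
    out <- list()
    for (p in tr$patient_id[tr$coalesced]) {
      onset <- tr$onset_day[tr$patient_id == p]
      sub <- subset_samples(coh$table, coh$table$samples$patient_id == p)
      d <- bray_curtis(sub)
      s <- sub$samples
      for (day in unique(s$day)) {
        o <- s$sample_id[s$site == "oral" & s$day == day]
        f <- s$sample_id[s$site == "stool" & s$day == day]
        if (length(o) == 1 && length(f) == 1)
          out[[length(out) + 1]] <- data.frame(since = day - onset,
                                               bc = d[o, f])
      }
    }
    do.call(rbind, out)
  }
  mixed <- paired_bc(0.15, seed = 61)
  bins <- cut(mixed$since, c(-Inf, 0, 6, Inf),
              labels = c("pre", "early", "late"))
  m <- tapply(mixed$bc, bins, mean)
  expect_gt(m["pre"], m["early"])
  expect_gt(m["early"], m["late"])

  flat <- paired_bc(0, seed = 62)
  pre <- flat$bc[flat$since <= 0]
  post <- flat$bc[flat$since > 0]
  se <- sqrt(stats::var(pre) / length(pre) + stats::var(post) / length(post))
  expect_lt(abs(mean(post) - mean(pre)), 3 * se + 0.01)
})

test_that("simulate_patient exposes the per-patient view consistently", {
  cfg <- sim_config(n_patients = 5, seed = 71)
  coh <- simulate_cohort(cfg)
  p3 <- simulate_patient(cfg, 3)
  expect_identical(p3$truth$coalesced,
                   coh$truth$coalesced[coh$truth$patient_id == "P003"])
  expect_identical(p3$outcome$recovery_day,
                   coh$outcomes$recovery_day[coh$outcomes$patient_id == "P003"])
  in_cohort <- coh$table$counts[coh$table$samples$patient_id == "P003", ]
  expect_identical(unname(p3$counts), unname(in_cohort))
  expect_true(all(p3$exposures$day >= 0))
})
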