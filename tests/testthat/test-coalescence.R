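two_patient_table <- function() {
  # P1: 3 oral + 2 stool; P2: 2 oral, no stool
  make_table(matrix(rpois(7 * 5, 10) + 1, 7, 5),
             patient_id = c(rep("P1", 5), rep("P2", 2)),
             site = c("oral", "oral", "oral", "stool", "stool", "oral", "oral"),
             day = c(0, 3, 7, 0, 7, 0, 3))
}

test_that("intra_patient_pairs enumerates all cross-site pairs with matrix lookups", {
  set.seed(41)
  tab <- two_patient_table()
  d <- bray_curtis(tab)
  pairs <- intra_patient_pairs(tab, d)
  expect_equal(nrow(pairs), 3 * 2)
  expect_true(all(pairs$patient_id == "P1"))
  expect_identical(attr(pairs, "no_pairs"), "P2")
  for (r in seq_len(nrow(pairs)))
    expect_equal(pairs$distance[r],
                 d[pairs$oral_sample[r], pairs$stool_sample[r]])
})


test_that("bottom-quartile rule calls floor(n/4) patients with the smallest minima", {
  pairs <- fake_pairs(seq(0.1, 0.8, by = 0.1))
  calls <- classify_coalescence(pairs)
  expect_equal(sum(calls$coalesced), 2)
  expect_setequal(calls$patient_id[calls$coalesced], c("PT001", "PT002"))
  expect_equal(sort(calls$rank), 1:8)
  # event day = later collection day of the minimizing pair
  expect_true(all(calls$event_day == 5))
})

test_that("eligibility requires at least min_pairs pairs and >= 4 eligible patients", {
  pairs <- fake_pairs(seq(0.1, 0.8, by = 0.1))
  # strip one patient down to 2 pairs -> ineligible
  pairs <- pairs[!(pairs$patient_id == "PT001" &
                     pairs$stool_sample == "PT001_S3"), ]
  calls <- classify_coalescence(pairs, min_pairs = 3)
  expect_false(calls$eligible[calls$patient_id == "PT001"])
  expect_match(calls$exclusion_reason[calls$patient_id == "PT001"], "2 oral-stool")
  expect_equal(sum(calls$eligible), 7)
  expect_equal(sum(calls$coalesced), 1)      # floor(7/4)

  few <- fake_pairs(c(0.1, 0.2, 0.3))
  expect_error(classify_coalescence(few), "quartile undefined")
})

test_that("classification is invariant to patient input order and ties break deterministically", {
  pairs <- fake_pairs(c(0.3, 0.1, 0.1, 0.5, 0.2, 0.6, 0.7, 0.4),
                      event_days = c(5, 9, 7, 5, 5, 5, 5, 5))
  calls1 <- classify_coalescence(pairs)
  shuffled <- pairs[rev(seq_len(nrow(pairs))), ]
  calls2 <- classify_coalescence(shuffled)
  expect_identical(calls1, calls2)
  # tie at 0.1 between PT002 (event day 9) and PT003 (event day 7):
  # earlier event day ranks first
  expect_equal(calls1$rank[calls1$patient_id == "PT003"], 1)
  expect_equal(calls1$rank[calls1$patient_id == "PT002"], 2)
})

test_that("shared/unique OTU ratio follows the set arithmetic", {
  # oral {A,B,C}, stool {B,C,D,E} -> shared 2, unique 3
  cnt <- rbind(c(1, 1, 1, 0, 0), c(0, 1, 1, 1, 1))
  tab <- make_table(cnt, c("P1", "P1"), c("oral", "stool"), c(4, 5))
  r <- shared_unique_ratio(tab)
  expect_equal(r$shared, 2)
  expect_equal(r$unique, 3)
  expect_equal(r$ratio, 2 / 3)
  expect_equal(r$day, 5)

  # identical presence sets -> undefined
  tab2 <- make_table(rbind(c(2, 3, 0), c(5, 1, 0)), c("P1", "P1"),
                     c("oral", "stool"), c(0, 0))
  r2 <- shared_unique_ratio(tab2)
  expect_true(r2$undefined)
  expect_true(is.na(r2$ratio))

  # disjoint sets -> ratio 0
  tab3 <- make_table(rbind(c(2, 0), c(0, 5)), c("P1", "P1"),
                     c("oral", "stool"), c(0, 2))
  expect_equal(shared_unique_ratio(tab3)$ratio, 0)

  # matching window: stool day 10 with nearest oral at day 6 is out of reach
  tab4 <- make_table(rbind(c(1, 1), c(1, 1)), c("P1", "P1"),
                     c("oral", "stool"), c(6, 10))
  expect_equal(nrow(shared_unique_ratio(tab4, window = 3)), 0)
  expect_equal(nrow(shared_unique_ratio(tab4, window = 4)), 1)
})

test_that("domination events use a strict 30% genus threshold", {
  cnt <- rbind(c(30, 70, 0),    # GenB 0.70 dominates; GenA exactly 0.30 does not
               c(52, 16, 32))   # GenA 0.52 and GenC 0.32 dominate
  tab <- make_table(cnt, c("P1", "P1"), c("oral", "stool"), c(7, 10))
  taxa <- taxonomy_map(colnames(tab$counts),
                       c("B;F;C;O;Fa;GenA", "B;F;C;O;Fa;GenB", "B;F;C;O;Fa;GenC"))
  ev <- detect_dominations(tab, taxa)
  expect_equal(nrow(ev), 3)
  expect_false(any(ev$genus == "GenA" & ev$site == "oral"))  # 0.30 exactly
  expect_true(all(ev$relative_abundance > 0.30))

  # a sample can host at most 3 events (abundances sum to 1)
  expect_lte(max(table(ev$sample_id)), 3)

  # concordant domination needs the same genus at both sites of one patient
  cnt2 <- rbind(c(52, 48, 0), c(61, 5, 34))
  tab2 <- make_table(cnt2, c("P1", "P1"), c("oral", "stool"), c(7, 10))
  conc <- concordant_dominations(detect_dominations(tab2, taxa))
  expect_equal(conc, data.frame(patient_id = "P1", genus = "GenA"))
})

test_that("oral taxa site-comparison records are complete bookkeeping", {
  cfg <- sim_config(n_patients = 12, seed = 8)
  coh <- simulate_cohort(cfg)
  calls <- cohort_min_distance_calls(coh)
  expect_warning(
    rec <- oral_taxa_site_comparison(coh$table, coh$taxonomy,
                                     c("Streptococcus", "NotAGenus"), calls),
    "NotAGenus")
  expect_true(all(rec$genus == "Streptococcus"))
  expect_lte(max(rec$timepoint), 4)
  # records <= patients x sites x timepoints, minus missing
  expect_lte(nrow(rec), 12 * 2 * 4)
  expect_true(all(rec$abundance >= 0 & rec$abundance <= 1))
})

test_that("site-effect test is calibrated under an equal-abundance null", {
  # synthetic coalesced patients with no oral/stool difference: the site
  # effect should be non-significant at alpha = 0.05 in >= 90% of replicates
  set.seed(55)
  p_vals <- replicate(40, {
    n_pat <- 25
    rec <- expand.grid(patient_id = sprintf("P%02d", 1:n_pat),
                       site = c("oral", "stool"), timepoint = 1:4,
                       stringsAsFactors = FALSE)
    u <- stats::rnorm(n_pat, 0, 0.05)
    rec$genus <- "Streptococcus"
    rec$coalesced <- TRUE
    rec$abundance <- stats::plogis(stats::qlogis(0.2) +
      u[match(rec$patient_id, sprintf("P%02d", 1:n_pat))] +
      stats::rnorm(nrow(rec), 0, 0.3))
    site_effect_tests(rec)$p
  })
  expect_gte(mean(p_vals > 0.05), 0.9)
})

test_that("classifier minima separate true coalescers on the synthetic cohort", {
  cfg <- sim_config(n_patients = 40, seed = 23)
  coh <- simulate_cohort(cfg)
  calls <- cohort_min_distance_calls(coh)
  tr <- coh$truth[match(calls$patient_id, coh$truth$patient_id), ]
  expect_gt(median(calls$min_distance[!tr$coalesced]),
            median(calls$min_distance[tr$coalesced]))
})
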