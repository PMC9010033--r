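# Fixtures and independent reference implementations used as oracles.
# These deliberately avoid the package's computational paths: distances are
# recomputed pair-by-pair from the definitions, UniFrac walks the tree with
# phangorn::Descendants, and the Cox partial likelihood is enumerated
# directly from its formula.

make_table <- function(counts, patient_id, site, day, ids = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  otu_table(counts, data.frame(sample_id = ids, patient_id = patient_id,
                               site = site, day = day,
                               stringsAsFactors = FALSE))
}

random_site_table <- function(n_samples, n_otus, seed, depth = 200) {
  set.seed(seed)
  counts <- t(stats::rmultinom(n_samples, depth,
                               stats::rgamma(n_otus, 0.6) + 1e-8))
  colnames(counts) <- sprintf("OTU_%04d", seq_len(n_otus))
  make_table(counts,
             patient_id = sprintf("P%02d", rep(1, n_samples)),
             site = rep(c("oral", "stool"), length.out = n_samples),
             day = seq_len(n_samples))
}

naive_bray_curtis <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# Per-pair UniFrac straight from the definition: enumerate each branch, find
# its descendant tips via phangorn, and accumulate shared/unique length.
naive_unifrac_pair <- function(x, y, tree, weighted) {
  px <- x / sum(x)
  py <- y / sum(y)
  tipnames <- tree$tip.label
  num <- 0
  den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    tips <- if (child <= length(tipnames)) child else
      phangorn::Descendants(tree, child, type = "tips")[[1]]
    lab <- tipnames[tips]
    a <- sum(px[lab], na.rm = TRUE)
    b <- sum(py[lab], na.rm = TRUE)
    l <- tree$edge.length[e]
    if (weighted) {
      num <- num + l * abs(a - b)
      den <- den + l * (a + b)
    } else {
      pa <- a > 0; pb <- b > 0
      if (pa || pb) {
        den <- den + l
        if (xor(pa, pb)) num <- num + l
      }
    }
  }
  if (den > 0) num / den else 0
}

naive_unifrac_matrix <- function(table, tree, weighted) {
  cnt <- table$counts
  n <- nrow(cnt)
  d <- matrix(0, n, n, dimnames = list(rownames(cnt), rownames(cnt)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- cnt[i, ]; y <- cnt[j, ]
    names(x) <- names(y) <- colnames(cnt)
    d[i, j] <- d[j, i] <- naive_unifrac_pair(x, y, tree, weighted)
  }
  d
}

# Breslow partial log-likelihood enumerated directly from the counting
# process: risk at event time t iff start < t <= stop.
naive_cox_loglik <- function(beta, cp, covariate) {
  x <- cp[[covariate]]
  ll <- 0
  for (t in sort(unique(cp$stop[cp$event]))) {
    at_risk <- cp$start < t & t <= cp$stop
    deaths <- cp$event & cp$stop == t
    ll <- ll + beta * sum(x[deaths]) -
      sum(deaths) * log(sum(exp(beta * x[at_risk])))
  }
  ll
}

# Six-patient hand-built counting-process table with 2 events; cumulative
# exposure paths written out explicitly.
hand_cp_table <- function() {
  rows <- list(
    # patient A: exposed from day 2, event at day 6
    data.frame(patient_id = "A", start = c(0, 2, 3, 4, 5), stop = c(2, 3, 4, 5, 6),
               event = c(FALSE, FALSE, FALSE, FALSE, TRUE), drug = c(0, 0, 1, 2, 3)),
    # patient B: never exposed, event at day 4
    data.frame(patient_id = "B", start = 0, stop = 4, event = TRUE, drug = 0),
    # patient C: exposed from day 1, censored at day 8
    data.frame(patient_id = "C", start = c(0, 1, 2, 3, 4, 5, 6, 7),
               stop = c(1, 2, 3, 4, 5, 6, 7, 8), event = FALSE,
               drug = c(0, 0, 1, 2, 3, 4, 5, 6)),
    # patient D: never exposed, censored day 7
    data.frame(patient_id = "D", start = 0, stop = 7, event = FALSE, drug = 0),
    # patient E: exposed days 0-1 only, censored day 6
    data.frame(patient_id = "E", start = c(0, 1, 2), stop = c(1, 2, 6),
               event = FALSE, drug = c(0, 1, 2)),
    # patient F: exposed from day 3, censored day 9
    data.frame(patient_id = "F", start = c(0, 4, 5, 6, 7, 8),
               stop = c(4, 5, 6, 7, 8, 9), event = FALSE,
               drug = c(0, 1, 2, 3, 4, 5)))
  cp <- do.call(rbind, rows)
  rownames(cp) <- NULL
  class(cp) <- c("counting_process", "data.frame")
  cp
}

# Distances between per-patient oral/stool pairs for a simulated cohort,
# computed patient-by-patient (the cross-site blocks are all the classifier
# consumes).
cohort_min_distance_calls <- function(cohort, weighted = TRUE) {
  pairs <- do.call(rbind, lapply(unique(cohort$table$samples$patient_id),
    function(p) {
      sub <- subset_samples(cohort$table, cohort$table$samples$patient_id == p)
      intra_patient_pairs(sub, unifrac(sub, cohort$tree, weighted = weighted))
    }))
  classify_coalescence(pairs)
}

# Synthetic per-patient pair lists with prescribed minima for classifier tests.
fake_pairs <- function(minima, n_pairs = 3, event_days = NULL) {
  # one synthetic patient per minimum; extra pairs have larger distances
  rows <- lapply(seq_along(minima), function(i) {
    ds <- c(minima[i], minima[i] + 0.2, minima[i] + 0.3)[seq_len(n_pairs)]
    ev <- if (is.null(event_days)) 5 else event_days[i]
    data.frame(patient_id = sprintf("PT%03d", i),
               oral_sample = sprintf("PT%03d_O%d", i, seq_len(n_pairs)),
               stool_sample = sprintf("PT%03d_S%d", i, seq_len(n_pairs)),
               oral_day = ev, stool_day = c(ev, ev + 3, ev + 6)[seq_len(n_pairs)],
               distance = ds, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
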