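#' Configuration for the synthetic longitudinal cohort
#'
#' The generator is a stand-in for the study cohort, not a fitted model: it
#' emulates the data structure (two body-site communities with a shared taxa
#' pool, twice-weekly sampling to neutrophil recovery, antibiotic-driven
#' convergence of stool toward oral composition in a subset of patients,
#' domination events, infections associated with coalescence) with simple,
#' clearly labelled distributional choices.
#'
#' Coalescence onset is a daily Bernoulli event with probability
#' `1 - exp(-h_t)` where `log h_t = log(baseline_daily_hazard) +
#' sum_d beta_d * x_d(t)` and `x_d(t)` is the cumulative number of therapy
#' days of drug `d` before day `t` — exactly the covariate the cumulative
#' time-varying Cox encoding reconstructs. After onset, the stool target
#' composition is the convex mixture `(1 - w_t) * gut + w_t * oral` with
#' `w_t = min(max_mix, coalescence_mix_rate * days_since_onset)`.
#'
#' @param n_patients cohort size
#' @param n_oral_taxa,n_gut_taxa,n_shared_taxa sizes of the site-specific and
#'   shared taxa pools
#' @param depth_mean expected reads per sample (Poisson)
#' @param sampling_interval_days days between samples (default 3,
#'   approximating twice-weekly collection)
#' @param recovery_day_range inclusive integer range for the neutrophil
#'   recovery day (default 18..35, bracketing the 22-day median time to
#'   maximal coalescence)
#' @param dirichlet_concentration total Dirichlet concentration of
#'   patient-level base compositions around the site mean profiles: patient
#'   profiles are drawn from `Dirichlet(theta * m_site)`. Small values give
#'   idiosyncratic patients; the default (3) keeps the major site taxa shared
#'   across patients so pooled samples cluster by body site
#' @param taxa_mean_decay exponential decay of the within-pool site mean
#'   profile; together with `dirichlet_concentration` calibrated to the
#'   cohort's printed anchors (median Shannon ~1.8, frequent >30% genus
#'   dominations, pooled body-site PERMANOVA R^2 near 0.1)
#' @param shared_mass_oral,shared_mass_gut expected fraction of each site's
#'   reads carried by the patient's common shared-taxa profile; this overlap
#'   sets the baseline oral-stool distance scale (defaults chosen so the
#'   per-patient minimum weighted UniFrac in non-coalescing patients sits
#'   near the cohort's printed median of ~0.4)
#' @param sample_overdispersion concentration of per-sample Dirichlet noise
#'   around the day's target composition
#' @param coalescence_mix_rate daily increment of the oral mixing weight
#' @param max_mix cap on the mixing weight
#' @param drug_log_hazards named numeric: per-cumulative-therapy-day log
#'   hazard ratio for each drug; defaults are the study's per-day estimates
#'   (levofloxacin 0.75, cefepime 1.10, meropenem 1.13, linezolid 1.15,
#'   metronidazole 1.13)
#' @param baseline_daily_hazard baseline daily coalescence hazard
#' @param exposure_pattern `"clinical"` (prophylaxis from day 0 switching to
#'   escalation drugs at a random fever day) or `"staggered"` (each drug
#'   starts at a uniform random day and continues; used for parameter
#'   recovery studies where covariate variation must be guaranteed)
#' @param stagger_start_range start-day range for `"staggered"`
#' @param fever_prob,fever_day_range neutropenic-fever model for `"clinical"`
#' @param death_prob probability of death during follow-up (independent
#'   censoring; rare by design)
#' @param infection_baseline_pre,infection_baseline_post infection
#'   probability for non-coalesced patients in each window
#' @param infection_odds_ratio_pre,infection_odds_ratio_post odds multipliers
#'   for coalesced patients (defaults are the study's estimates 4.93, 2.72)
#' @param seed integer master seed (< 2^31)
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_patients = 100,
                       n_oral_taxa = 60, n_gut_taxa = 80, n_shared_taxa = 40,
                       depth_mean = 5000,
                       sampling_interval_days = 3,
                       recovery_day_range = c(18, 35),
                       dirichlet_concentration = 3,
                       taxa_mean_decay = 0.25,
                       shared_mass_oral = 0.5, shared_mass_gut = 0.45,
                       sample_overdispersion = 50,
                       coalescence_mix_rate = 0.15,
                       max_mix = 0.95,
                       drug_log_hazards = c(levofloxacin = log(0.75),
                                            cefepime = log(1.10),
                                            meropenem = log(1.13),
                                            linezolid = log(1.15),
                                            metronidazole = log(1.13)),
                       baseline_daily_hazard = 0.006,
                       exposure_pattern = c("clinical", "staggered"),
                       stagger_start_range = c(0, 10),
                       fever_prob = 0.7, fever_day_range = c(2, 10),
                       death_prob = 0.02,
                       infection_baseline_pre = 0.25,
                       infection_baseline_post = 0.20,
                       infection_odds_ratio_pre = 4.93,
                       infection_odds_ratio_post = 2.72,
                       seed = 1) {
  exposure_pattern <- match.arg(exposure_pattern)
  cfg <- as.list(environment())
  counts <- c("n_patients", "n_oral_taxa", "n_gut_taxa", "n_shared_taxa")
  for (nm in counts)
    if (length(cfg[[nm]]) != 1 || cfg[[nm]] < 1 || cfg[[nm]] != round(cfg[[nm]]))
      stop(nm, " must be an integer >= 1")
  probs <- c("coalescence_mix_rate", "max_mix", "fever_prob", "death_prob",
             "infection_baseline_pre", "infection_baseline_post",
             "baseline_daily_hazard")
  for (nm in probs)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1) stop(nm, " must be in [0, 1]")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (dirichlet_concentration <= 0) stop("dirichlet_concentration must be > 0")
  if (taxa_mean_decay < 0) stop("taxa_mean_decay must be >= 0")
  if (sampling_interval_days < 1) stop("sampling_interval_days must be >= 1")
  if (infection_odds_ratio_pre <= 0 || infection_odds_ratio_post <= 0)
    stop("infection odds ratios must be > 0")
  if (is.null(names(drug_log_hazards)) || any(names(drug_log_hazards) == ""))
    stop("drug_log_hazards must be a named vector")
  if (diff(recovery_day_range) < 0 || recovery_day_range[1] < 1)
    stop("invalid recovery_day_range")
  if (abs(seed) >= 2^31) stop("seed must be < 2^31 in magnitude")
  structure(cfg, class = "sim_config")
}

patient_seed <- function(config, patient_index) {
  (abs(config$seed) * 48271 + patient_index * 69621) %% 2147483399 + 1
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a random rooted phylogeny for the synthetic taxa
#'
#' Random bifurcating topology (ape's `rtree`) with exponential branch
#' lengths and tip labels `OTU_0001..OTU_nnnn`.
#'
#' @param n_taxa number of tips (>= 2)
#' @param seed integer seed
#' @return rooted `phylo` with `n_taxa` tips and positive branch lengths
#' @export
simulate_tree <- function(n_taxa, seed = 1) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(seed %% 2147483647)
  tree <- ape::rtree(n_taxa, br = function(n) stats::rexp(n, rate = 10) + 1e-6)
  tree$tip.label <- sprintf("OTU_%04d", seq_len(n_taxa))
  tree
}

# Taxa pool bookkeeping: which OTU ids belong to the oral, shared and gut
# pools, plus a plausible (synthetic) genus assignment per OTU.
taxa_pools <- function(config) {
  n <- config$n_oral_taxa + config$n_shared_taxa + config$n_gut_taxa
  ids <- sprintf("OTU_%04d", seq_len(n))
  oral <- ids[seq_len(config$n_oral_taxa)]
  shared <- ids[config$n_oral_taxa + seq_len(config$n_shared_taxa)]
  gut <- ids[config$n_oral_taxa + config$n_shared_taxa + seq_len(config$n_gut_taxa)]
  oral_genera <- c("Streptococcus", "Stenotrophomonas", "Veillonella",
                   "Neisseria", "Actinomyces", "Rothia", "Haemophilus",
                   "Leptotrichia")
  shared_genera <- c("Streptococcus", "Staphylococcus", "Enterococcus",
                     "Lactobacillus", "Fusobacterium")
  gut_genera <- c("Bacteroides", "Blautia", "Faecalibacterium", "Clostridium",
                  "Escherichia", "Roseburia", "Bifidobacterium", "Akkermansia")
  genus <- character(n)
  names(genus) <- ids
  genus[oral] <- rep_len(oral_genera, length(oral))
  genus[shared] <- rep_len(shared_genera, length(shared))
  genus[gut] <- rep_len(gut_genera, length(gut))
  lineages <- c(
    Streptococcus = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Streptococcaceae;Streptococcus",
    Stenotrophomonas = "Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales;Xanthomonadaceae;Stenotrophomonas",
    Veillonella = "Bacteria;Firmicutes;Negativicutes;Veillonellales;Veillonellaceae;Veillonella",
    Neisseria = "Bacteria;Proteobacteria;Betaproteobacteria;Neisseriales;Neisseriaceae;Neisseria",
    Actinomyces = "Bacteria;Actinobacteria;Actinobacteria;Actinomycetales;Actinomycetaceae;Actinomyces",
    Rothia = "Bacteria;Actinobacteria;Actinobacteria;Micrococcales;Micrococcaceae;Rothia",
    Haemophilus = "Bacteria;Proteobacteria;Gammaproteobacteria;Pasteurellales;Pasteurellaceae;Haemophilus",
    Leptotrichia = "Bacteria;Fusobacteria;Fusobacteriia;Fusobacteriales;Leptotrichiaceae;Leptotrichia",
    Staphylococcus = "Bacteria;Firmicutes;Bacilli;Bacillales;Staphylococcaceae;Staphylococcus",
    Enterococcus = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Enterococcaceae;Enterococcus",
    Lactobacillus = "Bacteria;Firmicutes;Bacilli;Lactobacillales;Lactobacillaceae;Lactobacillus",
    Fusobacterium = "Bacteria;Fusobacteria;Fusobacteriia;Fusobacteriales;Fusobacteriaceae;Fusobacterium",
    Bacteroides = "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Bacteroidaceae;Bacteroides",
    Blautia = "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Blautia",
    Faecalibacterium = "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Faecalibacterium",
    Clostridium = "Bacteria;Firmicutes;Clostridia;Clostridiales;Clostridiaceae;Clostridium",
    Escherichia = "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia",
    Roseburia = "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Roseburia",
    Bifidobacterium = "Bacteria;Actinobacteria;Actinobacteria;Bifidobacteriales;Bifidobacteriaceae;Bifidobacterium",
    Akkermansia = "Bacteria;Verrucomicrobia;Verrucomicrobiae;Verrucomicrobiales;Akkermansiaceae;Akkermansia")
  list(ids = ids, oral = oral, shared = shared, gut = gut, genus = genus,
       taxonomy = taxonomy_map(ids, unname(lineages[genus])))
}

# Therapy-day schedule for one patient: list(drug = chr, day = int), 0-based
# days. Plain vectors, not a data.frame: this sits in the hot loop of
# cohort-scale parameter-recovery simulations.
simulate_exposure_schedule <- function(config, t_end, fever, fever_day) {
  drugs <- names(config$drug_log_hazards)
  sdrug <- character(0); sday <- integer(0)
  add <- function(drug, days) {
    days <- days[days >= 0 & days < t_end]
    if (length(days) > 0) {
      sdrug <<- c(sdrug, rep(drug, length(days)))
      sday <<- c(sday, as.integer(days))
    }
  }
  if (config$exposure_pattern == "staggered") {
    for (dr in drugs) {
      s <- sample(config$stagger_start_range[1]:config$stagger_start_range[2], 1)
      add(dr, s:(t_end - 1))
    }
  } else {
    prophylaxis <- drugs[1]
    stop_proph <- if (fever) fever_day - 1 else t_end - 1
    add(prophylaxis, 0:stop_proph)
    if (fever && length(drugs) > 1) {
      escal <- drugs[-1]
      # first-line empiric agent runs from fever onward
      add(escal[1], fever_day:(t_end - 1))
      for (dr in escal[-1]) {
        if (stats::runif(1) < 0.45) {
          s <- fever_day + sample(2:6, 1)
          add(dr, s:min(s + sample(5:12, 1), t_end - 1))
        }
      }
    }
  }
  list(drug = sdrug, day = sday)
}

# Daily-hazard onset draw. exposure_by_day: days x drugs 0/1 matrix whose row
# i is therapy on calendar day i-1. The hazard of risk interval (t-1, t]
# (t = 1..t_end) uses the cumulative therapy days 0..t-1 — identical to the
# cumulative covariate build_counting_process() reconstructs, so Cox fits on
# simulated cohorts estimate exactly the generating log hazard ratios.
simulate_onset <- function(config, exposure_by_day, t_end) {
  betas <- config$drug_log_hazards
  if (t_end < 1) return(NA_integer_)
  cum <- apply(exposure_by_day, 2, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  cum <- cum[seq_len(t_end), , drop = FALSE]
  log_h <- log(config$baseline_daily_hazard) +
    as.vector(cum %*% betas[colnames(exposure_by_day)])
  p <- 1 - exp(-exp(log_h))
  hit <- stats::runif(t_end) < p
  if (any(hit)) which(hit)[1] else NA_integer_
}

#' Simulate one synthetic patient
#'
#' Draws follow-up and censoring times, an antibiotic schedule, the daily
#' coalescence-onset process driven by cumulative exposure, longitudinal
#' oral/stool compositions (stool mixes toward oral after onset), multinomial
#' read counts, and infection labels whose odds depend on the true
#' coalescence flag. Reproducible: the patient's RNG stream is derived from
#' `config$seed` and `patient_index`.
#'
#' @param config a `sim_config`
#' @param patient_index positive integer
#' @param pools taxa pools from the internal pool builder; built from
#'   `config` when omitted
#' @param counts generate read counts (set `FALSE` for event-process-only
#'   studies such as hazard-recovery simulations)
#' @return list with `samples` (data.frame sample_id/patient_id/site/day),
#'   `counts` (matrix, `NULL` when `counts = FALSE`), `exposures`
#'   (drug/day rows), `outcome` (one-row data.frame) and `truth` (one-row
#'   data.frame: `coalesced`, `onset_day`, `recovery_day`, `death_day`,
#'   `fever_day`, `infection_pre`, `infection_post90`)
#' @export
simulate_patient <- function(config, patient_index, pools = NULL,
                             counts = TRUE) {
  core <- sim_patient_core(config, patient_index, pools, counts)
  sched <- core$sched
  list(samples = core$samples, counts = core$counts,
       exposures = if (length(sched$day) > 0)
         data.frame(patient_id = core$pid, drug = sched$drug, day = sched$day,
                    stringsAsFactors = FALSE)
       else data.frame(patient_id = character(0), drug = character(0),
                       day = integer(0)),
       outcome = data.frame(patient_id = core$pid, recovery_day = core$recovery,
                            death_day = core$death,
                            infection_pre = core$infection_pre,
                            infection_post90 = core$infection_post,
                            stringsAsFactors = FALSE),
       truth = data.frame(patient_id = core$pid, coalesced = core$coalesced,
                          onset_day = core$onset, recovery_day = core$recovery,
                          death_day = core$death, fever_day = core$fever_day,
                          infection_pre = core$infection_pre,
                          infection_post90 = core$infection_post,
                          stringsAsFactors = FALSE))
}

sim_patient_core <- function(config, patient_index, pools = NULL,
                             counts = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (counts && is.null(pools)) pools <- taxa_pools(config)
  set.seed(patient_seed(config, patient_index))
  pid <- sprintf("P%03d", patient_index)

  recovery <- sample(config$recovery_day_range[1]:config$recovery_day_range[2], 1)
  death <- if (stats::runif(1) < config$death_prob)
    sample(5:recovery, 1) else NA_integer_
  t_end <- min(recovery, death, na.rm = TRUE)
  fever <- stats::runif(1) < config$fever_prob
  fever_day <- min(sample(config$fever_day_range[1]:config$fever_day_range[2], 1),
                   max(t_end - 1, 1))

  sched <- simulate_exposure_schedule(config, t_end, fever, fever_day)
  drugs <- names(config$drug_log_hazards)
  expo <- matrix(0L, nrow = t_end, ncol = length(drugs),
                 dimnames = list(NULL, drugs))
  if (length(sched$day) > 0)
    expo[cbind(sched$day + 1L, match(sched$drug, drugs))] <- 1L
  # onset must precede censoring strictly (an onset on the recovery/death day
  # itself is unobservable and not a coalescence episode)
  onset <- simulate_onset(config, expo, t_end - 1L)
  coalesced <- !is.na(onset)

  p_pre <- stats::plogis(stats::qlogis(config$infection_baseline_pre) +
                           log(config$infection_odds_ratio_pre) * coalesced)
  p_post <- stats::plogis(stats::qlogis(config$infection_baseline_post) +
                            log(config$infection_odds_ratio_post) * coalesced)
  infection_pre <- stats::runif(1) < p_pre
  infection_post <- stats::runif(1) < p_post

  samples <- NULL
  cnt <- NULL
  if (counts) {
    sample_days <- seq(0, t_end, by = config$sampling_interval_days)
    samples <- data.frame(
      sample_id = c(sprintf("%s_O%02d", pid, seq_along(sample_days)),
                    sprintf("%s_S%02d", pid, seq_along(sample_days))),
      patient_id = pid,
      site = rep(c("oral", "stool"), each = length(sample_days)),
      day = rep(sample_days, 2), stringsAsFactors = FALSE)
    n_taxa <- length(pools$ids)
    theta <- config$dirichlet_concentration
    decay <- config$taxa_mean_decay
    # each site = site-specific profile + the patient's common shared-taxa
    # profile; profiles are Dirichlet draws around fixed site mean profiles
    # (exponentially decaying ranks), so the major taxa of each site recur
    # across patients and pooled samples cluster by body site, while the
    # shared mass ties a patient's two communities together
    mean_prof <- function(k) {
      w <- exp(-decay * (seq_len(k) - 1))
      w / sum(w)
    }
    oral_base <- numeric(n_taxa); names(oral_base) <- pools$ids
    gut_base <- numeric(n_taxa); names(gut_base) <- pools$ids
    shared_prof <- rdirichlet1(theta * mean_prof(length(pools$shared)))
    oral_base[pools$oral] <- (1 - config$shared_mass_oral) *
      rdirichlet1(theta * mean_prof(length(pools$oral)))
    oral_base[pools$shared] <- config$shared_mass_oral * shared_prof
    gut_base[pools$gut] <- (1 - config$shared_mass_gut) *
      rdirichlet1(theta * mean_prof(length(pools$gut)))
    gut_base[pools$shared] <- config$shared_mass_gut * shared_prof
    cnt <- matrix(0, nrow(samples), n_taxa,
                  dimnames = list(samples$sample_id, pools$ids))
    for (r in seq_len(nrow(samples))) {
      day <- samples$day[r]
      target <- if (samples$site[r] == "oral") oral_base else {
        if (coalesced && day >= onset) {
          w <- min(config$max_mix, config$coalescence_mix_rate * (day - onset + 1))
          (1 - w) * gut_base + w * oral_base
        } else gut_base
      }
      comp <- numeric(n_taxa)
      nz <- target > 0
      comp[nz] <- rdirichlet1(config$sample_overdispersion * target[nz])
      depth <- max(1L, stats::rpois(1, config$depth_mean))
      cnt[r, ] <- stats::rmultinom(1, depth, comp)
    }
  }

  list(pid = pid, samples = samples, counts = cnt, sched = sched,
       recovery = recovery, death = death,
       fever_day = if (fever) fever_day else NA_integer_,
       onset = onset, coalesced = coalesced,
       infection_pre = infection_pre, infection_post = infection_post)
}

#' Simulate a complete synthetic cohort
#'
#' @param config a `sim_config`
#' @param counts generate read counts and the tree/taxonomy (default `TRUE`);
#'   with `FALSE` only exposures, outcomes and ground truth are produced
#'   (fast path for parameter-recovery studies)
#' @return list of class `sim_cohort`: `table` (an [otu_table()] or `NULL`),
#'   `tree`, `taxonomy`, `exposures` (an `exposure_ledger`), `outcomes`
#'   (an `outcome_table`), `truth` (per-patient ground-truth data.frame),
#'   `config`
#' @export
simulate_cohort <- function(config, counts = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  pools <- NULL; tree <- NULL
  if (counts) {
    pools <- taxa_pools(config)
    tree <- simulate_tree(length(pools$ids), seed = config$seed)
  }
  patients <- lapply(seq_len(config$n_patients), function(i)
    sim_patient_core(config, i, pools = pools, counts = counts))
  n_exp <- vapply(patients, function(p) length(p$sched$day), integer(1))
  exposures <- exposure_ledger(data.frame(
    patient_id = rep(vapply(patients, `[[`, "", "pid"), n_exp),
    drug = unlist(lapply(patients, function(p) p$sched$drug)),
    day = unlist(lapply(patients, function(p) p$sched$day)),
    stringsAsFactors = FALSE))
  grab_int <- function(field) as.integer(vapply(patients, function(p)
    as.numeric(p[[field]]), numeric(1)))
  grab_lgl <- function(field) vapply(patients, function(p)
    as.logical(p[[field]]), logical(1))
  pid <- vapply(patients, `[[`, "", "pid")
  outcomes <- outcome_table(data.frame(
    patient_id = pid, recovery_day = grab_int("recovery"),
    death_day = grab_int("death"), infection_pre = grab_lgl("infection_pre"),
    infection_post90 = grab_lgl("infection_post"), stringsAsFactors = FALSE))
  truth <- data.frame(
    patient_id = pid, coalesced = grab_lgl("coalesced"),
    onset_day = grab_int("onset"), recovery_day = grab_int("recovery"),
    death_day = grab_int("death"), fever_day = grab_int("fever_day"),
    infection_pre = grab_lgl("infection_pre"),
    infection_post90 = grab_lgl("infection_post"), stringsAsFactors = FALSE)
  table <- NULL
  if (counts) {
    cnt <- do.call(rbind, lapply(patients, `[[`, "counts"))
    samp <- do.call(rbind, lapply(patients, `[[`, "samples"))
    table <- otu_table(cnt, samp)
  }
  structure(list(table = table, tree = tree,
                 taxonomy = if (counts) pools$taxonomy else NULL,
                 exposures = exposures, outcomes = outcomes, truth = truth,
                 config = config),
            class = "sim_cohort")
}

#' Write a simulated cohort to a directory
#'
#' Emits the package's interchange files: `otu_table.tsv`, `taxonomy.tsv`,
#' `tree.nwk`, `samples.tsv`, `exposures.tsv`, `outcomes.tsv` and
#' `truth.json`; all round-trip losslessly through the readers.
#'
#' @param cohort a `sim_cohort` generated with `counts = TRUE`
#' @param out_dir output directory (created if needed)
#' @return character vector of the file paths, invisibly
#' @export
write_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (is.null(cohort$table))
    stop("cohort was simulated without counts; nothing to write")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create directory ", out_dir)
  paths <- file.path(out_dir, c("otu_table.tsv", "taxonomy.tsv", "tree.nwk",
                                "samples.tsv", "exposures.tsv", "outcomes.tsv",
                                "truth.json"))
  names(paths) <- c("otu_table", "taxonomy", "tree", "samples", "exposures",
                    "outcomes", "truth")
  write_otu_table(cohort$table, paths["otu_table"])
  write_taxonomy(cohort$taxonomy, paths["taxonomy"])
  write_tree(cohort$tree, paths["tree"])
  utils::write.table(cohort$table$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_exposures(cohort$exposures, paths["exposures"])
  write_outcomes(cohort$outcomes, paths["outcomes"])
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "rows",
                       na = "null", digits = NA)
  invisible(paths)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir directory containing the interchange files
#' @return list with `table`, `tree`, `taxonomy`, `exposures`, `outcomes`,
#'   and `truth` (if `truth.json` is present)
#' @export
read_cohort <- function(dir) {
  out <- list(table = read_otu_table(file.path(dir, "otu_table.tsv")),
              tree = read_tree(file.path(dir, "tree.nwk")),
              taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
              exposures = read_exposures(file.path(dir, "exposures.tsv")),
              outcomes = read_outcomes(file.path(dir, "outcomes.tsv")))
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) out$truth <- jsonlite::fromJSON(tj)
  out
}

#' Area under the ROC curve of a score against binary truth
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' outranks a random negative, ties counted 1/2. Used to quantify how well
#' the per-patient minimum inter-site distance recovers ground-truth
#' coalescence (smaller distance = positive, so pass `-min_distance`).
#'
#' @param score numeric; higher = more positive
#' @param truth logical
#' @return AUC in \[0, 1\]
#' @export
auc_score <- function(score, truth) {
  stopifnot(length(score) == length(truth))
  ok <- !is.na(score) & !is.na(truth)
  score <- score[ok]; truth <- as.logical(truth[ok])
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("need both positive and negative cases")
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Hazard-ratio recovery study for the time-varying Cox engine
#'
#' Simulates independent cohorts in which coalescence onset is generated
#' under a proportional-hazards model with a single drug whose true
#' per-cumulative-therapy-day log hazard ratio is `log(true_hr)`, rebuilds
#' the counting-process table with the cumulative encoding, fits the
#' univariate time-varying Cox model, and returns the per-seed fitted HRs.
#' Drug start days are staggered uniformly so the covariate varies within
#' risk sets.
#'
#' @param true_hr generating per-day hazard ratio
#' @param n_patients patients per cohort (default 2000)
#' @param n_seeds number of independent cohorts (default 20)
#' @param seed master seed; cohort `k` uses `seed * 1000 + k`
#' @param baseline_daily_hazard baseline daily hazard (default 0.004)
#' @param recovery_day_range follow-up window (default 25..30 days)
#' @return data.frame: `seed`, `hr`, `log_hr`, `n_events`
#' @export
hazard_recovery_study <- function(true_hr, n_patients = 2000, n_seeds = 20,
                                  seed = 1, baseline_daily_hazard = 0.004,
                                  recovery_day_range = c(25, 30)) {
  rows <- lapply(seq_len(n_seeds), function(k) {
    cfg <- sim_config(n_patients = n_patients,
                      drug_log_hazards = c(drug = log(true_hr)),
                      baseline_daily_hazard = baseline_daily_hazard,
                      exposure_pattern = "staggered",
                      recovery_day_range = recovery_day_range,
                      seed = (seed * 1000 + k) %% 2147483647)
    coh <- simulate_cohort(cfg, counts = FALSE)
    ev <- data.frame(patient_id = coh$truth$patient_id,
                     event_day = coh$truth$onset_day)
    cp <- build_counting_process(coh$exposures, ev, coh$outcomes,
                                 encoding = "cumulative")
    fit <- fit_cox_tv(cp, "drug")
    data.frame(seed = k, hr = fit$hr, log_hr = fit$log_hr,
               n_events = fit$n_events)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
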