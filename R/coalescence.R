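#' All intra-patient oral x stool sample pairs with their distances
#'
#' Enumerates, for every patient, every (oral sample, stool sample) pair
#' regardless of collection day — the complete cross-site block of the
#' patient's longitudinal distance matrix — and attaches the pairwise
#' distance looked up from `d`. Patients lacking samples of one site
#' contribute no pairs and are listed in the `no_pairs` attribute.
#'
#' @param table an `otu_table`
#' @param d square `dist_matrix` covering all samples in `table`
#' @return data.frame: `patient_id`, `oral_sample`, `stool_sample`,
#'   `oral_day`, `stool_day`, `distance`; attribute `no_pairs` lists patients
#'   with zero cross-site pairs
#' @export
intra_patient_pairs <- function(table, d) {
  stopifnot(inherits(table, "otu_table"))
  ids <- table$samples$sample_id
  miss <- setdiff(ids, rownames(d))
  if (length(miss) > 0)
    stop("distance matrix missing sample(s): ", paste(miss, collapse = ", "))
  s <- table$samples
  out <- list()
  no_pairs <- character(0)
  for (p in unique(s$patient_id)) {
    oral <- s[s$patient_id == p & s$site == "oral", , drop = FALSE]
    stool <- s[s$patient_id == p & s$site == "stool", , drop = FALSE]
    if (nrow(oral) == 0 || nrow(stool) == 0) {
      no_pairs <- c(no_pairs, p)
      next
    }
    grid <- expand.grid(o = seq_len(nrow(oral)), f = seq_len(nrow(stool)))
    out[[p]] <- data.frame(
      patient_id = p,
      oral_sample = oral$sample_id[grid$o],
      stool_sample = stool$sample_id[grid$f],
      oral_day = oral$day[grid$o],
      stool_day = stool$day[grid$f],
      distance = unclass(d)[cbind(oral$sample_id[grid$o], stool$sample_id[grid$f])],
      stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(patient_id = character(0), oral_sample = character(0),
               stool_sample = character(0), oral_day = integer(0),
               stool_day = integer(0), distance = numeric(0))
  rownames(res) <- NULL
  attr(res, "no_pairs") <- no_pairs
  res
}

#' Bottom-quartile minimum-distance coalescence classifier
#'
#' The study's operational definition of oral-stool community coalescence:
#' take, per patient, the minimum distance over all intra-patient oral x
#' stool sample pairs; patients with at least `min_pairs` pairs are eligible;
#' rank eligible patients by ascending minimum distance and call the bottom
#' quartile (rank <= floor(n_eligible / 4)) coalesced. The event day is the
#' later collection day of the minimizing pair (the coalesced state exists
#' once both samples exist). Ties in the minimum distance are broken by
#' earlier event day, then lexicographic patient id, so the ranking is a
#' deterministic permutation of 1..n_eligible.
#'
#' @param pairs data.frame from [intra_patient_pairs()]
#' @param min_pairs minimum number of oral x stool pairs for eligibility
#'   (default 3: "more than two pairs")
#' @return data.frame of class `coalescence_calls`, one row per patient:
#'   `patient_id`, `n_pairs`, `eligible`, `exclusion_reason`, `min_distance`,
#'   `oral_sample`, `stool_sample`, `event_day`, `rank`, `coalesced`
#' @export
classify_coalescence <- function(pairs, min_pairs = 3) {
  pats <- unique(c(pairs$patient_id, attr(pairs, "no_pairs")))
  rows <- lapply(pats, function(p) {
    pp <- pairs[pairs$patient_id == p, , drop = FALSE]
    n <- nrow(pp)
    if (n < min_pairs)
      return(data.frame(patient_id = p, n_pairs = n, eligible = FALSE,
                        exclusion_reason = sprintf("only %d oral-stool pair(s), need >= %d", n, min_pairs),
                        min_distance = NA_real_, oral_sample = NA_character_,
                        stool_sample = NA_character_, event_day = NA_integer_,
                        stringsAsFactors = FALSE))
    ev_day <- pmax(pp$oral_day, pp$stool_day)
    # minimizing pair; among exact ties prefer earlier event day
    best <- order(pp$distance, ev_day)[1]
    data.frame(patient_id = p, n_pairs = n, eligible = TRUE,
               exclusion_reason = NA_character_,
               min_distance = pp$distance[best],
               oral_sample = pp$oral_sample[best],
               stool_sample = pp$stool_sample[best],
               event_day = as.integer(ev_day[best]),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  n_elig <- sum(calls$eligible)
  if (n_elig < 4)
    stop("bottom quartile undefined: only ", n_elig, " eligible patient(s)")
  calls$rank <- NA_integer_
  el <- which(calls$eligible)
  ord <- el[order(calls$min_distance[el], calls$event_day[el], calls$patient_id[el])]
  calls$rank[ord] <- seq_len(n_elig)
  calls$coalesced <- !is.na(calls$rank) & calls$rank <= floor(n_elig / 4)
  calls <- calls[order(calls$patient_id), , drop = FALSE]
  rownames(calls) <- NULL
  class(calls) <- c("coalescence_calls", "data.frame")
  calls
}

#' Shared-to-unique OTU ratio for matched oral/stool pairs
#'
#' For each patient, each stool sample is matched to the oral sample nearest
#' in collection day (within `window` days; exact same-day matches first,
#' ties broken toward the earlier oral day). For each matched pair the OTU
#' presence sets (count >= 1) give `shared = |oral intersect stool|` and
#' `unique = |oral symmetric-difference stool|`; `ratio = shared / unique`.
#' Pairs with `unique == 0` (identical presence sets) are kept but flagged
#' `undefined` with `ratio = NA` and should be excluded from model fits.
#'
#' @param table an `otu_table`
#' @param window maximum |oral day - stool day| for a match (default 3)
#' @return data.frame: `patient_id`, `day` (stool sample's day), `oral_sample`,
#'   `stool_sample`, `shared`, `unique`, `ratio`, `undefined`
#' @export
shared_unique_ratio <- function(table, window = 3) {
  stopifnot(inherits(table, "otu_table"))
  s <- table$samples
  pres <- table$counts >= 1
  out <- list()
  for (p in unique(s$patient_id)) {
    oral <- s[s$patient_id == p & s$site == "oral", , drop = FALSE]
    stool <- s[s$patient_id == p & s$site == "stool", , drop = FALSE]
    if (nrow(oral) == 0 || nrow(stool) == 0) next
    for (k in seq_len(nrow(stool))) {
      gap <- abs(oral$day - stool$day[k])
      if (min(gap) > window) next
      o <- order(gap, oral$day)[1]
      a <- pres[oral$sample_id[o], ]
      b <- pres[stool$sample_id[k], ]
      shared <- sum(a & b)
      uniq <- sum(xor(a, b))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = p, day = stool$day[k],
        oral_sample = oral$sample_id[o], stool_sample = stool$sample_id[k],
        shared = shared, unique = uniq,
        ratio = if (uniq > 0) shared / uniq else NA_real_,
        undefined = uniq == 0, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(patient_id = character(0), day = integer(0),
               oral_sample = character(0), stool_sample = character(0),
               shared = integer(0), unique = integer(0), ratio = numeric(0),
               undefined = logical(0))
  rownames(res) <- NULL
  res
}

#' Detect genus domination events
#'
#' A domination event is a sample in which a single genus exceeds
#' `threshold` (strictly) of the reads. Since abundances sum to one, a sample
#' can hold at most `floor(1/threshold)` events.
#'
#' @param table an `otu_table`
#' @param taxonomy taxonomy data.frame
#' @param threshold relative-abundance threshold, strict (default 0.30)
#' @return data.frame: `patient_id`, `sample_id`, `site`, `day`, `genus`,
#'   `relative_abundance`
#' @export
detect_dominations <- function(table, taxonomy, threshold = 0.30) {
  ra <- relative_abundance(table, taxonomy, level = "genus")
  hits <- which(ra > threshold, arr.ind = TRUE)
  s <- table$samples
  out <- data.frame(
    patient_id = s$patient_id[hits[, 1]],
    sample_id = s$sample_id[hits[, 1]],
    site = s$site[hits[, 1]],
    day = s$day[hits[, 1]],
    genus = colnames(ra)[hits[, 2]],
    relative_abundance = ra[hits],
    stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$day, out$sample_id, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genera dominating both body sites of the same patient
#'
#' A genus is a concordant dominator for a patient if it produced at least
#' one oral and at least one stool domination event for that patient at any
#' study day (simultaneity not required).
#'
#' @param events data.frame from [detect_dominations()]
#' @return data.frame: `patient_id`, `genus`
#' @export
concordant_dominations <- function(events) {
  key <- unique(events[, c("patient_id", "genus", "site")])
  tab <- table(paste(key$patient_id, key$genus, sep = "\r"), key$site)
  both <- rownames(tab)[rowSums(tab[, intersect(c("oral", "stool"), colnames(tab)),
                                    drop = FALSE] > 0) == 2]
  if (length(both) == 0)
    return(data.frame(patient_id = character(0), genus = character(0)))
  parts <- strsplit(both, "\r", fixed = TRUE)
  out <- data.frame(patient_id = vapply(parts, `[`, "", 1),
                    genus = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  out <- out[order(out$patient_id, out$genus), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Long-format genus abundances for repeated-measures site-effect tests
#'
#' Builds, for the listed genera, per-sample relative abundances at the first
#' `n_timepoints` sampling timepoints of each patient and site, annotated
#' with coalescence status — the input for the repeated-measures mixed model
#' that asks whether a genus' abundance differs between oral and stool.
#' Timepoints are the rank of a sample's day within its (patient, site)
#' series (1 = earliest).
#'
#' @param table an `otu_table`
#' @param taxonomy taxonomy data.frame
#' @param genera character vector of genus names; genera absent from the
#'   taxonomy are skipped with a warning
#' @param calls `coalescence_calls` from [classify_coalescence()]
#' @param n_timepoints timepoints per patient/site series to keep (default 4)
#' @return data.frame: `patient_id`, `site`, `timepoint`, `day`, `genus`,
#'   `abundance`, `coalesced`
#' @export
oral_taxa_site_comparison <- function(table, taxonomy, genera, calls,
                                      n_timepoints = 4) {
  known <- unique(taxonomy$genus[!is.na(taxonomy$genus)])
  absent <- setdiff(genera, known)
  if (length(absent) > 0) {
    warning("genus/genera absent from taxonomy, skipped: ",
            paste(absent, collapse = ", "))
    genera <- setdiff(genera, absent)
  }
  if (length(genera) == 0)
    return(data.frame(patient_id = character(0), site = character(0),
                      timepoint = integer(0), day = integer(0),
                      genus = character(0), abundance = numeric(0),
                      coalesced = logical(0)))
  ra <- relative_abundance(table, taxonomy, level = "genus")
  s <- table$samples
  tp <- stats::ave(s$day, s$patient_id, s$site, FUN = function(d) rank(d, ties.method = "first"))
  keep <- tp <= n_timepoints
  coal <- calls$coalesced[match(s$patient_id, calls$patient_id)]
  out <- do.call(rbind, lapply(genera, function(g) {
    ab <- if (g %in% colnames(ra)) ra[, g] else rep(0, nrow(ra))
    data.frame(patient_id = s$patient_id[keep], site = s$site[keep],
               timepoint = as.integer(tp[keep]), day = s$day[keep],
               genus = g, abundance = ab[keep], coalesced = coal[keep],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
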