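#' Prevalence filter for the antibiotic panel
#'
#' Keeps drugs administered (at least one therapy day) to strictly more than
#' `threshold` of the cohort, to avoid unstable effect estimates from rarely
#' used drugs.
#'
#' @param ledger an `exposure_ledger`
#' @param n_patients cohort size the proportion is computed against
#' @param threshold prevalence cutoff, strict (default 0.15)
#' @return character vector of retained drug names
#' @export
prevalence_filter <- function(ledger, n_patients, threshold = 0.15) {
  if (nrow(ledger) == 0) stop("empty exposure ledger")
  per_drug <- tapply(ledger$patient_id, ledger$drug,
                     function(p) length(unique(p)))
  sort(names(per_drug)[per_drug / n_patients > threshold])
}

#' Build a counting-process table for time-varying Cox models
#'
#' Expands each patient's risk period into `(start, stop]` intervals split at
#' every covariate change, with one covariate column per drug. The risk clock
#' is days since chemotherapy start; a patient is followed from day 0 until
#' coalescence (event) or censoring at neutrophil recovery or death,
#' whichever comes first. A therapy day `d` increments the exposure covariate
#' effective at the start of day `d + 1`, so exposure can never explain an
#' event that precedes it.
#'
#' Encodings: `"cumulative"` — running count of therapy days so far (the
#' per-additional-day model); `"any"` — indicator that switches to 1 the day
#' after the first therapy day and stays 1 (the once-exposed model).
#'
#' @param ledger an `exposure_ledger`
#' @param events either a `coalescence_calls` data.frame (eligible patients
#'   are used; `event_day` is taken where `coalesced`) or a plain data.frame
#'   with `patient_id` and `event_day` (`NA` = no event)
#' @param outcomes an `outcome_table` covering every patient in `events`
#' @param drugs drug names to encode (default: all drugs in the ledger)
#' @param encoding `"cumulative"` or `"any"`
#' @return data.frame of class `counting_process`: `patient_id`, `start`,
#'   `stop`, `event`, one column per drug; attributes `encoding` and `drugs`
#' @export
build_counting_process <- function(ledger, events, outcomes,
                                   drugs = NULL,
                                   encoding = c("cumulative", "any")) {
  encoding <- match.arg(encoding)
  if (inherits(events, "coalescence_calls")) {
    events <- events[events$eligible, , drop = FALSE]
    events <- data.frame(patient_id = events$patient_id,
                         event_day = ifelse(events$coalesced, events$event_day,
                                            NA_integer_))
  }
  if (is.null(drugs)) drugs <- sort(unique(ledger$drug))
  pats <- events$patient_id
  if (anyDuplicated(pats)) stop("duplicate patient_id in events")
  m <- match(pats, outcomes$patient_id)
  if (anyNA(m))
    stop("patient(s) missing from outcomes: ", paste(pats[is.na(m)], collapse = ", "))
  censor <- pmin(outcomes$recovery_day[m], outcomes$death_day[m], na.rm = TRUE)
  ev_day <- events$event_day
  bad <- !is.na(ev_day) & ev_day > censor
  if (any(bad))
    stop("event_day after censoring day for patient(s): ",
         paste(pats[bad], collapse = ", "))
  if (any(!is.na(ev_day) & ev_day <= 0))
    stop("degenerate event on day <= 0 (no prior risk interval) for patient(s): ",
         paste(pats[!is.na(ev_day) & ev_day <= 0], collapse = ", "))
  T_end <- ifelse(is.na(ev_day), censor, ev_day)
  drop <- T_end <= 0
  if (any(drop)) {
    warning("excluding patient(s) with no risk time: ",
            paste(pats[drop], collapse = ", "))
    pats <- pats[!drop]; ev_day <- ev_day[!drop]; T_end <- T_end[!drop]
  }
  n <- length(pats)
  if (n == 0) stop("no patients with risk time")
  max_t <- max(T_end)

  # per-drug exposure-by-day indicator matrices (patients x days 0..max_t-1),
  # then cumulative therapy days effective at interval (t-1, t]
  led <- ledger[ledger$patient_id %in% pats & ledger$drug %in% drugs &
                  ledger$day < max_t, , drop = FALSE]
  cov_at <- lapply(drugs, function(dr) {
    E <- matrix(0L, n, max_t)
    rows <- led[led$drug == dr, , drop = FALSE]
    if (nrow(rows) > 0) {
      pi <- match(rows$patient_id, pats)
      ok <- !is.na(pi)
      E[cbind(pi[ok], rows$day[ok] + 1L)] <- 1L
    }
    C <- t(apply(E, 1, cumsum))
    if (encoding == "any") C <- (C > 0) + 0L
    C
  })
  names(cov_at) <- drugs

  pat_idx <- rep.int(seq_len(n), T_end)
  day <- sequence(T_end)
  X <- vapply(drugs, function(dr) cov_at[[dr]][cbind(pat_idx, day)],
              numeric(length(day)))
  if (length(day) == 1L) X <- matrix(X, nrow = 1, dimnames = list(NULL, drugs))
  colnames(X) <- drugs

  # merge consecutive days with unchanged covariates
  new_pat <- day == 1L
  changed <- new_pat
  if (length(day) > 1 && length(drugs) > 0) {
    diff_any <- rowSums(abs(X[-1, , drop = FALSE] - X[-nrow(X), , drop = FALSE])) > 0
    changed <- new_pat | c(TRUE, diff_any)
  }
  grp <- cumsum(changed)
  start <- tapply(day, grp, min) - 1L
  stop_ <- tapply(day, grp, max)
  first <- which(changed)
  cp <- data.frame(patient_id = pats[pat_idx[first]],
                   start = as.integer(start), stop = as.integer(stop_),
                   stringsAsFactors = FALSE)
  cp$event <- !is.na(ev_day[pat_idx[first]]) &
    cp$stop == T_end[pat_idx[first]]
  cp <- cbind(cp, as.data.frame(X[first, , drop = FALSE]))
  rownames(cp) <- NULL
  attr(cp, "encoding") <- encoding
  attr(cp, "drugs") <- drugs
  class(cp) <- c("counting_process", "data.frame")
  cp
}

# Breslow/Efron partial log-likelihood, score and information for one
# covariate on a counting-process table; risk_sets precomputed per event time.
cox_lik <- function(beta, x, risk_sets, ties) {
  ll <- 0; U <- 0; I <- 0
  for (rs in risk_sets) {
    xr <- x[rs$risk]
    w <- exp(beta * xr)
    S0 <- sum(w); S1 <- sum(w * xr); S2 <- sum(w * xr^2)
    d <- length(rs$death)
    xd <- x[rs$death]
    if (ties == "breslow") {
      ll <- ll + beta * sum(xd) - d * log(S0)
      U <- U + sum(xd) - d * S1 / S0
      I <- I + d * (S2 / S0 - (S1 / S0)^2)
    } else { # efron
      wd <- exp(beta * xd)
      S0d <- sum(wd); S1d <- sum(wd * xd); S2d <- sum(wd * xd^2)
      ll <- ll + beta * sum(xd)
      for (k in seq_len(d) - 1L) {
        f <- k / d
        s0 <- S0 - f * S0d; s1 <- S1 - f * S1d; s2 <- S2 - f * S2d
        ll <- ll - log(s0)
        U <- U + (sum(xd) / d - s1 / s0)
        I <- I + (s2 / s0 - (s1 / s0)^2)
      }
    }
  }
  list(ll = ll, U = U, I = I)
}

#' Univariate time-varying Cox proportional hazards fit
#'
#' Maximizes the partial likelihood over counting-process risk sets (a row is
#' at risk at event time `t` iff `start < t <= stop`) by Newton-Raphson with
#' step-halving. Tied event days use the Breslow approximation by default
#' (events are day-granular, so ties are common); Efron is available. The
#' standard error comes from the observed information; CI and p are Wald.
#'
#' @param cp a `counting_process` table
#' @param covariate name of the covariate column to fit
#' @param ties `"breslow"` (default) or `"efron"`
#' @param max_iter,tol Newton-Raphson controls
#' @return list of class `cox_fit`: `covariate`, `log_hr`, `hr`, `se`,
#'   `ci_lower`, `ci_upper`, `p`, `loglik` (at the estimate and at 0),
#'   `n_events`, `converged`, `flag` (`"ok"`, `"no_information"`, or
#'   `"monotone_likelihood"`), `iterations`
#' @export
fit_cox_tv <- function(cp, covariate, ties = c("breslow", "efron"),
                       max_iter = 50, tol = 1e-10) {
  ties <- match.arg(ties)
  if (!covariate %in% names(cp)) stop("no covariate column '", covariate, "'")
  if (any(cp$start >= cp$stop)) stop("start must be < stop in every row")
  x <- cp[[covariate]]
  ev <- which(cp$event)
  if (length(ev) == 0) stop("no events in counting-process table")
  times <- sort(unique(cp$stop[ev]))
  risk_sets <- lapply(times, function(t) {
    list(risk = which(cp$start < t & t <= cp$stop),
         death = which(cp$event & cp$stop == t))
  })
  ll0 <- cox_lik(0, x, risk_sets, ties)$ll
  # no information: covariate constant within every risk set
  informative <- any(vapply(risk_sets, function(rs)
    length(unique(x[rs$risk])) > 1, logical(1)))
  if (!informative) {
    out <- list(covariate = covariate, log_hr = 0, hr = 1, se = Inf,
                ci_lower = 0, ci_upper = Inf, p = NA_real_,
                loglik = c(fit = ll0, null = ll0),
                n_events = length(ev), converged = FALSE,
                flag = "no_information", iterations = 0L)
    class(out) <- "cox_fit"
    return(out)
  }
  beta <- 0; ll <- ll0; iter <- 0L; flag <- "ok"; converged <- FALSE
  repeat {
    iter <- iter + 1L
    lk <- cox_lik(beta, x, risk_sets, ties)
    if (abs(lk$U) < 1e-9 && iter > 1L) { converged <- TRUE; ll <- lk$ll; break }
    step <- lk$U / lk$I
    new_beta <- beta + step
    new_ll <- cox_lik(new_beta, x, risk_sets, ties)$ll
    halvings <- 0L
    while (is.finite(new_ll) == FALSE || new_ll < lk$ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 30L) break
      step <- step / 2
      new_beta <- beta + step
      new_ll <- cox_lik(new_beta, x, risk_sets, ties)$ll
    }
    moved <- abs(new_beta - beta)
    beta <- new_beta; ll <- new_ll
    if (moved < tol) { converged <- TRUE; break }
    if (abs(beta) > 15) { flag <- "monotone_likelihood"; break }
    if (iter >= max_iter) break
  }
  info <- cox_lik(beta, x, risk_sets, ties)$I
  se <- if (info > 0) 1 / sqrt(info) else Inf
  z <- beta / se
  out <- list(covariate = covariate, log_hr = beta, hr = exp(beta), se = se,
              ci_lower = exp(beta - 1.96 * se), ci_upper = exp(beta + 1.96 * se),
              p = 2 * stats::pnorm(-abs(z)),
              loglik = c(fit = ll, null = ll0),
              n_events = length(ev),
              converged = converged && flag == "ok", flag = flag,
              iterations = iter)
  class(out) <- "cox_fit"
  out
}

#' @exportS3Method base::print
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox (time-varying) %s: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g [%s, %d events]\n",
              x$covariate, x$hr, x$ci_lower, x$ci_upper, x$p, x$flag, x$n_events))
  invisible(x)
}

#' Per-drug univariate time-varying Cox panel
#'
#' Applies the prevalence filter, then fits one univariate time-varying Cox
#' model per retained drug and per exposure encoding (cumulative therapy
#' days, and any-exposure indicator). Per-drug failures are recorded as
#' `NA` rows and the panel continues.
#'
#' @param ledger an `exposure_ledger`
#' @param events coalescence calls or plain events table
#'   (see [build_counting_process()])
#' @param outcomes an `outcome_table`
#' @param n_patients cohort size for the prevalence filter (default: number
#'   of patients in `events`)
#' @param threshold prevalence cutoff (default 0.15, strict)
#' @param encodings encodings to run (default both)
#' @param ties tie handling for [fit_cox_tv()]
#' @return data.frame: `drug`, `encoding`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `n_events`, `flag`
#' @export
run_antibiotic_panel <- function(ledger, events, outcomes, n_patients = NULL,
                                 threshold = 0.15,
                                 encodings = c("cumulative", "any"),
                                 ties = "breslow") {
  if (is.null(n_patients)) n_patients <- length(unique(events$patient_id))
  drugs <- prevalence_filter(ledger, n_patients, threshold)
  if (length(drugs) == 0) stop("no drug passes the prevalence filter")
  rows <- list()
  for (enc in encodings) {
    cp <- build_counting_process(ledger, events, outcomes, drugs, enc)
    for (dr in drugs) {
      fit <- tryCatch(fit_cox_tv(cp, dr, ties = ties), error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(fit, "error"))
        data.frame(drug = dr, encoding = enc, hr = NA_real_, ci_lower = NA_real_,
                   ci_upper = NA_real_, p = NA_real_, n_events = NA_integer_,
                   flag = paste("error:", conditionMessage(fit)),
                   stringsAsFactors = FALSE)
      else
        data.frame(drug = dr, encoding = enc, hr = fit$hr,
                   ci_lower = fit$ci_lower, ci_upper = fit$ci_upper, p = fit$p,
                   n_events = fit$n_events, flag = fit$flag,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
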