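#' Random-intercept linear mixed model for longitudinal responses
#'
#' Fits `response ~ fixed effects + (1 | group)` by REML (lme4 underneath):
#' the structure used for the diversity-over-time analyses, where the random
#' grouping is the patient. Reports fixed-effect estimates with Wald z tests
#' (large-sample; no denominator-df correction), the two variance components
#' (patient intercept and residual), and — when an interaction term is
#' present — a likelihood-ratio test of the model with vs without that term,
#' both refitted by maximum likelihood.
#'
#' @param data data.frame of long-format records
#' @param response name of the response column
#' @param fixed character vector of fixed-effect terms, e.g.
#'   `c("day", "coalesced", "day:coalesced")`
#' @param group name of the random-intercept grouping column
#'   (default `"patient_id"`)
#' @param reml fit by REML (default `TRUE`)
#' @return list of class `lmm_fit`: `coefficients` (data.frame with
#'   `estimate`, `se`, `z`, `p`), `varcomp` (`group`, `residual` variances),
#'   `converged`, `singular`, `lrt_interaction` (`statistic`, `df`, `p`, term)
#'   or `NULL`, `formula`, `n_obs`, `n_groups`, and the underlying `model`
#' @export
fit_lmm <- function(data, response, fixed, group = "patient_id", reml = TRUE) {
  if (!response %in% names(data)) stop("no response column '", response, "'")
  if (!group %in% names(data)) stop("no grouping column '", group, "'")
  data <- data[stats::complete.cases(data[, unique(c(response, all.vars(
    stats::reformulate(fixed)), group))]), , drop = FALSE]
  if (length(unique(data[[group]])) < 2) stop("need >= 2 groups (patients)")

  # reject aliased fixed-effect columns up front, naming them
  X <- stats::model.matrix(stats::reformulate(fixed), data)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])]
    stop("singular fixed-effect design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }

  fml <- stats::as.formula(paste(response, "~", paste(fixed, collapse = " + "),
                                 "+ (1 |", group, ")"))
  fit <- lme4::lmer(fml, data = data, REML = reml,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_group <- vc$vcov[vc$grp == group][1]
  v_resid <- vc$vcov[vc$grp == "Residual"][1]
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- est / se
  coefs <- data.frame(term = names(est), estimate = unname(est), se = unname(se),
                      z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
                      stringsAsFactors = FALSE)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) || length(conv_msgs) == 0

  lrt <- NULL
  inter <- grep(":", fixed, value = TRUE)
  if (length(inter) >= 1) {
    term <- inter[length(inter)]
    full_ml <- lme4::lmer(fml, data = data, REML = FALSE,
                          control = lme4::lmerControl(check.conv.singular = "ignore"))
    fml0 <- stats::as.formula(paste(response, "~",
                                    paste(setdiff(fixed, term), collapse = " + "),
                                    "+ (1 |", group, ")"))
    red_ml <- lme4::lmer(fml0, data = data, REML = FALSE,
                         control = lme4::lmerControl(check.conv.singular = "ignore"))
    stat <- as.numeric(2 * (stats::logLik(full_ml) - stats::logLik(red_ml)))
    lrt <- list(term = term, statistic = max(stat, 0), df = 1,
                p = stats::pchisq(max(stat, 0), df = 1, lower.tail = FALSE))
  }

  structure(list(coefficients = coefs,
                 varcomp = c(group = v_group, residual = v_resid),
                 converged = converged,
                 singular = lme4::isSingular(fit),
                 lrt_interaction = lrt,
                 formula = fml, n_obs = nrow(data),
                 n_groups = length(unique(data[[group]])),
                 model = fit),
            class = "lmm_fit")
}

#' @exportS3Method base::print
print.lmm_fit <- function(x, ...) {
  cat("Linear mixed model:", deparse(x$formula), "\n")
  cat(sprintf("  %d obs, %d groups; var(intercept) = %.4g, var(resid) = %.4g%s\n",
              x$n_obs, x$n_groups, x$varcomp["group"], x$varcomp["residual"],
              if (x$singular) " [singular]" else ""))
  print(x$coefficients, digits = 4, row.names = FALSE)
  if (!is.null(x$lrt_interaction))
    cat(sprintf("  LRT for %s: chi2 = %.4g (df 1), p = %.4g\n",
                x$lrt_interaction$term, x$lrt_interaction$statistic,
                x$lrt_interaction$p))
  invisible(x)
}

#' Rank-based group-difference tests with Benjamini-Hochberg adjustment
#'
#' Runs a Mann-Whitney (unpaired) or Wilcoxon signed-rank (paired) test for
#' each comparison in a family and adjusts the p-values with the BH step-up
#' procedure within that family. The family must be passed in full, since BH
#' is defined over the whole set of hypotheses (the study adjusted within
#' each taxonomy level).
#'
#' @param comparisons named list; each element is a list with numeric `x`,
#'   `y` and optional logical `paired` (default `FALSE`)
#' @param exact passed to [stats::wilcox.test()]; default `NULL`
#'   (exact when samples are small and untied)
#' @return data.frame: `comparison`, `statistic`, `p`, `q` (BH-adjusted),
#'   `degenerate` (all paired differences zero)
#' @export
group_difference_tests <- function(comparisons, exact = NULL) {
  if (is.null(names(comparisons)) || any(names(comparisons) == ""))
    stop("comparisons must be a named list")
  rows <- lapply(names(comparisons), function(nm) {
    cmp <- comparisons[[nm]]
    paired <- isTRUE(cmp$paired)
    if (paired && length(cmp$x) != length(cmp$y))
      stop("paired comparison '", nm, "' has unequal lengths")
    if (length(cmp$x) < 1 || length(cmp$y) < 1)
      stop("comparison '", nm, "' has an empty group")
    if (paired && all(cmp$x - cmp$y == 0))
      return(data.frame(comparison = nm, statistic = NA_real_, p = 1,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    wt <- suppressWarnings(stats::wilcox.test(cmp$x, cmp$y, paired = paired,
                                              exact = exact))
    data.frame(comparison = nm, statistic = unname(wt$statistic), p = wt$p.value,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out[, c("comparison", "statistic", "p", "q", "degenerate")]
}

#' Repeated-measures site-effect test per genus
#'
#' For each genus in the long records from [oral_taxa_site_comparison()],
#' fits `abundance ~ site + timepoint + (1 | patient)` within the requested
#' coalescence stratum and reports the Wald p for the site effect. Genera
#' with (near-)constant abundance are reported as degenerate instead of
#' being fitted.
#'
#' @param records data.frame from [oral_taxa_site_comparison()]
#' @param coalesced_only restrict to coalesced patients (default `TRUE`)
#' @return data.frame: `genus`, `estimate` (stool minus oral), `se`, `p`,
#'   `degenerate`
#' @export
site_effect_tests <- function(records, coalesced_only = TRUE) {
  if (coalesced_only) records <- records[records$coalesced %in% TRUE, , drop = FALSE]
  rows <- lapply(unique(records$genus), function(g) {
    dd <- records[records$genus == g, , drop = FALSE]
    if (nrow(dd) < 4 || stats::var(dd$abundance) < 1e-12 ||
        length(unique(dd$site)) < 2)
      return(data.frame(genus = g, estimate = NA_real_, se = NA_real_,
                        p = NA_real_, degenerate = TRUE, stringsAsFactors = FALSE))
    fit <- fit_lmm(dd, "abundance", c("site", "timepoint"))
    i <- grep("^site", fit$coefficients$term)[1]
    data.frame(genus = g, estimate = fit$coefficients$estimate[i],
               se = fit$coefficients$se[i], p = fit$coefficients$p[i],
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate longitudinal Shannon-diversity trajectories from the LMM
#'
#' Generates data directly from the random-intercept linear mixed model used
#' for the diversity-over-time analysis:
#' `y_ij = b0 + u_i + b_day * day_ij + b_coal * coal_i +
#' b_int * day_ij * coal_i + e_ij`, with `u_i ~ N(0, sd_patient^2)` and
#' `e_ij ~ N(0, sd_resid^2)`. A quarter of patients are labelled coalesced
#' (the cohort's observed coalescence fraction); samples are twice-weekly
#' from day 0 to day 28. Defaults reflect the cohort scale: intercept 1.81
#' (median oral Shannon diversity), a shallow background decline, and a
#' steeper decline in coalesced patients.
#'
#' @param n_patients number of patients (default 200)
#' @param interaction true coalescence-by-day interaction coefficient
#'   (Shannon units per day; default -0.017)
#' @param intercept,day_slope,coal_effect fixed effects
#' @param sd_patient,sd_resid random-intercept and residual SDs
#' @param days sampling days (default `seq(0, 28, by = 3)`)
#' @param coal_fraction fraction of patients labelled coalesced
#' @param seed integer seed
#' @return data.frame: `patient_id`, `day`, `coalesced`, `shannon`
#' @export
simulate_lmm_cohort <- function(n_patients = 200, interaction = -0.017,
                                intercept = 1.81, day_slope = -0.01,
                                coal_effect = -0.3, sd_patient = 0.4,
                                sd_resid = 0.5, days = seq(0, 28, by = 3),
                                coal_fraction = 0.25, seed = 1) {
  set.seed(seed %% 2147483647)
  coal <- seq_len(n_patients) <= round(coal_fraction * n_patients)
  u <- stats::rnorm(n_patients, 0, sd_patient)
  df <- expand.grid(patient = seq_len(n_patients), day = days)
  mu <- intercept + u[df$patient] + day_slope * df$day +
    coal_effect * coal[df$patient] + interaction * df$day * coal[df$patient]
  data.frame(patient_id = sprintf("P%03d", df$patient), day = df$day,
             coalesced = coal[df$patient],
             shannon = mu + stats::rnorm(nrow(df), 0, sd_resid),
             stringsAsFactors = FALSE)
}
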