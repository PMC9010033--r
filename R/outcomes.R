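#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Plain Pearson chi-squared (1 df) without continuity correction, matching
#' the convention of the clinical association analyses.
#'
#' @param tab 2x2 matrix of non-negative integer counts: rows = coalesced
#'   yes/no, columns = infected yes/no
#' @return list: `statistic`, `p`, `df`
#' @export
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-squared undefined")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE), df = 1)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' OR = ad/bc for the table (a, b / c, d); CI =
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). If any cell is zero, a
#' 0.5 continuity correction is added to every cell and the result is
#' flagged.
#'
#' @param tab 2x2 matrix: a = (coalesced, infected), b = (coalesced, not),
#'   c = (non-coalesced, infected), d = (non-coalesced, not)
#' @return list: `or`, `ci_lower`, `ci_upper`, `continuity_corrected`
#' @export
odds_ratio <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("expected a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  a <- t2[1, 1]; b <- t2[1, 2]; c_ <- t2[2, 1]; d <- t2[2, 2]
  or <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  list(or = or,
       ci_lower = exp(log(or) - 1.96 * se),
       ci_upper = exp(log(or) + 1.96 * se),
       continuity_corrected = corrected)
}

#' Coalescence vs infection association
#'
#' Cross-tabulates coalescence status against infection before neutrophil
#' recovery and infection in the 90 days after recovery, and reports the
#' Pearson chi-squared test and Woolf odds ratio for each window.
#'
#' @param calls `coalescence_calls` (only eligible patients are used)
#' @param outcomes an `outcome_table`
#' @return data.frame: `window`, `a`, `b`, `c`, `d`, `chi_sq`, `p`, `or`,
#'   `ci_lower`, `ci_upper`
#' @export
coalescence_outcome_association <- function(calls, outcomes) {
  calls <- calls[calls$eligible, , drop = FALSE]
  m <- match(calls$patient_id, outcomes$patient_id)
  if (anyNA(m))
    stop("patient(s) missing from outcomes: ",
         paste(calls$patient_id[is.na(m)], collapse = ", "))
  rows <- lapply(c(pre_recovery = "infection_pre", post_recovery_90d = "infection_post90"),
                 function(col) {
    inf <- outcomes[[col]][m]
    tab <- matrix(c(sum(calls$coalesced & inf), sum(calls$coalesced & !inf),
                    sum(!calls$coalesced & inf), sum(!calls$coalesced & !inf)),
                  nrow = 2, byrow = TRUE)
    cs <- chi_square(tab)
    or <- odds_ratio(tab)
    data.frame(a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
               chi_sq = cs$statistic, p = cs$p, or = or$or,
               ci_lower = or$ci_lower, ci_upper = or$ci_upper)
  })
  out <- cbind(window = names(rows), do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
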