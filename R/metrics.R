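# Evaluation metrics of a published literature: PPV, type S (sign) error
# rate, type M (exaggeration) factor, and p-curves.

.check_literature <- function(lit) {
  stopifnot(inherits(lit, "published_literature"))
  if (nrow(lit$findings) == 0) abort("The literature contains no findings.")
  invisible(lit)
}

#' Positive predictive value of a literature
#'
#' Fraction of published findings that are true positives: the true effect
#' exceeds the minimum of interest in absolute size AND the estimate has the
#' same sign as the true effect. Significant estimates with the wrong sign
#' count as false positives even when the underlying effect is true.
#'
#' @param lit A [simulate_literature()] result.
#' @return A proportion.
#' @export
ppv <- function(lit) {
  .check_literature(lit)
  mean(lit$findings$classification == "TP")
}

#' Type S (sign) error rate
#'
#' Proportion of published findings whose estimate has the opposite sign of
#' the true effect, counted over all published findings regardless of the
#' minimum-of-interest threshold. Undefined when any true effect is exactly
#' zero (as in the dichotomous model), in which case an error is raised.
#'
#' @param lit A [simulate_literature()] result.
#' @return A proportion.
#' @export
type_s_rate <- function(lit) {
  .check_literature(lit)
  if (any(lit$findings$true_es == 0)) {
    abort(paste0("Sign errors are undefined when the true effect is exactly zero; ",
                 "exclude the dichotomous model (or any point mass at 0) from type S analyses."))
  }
  mean(!lit$findings$sign_correct)
}

#' Type M (exaggeration) summary
#'
#' For published findings with the correct sign, the exaggeration factor is
#' the estimate divided by the true effect size (always positive on this
#' subset). Wrong-sign findings are excluded entirely rather than folded by
#' absolute value. Quantiles use the default linear interpolation between
#' order statistics (type 7).
#'
#' @param lit A [simulate_literature()] result.
#' @return Named numeric vector `c(median, q25, q75)` of the exaggeration
#'   factor.
#' @export
type_m_summary <- function(lit) {
  .check_literature(lit)
  keep <- lit$findings$sign_correct
  if (!any(keep)) abort("No sign-correct findings: the exaggeration factor is undefined.")
  exag <- lit$findings$estimate[keep] / lit$findings$true_es[keep]
  q <- quantile(exag, c(0.5, 0.25, 0.75), names = FALSE)
  c(median = q[1], q25 = q[2], q75 = q[3])
}

#' p-curve of published results
#'
#' Histogram of the p-values of published (hence significant) findings over
#' `(0, alpha]`, plus their median. Under a literature of pure null effects
#' pushed to significance, the curve is approximately flat; right skew
#' (small p-values over-represented) indicates evidential value.
#'
#' @param lit A [simulate_literature()] result.
#' @param bin_width Width of the histogram bins (default 0.005, i.e. 10 bins
#'   over (0, 0.05]).
#' @return A list with `bins` (tibble: `lower`, `upper`, `count`) and
#'   `median_p`. Counts sum to the number of findings.
#' @export
p_curve <- function(lit, bin_width = 0.005) {
  .check_literature(lit)
  if (!is.numeric(bin_width) || length(bin_width) != 1 || bin_width <= 0) {
    abort("`bin_width` must be a single positive number.")
  }
  alpha <- lit$config$alpha
  breaks <- seq(0, alpha, by = bin_width)
  if (breaks[length(breaks)] < alpha) breaks <- c(breaks, alpha)
  p <- lit$findings$p_value
  idx <- cut(p, breaks = breaks, right = TRUE) # bins are (lower, upper]
  counts <- as.integer(table(idx))
  list(
    bins = tibble(
      lower = breaks[-length(breaks)],
      upper = breaks[-1],
      count = counts
    ),
    median_p = median(p)
  )
}

#' One-row summary of a literature
#'
#' Collects the evaluation metrics of a simulated literature into a single
#' tibble row. Type S and type M entries are `NA` when undefined (true
#' effects exactly zero, or no sign-correct finding).
#'
#' @param lit A [simulate_literature()] result.
#' @return A one-row tibble with columns `ppv`, `type_s_rate`,
#'   `type_m_median`, `type_m_q25`, `type_m_q75`, `median_p`, `n_tp`,
#'   `n_fp`, `achieved_prevalence`, `achieved_power`, `n_per_group`,
#'   `n_published`.
#' @export
summarize_literature <- function(lit) {
  .check_literature(lit)
  f <- lit$findings
  n_tp <- sum(f$classification == "TP")
  has_zero <- any(f$true_es == 0)
  tm <- if (any(f$sign_correct)) {
    q <- quantile(f$estimate[f$sign_correct] / f$true_es[f$sign_correct],
                  c(0.5, 0.25, 0.75), names = FALSE)
    if (has_zero) c(NA_real_, NA_real_, NA_real_) else q
  } else {
    c(NA_real_, NA_real_, NA_real_)
  }
  tibble(
    ppv = n_tp / nrow(f),
    type_s_rate = if (has_zero) NA_real_ else mean(!f$sign_correct),
    type_m_median = tm[1],
    type_m_q25 = tm[2],
    type_m_q75 = tm[3],
    median_p = median(f$p_value),
    n_tp = n_tp,
    n_fp = nrow(f) - n_tp,
    achieved_prevalence = lit$achieved_prevalence,
    achieved_power = lit$achieved_power,
    n_per_group = lit$n_per_group,
    n_published = nrow(f)
  )
}
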