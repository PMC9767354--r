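# One simulated experiment: power-based sample sizing, two-group normal
# sampling with unit SD, pooled-variance Student's t-test, and the
# bias-driven publication decision.

#' Exact power of the two-sample t-test
#'
#' Two-sided power of an equal-variance two-sample Student's t-test with
#' `n_per_group` observations per arm, unit within-group SD and true
#' standardized difference `effect`, computed from the noncentral t
#' distribution with `df = 2n - 2` and noncentrality `effect * sqrt(n / 2)`.
#'
#' @param effect True standardized mean difference (Cohen's d).
#' @param n_per_group Sample size per arm (integer >= 2; vectorized).
#' @param alpha Two-sided significance level.
#' @return Rejection probability (equals `alpha` when `effect = 0`).
#' @export
power_for_sample_size <- function(effect, n_per_group, alpha = 0.05) {
  if (any(n_per_group < 2) || any(n_per_group != floor(n_per_group))) {
    abort("`n_per_group` must be integers >= 2.")
  }
  .check_prob(alpha, "alpha")
  df <- 2 * n_per_group - 2
  ncp <- effect * sqrt(n_per_group / 2)
  tcrit <- qt(1 - alpha / 2, df)
  pt(tcrit, df, ncp = ncp, lower.tail = FALSE) + pt(-tcrit, df, ncp = ncp)
}

#' Smallest sample size reaching a target power
#'
#' Returns the smallest integer `n >= 2` per group such that
#' [power_for_sample_size()] meets or exceeds `power` for the given
#' reference effect. The search brackets the solution by doubling and then
#' bisects, so it terminates for any attainable target (power tends to 1 as
#' n grows).
#'
#' @param effect Reference effect size (> 0).
#' @param power Target power, in (0, 1).
#' @param alpha Two-sided significance level.
#' @return Integer sample size per group.
#' @export
sample_size_for_power <- function(effect, power, alpha = 0.05) {
  if (!is.numeric(effect) || length(effect) != 1 || effect <= 0) {
    abort("`effect` must be a single positive number.")
  }
  if (power <= 0 || power >= 1) abort("`power` must lie strictly between 0 and 1.")
  .check_prob(alpha, "alpha")
  if (power_for_sample_size(effect, 2, alpha) >= power) return(2L)
  lo <- 2L # below target
  hi <- 4L
  while (power_for_sample_size(effect, hi, alpha) < power) {
    lo <- hi
    hi <- hi * 2L
  }
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    if (power_for_sample_size(effect, mid, alpha) >= power) hi <- mid else lo <- mid
  }
  hi
}

#' Run one two-group experiment
#'
#' Draws a control sample from `N(0, 1)` and a treatment sample from
#' `N(true_es, 1)`, each of size `n_per_group`, and compares them with a
#' two-tailed pooled-variance Student's t-test (`df = 2n - 2`). The effect
#' estimate is the difference of sample means (treatment minus control).
#' The t statistic is computed directly from the pooled variance for speed;
#' it is numerically identical to `stats::t.test(..., var.equal = TRUE)`.
#'
#' @param true_es True effect size for this experiment.
#' @param n_per_group Sample size per arm (>= 2).
#' @param alpha Significance level (recorded only; the decision is taken in
#'   [publish_decision()]).
#' @return A list with elements `true_es`, `estimate`, `p_value`,
#'   `n_per_group`, `repeats` (0) and `published` (FALSE): an experiment
#'   result in its pre-publication state.
#' @export
run_experiment <- function(true_es, n_per_group, alpha = 0.05) {
  if (length(n_per_group) != 1 || n_per_group < 2 || n_per_group != floor(n_per_group)) {
    abort("`n_per_group` must be a single integer >= 2.")
  }
  n <- as.integer(n_per_group)
  ctrl <- rnorm(n)
  trt <- rnorm(n, mean = true_es)
  est <- mean(trt) - mean(ctrl)
  pooled_var <- (sum((ctrl - mean(ctrl))^2) + sum((trt - mean(trt))^2)) / (2 * n - 2)
  tstat <- est / sqrt(pooled_var * 2 / n)
  p <- 2 * pt(abs(tstat), df = 2 * n - 2, lower.tail = FALSE)
  list(true_es = true_es, estimate = est, p_value = p,
       n_per_group = n, repeats = 0L, published = FALSE)
}

# Does a result satisfy the active publication rule?
.passes_rule <- function(result, rule, min_effect, alpha) {
  sig <- result$p_value < alpha
  if (rule == "significance_and_magnitude") {
    sig && abs(result$estimate) > min_effect
  } else {
    sig
  }
}

#' Publication decision with bias
#'
#' Applies the selective-publication rule to a first experiment result. A
#' result that passes the rule (p < alpha; under the magnitude rule also
#' `|estimate| > min_effect`) is published as-is with `repeats = 0`.
#' Otherwise, with probability `1 - bias` the result is simply not
#' published; with probability `bias` the experiment is re-run — fresh
#' samples, same true effect and sample size — until a result passes the
#' rule, and that final result is published with `repeats` counting the
#' re-runs. This models practices that push initially negative results to
#' significance (p-hacking, analytic flexibility), with only the final
#' significant result entering the literature.
#'
#' @param first_result Result of [run_experiment()].
#' @param bias Probability that a non-significant experiment is pushed to
#'   significance rather than shelved, in \[0, 1\].
#' @param rule `"significance_only"` (default) or
#'   `"significance_and_magnitude"`.
#' @param min_effect Minimum effect of interest (used by the magnitude
#'   rule).
#' @param alpha Two-sided significance level.
#' @param max_repeats Safety cap on re-runs; exceeding it signals a rule
#'   that is almost surely unsatisfiable and raises an error of class
#'   `litsim_repeat_cap`.
#' @return The experiment result list, with `published` set and, when
#'   published, satisfying the active rule.
#' @export
publish_decision <- function(first_result, bias,
                             rule = c("significance_only", "significance_and_magnitude"),
                             min_effect = 0.5, alpha = 0.05,
                             max_repeats = 1e6) {
  rule <- match.arg(rule)
  .check_prob(bias, "bias")
  if (.passes_rule(first_result, rule, min_effect, alpha)) {
    first_result$published <- TRUE
    first_result$repeats <- 0L
    return(first_result)
  }
  if (runif(1) >= bias) {
    first_result$published <- FALSE
    return(first_result)
  }
  reps <- 0L
  repeat {
    reps <- reps + 1L
    if (reps > max_repeats) {
      abort(
        sprintf(
          paste0("Exceeded %g re-runs without satisfying the publication rule ",
                 "('%s', true_es = %.3g, n = %d, alpha = %g): the configuration ",
                 "is almost surely unsatisfiable."),
          max_repeats, rule, first_result$true_es, first_result$n_per_group, alpha
        ),
        class = "litsim_repeat_cap"
      )
    }
    res <- run_experiment(first_result$true_es, first_result$n_per_group, alpha)
    if (.passes_rule(res, rule, min_effect, alpha)) {
      res$published <- TRUE
      res$repeats <- reps
      return(res)
    }
  }
}
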