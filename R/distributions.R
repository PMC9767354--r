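# Effect-size distribution models: two-component normal mixtures on the
# Cohen's d scale. Component A is always centred at 0; component B has mean
# mu_b. A standard deviation of 0 denotes an exact point mass, so the
# dichotomous model has zero sampling noise in the effect sizes themselves.

.model_presets <- list(
  dichotomous       = list(sd_a = 0,   mu_b = 1, sd_b = 0),
  two_peaks         = list(sd_a = 0.1, mu_b = 1, sd_b = 0.1),
  overlapping_peaks = list(sd_a = 0.3, mu_b = 1, sd_b = 0.3),
  two_normals       = list(sd_a = 0.1, mu_b = 0, sd_b = 1),
  single_normal     = list(mu_b = 0,   sd_b = 0, w_b = 0)
)

.model_names <- names(.model_presets)

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

#' Effect-size distribution of a research field
#'
#' Builds a two-component normal mixture describing the population of true
#' effect sizes (standardized mean differences) investigated in a field.
#' Component A is centred at zero with standard deviation `sd_a`; component B
#' is `N(mu_b, sd_b)` and receives mixture weight `w_b`. A standard deviation
#' of zero makes the component an exact point mass.
#'
#' Five named models are provided, differing in how sharply "null" and
#' "true" effects are separated:
#' \describe{
#'   \item{dichotomous}{point masses at 0 and 1 (`sd_a = sd_b = 0`,
#'     `mu_b = 1`); the classic screening set-up where effects either exist
#'     at a fixed magnitude or are exactly null.}
#'   \item{two_peaks}{`N(0, 0.1)` and `N(1, 0.1)`: well-separated peaks with
#'     mild variation.}
#'   \item{overlapping_peaks}{`N(0, 0.3)` and `N(1, 0.3)`: substantial
#'     overlap, so the true/false boundary is genuinely arbitrary.}
#'   \item{two_normals}{`N(0, 0.1)` and `N(0, 1)`: both centred at zero,
#'     differing only in spread; large effects exist but are rare.}
#'   \item{single_normal}{a single `N(0, sd_a)` (`w_b = 0`); prevalence of
#'     true effects is controlled through `sd_a` alone.}
#' }
#'
#' For the two-component models the free parameter is the weight `w_b`; for
#' `single_normal` it is `sd_a`. Either supply it directly or solve it from a
#' target prevalence with [distribution_for_prevalence()].
#'
#' @param model Model name, one of `"dichotomous"`, `"two_peaks"`,
#'   `"overlapping_peaks"`, `"two_normals"`, `"single_normal"`.
#' @param w_b Mixture weight of component B, in \[0, 1\]. Required for the
#'   two-component models; must be 0 (or omitted) for `single_normal`.
#' @param sd_a Standard deviation of component A (>= 0). Required for
#'   `single_normal`; defaults to the model preset otherwise.
#' @param mu_b,sd_b Mean and standard deviation of component B; default to
#'   the model presets and rarely need changing.
#' @return An object of class `effect_distribution`.
#' @examples
#' effect_distribution("dichotomous", w_b = 0.5)
#' effect_distribution("single_normal", sd_a = 1)
#' @export
effect_distribution <- function(model = .model_names,
                                w_b = NULL, sd_a = NULL,
                                mu_b = NULL, sd_b = NULL) {
  model <- match.arg(model)
  preset <- .model_presets[[model]]
  sd_a <- sd_a %||% preset$sd_a
  mu_b <- mu_b %||% preset$mu_b
  sd_b <- sd_b %||% preset$sd_b
  w_b  <- w_b  %||% preset$w_b
  if (model == "single_normal") {
    if (is.null(sd_a)) {
      abort("`sd_a` must be supplied for the single_normal model (it controls prevalence).")
    }
    if (w_b != 0) abort("single_normal requires `w_b` = 0.")
  }
  if (is.null(w_b)) {
    abort(sprintf(paste0("`w_b` must be supplied for the %s model, ",
                         "either directly or via distribution_for_prevalence()."), model))
  }
  for (nm in c("sd_a", "mu_b", "sd_b", "w_b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (sd_a < 0 || sd_b < 0) abort("Standard deviations must be non-negative.")
  .check_prob(w_b, "w_b")
  if (model == "dichotomous" && (sd_a != 0 || sd_b != 0)) {
    abort("dichotomous requires sd_a = sd_b = 0 (exact point masses).")
  }
  structure(
    list(model = model, sd_a = sd_a, mu_b = mu_b, sd_b = sd_b, w_b = w_b),
    class = "effect_distribution"
  )
}

#' @export
print.effect_distribution <- function(x, ...) {
  cat(sprintf(
    "<effect_distribution: %s>\n  A: N(0, %g)  B: N(%g, %g)  weight of B: %g\n",
    x$model, x$sd_a, x$mu_b, x$sd_b, x$w_b
  ))
  invisible(x)
}

# P(|X| > m) for X ~ N(mu, sd); point mass when sd = 0.
.tail_mass <- function(mu, sd, m) {
  if (sd == 0) return(as.numeric(abs(mu) > m))
  pnorm(-m, mean = mu, sd = sd) + pnorm(m, mean = mu, sd = sd, lower.tail = FALSE)
}

# E[|X| * 1{|X| > m}] for X ~ N(mu, sd) (unnormalized truncated absolute
# moment, both tails); point mass when sd = 0.
.abs_partial_mean <- function(mu, sd, m) {
  if (sd == 0) return(abs(mu) * as.numeric(abs(mu) > m))
  z_up <- (m - mu) / sd
  z_lo <- (-m - mu) / sd
  upper <- mu * pnorm(z_up, lower.tail = FALSE) + sd * dnorm(z_up)
  lower <- -(mu * pnorm(z_lo) - sd * dnorm(z_lo))
  upper + lower
}

#' Draw effect sizes from a distribution model
#'
#' Samples `n` effect sizes from the mixture: each draw comes from component
#' B with probability `w_b`, otherwise from component A. Degenerate
#' components (SD 0) return their mean exactly. Draws consume R's global RNG
#' stream; seed with [set.seed()] or via the `seed` field of
#' [simulation_config()] for reproducibility.
#'
#' @param dist An [effect_distribution()].
#' @param n Number of draws (positive integer).
#' @return Numeric vector of length `n`.
#' @export
sample_effects <- function(dist, n) {
  stopifnot(inherits(dist, "effect_distribution"))
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    abort("`n` must be a single positive integer.")
  }
  n <- as.integer(n)
  from_b <- runif(n) < dist$w_b
  es <- numeric(n)
  n_a <- sum(!from_b)
  n_b <- n - n_a
  if (n_a > 0) {
    es[!from_b] <- if (dist$sd_a == 0) 0 else rnorm(n_a, 0, dist$sd_a)
  }
  if (n_b > 0) {
    es[from_b] <- if (dist$sd_b == 0) dist$mu_b else rnorm(n_b, dist$mu_b, dist$sd_b)
  }
  es
}

#' Prevalence of true effects
#'
#' Closed-form probability that an effect drawn from `dist` is "true", i.e.
#' that its absolute size exceeds the minimum effect of interest:
#' `P(|ES| > min_effect)`, combining the two-tailed normal masses of both
#' mixture components (point masses contribute 0 or 1 by position).
#'
#' @param dist An [effect_distribution()].
#' @param min_effect Minimum effect size of interest (Cohen's d units,
#'   default 0.5). Effects with `|ES|` exactly equal to the threshold count
#'   as false (strict inequality).
#' @return A probability.
#' @examples
#' true_prevalence(effect_distribution("single_normal", sd_a = 1)) # ~0.617
#' @export
true_prevalence <- function(dist, min_effect = 0.5) {
  stopifnot(inherits(dist, "effect_distribution"))
  if (!is.numeric(min_effect) || length(min_effect) != 1 || min_effect <= 0) {
    abort("`min_effect` must be a single positive number.")
  }
  (1 - dist$w_b) * .tail_mass(0, dist$sd_a, min_effect) +
    dist$w_b * .tail_mass(dist$mu_b, dist$sd_b, min_effect)
}

# Resolve the fixed component parameters of a two-component model, with
# optional overrides, without requiring w_b.
.component_params <- function(model, sd_a = NULL, mu_b = NULL, sd_b = NULL) {
  if (!model %in% .model_names) {
    abort(sprintf("Unknown model '%s'.", model))
  }
  preset <- .model_presets[[model]]
  list(
    sd_a = sd_a %||% preset$sd_a %||% abort("`sd_a` required for this model."),
    mu_b = mu_b %||% preset$mu_b,
    sd_b = sd_b %||% preset$sd_b
  )
}

#' Achievable prevalence bounds of a two-component model
#'
#' When prevalence is controlled through the mixture weight `w_b` with the
#' component parameters held fixed, the attainable prevalences form the
#' closed interval between the two components' own tail masses beyond the
#' minimum of interest. Targets outside this interval cannot be reached
#' without changing the components or the threshold — e.g. the wider
#' component `N(0, 1)` of the two-normals model has only
#' `2 * (1 - pnorm(0.5))`, about 62%, of its mass beyond 0.5, which caps
#' that model's prevalence.
#'
#' @param model Name of a two-component model (`"dichotomous"`,
#'   `"two_peaks"`, `"overlapping_peaks"`, `"two_normals"`).
#' @param min_effect Minimum effect size of interest.
#' @param sd_a,mu_b,sd_b Optional overrides of the fixed component
#'   parameters.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
prevalence_bounds <- function(model, min_effect = 0.5,
                              sd_a = NULL, mu_b = NULL, sd_b = NULL) {
  if (identical(model, "single_normal")) {
    abort("single_normal prevalence is controlled by `sd_a`; any prevalence in (0, 1) is achievable.")
  }
  pars <- .component_params(model, sd_a, mu_b, sd_b)
  p_a <- .tail_mass(0, pars$sd_a, min_effect)
  p_b <- .tail_mass(pars$mu_b, pars$sd_b, min_effect)
  c(lower = min(p_a, p_b), upper = max(p_a, p_b))
}

#' Solve the mixture weight for a target prevalence
#'
#' For a two-component model with fixed component parameters, finds the
#' weight `w_b` such that `P(|ES| > min_effect)` equals `target`. Since the
#' prevalence is linear in the weight, the solution is
#' `w_b = (target - p_A) / (p_B - p_A)` where `p_A`, `p_B` are the
#' components' two-tailed masses beyond the threshold.
#'
#' @inheritParams prevalence_bounds
#' @param target Desired prevalence of true effects, in \[0, 1\].
#' @return The solved weight `w_b`.
#' @section Errors: if `target` lies outside the achievable interval (see
#'   [prevalence_bounds()]) an error of class
#'   `litsim_unachievable_prevalence` is thrown, carrying the bounds in its
#'   `lower`/`upper` fields. This reproduces the scenario-table cells that
#'   cannot be simulated without changing other parameters.
#' @export
solve_weight_for_prevalence <- function(model, target, min_effect = 0.5,
                                        sd_a = NULL, mu_b = NULL, sd_b = NULL) {
  .check_prob(target, "target")
  pars <- .component_params(model, sd_a, mu_b, sd_b)
  p_a <- .tail_mass(0, pars$sd_a, min_effect)
  p_b <- .tail_mass(pars$mu_b, pars$sd_b, min_effect)
  if (p_a == p_b) {
    abort("Both components have identical tail mass; the weight cannot control prevalence.")
  }
  lo <- min(p_a, p_b)
  hi <- max(p_a, p_b)
  if (target < lo - 1e-12 || target > hi + 1e-12) {
    abort(
      sprintf(
        paste0("Prevalence %.4g is not achievable for the %s model with the minimum ",
               "of interest at %g: attainable range is [%.4g, %.4g]. ",
               "Change the component parameters or the minimum of interest."),
        target, model, min_effect, lo, hi
      ),
      class = "litsim_unachievable_prevalence",
      model = model, target = target, lower = lo, upper = hi
    )
  }
  w <- (target - p_a) / (p_b - p_a)
  min(max(w, 0), 1)
}

#' Solve the single-normal SD for a target prevalence
#'
#' For the single-normal model, prevalence is `2 * (1 - pnorm(min_effect /
#' sd_a))`, so the SD achieving a target prevalence is
#' `min_effect / qnorm(1 - target / 2)`.
#'
#' @param target Desired prevalence, strictly between 0 and 1.
#' @param min_effect Minimum effect size of interest.
#' @return The solved `sd_a`.
#' @export
solve_sd_for_prevalence <- function(target, min_effect = 0.5) {
  if (!is.numeric(target) || length(target) != 1 || is.na(target) ||
      target <= 0 || target >= 1) {
    abort("`target` must lie strictly between 0 and 1: no finite SD attains a prevalence of exactly 0 or 1.")
  }
  min_effect / qnorm(1 - target / 2)
}

#' Build a distribution with a solved prevalence
#'
#' Convenience wrapper: solves the model's free parameter (`w_b` for
#' two-component models, `sd_a` for `single_normal`) so that the prevalence
#' of true effects equals `prevalence`, and returns the resulting
#' [effect_distribution()].
#'
#' @param model Model name.
#' @param prevalence Target prevalence of true effects.
#' @param min_effect Minimum effect size of interest.
#' @return An `effect_distribution`.
#' @export
distribution_for_prevalence <- function(model, prevalence, min_effect = 0.5) {
  model <- match.arg(model, .model_names)
  if (model == "single_normal") {
    effect_distribution(model, sd_a = solve_sd_for_prevalence(prevalence, min_effect))
  } else {
    effect_distribution(model,
      w_b = solve_weight_for_prevalence(model, prevalence, min_effect))
  }
}

#' Typical true effect size
#'
#' The mean absolute effect size among true effects, `E[|ES| given |ES| >
#' min_effect]`. This is the "typical" effect a researcher in the field
#' might power an experiment to detect, and it is the default reference
#' effect for sample-size calculations in [simulate_literature()]. The
#' absolute value matters: for mixtures symmetric about zero the signed
#' conditional mean vanishes and could not serve as a power reference.
#'
#' @param dist An [effect_distribution()].
#' @param min_effect Minimum effect size of interest.
#' @param method `"analytic"` (truncated-normal moments, default) or
#'   `"monte_carlo"` (mean of `n_draws` sampled effects beyond the
#'   threshold, mirroring a 100,000-draw estimation procedure).
#' @param n_draws Number of draws for the Monte Carlo method.
#' @return The conditional mean absolute effect size (always >=
#'   `min_effect`).
#' @export
typical_true_effect <- function(dist, min_effect = 0.5,
                                method = c("analytic", "monte_carlo"),
                                n_draws = 100000) {
  stopifnot(inherits(dist, "effect_distribution"))
  method <- match.arg(method)
  prev <- true_prevalence(dist, min_effect)
  if (prev <= 0) {
    abort("The distribution has no mass beyond the minimum of interest; the typical true effect (and hence power) is undefined.")
  }
  if (method == "analytic") {
    num <- (1 - dist$w_b) * .abs_partial_mean(0, dist$sd_a, min_effect) +
      dist$w_b * .abs_partial_mean(dist$mu_b, dist$sd_b, min_effect)
    num / prev
  } else {
    es <- sample_effects(dist, n_draws)
    keep <- abs(es) > min_effect
    if (!any(keep)) {
      abort("No sampled effects exceeded the minimum of interest; increase `n_draws` or check the distribution.")
    }
    mean(abs(es[keep]))
  }
}
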