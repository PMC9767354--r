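# Drive the simulation loop until the target number of published findings
# is reached, recording full provenance of every finding.

.publication_rules <- c("significance_only", "significance_and_magnitude")
.power_references <- c("typical_true_mean", "min_effect", "twice_min_effect")

#' Configuration of one simulated literature
#'
#' Bundles everything needed to simulate a published literature: the
#' effect-size distribution, the power target and its reference effect, the
#' bias parameter, the publication rule, the number of findings to publish
#' and the seed.
#'
#' @param distribution An [effect_distribution()].
#' @param power Target statistical power used to size the experiments, in
#'   (0, 1).
#' @param bias Probability that a non-significant experiment is pushed to
#'   significance and published, in \[0, 1\].
#' @param alpha Two-sided significance level (default 0.05).
#' @param min_effect Minimum effect size of interest separating true from
#'   null effects (default 0.5, a medium effect on the Cohen scale).
#' @param publication_rule `"significance_only"` (default: any significant
#'   result is published) or `"significance_and_magnitude"` (published only
#'   if additionally `|estimate| > min_effect`).
#' @param power_reference Which effect the sample size is powered for:
#'   `"typical_true_mean"` (default; the mean absolute true effect of the
#'   distribution, see [typical_true_effect()]), `"min_effect"`, or
#'   `"twice_min_effect"`.
#' @param n_published Number of published findings to accumulate (default
#'   5000).
#' @param seed Optional integer seed; when supplied the simulation is fully
#'   reproducible.
#' @param n_per_group Optional explicit per-arm sample size, overriding the
#'   power calculation (needed e.g. when the distribution has zero
#'   prevalence and the typical true effect is undefined).
#' @param max_repeats Safety cap on bias re-runs per experiment.
#' @param label Optional scenario label used in error messages and outputs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(distribution,
                              power = 0.8,
                              bias = 0.1,
                              alpha = 0.05,
                              min_effect = 0.5,
                              publication_rule = .publication_rules,
                              power_reference = .power_references,
                              n_published = 5000,
                              seed = NULL,
                              n_per_group = NULL,
                              max_repeats = 1e6,
                              label = NULL) {
  stopifnot(inherits(distribution, "effect_distribution"))
  publication_rule <- match.arg(publication_rule)
  power_reference <- match.arg(power_reference)
  if (power <= 0 || power >= 1) abort("`power` must lie strictly between 0 and 1.")
  .check_prob(bias, "bias")
  .check_prob(alpha, "alpha")
  if (min_effect <= 0) abort("`min_effect` must be positive.")
  if (n_published < 1 || n_published != floor(n_published)) {
    abort("`n_published` must be a positive integer.")
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1 || seed != floor(seed)) {
      abort("`seed` must be a single integer.")
    }
    seed <- as.integer(seed)
  }
  if (!is.null(n_per_group) &&
      (n_per_group < 2 || n_per_group != floor(n_per_group))) {
    abort("`n_per_group` must be an integer >= 2 when supplied.")
  }
  structure(
    list(
      distribution = distribution, power = power, bias = bias, alpha = alpha,
      min_effect = min_effect, publication_rule = publication_rule,
      power_reference = power_reference, n_published = as.integer(n_published),
      seed = seed, n_per_group = n_per_group, max_repeats = max_repeats,
      label = label
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_config%s>\n  model: %s  power: %g (%s)  bias: %g\n",
           "  alpha: %g  min effect: %g  rule: %s\n",
           "  findings: %d  seed: %s\n"),
    if (is.null(x$label)) "" else paste0(" '", x$label, "'"),
    x$distribution$model, x$power, x$power_reference, x$bias,
    x$alpha, x$min_effect, x$publication_rule,
    x$n_published, if (is.null(x$seed)) "<none>" else x$seed
  ))
  invisible(x)
}

# Reference effect used for the sample-size calculation.
.resolve_reference_effect <- function(config) {
  switch(config$power_reference,
    typical_true_mean = typical_true_effect(config$distribution, config$min_effect),
    min_effect = config$min_effect,
    twice_min_effect = 2 * config$min_effect
  )
}

#' Simulate a published literature
#'
#' Resolves the per-arm sample size once from the power specification, then
#' repeatedly draws an effect from the distribution, runs an experiment
#' ([run_experiment()]) and applies the publication decision
#' ([publish_decision()]), until `n_published` findings have entered the
#' literature. Every drawn effect is recorded (published or not) so that the
#' achieved prevalence of true effects can be reported. Findings are
#' classified by the true effect, never the estimate: a finding is a true
#' positive iff `|true_es| > min_effect` and the estimate has the correct
#' sign; every other published finding is a false positive (including
#' significant estimates with the wrong sign).
#'
#' All randomness — effect draws, sampling and bias coin-flips — consumes a
#' single RNG stream in that fixed order, so a run is fully determined by
#' `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `published_literature`: a list with
#'   `findings` (a tibble with one row per published finding: `true_es`,
#'   `estimate`, `p_value`, `repeats`, `is_true_effect`, `sign_correct`,
#'   `classification`), `n_experiments_total` (distinct effects drawn),
#'   `achieved_prevalence`, `n_per_group`, `achieved_power`,
#'   `reference_effect`, and the `config`.
#' @export
simulate_literature <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  runner <- function() .simulate_literature_impl(config)
  res <- tryCatch(
    if (is.null(config$seed)) runner() else withr::with_seed(config$seed, runner()),
    litsim_repeat_cap = function(e) {
      abort(
        sprintf("%sWhile simulating %s: %s",
                "", config$label %||% "a literature", conditionMessage(e)),
        class = "litsim_repeat_cap", parent = e
      )
    },
    litsim_unachievable_prevalence = function(e) {
      abort(
        sprintf("While simulating %s: %s",
                config$label %||% "a literature", conditionMessage(e)),
        class = "litsim_unachievable_prevalence", parent = e
      )
    }
  )
  res
}

.simulate_literature_impl <- function(config) {
  dist <- config$distribution
  m <- config$min_effect
  ref <- .resolve_reference_effect(config)
  n <- config$n_per_group %||% sample_size_for_power(ref, config$power, config$alpha)
  n <- as.integer(n)
  achieved_power <- power_for_sample_size(ref, n, config$alpha)

  target <- config$n_published
  true_es <- numeric(target)
  estimate <- numeric(target)
  p_value <- numeric(target)
  repeats <- integer(target)

  k <- 0L
  drawn_total <- 0L
  drawn_true <- 0L
  while (k < target) {
    es <- sample_effects(dist, 1)
    drawn_total <- drawn_total + 1L
    if (abs(es) > m) drawn_true <- drawn_true + 1L
    first <- run_experiment(es, n, config$alpha)
    res <- publish_decision(first, config$bias, config$publication_rule,
                            m, config$alpha, config$max_repeats)
    if (res$published) {
      k <- k + 1L
      true_es[k] <- res$true_es
      estimate[k] <- res$estimate
      p_value[k] <- res$p_value
      repeats[k] <- res$repeats
    }
  }

  is_true <- abs(true_es) > m
  sign_ok <- sign(estimate) == sign(true_es)
  findings <- tibble(
    true_es = true_es,
    estimate = estimate,
    p_value = p_value,
    repeats = repeats,
    is_true_effect = is_true,
    sign_correct = sign_ok,
    classification = ifelse(is_true & sign_ok, "TP", "FP")
  )
  structure(
    list(
      findings = findings,
      n_experiments_total = drawn_total,
      achieved_prevalence = drawn_true / drawn_total,
      n_per_group = n,
      achieved_power = achieved_power,
      reference_effect = ref,
      config = config
    ),
    class = "published_literature"
  )
}

#' @export
print.published_literature <- function(x, ...) {
  cat(sprintf(
    paste0("<published_literature: %d findings (%s model)>\n",
           "  n per group: %d  achieved power: %.3f  reference effect: %.3f\n",
           "  effects drawn: %d  achieved prevalence: %.3f\n",
           "  PPV: %.3f\n"),
    nrow(x$findings), x$config$distribution$model,
    x$n_per_group, x$achieved_power, x$reference_effect,
    x$n_experiments_total, x$achieved_prevalence,
    mean(x$findings$classification == "TP")
  ))
  invisible(x)
}
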