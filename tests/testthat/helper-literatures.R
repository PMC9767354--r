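# Build a published_literature object directly from known finding values,
# applying the classification rules independently of the simulator, so that
# metric arithmetic can be checked against hand-computable cases.
fake_literature <- function(true_es, estimate, p_value,
                            min_effect = 0.5, alpha = 0.05) {
  is_true <- abs(true_es) > min_effect
  sign_ok <- sign(estimate) == sign(true_es)
  cfg <- simulation_config(
    effect_distribution("dichotomous", w_b = 0.5),
    alpha = alpha, min_effect = min_effect, n_published = length(true_es)
  )
  structure(
    list(
      findings = tibble::tibble(
        true_es = true_es, estimate = estimate, p_value = p_value,
        repeats = 0L, is_true_effect = is_true, sign_correct = sign_ok,
        classification = ifelse(is_true & sign_ok, "TP", "FP")
      ),
      n_experiments_total = length(true_es),
      achieved_prevalence = mean(is_true),
      n_per_group = 17L,
      achieved_power = 0.8,
      reference_effect = 1,
      config = cfg
    ),
    class = "published_literature"
  )
}

# Short-hand for a seeded simulated literature.
sim_lit <- function(model, prevalence, power, bias, n_published, seed, ...) {
  cfg <- simulation_config(
    distribution_for_prevalence(model, prevalence),
    power = power, bias = bias, n_published = n_published, seed = seed, ...
  )
  simulate_literature(cfg)
}
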