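# shared fixtures: a minimal well-formed profile and simulation shortcuts

fixture_profile <- function(subject_id = "P01", visit = "baseline",
                            glucose = c(9, 9, 12, 11, 10, 9, 8),
                            insulin = c(60, 60, 250, 300, 280, 200, 120),
                            cpeptide = c(1.0, 1.0, 1.8, 2.2, 2.1, 1.8, 1.4),
                            uge = 5) {
  mmtt_profile(subject_id = subject_id, visit = visit, arm = "placebo",
               times = c(-15, 0, 30, 60, 90, 120, 180),
               glucose = glucose, insulin = insulin, cpeptide = cpeptide,
               uge_0_3h = uge, weight = 90, height = 170, age = 57,
               sex = "M", diabetic = TRUE)
}

noise_free_config <- function(...) {
  trial_config(noise_glucose = 0, noise_cpeptide = 0, noise_insulin = 0,
               noise_uge = 0, ...)
}

# minimal-regularisation fitting options used for noise-free data
noise_free_fit_config <- function() {
  fit_config(smoothing = list(spar = -1.5, lambda = 0.1))
}

kinetics_for <- function(truth) {
  kinetic_parameters(truth$age, truth$sex,
                     body_surface_area(truth$weight, truth$height),
                     truth$diabetic)
}

draw_truth <- function(seed) {
  set.seed(seed)
  mmttfit:::draw_subject_truth()
}

recovery_errors <- function(truth, fit) {
  gr <- fit$observed_glucose_range
  ti <- truth_indices(truth, gr)
  c(gs = glucose_sensitivity(fit$dose_response, gr[1], gr[2]) /
      ti$glucose_sensitivity - 1,
    isr9 = as.numeric(isr_at_glucose(fit$dose_response, 9)) /
      ti$isr_at_9 - 1,
    total = total_insulin_secretion(fit) / ti$total_secretion - 1,
    rate = fit$rate_sensitivity / ti$rate_sensitivity - 1)
}
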