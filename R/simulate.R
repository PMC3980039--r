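#' Ground-truth subject parameters for simulation
#'
#' Defines one simulated subject: the true beta cell dose-response
#' (reference secretion at 9 mmol/l, mean slope, mild convex curvature),
#' the true potentiation swing and rate sensitivity, insulin clearance,
#' fasting glucose, meal excursion amplitude, renal threshold and
#' anthropometrics.
#'
#' @param isr9 True secretion at 9 mmol/l glucose, pmol min^-1 m^-2.
#' @param glucose_sens True dose-response slope at 9 mmol/l,
#'   pmol min^-1 m^-2 (mmol/l)^-1.
#' @param curvature Quadratic curvature of the dose-response,
#'   pmol min^-1 m^-2 (mmol/l)^-2. Default 0: over the hyperglycaemic
#'   range an MMTT explores in type 2 diabetes the mean ISR-glucose
#'   relation is close to linear, and a linear truth keeps the reference
#'   secretion at 9 mmol/l well defined when 9 mmol/l lies below the
#'   observed glucose range.
#' @param rate_sensitivity True derivative-component parameter,
#'   pmol m^-2 (mmol/l)^-1.
#' @param potentiation_swing Log-scale range of the rising potentiation
#'   trajectory. The default is 0 (flat potentiation): a 7-sample test
#'   cannot separate a sustained potentiation drift from the derivative
#'   component, so the validation population keeps the drift out of the
#'   truth; nonzero values are used in scenarios that exercise the
#'   potentiation machinery itself.
#' @param insulin_clearance True insulin clearance, l min^-1 m^-2.
#' @param fasting_glucose Fasting plasma glucose, mmol/l.
#' @param excursion_amplitude Peak meal-induced glucose rise for a 100-g
#'   carbohydrate meal, mmol/l.
#' @param renal_threshold Renal glucose threshold, mmol/l (4-14).
#' @param weight,height,age,sex,diabetic Anthropometrics.
#' @return A list of class `subject_truth`.
#' @export
subject_truth <- function(isr9 = 140, glucose_sens = 40, curvature = 0,
                          rate_sensitivity = 350,
                          potentiation_swing = 0,
                          insulin_clearance = 1.0,
                          fasting_glucose = 9.5,
                          excursion_amplitude = 5,
                          renal_threshold = 10,
                          weight = 90, height = 170, age = 57,
                          sex = "M", diabetic = TRUE) {
  stopifnot(isr9 > 0, glucose_sens > 0, rate_sensitivity >= 0,
            insulin_clearance > 0, fasting_glucose > 0,
            excursion_amplitude >= 0,
            renal_threshold >= 4, renal_threshold <= 14)
  structure(list(isr9 = isr9, glucose_sens = glucose_sens,
                 curvature = curvature,
                 rate_sensitivity = rate_sensitivity,
                 potentiation_swing = potentiation_swing,
                 insulin_clearance = insulin_clearance,
                 fasting_glucose = fasting_glucose,
                 excursion_amplitude = excursion_amplitude,
                 renal_threshold = renal_threshold,
                 weight = weight, height = height, age = age, sex = sex,
                 diabetic = diabetic),
            class = "subject_truth")
}

# true dose-response: f(G) = isr9 + gs (G - 9) + curvature (G - 9)^2,
# floored at zero
truth_dose_response <- function(truth, g) {
  pmax(truth$isr9 + truth$glucose_sens * (g - 9) +
         truth$curvature * (g - 9)^2, 0)
}

# true potentiation: exponential ramp in time, renormalised to unit
# time-average over [0, 180] on a 1-min grid
truth_potentiation <- function(truth, t) {
  p <- exp(truth$potentiation_swing * (t / 180 - 0.5))
  tg <- 0:180
  pg <- exp(truth$potentiation_swing * (tg / 180 - 0.5))
  p / (trapezoid_auc(tg, pg) / 180)
}

truth_isr <- function(truth, t, glucose_scale = 1, gs_multiplier = 1,
                      schedule = mmtt_schedule()) {
  cur <- truth_glucose_curve(truth, schedule, glucose_scale)
  g <- cur$g(t)
  dg <- cur$dg(t)
  f <- pmax(truth$isr9 + gs_multiplier * truth$glucose_sens * (g - 9) +
              truth$curvature * (g - 9)^2, 0)
  pmax(truth_potentiation(truth, t) * f +
         truth$rate_sensitivity * pmax(dg, 0), 0)
}

# gamma-like unimodal meal pulse peaking at 45 min, zero for t <= 0
meal_pulse <- function(t, peak_time = 45, shape = 2) {
  ifelse(t <= 0, 0,
         (t / peak_time)^shape * exp(shape * (1 - t / peak_time)))
}

# The true continuous glucose trajectory is the natural cubic spline
# through the gamma-pulse excursion sampled at the schedule times: plasma
# glucose between draws is by construction the minimum-curvature curve
# consistent with the samples, so the continuous trajectory (and its
# derivative, which drives the secretion model's rate component) is
# recoverable from the sampled record alone.
truth_glucose_curve <- function(truth, schedule = mmtt_schedule(),
                                glucose_scale = 1, carb = 100) {
  vals <- glucose_scale * (truth$fasting_glucose +
                             truth$excursion_amplitude * (carb / 100) *
                             meal_pulse(schedule))
  sf <- stats::splinefun(schedule, vals, method = "natural")
  list(g = function(t) sf(t), dg = function(t) sf(t, deriv = 1))
}

truth_glucose <- function(truth, t, glucose_scale = 1, carb = 100,
                          schedule = mmtt_schedule()) {
  truth_glucose_curve(truth, schedule, glucose_scale, carb)$g(t)
}

#' Noiseless meal glucose excursion
#'
#' Deterministic glucose trajectory: fasting level before the meal, then a
#' smooth unimodal excursion (gamma-like pulse peaking near 45 min) scaled
#' by the meal's carbohydrate content, decaying toward baseline by 180 min.
#'
#' @param truth A [subject_truth()].
#' @param meal A [meal_spec()].
#' @param schedule Sampling times, minutes, within \[-15, 180\].
#' @return Glucose, mmol/l, at each schedule time.
#' @export
simulate_glucose_profile <- function(truth, meal = meal_spec(),
                                     schedule = mmtt_schedule()) {
  stopifnot(all(schedule >= -15), all(schedule <= 180))
  truth_glucose(truth, schedule, carb = meal$carbohydrate_g,
                schedule = schedule)
}

#' Default FS-MMTT sampling schedule
#' @return Times in minutes: -15, 0, 30, 60, 90, 120, 180.
#' @export
mmtt_schedule <- function() c(-15, 0, 30, 60, 90, 120, 180)

#' Trial simulation settings
#'
#' @param arms Named list of per-arm endpoint effects, each a list with
#'   `glucose_lowering` (fractional lowering of the whole glucose
#'   profile), `threshold_shift` (additive change in the renal glucose
#'   threshold, mmol/l; SGLT2 inhibition lowers it) and `gs_multiplier`
#'   (multiplier on true beta cell glucose sensitivity).
#' @param n_per_arm Subjects per arm.
#' @param noise_glucose,noise_cpeptide,noise_insulin Multiplicative
#'   log-normal measurement noise SDs (fractions; defaults 1, 4 and 6
#'   percent).
#' @param noise_uge Log-normal noise SD on the urine glucose mass.
#' @param renal_clearance_above_threshold Glucose clearance applied to the
#'   excess of plasma glucose over the renal threshold, l/min.
#' @param seed Global integer seed; expanded deterministically into
#'   per-subject, per-visit substreams.
#' @param schedule Sampling schedule, minutes.
#' @return A list of class `trial_config`.
#' @export
trial_config <- function(
    arms = list(
      placebo = list(glucose_lowering = 0, threshold_shift = 0,
                     gs_multiplier = 1),
      treated = list(glucose_lowering = 0.08, threshold_shift = -5,
                     gs_multiplier = 1.15)),
    n_per_arm = 40,
    noise_glucose = 0.01, noise_cpeptide = 0.04, noise_insulin = 0.06,
    noise_uge = 0.05,
    renal_clearance_above_threshold = 0.09,
    seed = 1, schedule = mmtt_schedule()) {
  stopifnot(n_per_arm >= 1, noise_glucose >= 0, noise_cpeptide >= 0,
            noise_insulin >= 0, noise_uge >= 0)
  structure(list(arms = arms, n_per_arm = n_per_arm,
                 noise_glucose = noise_glucose,
                 noise_cpeptide = noise_cpeptide,
                 noise_insulin = noise_insulin, noise_uge = noise_uge,
                 renal_clearance_above_threshold =
                   renal_clearance_above_threshold,
                 seed = seed, schedule = schedule),
            class = "trial_config")
}

# Deterministic seed splitting: a subject keeps its substream when
# n_per_arm grows, and baseline/endpoint visits draw independent noise.
substream_seed <- function(seed, arm_index, subject_index, visit_code) {
  (as.numeric(seed) %% 65011 * 32771 + arm_index * 4099 +
     subject_index * 211 + visit_code) %% 2147483647
}

#' Simulate one subject-visit MMTT
#'
#' Forward-simulates the full observable record implied by a ground
#' truth: noiseless glucose excursion, secretion from the beta cell model
#' equations applied to the noiseless glucose, plasma C-peptide through
#' the two-compartment kinetics, insulin consistent with the true
#' clearance, urinary glucose from a renal threshold model, then
#' multiplicative log-normal measurement noise on the sampled values.
#'
#' @param truth A [subject_truth()].
#' @param config A [trial_config()].
#' @param seed Integer seed for the measurement noise.
#' @param visit,arm,subject_id Labels for the resulting profile.
#' @param effects Optional arm-effect list (as in [trial_config()] arms)
#'   applied to the truth before simulation.
#' @return An [mmtt_profile()].
#' @export
simulate_subject <- function(truth, config = trial_config(), seed = 1,
                             visit = "baseline", arm = "placebo",
                             subject_id = "S1", effects = NULL) {
  glucose_scale <- 1; gs_mult <- 1; thr <- truth$renal_threshold
  if (!is.null(effects)) {
    glucose_scale <- 1 - effects$glucose_lowering
    gs_mult <- effects$gs_multiplier
    thr <- min(max(thr + effects$threshold_shift, 1), 14)
  }
  sched <- config$schedule
  bsa <- body_surface_area(truth$weight, truth$height)
  kin <- kinetic_parameters(truth$age, truth$sex, bsa, truth$diabetic)

  grid <- seq(0, 180, by = 5)
  isr_grid <- truth_isr(truth, grid, glucose_scale, gs_mult,
                        schedule = sched)
  c0 <- isr_grid[1] * bsa / (kin$volume * kin$k01) / 1000
  cp_grid <- simulate_cpeptide(grid, isr_grid, kin, bsa, c0)

  g_sched <- truth_glucose(truth, sched, glucose_scale, schedule = sched)
  cp_sched <- ifelse(sched <= 0, c0,
                     stats::approx(grid, cp_grid, pmax(sched, 0))$y)
  isr_sched <- truth_isr(truth, pmax(sched, 0), glucose_scale, gs_mult,
                         schedule = sched)
  ins_sched <- isr_sched / truth$insulin_clearance    # pmol/l

  fine <- 0:180
  g_fine <- truth_glucose(truth, fine, glucose_scale, schedule = sched)
  uge_mmol <- config$renal_clearance_above_threshold *
    trapezoid_auc(fine, pmax(g_fine - thr, 0))
  uge_g <- uge_mmol * 0.18016

  set.seed(as.integer(seed))
  n <- length(sched)
  g_obs <- g_sched * exp(stats::rnorm(n, 0, config$noise_glucose))
  cp_obs <- cp_sched * exp(stats::rnorm(n, 0, config$noise_cpeptide))
  ins_obs <- ins_sched * exp(stats::rnorm(n, 0, config$noise_insulin))
  uge_obs <- uge_g * exp(stats::rnorm(1, 0, config$noise_uge))

  mmtt_profile(subject_id = subject_id, visit = visit, arm = arm,
               times = sched, glucose = g_obs, insulin = ins_obs,
               cpeptide = cp_obs, uge_0_3h = uge_obs,
               weight = truth$weight, height = truth$height,
               age = truth$age, sex = truth$sex, diabetic = truth$diabetic)
}

# Population draw of one subject truth; distributions emulate the
# baseline characteristics of FS-MMTT cohorts in long-standing type 2
# diabetes (fasting glucose ~9.5 mmol/l, glucose sensitivity ~25-60,
# secretion at 9 mmol/l ~100-200, rate sensitivity ~200-600).
draw_subject_truth <- function() {
  rlnorm_m <- function(m, cv) stats::rlnorm(1, log(m) - 0.5 * log(1 + cv^2),
                                            sqrt(log(1 + cv^2)))
  tnorm <- function(m, s, lo, hi) min(max(stats::rnorm(1, m, s), lo), hi)
  isr9 <- rlnorm_m(140, 0.25)
  glucose_sens <- rlnorm_m(40, 0.3)
  # basal secretion must stay positive: fasting glucose cannot sit below
  # the point where the subject's dose-response falls under
  # 20 pmol min^-1 m^-2
  fg_floor <- 9 - (isr9 - 20) / glucose_sens
  subject_truth(
    isr9 = isr9,
    glucose_sens = glucose_sens,
    curvature = 0,
    rate_sensitivity = rlnorm_m(350, 0.4),
    potentiation_swing = 0,
    insulin_clearance = tnorm(1.0, 0.15, 0.5, 1.8),
    fasting_glucose = tnorm(9.5, 1.5, max(6, fg_floor), 14),
    excursion_amplitude = tnorm(5, 1, 2, 9),
    renal_threshold = tnorm(10, 1, 6, 14),
    weight = tnorm(90, 18, 50, 160), height = tnorm(170, 9, 145, 200),
    age = tnorm(57, 9, 30, 80),
    sex = if (stats::runif(1) < 0.5) "M" else "F")
}

#' Simulate a two-visit, multi-arm MMTT trial
#'
#' Draws per-subject truths from the population model, simulates a
#' baseline and an endpoint visit per subject, and applies the configured
#' arm effects (renal threshold shift, glucose lowering, glucose
#' sensitivity change) to the endpoint truths of each arm.
#'
#' @param config A [trial_config()].
#' @return A list with `profiles` (list of [mmtt_profile()], two per
#'   subject) and `truth` (data frame of hidden per-subject truths and the
#'   applied endpoint effects, never read by the analysis pipeline).
#' @export
simulate_trial <- function(config = trial_config()) {
  profiles <- list()
  truth_rows <- list()
  arm_names <- names(config$arms)
  for (a in seq_along(arm_names)) {
    eff <- config$arms[[a]]
    for (s in seq_len(config$n_per_arm)) {
      set.seed(as.integer(substream_seed(config$seed, a, s, 0)))
      tr <- draw_subject_truth()
      id <- sprintf("%s-%03d", arm_names[a], s)
      base <- simulate_subject(tr, config,
                               seed = substream_seed(config$seed, a, s, 1),
                               visit = "baseline", arm = arm_names[a],
                               subject_id = id)
      endp <- simulate_subject(tr, config,
                               seed = substream_seed(config$seed, a, s, 2),
                               visit = "endpoint", arm = arm_names[a],
                               subject_id = id, effects = eff)
      profiles <- c(profiles, list(base, endp))
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject_id = id, arm = arm_names[a],
        isr9 = tr$isr9, glucose_sens = tr$glucose_sens,
        rate_sensitivity = tr$rate_sensitivity,
        insulin_clearance = tr$insulin_clearance,
        fasting_glucose = tr$fasting_glucose,
        renal_threshold = tr$renal_threshold,
        glucose_lowering = eff$glucose_lowering,
        threshold_shift = eff$threshold_shift,
        gs_multiplier = eff$gs_multiplier)
    }
  }
  list(profiles = profiles, truth = do.call(rbind, truth_rows))
}

#' True secretion indices implied by a subject truth
#'
#' Evaluates the generating model on the same definitions the fitting
#' pipeline uses (chord slope over an observed glucose range, secretion at
#' 9 mmol/l, trapezoid integral of the true 5-min ISR grid), so recovery
#' can be scored against like-for-like targets.
#'
#' @param truth A [subject_truth()].
#' @param g_range Observed glucose range (mmol/l) over which the mean
#'   slope is taken.
#' @param glucose_scale,gs_multiplier Endpoint effects, as applied in
#'   [simulate_subject()].
#' @return A list with `glucose_sensitivity`, `isr_at_9`,
#'   `total_secretion` (nmol/m^2) and `rate_sensitivity`.
#' @export
truth_indices <- function(truth, g_range, glucose_scale = 1,
                          gs_multiplier = 1) {
  f <- function(g) pmax(truth$isr9 +
                          gs_multiplier * truth$glucose_sens * (g - 9) +
                          truth$curvature * (g - 9)^2, 0)
  grid <- seq(0, 180, by = 5)
  list(glucose_sensitivity =
         (f(g_range[2]) - f(g_range[1])) / (g_range[2] - g_range[1]),
       isr_at_9 = f(9),
       total_secretion =
         trapezoid_auc(grid, truth_isr(truth, grid, glucose_scale,
                                       gs_multiplier)) / 1000,
       rate_sensitivity = truth$rate_sensitivity)
}
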