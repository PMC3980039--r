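test_that("dose-response evaluation, chord slope and extrapolation", {
  dr_lin <- dose_response(c(4, 14), c(40, 140))       # f(G) = 10 G
  expect_equal(as.numeric(isr_at_glucose(dr_lin, 9)), 90)
  expect_equal(glucose_sensitivity(dr_lin, 5, 12), 10)
  # quadratic sampled densely: mean slope over [5, 10] = chord = 15
  g <- seq(4, 12, by = 0.05)
  dr_sq <- dose_response(g, g^2)
  expect_equal(glucose_sensitivity(dr_sq, 5, 10), 15, tolerance = 1e-9)
  expect_equal(glucose_sensitivity(dose_response(c(5, 10), c(7, 7)),
                                   5, 10), 0)
  dr2 <- dose_response(c(5, 10), c(50, 150))
  expect_equal(as.numeric(isr_at_glucose(dr2, 9)), 130)
  v12 <- isr_at_glucose(dr2, 12)
  expect_equal(as.numeric(v12), 190)
  expect_true(isTRUE(attr(v12, "extrapolated")))
  expect_error(glucose_sensitivity(dr2, 9, 9), "degenerate")
})

test_that("secretion rate adds dose-response, potentiation and the
           one-sided derivative component", {
  # a profile whose glucose ramps linearly: spline G(t) is exact and
  # dG/dt is constant, so the components can be checked analytically
  tt <- c(-15, 0, 30, 60, 90, 120, 180)
  gl <- 9 + pmax(tt, 0) * 0.01             # +0.01 mmol/l per min
  p <- fixture_profile(glucose = gl)
  kin <- kinetic_parameters(57, "M", body_surface_area(90, 170), TRUE)
  fit <- fit_secretion_model(p, kin, noise_free_fit_config())
  # overwrite the fitted components with known values; the evaluator is
  # what is under test
  fit$dose_response <- dose_response(c(4, 14), c(40, 140))   # f = 10 G
  fit$potentiation_values <- rep(1, length(fit$potentiation_values))
  fit$rate_sensitivity <- 500
  g90 <- predict(fit$glucose_spline, 90)$y
  dg90 <- predict(fit$glucose_spline, 90, deriv = 1)$y
  expect_equal(secretion_rate(fit, 90), 10 * g90 + 500 * max(dg90, 0),
               tolerance = 1e-9)
  expect_equal(dg90, 0.01, tolerance = 0.05)  # spline wiggle at the
                                              # pre-meal kink
  # falling glucose: derivative component inactive
  fit$rate_sensitivity <- 0
  base <- secretion_rate(fit, 90)
  fit$rate_sensitivity <- 500
  gl_f <- 14 - pmax(tt, 0) * 0.01
  p2 <- fixture_profile(glucose = gl_f, cpeptide = rev(c(1, 1, 1.4, 1.8,
                                                         2.1, 2.2, 2.4)))
  fit2 <- fit_secretion_model(p2, kin, noise_free_fit_config())
  fit2$dose_response <- dose_response(c(4, 16), c(40, 160))
  fit2$potentiation_values <- rep(1, length(fit2$potentiation_values))
  fit2$rate_sensitivity <- 500
  g90f <- predict(fit2$glucose_spline, 90)$y
  expect_equal(secretion_rate(fit2, 90), 10 * g90f, tolerance = 1e-6)
  expect_error(secretion_rate(fit, 200), "\\[0, 180\\]")
})

test_that("fitting requires identifiable input", {
  p <- fixture_profile(cpeptide = c(1, 1, NA, NA, NA, 1.8, 1.4))
  kin <- kinetic_parameters(57, "M", 2, TRUE)
  expect_error(fit_secretion_model(p, kin), "at least 5")
  p2 <- fixture_profile(glucose = rep(9, 7))
  expect_error(fit_secretion_model(p2, kin), "unidentifiable")
})

test_that("noise-free closed loop recovers the generating indices", {
  cfg <- noise_free_config()
  for (s in 1:4) {
    tr <- draw_truth(400 + s)
    p <- simulate_subject(tr, cfg, seed = s)
    fit <- fit_secretion_model(p, kinetics_for(tr),
                               noise_free_fit_config())
    err <- recovery_errors(tr, fit)
    expect_lt(abs(err["gs"]), 0.03)
    expect_lt(abs(err["isr9"]), 0.03)
    expect_lt(abs(err["total"]), 0.03)
    expect_lt(abs(err["rate"]), 0.15)   # weakly identified from 7 samples
  }
})

test_that("every fit keeps unit-mean potentiation and a complete
           non-negative ISR grid", {
  cfg <- trial_config()
  for (s in 1:5) {
    tr <- draw_truth(500 + s)
    p <- simulate_subject(tr, cfg, seed = 40 + s)
    fit <- fit_secretion_model(p, kinetics_for(tr))
    expect_equal(trapezoid_auc(fit$grid, fit$potentiation) / 180, 1,
                 tolerance = 1e-6)
    expect_length(fit$isr_grid, 37)
    expect_identical(fit$grid, seq(0, 180, by = 5))
    expect_true(all(fit$isr_grid >= 0))
    expect_true(all(fit$potentiation > 0))
  }
})

test_that("smoothing selection drives residual SDs to the measurement
           error targets on noisy data and flags the noiseless boundary", {
  cfg <- trial_config()
  g_sd <- cp_sd <- numeric(0)
  for (s in 1:6) {
    tr <- draw_truth(600 + s)
    p <- simulate_subject(tr, cfg, seed = 60 + s)
    sel <- select_smoothing(p, kinetics_for(tr))
    g_sd <- c(g_sd, sel$glucose_resid_sd)
    cp_sd <- c(cp_sd, sel$cp_resid_sd)
  }
  expect_gt(mean(g_sd), 0.7); expect_lt(mean(g_sd), 1.3)
  expect_gt(mean(cp_sd), 2.8); expect_lt(mean(cp_sd), 5.2)
  # noiseless input: targets unreachable from above, boundary returned
  tr <- draw_truth(699)
  p0 <- simulate_subject(tr, noise_free_config(), seed = 1)
  sel0 <- select_smoothing(p0, kinetics_for(tr))
  expect_lt(sel0$glucose_resid_sd, 1.3)
  expect_lt(sel0$cp_resid_sd, 5.2)
  expect_true(is.na(sel0$flags[["cpeptide"]]) ||
                sel0$flags[["cpeptide"]] == "at_upper_bound")
})

test_that("self-consistency: the fitted ISR grid reproduces the observed
           C-peptide within the selected residual band", {
  cfg <- trial_config()
  tr <- draw_truth(700)
  p <- simulate_subject(tr, cfg, seed = 70)
  fit <- fit_secretion_model(p, kinetics_for(tr))
  kin <- kinetics_for(tr)
  bsa <- body_surface_area(p$weight, p$height)
  cp_sim <- simulate_cpeptide(fit$grid, fit$isr_grid, kin, bsa, fit$c0)
  obs_t <- fit$cp_obs_times
  pred <- approx(fit$grid, cp_sim, obs_t)$y
  resid <- (fit$cp_obs - pred) / fit$cp_obs
  sd_hat <- 100 * sqrt(sum(resid^2) / (length(resid) - fit$cp_resid_dof))
  expect_lt(sd_hat, 1.3 * fit_config()$cp_resid_target + 0.5)
})

test_that("fitted ISR agrees with an unstructured regularised
           deconvolution on noiseless data", {
  # flat potentiation, no derivative component: ISR(t) = f(G(t)), which an
  # unstructured deconvolution can also represent
  tr <- subject_truth(rate_sensitivity = 0)
  p <- simulate_subject(tr, noise_free_config(), seed = 1)
  bsa <- body_surface_area(tr$weight, tr$height)
  kin <- kinetics_for(tr)
  fit <- fit_secretion_model(p, kin, noise_free_fit_config())
  grid <- fit$grid
  c0 <- fasting_value(p, "cpeptide")
  # independent linear response map built by probing the forward model
  H <- sapply(seq_along(grid), function(j) {
    e <- numeric(length(grid)); e[j] <- 1
    simulate_cpeptide(grid, e, kin, bsa, 0)
  })
  h0 <- simulate_cpeptide(grid, numeric(length(grid)), kin, bsa, c0)
  obs_t <- p$times[p$times >= 0]
  W <- t(sapply(obs_t, function(t) {
    j <- findInterval(t, grid, all.inside = TRUE)
    w <- (t - grid[j]) / 5
    r <- numeric(length(grid)); r[j] <- 1 - w; r[j + 1] <- w; r
  }))
  cp <- p$cpeptide[p$times >= 0]
  basal <- c0 * kin$k01 * kin$volume * 1000 / bsa
  D2 <- diff(diag(length(grid)), differences = 2)
  X <- rbind((W %*% H) / cp, c(1, numeric(length(grid) - 1)) / basal,
             sqrt(1e-6) * D2)
  y <- c((cp - W %*% h0) / cp, 1, numeric(nrow(D2)))
  isr_oracle <- pracma::lsqnonneg(X, y)$x
  # agreement to the oracle's own resolution: exact on the integral and at
  # the observation nodes; mid-interval values reflect the oracle's
  # smoothness prior (it cannot localise the early rise from 6 samples)
  expect_equal(trapezoid_auc(grid, fit$isr_grid),
               trapezoid_auc(grid, isr_oracle), tolerance = 0.01)
  iobs <- match(obs_t, grid)
  expect_lt(max(abs(fit$isr_grid - isr_oracle)[iobs] / isr_oracle[iobs]),
            0.05)
  rel <- (fit$isr_grid - isr_oracle) / pmax(isr_oracle, 1)
  expect_lt(sqrt(mean(rel^2)), 0.03)
  expect_lt(max(abs(rel)), 0.10)
})

test_that("scaling the true dose-response scales the recovered secretion
           at 9 mmol/l proportionally", {
  cfg <- noise_free_config()
  for (s in 1:3) {
    tr <- draw_truth(800 + s)
    tr_hi <- tr
    tr_hi$isr9 <- tr$isr9 * 1.5
    tr_hi$glucose_sens <- tr$glucose_sens * 1.5
    f1 <- fit_secretion_model(simulate_subject(tr, cfg, seed = s),
                              kinetics_for(tr), noise_free_fit_config())
    f2 <- fit_secretion_model(simulate_subject(tr_hi, cfg, seed = s),
                              kinetics_for(tr), noise_free_fit_config())
    ratio <- as.numeric(isr_at_glucose(f2$dose_response, 9)) /
      as.numeric(isr_at_glucose(f1$dose_response, 9))
    expect_equal(ratio, 1.5, tolerance = 0.05)
  }
})

test_that("total secretion and insulin clearance follow their
           definitions", {
  tr <- draw_truth(900)
  p <- simulate_subject(tr, noise_free_config(), seed = 9)
  fit <- fit_secretion_model(p, kinetics_for(tr), noise_free_fit_config())
  expect_equal(total_insulin_secretion(fit),
               trapezoid_auc(fit$grid, fit$isr_grid) / 1000)
  # constant ISR 100 over 180 min integrates to 18 nmol/m^2
  fit$isr_grid <- rep(100, 37)
  expect_equal(total_insulin_secretion(fit), 18)
  # unit cancellation: 18 nmol/m^2 over AUC 18000 pmol min/l -> 1.0
  p_const <- fixture_profile(insulin = c(100, 100, 100, 100, 100, 100, 100))
  expect_equal(insulin_clearance(18, p_const), 1.0)
  # doubling insulin halves clearance
  p_double <- fixture_profile(insulin = rep(200, 7))
  expect_equal(insulin_clearance(18, p_double), 0.5)
  # fewer than five insulin measurements: filtered to NA
  p_few <- fixture_profile(insulin = c(60, 60, 250, 300, NA, NA, NA))
  expect_true(is.na(insulin_clearance(18, p_few)))
})
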