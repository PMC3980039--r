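#' Beta cell function and insulin sensitivity indices for one profile
#'
#' Runs the full per-subject-visit analysis: secretion-model fit
#' (dose-response, potentiation, rate sensitivity), derived indices
#' (glucose sensitivity over the observed glucose range, ISR at 9 mmol/l,
#' total insulin secretion), insulin clearance (with the >= 5
#' insulin-sample filter), mean postprandial glucose, and OGIS with the
#' urinary-glucose correction.
#'
#' @param profile An [mmtt_profile()].
#' @param meal A [meal_spec()].
#' @param config A [fit_config()].
#' @param kinetics Optional [kinetic_parameters()]; derived from the
#'   profile's anthropometrics when NULL.
#' @return A one-row data frame with the index columns plus fit
#'   diagnostics (residual SDs, convergence).
#' @export
beta_cell_indices <- function(profile, meal = meal_spec(),
                              config = fit_config(), kinetics = NULL) {
  bsa <- body_surface_area(profile$weight, profile$height)
  if (is.null(kinetics))
    kinetics <- kinetic_parameters(profile$age, profile$sex, bsa,
                                   profile$diabetic)
  fit <- fit_secretion_model(profile, kinetics, config)
  gr <- fit$observed_glucose_range
  total <- total_insulin_secretion(fit)
  og <- tryCatch(ogis_2h(profile, meal, bsa), error = function(e) NA_real_)
  renal <- renal_glucose_clearance(profile$uge_0_3h,
                                   postprandial_auc(profile, "glucose"),
                                   bsa)
  data.frame(
    subject_id = profile$subject_id, visit = profile$visit,
    arm = profile$arm,
    glucose_sensitivity = glucose_sensitivity(fit$dose_response,
                                              gr[1], gr[2]),
    isr_at_9 = as.numeric(isr_at_glucose(fit$dose_response, 9)),
    rate_sensitivity = fit$rate_sensitivity,
    total_secretion = total,
    insulin_clearance = insulin_clearance(total, profile),
    ogis = og,
    ogis_c = ogis_corrected(og, renal),
    renal_clearance = renal,
    mpg_0_3h = mpg_0_3h(profile),
    fasting_glucose = fasting_value(profile, "glucose"),
    uge_0_3h = profile$uge_0_3h,
    residual_sd_glucose = fit$residual_sd_glucose,
    residual_sd_cpeptide = fit$residual_sd_cpeptide,
    converged = fit$converged)
}

#' Analyse every profile of a trial dataset
#'
#' @param profiles List of [mmtt_profile()] objects.
#' @param meal,config Passed to [beta_cell_indices()].
#' @return A data frame with one row per subject-visit.
#' @export
analyze_trial <- function(profiles, meal = meal_spec(),
                          config = fit_config()) {
  do.call(rbind, lapply(profiles, beta_cell_indices, meal = meal,
                        config = config))
}

# parameters analysed on the log scale (log-normal distributions) and the
# parameter using the rank-based test
log_scale_parameters <- c("glucose_sensitivity", "ogis", "ogis_c")
rank_test_parameters <- c("rate_sensitivity")

#' Between-arm comparison of baseline-to-endpoint changes
#'
#' Reshapes per-subject-visit indices into change records and applies the
#' trial statistics parameter by parameter: ANCOVA with baseline value and
#' HbA1c stratum as covariates (log scale for glucose sensitivity and the
#' OGIS measures), Kruskal-Wallis for rate sensitivity. Complete-case per
#' parameter; p < 0.05 two-sided is the significance convention.
#'
#' @param indices Data frame from [analyze_trial()].
#' @param comparator_arm Reference arm label.
#' @param parameters Character vector of index columns to analyse.
#' @param hba1c_high Optional named logical vector (by subject_id) of the
#'   baseline HbA1c >= 9 percent stratum; defaults to all FALSE.
#' @return A data frame with one row per (parameter, arm contrast).
#' @export
compare_arms <- function(indices, comparator_arm,
                         parameters = c("glucose_sensitivity", "isr_at_9",
                                        "rate_sensitivity",
                                        "total_secretion",
                                        "insulin_clearance",
                                        "ogis", "ogis_c", "uge_0_3h"),
                         hba1c_high = NULL) {
  out <- list()
  for (par in parameters) {
    wide <- merge(
      indices[indices$visit == "baseline",
              c("subject_id", "arm", par)],
      indices[indices$visit == "endpoint", c("subject_id", par)],
      by = "subject_id", suffixes = c("_baseline", "_endpoint"))
    h <- if (is.null(hba1c_high)) FALSE else
      unname(hba1c_high[wide$subject_id])
    rec <- change_records(wide$subject_id, wide$arm,
                          wide[[paste0(par, "_baseline")]],
                          wide[[paste0(par, "_endpoint")]], h)
    if (par %in% rank_test_parameters) {
      kw <- kruskal_wallis_change(rec)
      arms <- setdiff(names(kw$mean_change), comparator_arm)
      out[[par]] <- data.frame(
        parameter = par, arm = arms,
        lsm_diff = as.numeric(kw$mean_change[arms] -
                                kw$mean_change[comparator_arm]),
        sem = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
        p_value = kw$p_value, test = "kruskal-wallis", transform = "rank")
    } else {
      res <- ancova_lsm_change(rec, comparator_arm,
                               log_scale = par %in% log_scale_parameters)
      out[[par]] <- data.frame(
        parameter = par, arm = res$contrasts$arm,
        lsm_diff = res$contrasts$lsm_diff, sem = res$contrasts$sem,
        ci_lo = res$contrasts$ci_lo, ci_hi = res$contrasts$ci_hi,
        p_value = res$contrasts$p_value, test = "ancova",
        transform = res$transform)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write per-subject-visit results and a run manifest
#'
#' @param indices Data frame from [analyze_trial()].
#' @param results_path Output CSV path.
#' @param manifest_path Optional JSON manifest path recording the fitting
#'   configuration, seed, kinetic-parameter convention and package
#'   version.
#' @param config The [fit_config()] used.
#' @param seed The seed used for any simulation input.
#' @return Invisibly, `results_path`.
#' @export
write_results <- function(indices, results_path, manifest_path = NULL,
                          config = fit_config(), seed = NA) {
  utils::write.csv(indices, results_path, row.names = FALSE, na = "")
  if (!is.null(manifest_path)) {
    manifest <- list(
      package = "mmttfit",
      version = as.character(utils::packageVersion("mmttfit")),
      seed = seed,
      config = unclass(config)[!vapply(unclass(config), is.null,
                                       logical(1))],
      cpeptide_kinetics = "population two-compartment (anthropometric regression, diabetic class)",
      n_rows = nrow(indices))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(results_path)
}
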