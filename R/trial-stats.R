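#' Build baseline/endpoint change records
#'
#' @param subject_id,arm Character vectors.
#' @param baseline_value,endpoint_value Numeric parameter values.
#' @param baseline_hba1c_high Logical; baseline HbA1c >= 9.0 percent
#'   (75 mmol/mol), the glycaemic-control covariate.
#' @return A data frame of class `change_records`.
#' @export
change_records <- function(subject_id, arm, baseline_value, endpoint_value,
                           baseline_hba1c_high = FALSE) {
  df <- data.frame(subject_id = as.character(subject_id),
                   arm = as.character(arm),
                   baseline_value = as.numeric(baseline_value),
                   endpoint_value = as.numeric(endpoint_value),
                   baseline_hba1c_high = as.logical(baseline_hba1c_high))
  class(df) <- c("change_records", "data.frame")
  df
}

#' ANCOVA least-squares-mean changes between arms
#'
#' Fits endpoint ~ baseline + HbA1c stratum + treatment arm by ordinary
#' least squares (complete cases). Least-squares means are model
#' predictions at the grand-mean covariates; the reported "change" LSM is
#' the adjusted endpoint LSM minus the pooled baseline mean. Comparator-
#' subtracted differences carry SEs, t-based 95 percent CIs and two-sided
#' p-values on residual degrees of freedom. With `log_scale = TRUE`,
#' significance testing is performed on log-transformed values while
#' point estimates are reported on the original scale.
#'
#' A covariate that is constant across the records (for example a single
#' HbA1c stratum) carries no information and is dropped from the design;
#' a deficiency that leaves an arm effect inestimable is an error.
#'
#' @param records A [change_records()] data frame (>= 2 arms, >= 3
#'   complete records each).
#' @param comparator_arm Reference arm label (placebo or active
#'   comparator).
#' @param log_scale Test on the log scale (used for parameters with
#'   log-normal distributions such as glucose sensitivity and OGIS).
#' @return A list of class `trial_result`: `per_arm` (n, LSM endpoint,
#'   LSM change, SEM per arm) and `contrasts` (comparator-subtracted LSM
#'   difference, SEM, CI, p per non-comparator arm), plus `transform`,
#'   `test` and residual `df`.
#' @export
ancova_lsm_change <- function(records, comparator_arm,
                              log_scale = FALSE) {
  rec <- records[stats::complete.cases(
    records[, c("arm", "baseline_value", "endpoint_value",
                "baseline_hba1c_high")]), ]
  arms <- unique(rec$arm)
  if (length(arms) < 2)
    stop("ANCOVA needs at least 2 arms with data", call. = FALSE)
  if (!comparator_arm %in% arms)
    stop("comparator arm '", comparator_arm, "' has no records",
         call. = FALSE)
  n_arm <- table(rec$arm)
  if (any(n_arm < 3))
    stop("arms with fewer than 3 complete records: ",
         paste(names(n_arm)[n_arm < 3], collapse = ", "), call. = FALSE)
  if (log_scale && any(rec$baseline_value <= 0 | rec$endpoint_value <= 0))
    stop("log-scale analysis requires positive values", call. = FALSE)

  rec$arm <- stats::relevel(factor(rec$arm), ref = comparator_arm)
  fit_one <- function(y, x) {
    d <- data.frame(y = y, x = x, h = as.numeric(rec$baseline_hba1c_high),
                    arm = rec$arm)
    drop_base <- stats::sd(d$x) < 1e-12
    drop_h <- stats::sd(d$h) < 1e-12
    form <- stats::reformulate(
      c(if (!drop_base) "x", if (!drop_h) "h", "arm"), response = "y")
    m <- stats::lm(form, data = d)
    if (anyNA(stats::coef(m)))
      stop("rank-deficient ANCOVA design: ",
           paste(names(stats::coef(m))[is.na(stats::coef(m))],
                 collapse = ", "), call. = FALSE)
    list(m = m, d = d, drop_base = drop_base, drop_h = drop_h)
  }

  raw <- fit_one(rec$endpoint_value, rec$baseline_value)
  test_fit <- if (log_scale)
    fit_one(log(rec$endpoint_value), log(rec$baseline_value)) else raw

  # LSM per arm: prediction at grand-mean covariates
  lsm_of <- function(f) {
    nd <- data.frame(x = mean(f$d$x), h = mean(f$d$h),
                     arm = factor(levels(rec$arm), levels = levels(rec$arm)))
    pr <- stats::predict(f$m, newdata = nd, se.fit = TRUE)
    list(est = pr$fit, se = pr$se.fit)
  }
  lsm <- lsm_of(raw)
  base_mean <- mean(rec$baseline_value)
  per_arm <- data.frame(arm = levels(rec$arm),
                        n = as.integer(table(rec$arm)[levels(rec$arm)]),
                        lsm_endpoint = as.numeric(lsm$est),
                        lsm_change = as.numeric(lsm$est) - base_mean,
                        sem = as.numeric(lsm$se))

  # comparator-subtracted differences: the arm coefficients themselves
  contrast_of <- function(f) {
    cf <- stats::coef(f$m); V <- stats::vcov(f$m)
    idx <- grep("^arm", names(cf))
    data.frame(arm = sub("^arm", "", names(cf)[idx]),
               diff = as.numeric(cf[idx]),
               sem = sqrt(diag(V)[idx]),
               df = f$m$df.residual)
  }
  raw_c <- contrast_of(raw)
  test_c <- contrast_of(test_fit)
  tcrit <- stats::qt(0.975, raw_c$df)
  contrasts <- data.frame(
    arm = raw_c$arm,
    lsm_diff = raw_c$diff,
    sem = raw_c$sem,
    ci_lo = raw_c$diff - tcrit * raw_c$sem,
    ci_hi = raw_c$diff + tcrit * raw_c$sem,
    p_value = 2 * stats::pt(-abs(test_c$diff / test_c$sem), test_c$df))

  structure(list(per_arm = per_arm, contrasts = contrasts,
                 transform = if (log_scale) "log" else "raw",
                 test = "ancova", df = raw$m$df.residual,
                 comparator = comparator_arm),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %s (%s scale), comparator %s\n",
              x$test, x$transform, x$comparator))
  print(x$per_arm, row.names = FALSE)
  cat("contrasts vs comparator:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Kruskal-Wallis test on baseline-to-endpoint changes
#'
#' Rank-based between-arm comparison of endpoint minus baseline changes,
#' used for heavily non-normal parameters (rate sensitivity). Tie-corrected
#' H statistic with the chi-square approximation.
#'
#' @param records A [change_records()] data frame (>= 2 arms, >= 2
#'   records each).
#' @return A list with `statistic` (H), `df`, `p_value` and per-arm
#'   mean changes.
#' @export
kruskal_wallis_change <- function(records) {
  rec <- records[stats::complete.cases(
    records[, c("arm", "baseline_value", "endpoint_value")]), ]
  n_arm <- table(rec$arm)
  if (length(n_arm) < 2 || any(n_arm < 2))
    stop("Kruskal-Wallis needs >= 2 arms with >= 2 records each",
         call. = FALSE)
  change <- rec$endpoint_value - rec$baseline_value
  if (stats::sd(change) < 1e-300 || length(unique(change)) == 1L) {
    return(list(statistic = 0, df = length(n_arm) - 1L, p_value = 1,
                mean_change = tapply(change, rec$arm, mean)))
  }
  kw <- stats::kruskal.test(change, factor(rec$arm))
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p_value = kw$p.value,
       mean_change = tapply(change, rec$arm, mean))
}
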