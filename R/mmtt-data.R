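#' MMTT subject-visit profile
#'
#' Container for one subject-visit of a frequently sampled mixed-meal
#' tolerance test (FS-MMTT): timed plasma glucose, insulin and C-peptide
#' samples plus the 3-h urinary glucose collection and anthropometrics.
#'
#' @param subject_id Character subject identifier.
#' @param visit `"baseline"` or `"endpoint"`.
#' @param arm Treatment arm label.
#' @param times Sampling times in minutes relative to the start of the meal,
#'   strictly increasing, within \[-15, 180\].
#' @param glucose Plasma glucose, mmol/l, one value per time (NA allowed).
#' @param insulin Plasma insulin, pmol/l, one value per time (NA allowed;
#'   insulin is used only for clearance and OGIS, never for model fitting).
#' @param cpeptide Plasma C-peptide, nmol/l, one value per time (NA allowed).
#' @param uge_0_3h Urinary glucose excreted over the -15 to +180 min
#'   collection, grams (NA if not collected).
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @param age Age, years.
#' @param sex `"M"` or `"F"`.
#' @param diabetic Logical; type 2 diabetes status.
#'
#' @return An object of class `mmtt_profile`.
#' @export
mmtt_profile <- function(subject_id, visit, arm, times, glucose,
                         insulin = rep(NA_real_, length(times)),
                         cpeptide = rep(NA_real_, length(times)),
                         uge_0_3h = NA_real_,
                         weight, height, age, sex, diabetic = TRUE) {
  visit <- match.arg(visit, c("baseline", "endpoint"))
  sex <- match.arg(sex, c("M", "F"))
  times <- as.numeric(times)
  n <- length(times)
  stopifnot(length(glucose) == n, length(insulin) == n, length(cpeptide) == n)
  ord <- order(times)
  x <- structure(
    list(subject_id = as.character(subject_id), visit = visit,
         arm = as.character(arm), times = times[ord],
         glucose = as.numeric(glucose)[ord],
         insulin = as.numeric(insulin)[ord],
         cpeptide = as.numeric(cpeptide)[ord],
         uge_0_3h = as.numeric(uge_0_3h),
         weight = as.numeric(weight), height = as.numeric(height),
         age = as.numeric(age), sex = sex, diabetic = isTRUE(diabetic)),
    class = "mmtt_profile")
  validate_mmtt_profile(x)
  x
}

validate_mmtt_profile <- function(x) {
  id <- sprintf("%s/%s", x$subject_id, x$visit)
  t <- x$times
  if (anyDuplicated(t))
    stop("duplicate sampling times for ", id, call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("non-monotone sampling times for ", id, call. = FALSE)
  if (any(t < -15 - 1e-9) || any(t > 180 + 1e-9))
    stop("sampling times outside [-15, 180] min for ", id, call. = FALSE)
  bad <- which(!is.na(x$glucose) & x$glucose <= 0)
  if (length(bad))
    stop("non-positive glucose for ", id, " at t = ",
         paste(t[bad], collapse = ", "), " min", call. = FALSE)
  bad <- which(!is.na(x$cpeptide) & x$cpeptide < 0)
  if (length(bad))
    stop("negative C-peptide for ", id, " at t = ",
         paste(t[bad], collapse = ", "), " min", call. = FALSE)
  bad <- which(!is.na(x$insulin) & x$insulin < 0)
  if (length(bad))
    stop("negative insulin for ", id, " at t = ",
         paste(t[bad], collapse = ", "), " min", call. = FALSE)
  if (!is.na(x$uge_0_3h) && x$uge_0_3h < 0)
    stop("negative urinary glucose for ", id, call. = FALSE)
  if (any(!is.finite(c(x$weight, x$height, x$age))) ||
      x$weight <= 0 || x$height <= 0 || x$age <= 0)
    stop("invalid anthropometrics for ", id, call. = FALSE)
  invisible(x)
}

#' @export
print.mmtt_profile <- function(x, ...) {
  cat(sprintf("<mmtt_profile> %s %s (%s): %d samples, t in [%g, %g] min\n",
              x$subject_id, x$visit, x$arm, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Standard test meal
#'
#' The standardised liquid mixed meal: defaults are approximately 100 g of
#' carbohydrate and 2930 kJ, consumed within 15 min.
#'
#' @param carbohydrate_g Carbohydrate content, grams.
#' @param energy_kJ Energy content, kJ.
#' @param duration_min Time allowed to finish the meal, minutes.
#' @return A list of class `meal_spec`.
#' @export
meal_spec <- function(carbohydrate_g = 100, energy_kJ = 2930,
                      duration_min = 15) {
  stopifnot(carbohydrate_g > 0, energy_kJ > 0, duration_min > 0)
  structure(list(carbohydrate_g = carbohydrate_g, energy_kJ = energy_kJ,
                 duration_min = duration_min), class = "meal_spec")
}

#' Fasting (pre-meal) value
#'
#' The baseline value of an analyte is the mean of the -15 and 0 min samples
#' when both are present, otherwise the single available pre-meal sample.
#'
#' @param profile An [mmtt_profile()].
#' @param analyte `"glucose"`, `"insulin"` or `"cpeptide"`.
#' @return A single numeric value, or NA if no pre-meal sample exists.
#' @export
fasting_value <- function(profile,
                          analyte = c("glucose", "insulin", "cpeptide")) {
  analyte <- match.arg(analyte)
  pre <- profile$times <= 0
  v <- profile[[analyte]][pre]
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Trapezoid area under the curve
#'
#' Exact trapezoid-rule integral of sampled values on their observed time
#' grid. Missing values (and their times) are dropped before integration.
#'
#' @param times Sampling times, minutes, increasing.
#' @param values Values at each time (concentration units).
#' @return The integral in value-units times minutes.
#' @export
trapezoid_auc <- function(times, values) {
  stopifnot(length(times) == length(values))
  keep <- !is.na(values) & !is.na(times)
  t <- times[keep]; v <- values[keep]
  if (length(t) < 2)
    stop("trapezoid_auc needs at least 2 non-missing points", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  sum(diff(t) * (v[-length(v)] + v[-1]) / 2)
}

# AUC restricted to the 3-h postprandial window [0, 180]; the -15 min
# sample informs the fasting value only, never the AUC.
postprandial_auc <- function(profile, analyte) {
  keep <- profile$times >= 0
  trapezoid_auc(profile$times[keep], profile[[analyte]][keep])
}

#' Mean postprandial plasma glucose (MPG 0-3 h)
#'
#' Glucose AUC over the 3-h postprandial window \[0, 180\] min (trapezoid
#' rule) divided by 180 min.
#'
#' @param profile An [mmtt_profile()].
#' @return Mean plasma glucose, mmol/l.
#' @export
mpg_0_3h <- function(profile) {
  keep <- profile$times >= 0 & !is.na(profile$glucose)
  t <- profile$times[keep]
  if (!length(t) || min(t) > 0 || max(t) < 180)
    stop("mpg_0_3h needs glucose at both t = 0 and t = 180 min",
         call. = FALSE)
  postprandial_auc(profile, "glucose") / 180
}

#' Body surface area (DuBois-DuBois)
#'
#' @param weight Body weight, kg.
#' @param height Height, cm.
#' @return Body surface area, m^2.
#' @export
body_surface_area <- function(weight, height) {
  if (any(!is.finite(weight)) || any(!is.finite(height)) ||
      any(weight <= 0) || any(height <= 0))
    stop("weight and height must be positive", call. = FALSE)
  0.007184 * weight^0.425 * height^0.725
}

#' Read MMTT profiles from CSV
#'
#' Reads a long-format samples table (columns `subject_id`, `visit`, `arm`,
#' `time_min`, `glucose`, `insulin`, `cpeptide`) plus a companion metadata
#' table keyed by (`subject_id`, `visit`) with columns `uge_0_3h`, `weight`,
#' `height`, `age`, `sex`, `diabetic`. Empty cells become NA, never zero.
#'
#' @param samples_path Path to the long-format samples CSV.
#' @param meta_path Path to the subject-visit metadata CSV.
#' @return A list of [mmtt_profile()] objects, one per subject-visit.
#' @export
read_mmtt_csv <- function(samples_path, meta_path) {
  smp <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "arm", "time_min", "glucose",
            "insulin", "cpeptide")
  if (!all(need %in% names(smp)))
    stop("samples CSV missing columns: ",
         paste(setdiff(need, names(smp)), collapse = ", "), call. = FALSE)
  needm <- c("subject_id", "visit", "uge_0_3h", "weight", "height",
             "age", "sex", "diabetic")
  if (!all(needm %in% names(meta)))
    stop("metadata CSV missing columns: ",
         paste(setdiff(needm, names(meta)), collapse = ", "), call. = FALSE)
  key <- interaction(smp$subject_id, smp$visit, drop = TRUE)
  dup <- duplicated(data.frame(key, smp$time_min))
  if (any(dup)) {
    d <- smp[dup, ][1, ]
    stop(sprintf("duplicate sample for %s/%s at t = %g min",
                 d$subject_id, d$visit, d$time_min), call. = FALSE)
  }
  out <- lapply(split(smp, key), function(df) {
    df <- df[order(df$time_min), ]
    m <- meta[meta$subject_id == df$subject_id[1] &
                meta$visit == df$visit[1], ]
    if (nrow(m) != 1)
      stop("metadata row missing or duplicated for ",
           df$subject_id[1], "/", df$visit[1], call. = FALSE)
    mmtt_profile(subject_id = df$subject_id[1], visit = df$visit[1],
                 arm = df$arm[1], times = df$time_min,
                 glucose = df$glucose, insulin = df$insulin,
                 cpeptide = df$cpeptide, uge_0_3h = m$uge_0_3h,
                 weight = m$weight, height = m$height, age = m$age,
                 sex = m$sex, diabetic = as.logical(m$diabetic))
  })
  unname(out)
}

#' Write MMTT profiles to CSV
#'
#' Inverse of [read_mmtt_csv()]: writes the long-format samples table and
#' the companion subject-visit metadata table.
#'
#' @param profiles A list of [mmtt_profile()] objects.
#' @param samples_path,meta_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_mmtt_csv <- function(profiles, samples_path, meta_path) {
  smp <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, visit = p$visit, arm = p$arm,
               time_min = p$times, glucose = p$glucose, insulin = p$insulin,
               cpeptide = p$cpeptide)))
  meta <- do.call(rbind, lapply(profiles, function(p)
    data.frame(subject_id = p$subject_id, visit = p$visit,
               uge_0_3h = p$uge_0_3h, weight = p$weight, height = p$height,
               age = p$age, sex = p$sex, diabetic = p$diabetic)))
  utils::write.csv(smp, samples_path, row.names = FALSE, na = "")
  utils::write.csv(meta, meta_path, row.names = FALSE, na = "")
  invisible(c(samples_path, meta_path))
}

# usable (glucose, C-peptide) pairs for model fitting
n_usable_pairs <- function(profile) {
  sum(!is.na(profile$glucose) & !is.na(profile$cpeptide))
}
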