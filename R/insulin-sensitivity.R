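# Constants of the published 2-h OGIS closed form (glucose in mg/dl,
# insulin in pmol/l, dose in g/m^2; result in ml min^-1 m^-2). Locked
# here and consistency-tested against an independent re-typing.
ogis_constants <- function() {
  list(p1 = 289, p2 = 270, p3 = 14000, p4 = 440,
       p5 = 637e-6, p6 = 117,
       v_glucose = 1e4,    # glucose distribution volume term, ml/m^2
       g_clamp = 90,       # reference clamp glucose, mg/dl
       dt = 30)            # t2 - t1 = 120 - 90 min
}

GLUCOSE_MG_PER_MMOL <- 18.016   # molar mass 180.16 g/mol, mg/dl per mmol/l

#' OGIS insulin sensitivity index (2-h variant)
#'
#' Evaluates the published oral glucose insulin sensitivity closed form
#' from the 0, 90 and 120 min samples of the meal test. The glucose dose
#' supplied to the formula is the meal's carbohydrate content normalised
#' by body surface area. The fasting (0 min) values use the pre-meal
#' baseline convention (mean of the -15 and 0 min samples).
#'
#' @param profile An [mmtt_profile()] with glucose and insulin at 0, 90
#'   and 120 min.
#' @param meal A [meal_spec()]; the carbohydrate content acts as the
#'   glucose dose.
#' @param bsa Body surface area, m^2 (computed from the profile if NULL).
#' @return OGIS, ml min^-1 m^-2.
#' @export
ogis_2h <- function(profile, meal = meal_spec(), bsa = NULL) {
  if (is.null(bsa)) bsa <- body_surface_area(profile$weight, profile$height)
  val_at <- function(analyte, t) {
    i <- which(abs(profile$times - t) < 1e-9)
    if (!length(i)) return(NA_real_)
    profile[[analyte]][i]
  }
  g0 <- fasting_value(profile, "glucose")
  i0 <- fasting_value(profile, "insulin")
  g90 <- val_at("glucose", 90); g120 <- val_at("glucose", 120)
  i90 <- val_at("insulin", 90)
  if (anyNA(c(g0, g90, g120, i0, i90)))
    stop("OGIS needs glucose and insulin at 0, 90 and 120 min",
         call. = FALSE)
  if (any(c(g0, g90, g120) <= 0) || any(c(i0, i90) < 0))
    stop("non-physiological glucose/insulin values", call. = FALSE)
  ogis_formula(g0, g90, g120, i0, i90,
               dose_g_m2 = meal$carbohydrate_g / bsa)
}

# the closed form itself; glucose arguments in mmol/l, insulin in pmol/l
ogis_formula <- function(g0, g90, g120, i0, i90, dose_g_m2) {
  k <- ogis_constants()
  G0 <- g0 * GLUCOSE_MG_PER_MMOL
  G1 <- g90 * GLUCOSE_MG_PER_MMOL
  G2 <- g120 * GLUCOSE_MG_PER_MMOL
  B <- k$p4 * ((k$p1 * dose_g_m2 - k$v_glucose * (G2 - G1) / k$dt) / G1 +
                 k$p3 / G0) / (i90 - i0 + k$p2)
  Bp <- (k$p5 * (G1 - k$g_clamp) + 1) * B
  (Bp + sqrt(Bp^2 + 4 * k$p5 * k$p6 * (G1 - k$g_clamp) * B)) / 2
}

#' Renal glucose clearance from urinary glucose excretion
#'
#' UGE divided by the plasma glucose AUC over the test, normalised by
#' body surface area: the insulin-independent glucose disposal SGLT2
#' inhibition adds.
#'
#' @param uge_g Urinary glucose over the collection, grams.
#' @param glucose_auc Plasma glucose AUC over \[0, 180\] min, mmol.min/l.
#' @param bsa Body surface area, m^2.
#' @return Clearance, ml min^-1 m^-2.
#' @export
renal_glucose_clearance <- function(uge_g, glucose_auc, bsa) {
  if (is.na(uge_g)) return(NA_real_)
  if (uge_g < 0) stop("urinary glucose must be non-negative", call. = FALSE)
  stopifnot(glucose_auc > 0, bsa > 0)
  uge_mmol <- uge_g / 0.18016               # g -> mmol
  (uge_mmol / glucose_auc) * 1000 / bsa     # l/min -> ml/min, per m^2
}

#' UGE-corrected OGIS
#'
#' Subtracts renal glucose clearance from OGIS. Uncorrected OGIS counts
#' urinary glucose loss as insulin-mediated disposal and therefore
#' overestimates insulin-sensitivity improvements under SGLT2 inhibition.
#'
#' @param ogis OGIS, ml min^-1 m^-2.
#' @param renal Renal glucose clearance, ml min^-1 m^-2.
#' @return Corrected index, ml min^-1 m^-2.
#' @export
ogis_corrected <- function(ogis, renal) {
  if (is.na(ogis) || is.na(renal)) return(NA_real_)
  stopifnot(is.finite(ogis), is.finite(renal))
  ogis - renal
}

#' Insulin sensitivity with urinary-glucose correction for one profile
#'
#' @param profile An [mmtt_profile()].
#' @param meal A [meal_spec()].
#' @return A list with `ogis`, `renal_clearance` and `ogis_c`
#'   (ml min^-1 m^-2); `ogis_c = ogis - renal_clearance`.
#' @export
sensitivity_result <- function(profile, meal = meal_spec()) {
  bsa <- body_surface_area(profile$weight, profile$height)
  og <- ogis_2h(profile, meal, bsa)
  renal <- renal_glucose_clearance(profile$uge_0_3h,
                                   postprandial_auc(profile, "glucose"),
                                   bsa)
  list(ogis = og, renal_clearance = renal,
       ogis_c = ogis_corrected(og, renal))
}
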