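# Anthropometric, blood-pressure, glycemic and lipid indices, and the
# four-way metabolic phenotype. Units throughout: glucose/lipids mg/dL,
# insulin UI/mL, blood pressure mm Hg, masses kg, height m.

#' Mean blood pressure
#'
#' The plain arithmetic mean `(SBP + DBP) / 2` — the summary used for the
#' cohort's "mean blood pressure", deliberately not the
#' `(SBP + 2 DBP) / 3` mean-arterial-pressure formula.
#'
#' @param sbp,dbp Systolic and diastolic pressure, mm Hg; requires
#'   `sbp > dbp > 0`. Vectorized.
#' @return mm Hg.
#' @export
#' @examples
#' mean_blood_pressure(134.26, 85.16) # 109.71
mean_blood_pressure <- function(sbp, dbp) {
  if (any(dbp <= 0)) stop("domain error: pressures must be positive",
                          call. = FALSE)
  if (any(dbp >= sbp)) stop("domain error: requires sbp > dbp", call. = FALSE)
  (sbp + dbp) / 2
}

#' HOMA-IR insulin-resistance index
#'
#' `insulin (UI/mL) * glucose (mmol/L) / 22.5`, with glucose converted from
#' mg/dL by the factor 0.0555. The model's calibration point (glucose
#' 5 mmol/L, insulin 4.5 UI/mL) gives 1.0.
#'
#' @param glucose Fasting plasma glucose, mg/dL (> 0). Vectorized.
#' @param insulin Fasting plasma insulin, UI/mL (> 0).
#' @return Dimensionless index.
#' @export
#' @examples
#' homa_ir(90.09, 4.5) # ~1.0
homa_ir <- function(glucose, insulin) {
  if (any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE)) {
    stop("domain error: glucose and insulin must be positive", call. = FALSE)
  }
  insulin * (glucose * 0.0555) / 22.5
}

#' QUICKI insulin-sensitivity index
#'
#' `1 / (log10(insulin) + log10(glucose))` with insulin in UI/mL and glucose
#' in mg/dL (the index's standard convention; base-10 logarithms).
#'
#' @inheritParams homa_ir
#' @return Dimensionless index; strictly decreasing in insulin at fixed
#'   glucose.
#' @export
#' @examples
#' quicki(93.56, 8.08) # ~0.3474
quicki <- function(glucose, insulin) {
  if (any(glucose <= 0, na.rm = TRUE) || any(insulin <= 0, na.rm = TRUE)) {
    stop("domain error: glucose and insulin must be positive", call. = FALSE)
  }
  s <- log10(insulin) + log10(glucose)
  if (any(s == 0, na.rm = TRUE)) {
    stop("domain error: log10(insulin) + log10(glucose) is zero",
         call. = FALSE)
  }
  1 / s
}

#' Lipid ratios
#'
#' LDL-C/HDL-C and triglycerides/HDL-C.
#'
#' @param ldl,hdl,tg Concentrations in mg/dL; `hdl > 0`. Vectorized.
#' @return A list with `ldl_hdl_ratio` and `tg_hdl_ratio`.
#' @export
lipid_ratios <- function(ldl, hdl, tg) {
  if (any(hdl <= 0, na.rm = TRUE)) {
    stop("domain error: hdl must be positive", call. = FALSE)
  }
  list(ldl_hdl_ratio = ldl / hdl, tg_hdl_ratio = tg / hdl)
}

#' Metabolic phenotype classification
#'
#' Four-way label crossing BMI status with metabolic health. Metabolically
#' unhealthy means at least one of: triglycerides >= 150 mg/dL; HDL-C < 40
#' (men) or < 50 (women) mg/dL; SBP >= 130 or DBP >= 85 mm Hg; glycemia
#' > 100 mg/dL (strict). Normal-weight is `18.5 < BMI < 25`; overweight-
#' obese is `BMI >= 25`; BMI <= 18.5 (strict lower bound) or any missing
#' input returns `NA` (unclassified).
#'
#' @param bmi kg/m^2.
#' @param tg,hdl,glucose mg/dL.
#' @param sex `"male"`/`"female"` (factor or character). Sets the HDL cut.
#' @param sbp,dbp mm Hg.
#' @return Factor with levels `MHNW`, `MUNW`, `MHOO`, `MUOO` (NA when
#'   unclassifiable). Vectorized.
#' @export
#' @examples
#' classify_phenotype(24, 120, 55, "female", 118, 75, 95) # MHNW
classify_phenotype <- function(bmi, tg, hdl, sex, sbp, dbp, glucose) {
  sex <- tolower(as.character(sex))
  hdl_cut <- ifelse(sex == "male", 40, 50)
  unhealthy <- (tg >= 150) | (hdl < hdl_cut) |
    (sbp >= 130) | (dbp >= 85) | (glucose > 100)
  obese <- bmi >= 25
  lab <- ifelse(obese,
                ifelse(unhealthy, "MUOO", "MHOO"),
                ifelse(unhealthy, "MUNW", "MHNW"))
  lab[!(bmi > 18.5)] <- NA            # below-range BMI unclassified
  lab[is.na(bmi) | is.na(tg) | is.na(hdl) | is.na(sbp) | is.na(dbp) |
        is.na(glucose) | !(sex %in% c("male", "female"))] <- NA
  factor(lab, levels = c("MHNW", "MUNW", "MHOO", "MUOO"))
}

#' Derive all clinical index columns for a participant table
#'
#' Adds (or recomputes) BMI, lean/fat mass indices, mean blood pressure,
#' HOMA-IR, QUICKI, insulin/glucose ratio, lipid ratios and the metabolic
#' phenotype. Missing biomarker values propagate as `NA`; each downstream
#' analysis uses pairwise-complete rows.
#'
#' @param participants Data frame as from [read_participants()] with (some
#'   of) the columns `weight`, `height`, `lean_mass`, `fat_mass`, `sbp`,
#'   `dbp`, `glucose`, `insulin`, `tc`, `hdl`, `ldl`, `tg`.
#' @return The input with derived columns `bmi`, `lean_mass_index`,
#'   `fat_mass_index`, `mean_bp`, `homa`, `quicki`, `insulin_glucose_ratio`,
#'   `ldl_hdl_ratio`, `tg_hdl_ratio`, `phenotype` appended.
#' @export
derive_indices <- function(participants) {
  p <- participants
  has <- function(...) all(c(...) %in% names(p))
  na_if_bad <- function(x, bad) ifelse(!is.na(x) & bad, NA_real_, x)
  if (has("weight", "height")) p$bmi <- p$weight / p$height^2
  if (has("lean_mass", "height")) {
    p$lean_mass_index <- p$lean_mass / p$height^2
  }
  if (has("fat_mass", "height")) p$fat_mass_index <- p$fat_mass / p$height^2
  if (has("sbp", "dbp")) {
    ok <- !is.na(p$sbp) & !is.na(p$dbp) & p$sbp > p$dbp & p$dbp > 0
    p$mean_bp <- ifelse(ok, (p$sbp + p$dbp) / 2, NA_real_)
  }
  if (has("glucose", "insulin")) {
    g <- na_if_bad(p$glucose, p$glucose <= 0)
    i <- na_if_bad(p$insulin, p$insulin <= 0)
    p$homa <- i * (g * 0.0555) / 22.5
    p$quicki <- 1 / (log10(i) + log10(g))
    p$insulin_glucose_ratio <- i / g
  }
  if (has("ldl", "hdl")) {
    h <- na_if_bad(p$hdl, p$hdl <= 0)
    p$ldl_hdl_ratio <- p$ldl / h
  }
  if (has("tg", "hdl")) {
    h <- na_if_bad(p$hdl, p$hdl <= 0)
    p$tg_hdl_ratio <- p$tg / h
  }
  if (has("bmi", "tg", "hdl", "sex", "sbp", "dbp", "glucose")) {
    p$phenotype <- classify_phenotype(p$bmi, p$tg, p$hdl, p$sex,
                                      p$sbp, p$dbp, p$glucose)
  }
  p
}
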