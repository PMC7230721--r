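# Stoichiometric conversion of steady-state gas exchange to energy
# expenditure and substrate oxidation. Gases enter the equations in L/min;
# the Weir rate (kcal/min) is scaled x1440 to kcal/day; Frayn oxidation
# rates stay g/min.

#' Stoichiometry configuration
#'
#' @param n_urinary Urinary nitrogen excretion in g/day (default 0; the
#'   protein term is dropped when nitrogen is not measured). The Frayn
#'   equations internally use g/min (`n_urinary / 1440`).
#' @param kcal_per_g_fat Energy equivalent of triglyceride, kcal/g
#'   (default 9.75).
#' @param kcal_per_g_cho Energy equivalent of carbohydrate oxidised as
#'   glucose, kcal/g (default 3.74). Together with 9.75 kcal/g fat this
#'   closes the energy balance: fat%BMR + CHO%BMR stays within a few percent
#'   of 100 across the physiological RER range (see the methods vignette).
#' @return A `stoichiometry_config` list.
#' @export
stoichiometry_config <- function(n_urinary = 0, kcal_per_g_fat = 9.75,
                                 kcal_per_g_cho = 3.74) {
  stopifnot(n_urinary >= 0, kcal_per_g_fat > 0, kcal_per_g_cho > 0)
  structure(list(n_urinary = n_urinary, kcal_per_g_fat = kcal_per_g_fat,
                 kcal_per_g_cho = kcal_per_g_cho),
            class = "stoichiometry_config")
}

#' Basal metabolic rate by the abbreviated Weir equation
#'
#' `BMR (kcal/day) = 1440 * (3.941 * VO2 + 1.106 * VCO2) - 2.17 * N` with
#' VO2/VCO2 in L/min and urinary nitrogen N in g/day.
#'
#' @param vo2,vco2 Gas rates in L/min (> 0). Vectorized.
#' @param cfg A [stoichiometry_config()].
#' @return kcal/day.
#' @export
#' @examples
#' weir_bmr(0.200, 0.160) # 1389.83
weir_bmr <- function(vo2, vco2, cfg = stoichiometry_config()) {
  if (any(vo2 <= 0) || any(vco2 <= 0)) {
    stop("domain error: gas rates must be positive", call. = FALSE)
  }
  1440 * (3.941 * vo2 + 1.106 * vco2) - 2.17 * cfg$n_urinary
}

#' Fat oxidation rate by the Frayn equation
#'
#' `BFox (g/min) = 1.67 * VO2 - 1.67 * VCO2 - 1.92 * n` with gases in L/min
#' and n in g nitrogen/min. Zero exactly at RER = 1 (n = 0); negative for
#' RER > 1 inputs, which are reported as-is (flagged, not clamped — the RER
#' validity rule upstream is the single exclusion gatekeeper).
#'
#' @inheritParams weir_bmr
#' @return g/min.
#' @export
frayn_fat_ox <- function(vo2, vco2, cfg = stoichiometry_config()) {
  if (any(vo2 <= 0) || any(vco2 <= 0)) {
    stop("domain error: gas rates must be positive", call. = FALSE)
  }
  1.67 * vo2 - 1.67 * vco2 - 1.92 * (cfg$n_urinary / 1440)
}

#' Carbohydrate oxidation rate by the Frayn equation
#'
#' `BCHox (g/min) = 4.55 * VCO2 - 3.21 * VO2 - 2.87 * n` with gases in
#' L/min and n in g nitrogen/min. Zero exactly at RER = 3.21/4.55 (n = 0).
#'
#' @inheritParams weir_bmr
#' @return g/min.
#' @export
frayn_cho_ox <- function(vo2, vco2, cfg = stoichiometry_config()) {
  if (any(vo2 <= 0) || any(vco2 <= 0)) {
    stop("domain error: gas rates must be positive", call. = FALSE)
  }
  4.55 * vco2 - 3.21 * vo2 - 2.87 * (cfg$n_urinary / 1440)
}

#' Oxidation rate as a percentage of BMR
#'
#' `100 * (rate * kcal_per_g * 1440) / bmr`: the oxidation rate (g/min) is
#' converted to kcal/day via its energy equivalent and expressed relative to
#' the Weir BMR. Negative rates yield negative percentages (flagged
#' upstream, never truncated here).
#'
#' @param rate Oxidation rate, g/min.
#' @param kcal_per_g Energy equivalent, kcal/g.
#' @param bmr Basal metabolic rate, kcal/day (> 0).
#' @return Percent of BMR.
#' @export
pct_of_bmr <- function(rate, kcal_per_g, bmr) {
  if (any(bmr <= 0)) stop("domain error: bmr must be positive", call. = FALSE)
  100 * (rate * kcal_per_g * 1440) / bmr
}

#' Metabolic outputs for a selected steady-state window
#'
#' Applies the Weir and Frayn equations to the window's mean gas exchange
#' (mL/min converted to L/min) and expresses the oxidation rates as
#' percentages of BMR. `oxidation_valid` carries the [rer_validity()] flag;
#' when `FALSE` the oxidation fields are still computed but the participant
#' is excluded from substrate-oxidation analyses downstream (BMR is kept).
#'
#' @param window A one-row window from [select_most_stable()].
#' @param cfg A [stoichiometry_config()].
#' @return One-row data frame: `bmr_kcal_d`, `bfox_g_min`, `bfox_pct_bmr`,
#'   `bchox_g_min`, `bchox_pct_bmr`, `mean_rer`, `oxidation_valid`.
#' @export
compute_metabolics <- function(window, cfg = stoichiometry_config()) {
  vo2 <- window$mean_vo2 / 1000   # mL/min -> L/min
  vco2 <- window$mean_vco2 / 1000
  bmr <- weir_bmr(vo2, vco2, cfg)
  bfox <- frayn_fat_ox(vo2, vco2, cfg)
  bchox <- frayn_cho_ox(vo2, vco2, cfg)
  data.frame(bmr_kcal_d = bmr,
             bfox_g_min = bfox,
             bfox_pct_bmr = pct_of_bmr(bfox, cfg$kcal_per_g_fat, bmr),
             bchox_g_min = bchox,
             bchox_pct_bmr = pct_of_bmr(bchox, cfg$kcal_per_g_cho, bmr),
             mean_rer = window$mean_rer,
             oxidation_valid = rer_validity(window$mean_rer))
}
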