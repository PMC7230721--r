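# Seeded synthetic cohorts and breath-by-breath traces. The generator
# states a world: per-sex normal distributions with the study cohort's
# published means/SDs, a planted RER -> ln-insulin link, a planted
# lean-mass -> BMR link, and traces with an exponentially decaying initial
# transient plus multiplicative breath noise. Correlations beyond the
# planted ones are zero. All generators are pure functions of
# (config, seed).

# truncated normal by rejection; adequate far from the tails
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lower | x > upper)
  }
  x
}

#' Per-sex cohort distribution parameters
#'
#' Means and SDs used by [simulate_cohort()]: age (years), height (m,
#' chosen as typical adult values — the source table reports only indices),
#' lean/fat mass indices (kg/m^2), waist (cm), visceral adipose tissue (g),
#' systolic/diastolic pressure (mm Hg), total/HDL/LDL cholesterol and
#' triglycerides (mg/dL). Glucose is drawn sex-pooled: mean 93.56, SD
#' 11.36 mg/dL.
#'
#' @return Named list with `male` and `female` data frames
#'   (`var`, `mean`, `sd`) and the pooled `glucose` parameters.
#' @export
table1_defaults <- function() {
  male <- data.frame(
    var  = c("age", "height", "lean_mass_index", "fat_mass_index", "waist",
             "vat_mass", "sbp", "dbp", "tc", "hdl", "ldl", "tg"),
    mean = c(54.2, 1.76, 17.49, 10.15, 103.13,
             986.4, 134.26, 85.16, 200.67, 55.33, 138.79, 125.06),
    sd   = c(5.2, 0.06, 2.06, 3.20, 8.45,
             388.8, 13.84, 10.87, 32.29, 12.86, 78.00, 27.93))
  female <- data.frame(
    var  = male$var,
    mean = c(52.7, 1.63, 13.26, 11.28, 88.09,
             607.4, 120.92, 77.64, 211.03, 61.73, 124.78, 127.27),
    sd   = c(4.6, 0.06, 1.78, 2.95, 9.91,
             298.7, 14.85, 11.44, 31.70, 11.06, 49.88, 26.63))
  list(male = male, female = female,
       glucose = c(mean = 93.56, sd = 11.36))
}

#' Cohort simulation configuration
#'
#' @param n Number of participants (>= 4). Default 71, the study size.
#' @param sex_ratio Probability of male (default 34/71).
#' @param seed Integer seed.
#' @param table1_params Per-sex distribution parameters, see
#'   [table1_defaults()].
#' @param effect_rer_insulin Planted standardized slope of ln-insulin on
#'   z-scored basal RER (default +0.33: higher basal RER, i.e. more
#'   carbohydrate-leaning substrate use, goes with higher fasting insulin).
#' @param effect_lean_bmr Planted BMR slope, kcal/day per kg lean mass
#'   (default 20).
#' @param bmr_intercept,bmr_sd Intercept (kcal/day) and residual SD of the
#'   planted BMR model (defaults 450 and 150, giving sex means near the
#'   published 1548/1098 kcal/day).
#' @param insulin_sd_ln SD of ln-insulin (default 0.55; reproduces the
#'   published insulin mean ~8.1 and SD ~4.8 UI/mL via the lognormal).
#' @return A `cohort_sim_config` list.
#' @export
cohort_sim_config <- function(n = 71, sex_ratio = 34 / 71, seed = 20200423,
                              table1_params = table1_defaults(),
                              effect_rer_insulin = 0.33,
                              effect_lean_bmr = 20,
                              bmr_intercept = 450, bmr_sd = 150,
                              insulin_sd_ln = 0.55) {
  if (n < 4) stop("config error: n must be >= 4", call. = FALSE)
  if (sex_ratio <= 0 || sex_ratio >= 1) {
    stop("config error: sex_ratio must be in (0,1)", call. = FALSE)
  }
  if (any(table1_params$male$sd <= 0) || any(table1_params$female$sd <= 0)) {
    stop("config error: all SDs must be positive", call. = FALSE)
  }
  structure(list(n = n, sex_ratio = sex_ratio, seed = as.integer(seed),
                 table1_params = table1_params,
                 effect_rer_insulin = effect_rer_insulin,
                 effect_lean_bmr = effect_lean_bmr,
                 bmr_intercept = bmr_intercept, bmr_sd = bmr_sd,
                 insulin_sd_ln = insulin_sd_ln),
            class = "cohort_sim_config")
}

#' Simulate a participant cohort with planted truth
#'
#' Draws sex, then per-sex truncated normals for age, height, lean/fat mass
#' indices, waist, visceral fat, blood pressure and lipids; weight is
#' lean + fat mass divided by 0.96 (the remainder standing in for bone
#' mineral), so BMI means land near the published per-sex values. Plants:
#' basal RER ~ Normal(0.85, 0.05) truncated to [0.72, 0.98]; true BMR =
#' intercept + `effect_lean_bmr` x lean mass + noise; ln-insulin = mu +
#' sd_ln x (beta x z(RER) + sqrt(1 - beta^2) x eps) so the RER/ln-insulin
#' correlation is `effect_rer_insulin`; glucose sex-pooled. The true
#' breath-free gas rates (L/min) invert the Weir equation at the planted
#' BMR and RER: `vo2* = BMR / (1440 (3.941 + 1.106 RER))`,
#' `vco2* = RER vo2*`.
#'
#' @param cfg A [cohort_sim_config()].
#' @return List of class `calorflex_cohort` with `participants` (observable
#'   table: id, sex, age, height, weight, lean/fat mass, waist, vat_mass,
#'   sbp, dbp, glucose, insulin, tc, hdl, ldl, tg) and `truth` (id,
#'   bmr_true, rer_true, vo2_star, vco2_star, lean_mass).
#' @export
simulate_cohort <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  sex <- factor(ifelse(stats::runif(n) < cfg$sex_ratio, "male", "female"),
                levels = c("female", "male"))
  draw <- function(var) {
    out <- numeric(n)
    for (s in c("male", "female")) {
      tab <- cfg$table1_params[[s]]
      i <- which(sex == s)
      row <- tab[tab$var == var, ]
      out[i] <- rtnorm(length(i), row$mean, row$sd, lower = row$mean / 10)
    }
    out
  }
  age <- draw("age"); height <- draw("height")
  lmi <- draw("lean_mass_index"); fmi <- draw("fat_mass_index")
  waist <- draw("waist"); vat <- draw("vat_mass")
  sbp <- draw("sbp"); dbp <- draw("dbp")
  dbp <- pmin(dbp, sbp - 5)                      # enforce dbp < sbp
  tc <- draw("tc"); hdl <- draw("hdl"); ldl <- draw("ldl"); tg <- draw("tg")
  lean_mass <- lmi * height^2
  fat_mass <- fmi * height^2
  weight <- (lean_mass + fat_mass) / 0.96
  gl <- cfg$table1_params$glucose
  glucose <- rtnorm(n, gl[["mean"]], gl[["sd"]], lower = 50)

  rer <- rtnorm(n, 0.85, 0.05, lower = 0.72, upper = 0.98)
  z_rer <- (rer - mean(rer)) / stats::sd(rer)
  beta <- cfg$effect_rer_insulin
  mu_ln <- log(8.08) - cfg$insulin_sd_ln^2 / 2
  ln_ins <- mu_ln + cfg$insulin_sd_ln *
    (beta * z_rer + sqrt(max(0, 1 - beta^2)) * stats::rnorm(n))
  insulin <- exp(ln_ins)

  bmr <- cfg$bmr_intercept + cfg$effect_lean_bmr * lean_mass +
    stats::rnorm(n, 0, cfg$bmr_sd)
  bmr <- pmax(bmr, 600)
  vo2_star <- bmr / (1440 * (3.941 + 1.106 * rer))  # L/min
  vco2_star <- rer * vo2_star

  id <- sprintf("P%03d", seq_len(n))
  participants <- data.frame(
    id = id, sex = sex, age = age, height = height, weight = weight,
    lean_mass = lean_mass, fat_mass = fat_mass, waist = waist,
    vat_mass = vat, sbp = sbp, dbp = dbp, glucose = glucose,
    insulin = insulin, tc = tc, hdl = hdl, ldl = ldl, tg = tg)
  truth <- data.frame(id = id, bmr_true = bmr, rer_true = rer,
                      vo2_star = vo2_star, vco2_star = vco2_star,
                      lean_mass = lean_mass)
  structure(list(participants = participants, truth = truth, config = cfg),
            class = "calorflex_cohort")
}

#' Trace simulation configuration
#'
#' @param duration_s Recording length, seconds (default 1800 = 30 min).
#' @param breath_interval_s,breath_interval_sd Mean and SD of the breath
#'   renewal process, seconds (defaults 4.0 and 0.8; intervals truncated at
#'   0.5 s).
#' @param transient_tau_s Time constant of the initial non-steady decay,
#'   seconds (default 180): gas exchange starts elevated and settles to
#'   basal.
#' @param transient_amp Fractional elevation at t = 0 (default 0.25).
#' @param noise_cv_pct Multiplicative breath-to-breath noise CV on VO2 and
#'   VCO2, percent (default 4; below 10 for "compliant" traces).
#' @param noise_ar1 Lag-1 autocorrelation of the multiplicative noise
#'   (default 0 = white breath noise). Values near 1 emulate slow
#'   physiological drifts that survive epoch averaging and can defeat the
#'   steady-state criteria.
#' @param drift_pct Linear drift over the whole recording, percent
#'   (default 0).
#' @param seed Integer seed.
#' @return A `trace_sim_config` list.
#' @export
trace_sim_config <- function(duration_s = 1800, breath_interval_s = 4.0,
                             breath_interval_sd = 0.8,
                             transient_tau_s = 180, transient_amp = 0.25,
                             noise_cv_pct = 4, noise_ar1 = 0,
                             drift_pct = 0, seed = 20200423) {
  stopifnot(duration_s > 0, breath_interval_s > 0, breath_interval_sd > 0,
            transient_tau_s > 0, transient_amp >= 0, noise_cv_pct >= 0,
            noise_ar1 >= 0, noise_ar1 < 1)
  structure(list(duration_s = duration_s,
                 breath_interval_s = breath_interval_s,
                 breath_interval_sd = breath_interval_sd,
                 transient_tau_s = transient_tau_s,
                 transient_amp = transient_amp,
                 noise_cv_pct = noise_cv_pct, noise_ar1 = noise_ar1,
                 drift_pct = drift_pct, seed = as.integer(seed)),
            class = "trace_sim_config")
}

#' Simulate a breath-by-breath basal recording
#'
#' Breath times come from a truncated-normal renewal process. Instantaneous
#' oxygen uptake is `vo2*(t) = vo2* x (1 + A exp(-t / tau)) x (1 + drift)
#' x (1 + e(t))` with multiplicative noise `e(t)` of CV `noise_cv_pct`
#' (optionally AR(1)-correlated across breaths); VCO2 is generated
#' analogously with independent noise, so the planted RER is preserved in
#' expectation. Minute ventilation tracks VO2 with a ventilatory equivalent
#' of 26 L per L O2 and half the noise CV.
#'
#' @param vo2_star,vco2_star Planted basal gas rates, L/min (> 0).
#' @param cfg A [trace_sim_config()].
#' @param participant_id Identifier stored on the trace.
#' @return A [gas_trace()] with `duration_s = cfg$duration_s` and gas
#'   columns in mL/min (VE in L/min).
#' @export
simulate_trace <- function(vo2_star, vco2_star, cfg = trace_sim_config(),
                           participant_id = "sim") {
  stopifnot(inherits(cfg, "trace_sim_config"), vo2_star > 0, vco2_star > 0)
  set.seed(cfg$seed)
  n_max <- ceiling(cfg$duration_s / cfg$breath_interval_s * 1.5) + 20
  gaps <- rtnorm(n_max, cfg$breath_interval_s, cfg$breath_interval_sd,
                 lower = 0.5)
  t <- cumsum(gaps)
  t <- t[t < cfg$duration_s]
  n <- length(t)
  cv <- cfg$noise_cv_pct / 100
  noise <- function(k, rel_cv) {
    if (rel_cv == 0) return(rep(1, k))
    rho <- cfg$noise_ar1
    if (rho == 0) return(1 + stats::rnorm(k, 0, rel_cv))
    e <- numeric(k)
    e[1] <- stats::rnorm(1, 0, rel_cv)
    innov <- stats::rnorm(k - 1, 0, rel_cv * sqrt(1 - rho^2))
    for (i in 2:k) e[i] <- rho * e[i - 1] + innov[i - 1]
    1 + e
  }
  shape <- (1 + cfg$transient_amp * exp(-t / cfg$transient_tau_s)) *
    (1 + cfg$drift_pct / 100 * t / cfg$duration_s)
  vo2 <- vo2_star * 1000 * shape * noise(n, cv)
  vco2 <- vco2_star * 1000 * shape * noise(n, cv)
  ve <- vo2_star * 26 * shape * noise(n, cv / 2)
  gas_trace(t, vo2, vco2, ve, participant_id, duration_s = cfg$duration_s)
}

#' Write a small fixture suite to disk
#'
#' Generates a seeded cohort (default n = 12), one trace per participant
#' (trace seed = `seed + participant index`), and writes
#' `participants.csv`, `traces/<id>.csv` and `truth.json` under `out_dir`.
#' Regeneration with the same seed is numerically identical.
#'
#' @param out_dir Writable directory (created if absent).
#' @param n Cohort size (>= 4).
#' @param seed Integer seed.
#' @param trace_cfg Base [trace_sim_config()]; its seed field is replaced
#'   per participant.
#' @return Invisibly, a list with the file paths.
#' @export
make_fixture_suite <- function(out_dir, n = 12, seed = 20200423,
                               trace_cfg = trace_sim_config()) {
  cohort <- simulate_cohort(cohort_sim_config(n = n, seed = seed))
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  part_path <- file.path(out_dir, "participants.csv")
  write_participants(cohort$participants, part_path)
  trace_paths <- character(n)
  for (i in seq_len(n)) {
    tc <- trace_cfg
    tc$seed <- as.integer(seed + i)
    tr <- simulate_trace(cohort$truth$vo2_star[i], cohort$truth$vco2_star[i],
                         tc, participant_id = cohort$truth$id[i])
    trace_paths[i] <- file.path(out_dir, "traces",
                                paste0(cohort$truth$id[i], ".csv"))
    write_trace(tr, trace_paths[i])
  }
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(cohort$truth, truth_path, digits = NA)
  invisible(list(participants = part_path, traces = trace_paths,
                 truth = truth_path))
}
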