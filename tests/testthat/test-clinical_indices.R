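test_that("mean_blood_pressure is the arithmetic mean, not MAP", {
  expect_equal(mean_blood_pressure(134.26, 85.16), 109.71)
  expect_equal(mean_blood_pressure(120.92, 77.64), 99.28)
  # distinguishes from (sbp + 2 dbp)/3
  expect_false(isTRUE(all.equal(mean_blood_pressure(134.26, 85.16),
                                (134.26 + 2 * 85.16) / 3)))
  eps <- 1e-6
  expect_equal(mean_blood_pressure(80 + eps, 80), (160 + eps) / 2)
  expect_error(mean_blood_pressure(80, 80), "domain")
})

test_that("homa_ir uses mmol/L glucose over 22.5", {
  expect_equal(homa_ir(90.09, 4.5), 4.5 * 90.09 * 0.0555 / 22.5)
  expect_equal(homa_ir(90.09, 4.5), 1.0, tolerance = 1e-3)
  expect_equal(homa_ir(99.10, 10), 10 * 99.10 * 0.0555 / 22.5)
  expect_equal(round(homa_ir(99.10, 10), 3), 2.444)
  expect_equal(homa_ir(95, 12), 2 * homa_ir(95, 6))   # linear in insulin
  expect_error(homa_ir(-1, 5), "domain")
})

test_that("quicki uses base-10 logs and is monotone in insulin", {
  expect_equal(quicki(10, 1), 1.0)
  expect_equal(quicki(93.56, 8.08), 1 / (log10(8.08) + log10(93.56)))
  expect_equal(round(quicki(93.56, 8.08), 4), 0.3474)
  ins <- seq(2, 30, by = 2)
  expect_true(all(diff(quicki(90, ins)) < 0))
  expect_error(quicki(90, 0), "domain")
})

test_that("lipid ratios divide by HDL", {
  expect_equal(lipid_ratios(100, 50, 150)$ldl_hdl_ratio, 2.0)
  expect_equal(lipid_ratios(100, 50, 150)$tg_hdl_ratio, 3.0)
  expect_equal(round(lipid_ratios(138.79, 55.33, 125.06)$ldl_hdl_ratio, 3),
               2.508)
  expect_error(lipid_ratios(100, 0, 150), "domain")
})

test_that("classify_phenotype follows the stated boundary conventions", {
  expect_equal(as.character(
    classify_phenotype(24.0, 120, 55, "female", 118, 75, 95)), "MHNW")
  # tg boundary inclusive
  expect_equal(as.character(
    classify_phenotype(27.0, 150, 45, "male", 120, 70, 90)), "MUOO")
  # glycemia strictly > 100
  expect_equal(as.character(
    classify_phenotype(26.0, 100, 60, "female", 120, 70, 100)), "MHOO")
  expect_equal(as.character(
    classify_phenotype(26.0, 100, 60, "female", 120, 70, 101)), "MUOO")
  # sex-specific HDL cuts, strict <
  expect_equal(as.character(
    classify_phenotype(24, 100, 40, "male", 120, 70, 90)), "MHNW")
  expect_equal(as.character(
    classify_phenotype(24, 100, 49, "female", 120, 70, 90)), "MUNW")
  # BMI 25 is overweight-obese; BMI 18.5 unclassified
  expect_equal(as.character(
    classify_phenotype(25, 100, 60, "male", 120, 70, 90)), "MHOO")
  expect_true(is.na(classify_phenotype(18.5, 100, 60, "male", 120, 70, 90)))
  # missing input -> unclassified
  expect_true(is.na(classify_phenotype(26, NA, 60, "male", 120, 70, 90)))
})

test_that("every boundary combination receives exactly one label", {
  g <- expand.grid(bmi = c(24.9, 25.0), tg = c(149, 150),
                   hdl = c(39, 40, 49, 50), sbp = c(129, 130),
                   dbp = c(84, 85), glucose = c(100, 101),
                   sex = c("male", "female"), stringsAsFactors = FALSE)
  lab <- classify_phenotype(g$bmi, g$tg, g$hdl, g$sex, g$sbp, g$dbp,
                            g$glucose)
  expect_false(anyNA(lab))
  expect_true(all(lab %in% c("MHNW", "MUNW", "MHOO", "MUOO")))
  # spot-check the partition logic against a direct recomputation
  unhealthy <- g$tg >= 150 | g$hdl < ifelse(g$sex == "male", 40, 50) |
    g$sbp >= 130 | g$dbp >= 85 | g$glucose > 100
  expect_equal(grepl("MU", lab), unhealthy)
  expect_equal(grepl("OO", lab), g$bmi >= 25)
})

test_that("HOMA and QUICKI are inversely rank-ordered on a synthetic cohort", {
  co <- simulate_cohort(cohort_sim_config(n = 100, seed = 17))
  p <- derive_indices(co$participants)
  expect_lt(cor(p$homa, p$quicki, method = "spearman"), 0)
})

test_that("derive_indices computes anthropometric identities", {
  d <- data.frame(id = "A", sex = factor("male", c("female", "male")),
                  age = 50, weight = 80, height = 1.75, lean_mass = 55,
                  fat_mass = 20, sbp = 125, dbp = 80, glucose = 95,
                  insulin = 8, tc = 200, hdl = 55, ldl = 130, tg = 120)
  p <- derive_indices(d)
  expect_equal(p$bmi, 80 / 1.75^2)
  expect_equal(p$lean_mass_index, 55 / 1.75^2)
  expect_equal(p$fat_mass_index, 20 / 1.75^2)
  expect_equal(p$mean_bp, 102.5)
  expect_equal(p$insulin_glucose_ratio, 8 / 95)
  expect_equal(as.character(p$phenotype), "MHOO")
})
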