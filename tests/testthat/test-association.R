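test_that("normality screen behaves at its stated error rates", {
  set.seed(20200423)
  normal_pass <- lognormal_reject <- 0L
  for (i in 1:100) {
    if (normality_screen(rnorm(60))) normal_pass <- normal_pass + 1L
    if (!normality_screen(exp(rnorm(60)))) {
      lognormal_reject <- lognormal_reject + 1L
    }
  }
  expect_gte(normal_pass, 90L)
  expect_gte(lognormal_reject, 90L)
  expect_false(normality_screen(rep(3, 20)))      # degenerate
  expect_error(normality_screen(rnorm(5)), "insufficient")
})

test_that("napierian transform is the elementwise natural log", {
  expect_equal(napierian_transform(c(1, exp(1), exp(2))), c(0, 1, 2))
  x <- c(0.5, 2, 9)
  expect_equal(exp(napierian_transform(x)), x)
  expect_error(napierian_transform(c(1, 0)), "domain")
})

test_that("sex_ttest is the pooled-variance Student t", {
  g <- factor(rep(c("a", "b"), each = 3))
  r <- sex_ttest(c(1, 2, 3, 1, 2, 3), g)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  r2 <- sex_ttest(c(1, 2, 3, 4, 5, 6), g)
  expect_equal(r2$t, -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(r2$df, 4)
  expect_equal(round(r2$p, 4), 0.0213)
  r3 <- sex_ttest(c(1, 2, 3, 4, 5, 6), factor(rep(c("a", "b"), each = 3),
                                              levels = c("b", "a")))
  expect_equal(r3$t, -r2$t)
  expect_equal(r3$p, r2$p)
  expect_error(sex_ttest(rep(1, 6), g), "degenerate")
})

test_that("fit_model reproduces hand-solved normal equations", {
  d <- data.frame(x = c(1, 2, 3), y = c(1, 2, 4))
  r <- fit_model(d, "y", "x", "none", transform = "none")
  expect_equal(r$adj_r2, 0.92857143, tolerance = 1e-6)
  expect_equal(r$f_stat, 27.0, tolerance = 1e-6)
  expect_equal(r$beta_std, sqrt(0.96428571), tolerance = 1e-6)
  expect_equal(r$df1, 1L)
  expect_equal(r$df2, 1L)

  # perfect fit
  d2 <- data.frame(x = rnorm(20))
  d2$y <- 2 * d2$x + 5
  r2 <- suppressWarnings(   # lm warns on an essentially perfect fit
    fit_model(d2, "y", "x", "none", transform = "none"))
  expect_equal(r2$beta_std, 1)
  expect_equal(r2$adj_r2, 1)
  expect_lt(r2$p_value, 1e-12)

  # collinear design errors
  d3 <- data.frame(x = 1:10, age = 2 * (1:10) + 3)
  d3$y <- rnorm(10)
  expect_error(fit_model(d3, "y", "x", "age", transform = "none"),
               "singular")
})

test_that("fit_model agrees with the normal-equations oracle", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(15:50, 1)
    covariate <- sample(c("none", "age", "sex", "lean_mass"), 1)
    d <- data.frame(x = rnorm(n), age = runif(n, 40, 65),
                    lean_mass = runif(n, 35, 60),
                    sex = factor(sample(c("female", "male"), n, TRUE)))
    d$y <- 0.4 * d$x + 0.01 * d$age + rnorm(n)
    r <- fit_model(d, "y", "x", covariate, transform = "none")
    zy <- scale(d$y)[, 1]; zx <- scale(d$x)[, 1]
    X <- switch(covariate,
                none = cbind(zx),
                sex = cbind(zx, as.numeric(d$sex == "male")),
                cbind(zx, d[[covariate]]))
    o <- naive_ols(zy, X)
    expect_equal(r$beta_std, o$beta[2], tolerance = 1e-8)
    expect_equal(r$f_stat, (o$beta[2] / o$se[2])^2, tolerance = 1e-8)
    expect_equal(r$adj_r2, o$adj_r2, tolerance = 1e-8)
    expect_equal(r$df2, o$df2)
  }
})

test_that("simple-model F equals the squared correlation t", {
  set.seed(8)
  n <- 40
  d <- data.frame(x = rnorm(n))
  d$y <- 0.3 * d$x + rnorm(n)
  r <- fit_model(d, "y", "x", "none", transform = "none")
  rho <- cor(d$x, d$y)
  t_rho <- rho * sqrt((n - 2) / (1 - rho^2))
  expect_equal(r$f_stat, t_rho^2, tolerance = 1e-10)
  expect_equal(r$beta_std, rho, tolerance = 1e-10)
})

test_that("a planted standardized effect is recovered on average", {
  set.seed(20200423)
  betas <- replicate(200, {
    x <- rnorm(57)
    zx <- (x - mean(x)) / sd(x)
    y <- 0.35 * zx + sqrt(1 - 0.35^2) * rnorm(57)
    fit_model(data.frame(x = x, y = y), "y", "x", "none",
              transform = "none")$beta_std
  })
  expect_lt(abs(mean(betas) - 0.35), 0.05)
})

test_that("auto transform logs non-normal positive outcomes", {
  set.seed(12)
  d <- data.frame(x = rnorm(60))
  d$y <- exp(1 + 0.5 * d$x + rnorm(60))    # lognormal outcome
  r <- fit_model(d, "y", "x", "none", transform = "auto")
  expect_true("outcome" %in% r$transformed)
  r_none <- fit_model(d, "y", "x", "none", transform = "none")
  expect_length(r_none$transformed, 0)
})

test_that("phenotype_anova reduces to known identities", {
  # identical group distributions -> F = 0, p = 1
  d0 <- data.frame(phenotype = factor(rep(c("MHNW", "MUNW", "MHOO", "MUOO"),
                                          each = 4)),
                   y = rep(c(1, 2, 3, 4), times = 4))
  r0 <- phenotype_anova(d0, "y", "none")
  expect_equal(r0$f_stat, 0)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$df1, 3)

  # two groups: F = t^2, same p as the pooled t-test
  d2 <- data.frame(phenotype = factor(rep(c("A", "B"), each = 3)),
                   y = c(1, 2, 3, 4, 5, 6))
  r2 <- phenotype_anova(d2, "y", "none")
  expect_equal(r2$f_stat, 13.5, tolerance = 1e-10)
  expect_equal(round(r2$p_value, 4), 0.0213)

  # a covariate orthogonal to the groups barely changes F
  set.seed(3)
  n <- 120
  d3 <- data.frame(phenotype = factor(rep(c("A", "B", "C"), each = n / 3)),
                   age = rnorm(n))
  d3$age <- ave(d3$age, d3$phenotype,
                FUN = function(x) x - mean(x))   # exactly orthogonal
  d3$y <- as.numeric(d3$phenotype) + rnorm(n)
  f_unadj <- phenotype_anova(d3, "y", "none")$f_stat
  f_adj <- phenotype_anova(d3, "y", "age")$f_stat
  expect_lt(abs(f_adj - f_unadj) / f_unadj, 0.10)

  expect_error(phenotype_anova(
    data.frame(phenotype = factor(rep("A", 5)), y = rnorm(5)), "y"),
    "groups")
})

test_that("build_report_tables shapes the reporting grid", {
  d <- synth_analysis_table(60, seed = 21)
  tabs <- build_report_tables(d)
  expect_equal(nrow(tabs$associations), 5 * 13 * 4)
  expect_setequal(unique(tabs$associations$model),
                  paste0("model_", 0:3))
  expect_true(all(tabs$associations$df1 == 1, na.rm = TRUE))
  expect_true(all(c("mean_men", "mean_women", "p_sex") %in%
                    names(tabs$descriptives)))
  expect_equal(nrow(tabs$phenotype_comparison), 5 * 4)

  # all-missing outcome column -> NA cells with n_used 0
  d$homa <- NA_real_
  tabs2 <- build_report_tables(d, exposures = "bmr_kcal_d",
                               outcomes = "homa")
  expect_true(all(is.na(tabs2$associations$f_stat)))
  expect_true(all(tabs2$associations$n_used == 0))

  # empty cohort: no crash
  expect_no_error(build_report_tables(d[0, ]))
})
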