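# Statistical surface: normality screening with natural-log transform,
# sex comparisons, covariate-adjusted regressions with standardized
# exposure coefficients (Models 0-3), and phenotype ANOVA/ANCOVA.

# Covariate vocabulary of the four regression models.
MODEL_COVARIATES <- c(none = "none", sex = "sex", age = "age",
                      lean_mass = "lean_mass")

#' Normality screen
#'
#' Automates the usual visual-plus-test screen with a Shapiro-Wilk test:
#' a variable is flagged non-normal when the test rejects at `alpha`.
#' Constant (zero-variance) vectors are degenerate and flagged non-normal.
#'
#' @param values Numeric vector; at least 8 non-missing values.
#' @param alpha Rejection level (default 0.05).
#' @return `TRUE` if consistent with normality, `FALSE` otherwise.
#' @export
normality_screen <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  if (length(x) < 8L) {
    stop("insufficient data: need >= 8 values for the normality screen",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) return(FALSE)      # degenerate
  stats::shapiro.test(x)$p.value >= alpha
}

#' Natural-logarithm transform
#'
#' Elementwise natural log for positively valued, non-normal variables.
#'
#' @param values Positive numeric vector (`NA` passed through).
#' @return `log(values)`.
#' @export
napierian_transform <- function(values) {
  if (any(values <= 0, na.rm = TRUE)) {
    stop("domain error: natural-log transform requires positive values",
         call. = FALSE)
  }
  log(values)
}

#' Unpaired two-sided Student t-test between sexes
#'
#' Equal-variance (pooled) t with `df = n1 + n2 - 2`. Group order follows
#' the factor levels of `group`; swapping labels flips the sign of `t` and
#' leaves `p` unchanged.
#'
#' @param values Numeric vector.
#' @param group Two-level factor (e.g. sex) aligned with `values`.
#' @return List with `t`, `df`, `p`, and per-group `n`.
#' @export
sex_ttest <- function(values, group) {
  group <- droplevels(factor(group))
  keep <- !is.na(values) & !is.na(group)
  values <- values[keep]; group <- group[keep]
  if (nlevels(group) != 2L || any(table(group) < 2L)) {
    stop("need two groups with >= 2 values each", call. = FALSE)
  }
  v <- tapply(values, group, stats::var)
  if (all(v == 0)) stop("degenerate: zero variance in both groups",
                        call. = FALSE)
  ht <- stats::t.test(values ~ group, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, n = as.integer(table(group)))
}

#' Covariate-adjusted association between an exposure and an outcome
#'
#' Ordinary least squares on complete rows of `outcome ~ exposure
#' (+ covariate)`. The outcome and exposure are z-scored on the analyzed
#' subsample (marginal standardization), so the exposure coefficient is the
#' standardized beta; covariates (sex factor, age, lean mass) enter on their
#' original scale. The reported F is the exposure's partial F, i.e. the
#' squared t of its coefficient, with `df1 = 1` and `df2 = n - k - 1`;
#' `adj_r2` is the adjusted R-squared of the full model.
#'
#' Under `transform = "auto"`, the outcome and the exposure are each
#' ln-transformed (before z-scoring) when the normality screen flags them
#' non-normal and all values are positive; variables with non-positive
#' values are left untransformed with a warning, and variables with fewer
#' than 8 complete values are not screened.
#'
#' @param data Data frame holding the variables.
#' @param outcome,exposure Column names.
#' @param covariate One of `"none"`, `"sex"`, `"age"`, `"lean_mass"`
#'   (Models 0-3 respectively).
#' @param transform `"auto"` (screen-driven ln transform), `"none"`, or
#'   `"log"` (force ln on outcome and exposure).
#' @param alpha Screening level for `"auto"`.
#' @return An `association_result` list: `outcome`, `exposure`,
#'   `covariate`, `f_stat`, `df1`, `df2`, `p_value`, `adj_r2`, `beta_std`,
#'   `n_used`, `transformed` (character vector naming ln-transformed roles).
#' @export
fit_model <- function(data, outcome, exposure,
                      covariate = c("none", "sex", "age", "lean_mass"),
                      transform = c("auto", "none", "log"), alpha = 0.05) {
  covariate <- match.arg(covariate)
  transform <- match.arg(transform)
  cols <- c(outcome, exposure, if (covariate != "none") covariate)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    stop("variable(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[, cols, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  k <- if (covariate == "none") 1L else 2L
  if (n < k + 2L) stop("insufficient rows for model fit", call. = FALSE)

  maybe_log <- function(x, role) {
    if (transform == "none") return(list(x = x, logged = FALSE))
    if (transform == "log" ||
        (n >= 8L && !normality_screen(x, alpha))) {
      if (any(x <= 0)) {
        warning(sprintf("%s left untransformed: non-positive values", role))
        return(list(x = x, logged = FALSE))
      }
      return(list(x = log(x), logged = TRUE))
    }
    list(x = x, logged = FALSE)
  }
  y <- maybe_log(d[[outcome]], "outcome")
  x <- maybe_log(d[[exposure]], "exposure")
  transformed <- c(if (y$logged) "outcome", if (x$logged) "exposure")

  zscore <- function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("singular-fit error: zero-variance variable",
                     call. = FALSE)
    (v - mean(v)) / s
  }
  dd <- data.frame(.y = zscore(y$x), .x = zscore(x$x))
  fml <- .y ~ .x
  if (covariate != "none") {
    dd$.c <- d[[covariate]]
    fml <- .y ~ .x + .c
  }
  fit <- stats::lm(fml, data = dd)
  cf <- summary(fit)$coefficients
  if (anyNA(coef(fit)) || !(".x" %in% rownames(cf))) {
    stop("singular-fit error: collinear design", call. = FALSE)
  }
  df2 <- fit$df.residual
  t_x <- cf[".x", "t value"]
  res <- list(outcome = outcome, exposure = exposure, covariate = covariate,
              f_stat = t_x^2, df1 = 1L, df2 = df2,
              p_value = cf[".x", "Pr(>|t|)"],
              adj_r2 = summary(fit)$adj.r.squared,
              beta_std = unname(coef(fit)[".x"]),
              n_used = n, transformed = transformed)
  class(res) <- "association_result"
  res
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "%s ~ %s (covariate: %s)\n  F(1, %d) = %.3f, p = %.4g, adj R2 = %.3f, beta_std = %.3f, n = %d\n",
    x$outcome, x$exposure, x$covariate, x$df2, x$f_stat, x$p_value,
    x$adj_r2, x$beta_std, x$n_used))
  if (length(x$transformed)) {
    cat("  ln-transformed:", paste(x$transformed, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Phenotype group comparison (ANOVA / ANCOVA)
#'
#' One-way ANOVA of `outcome` across phenotype groups (covariate
#' `"none"`), or the group factor's partial F after adjusting for a single
#' covariate (ANCOVA). `df1 = groups - 1`. When the between-group sum of
#' squares is exactly zero (identical group distributions) the F is 0 with
#' p = 1.
#'
#' @param data Data frame with a `phenotype` column (factor) and the
#'   outcome/covariate columns.
#' @param outcome Outcome column name.
#' @param covariate `"none"`, `"sex"`, `"age"`, or `"lean_mass"`.
#' @param group Grouping column name (default `"phenotype"`).
#' @return List with `f_stat`, `df1`, `df2`, `p_value`, `n_used`.
#' @export
phenotype_anova <- function(data, outcome,
                            covariate = c("none", "sex", "age", "lean_mass"),
                            group = "phenotype") {
  covariate <- match.arg(covariate)
  cols <- c(outcome, group, if (covariate != "none") covariate)
  d <- data[, cols, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  g <- droplevels(factor(d[[group]]))
  if (nlevels(g) < 2L) stop("need >= 2 non-empty groups", call. = FALSE)
  dd <- data.frame(.y = d[[outcome]], .g = g)
  if (covariate != "none") dd$.c <- d[[covariate]]
  reduced <- if (covariate == "none") stats::lm(.y ~ 1, data = dd) else
    stats::lm(.y ~ .c, data = dd)
  full <- if (covariate == "none") stats::lm(.y ~ .g, data = dd) else
    stats::lm(.y ~ .c + .g, data = dd)
  cmp <- stats::anova(reduced, full)
  ss_group <- cmp$`Sum of Sq`[2L]
  df1 <- cmp$Df[2L]
  df2 <- full$df.residual
  if (!is.na(ss_group) && ss_group < .Machine$double.eps^0.5 * sum(dd$.y^2 + 1)) {
    return(list(f_stat = 0, df1 = df1, df2 = df2, p_value = 1,
                n_used = nrow(dd)))
  }
  list(f_stat = cmp$F[2L], df1 = df1, df2 = df2,
       p_value = cmp$`Pr(>F)`[2L], n_used = nrow(dd))
}

# Outcomes of the association grid, in report order.
ASSOCIATION_OUTCOMES <- c("sbp", "dbp", "mean_bp", "glucose", "insulin",
                          "quicki", "homa", "tc", "hdl", "ldl", "tg",
                          "ldl_hdl_ratio", "tg_hdl_ratio")

# Calorimetry exposures, in report order.
ASSOCIATION_EXPOSURES <- c("bmr_kcal_d", "bfox_g_min", "bfox_pct_bmr",
                           "bchox_g_min", "bchox_pct_bmr")

#' Build report tables
#'
#' Assembles (i) per-sex descriptives with unpaired t-tests, (ii) the
#' exposure x outcome x model association grid with significance flags at
#' `alpha`, and (iii) a phenotype group-comparison table (ANOVA plus
#' ANCOVAs adjusting for sex, age and lean mass). Rows whose model cannot
#' be fitted (all-missing columns, too few rows) are kept as `NA` cells
#' with `n_used = 0` rather than dropped.
#'
#' @param data Participant table after [derive_indices()], with metabolic
#'   columns merged in where available.
#' @param exposures,outcomes Column-name vectors; defaults cover the full
#'   reporting grid. Exposures/outcomes absent from `data` are skipped.
#' @param alpha Significance level for flagging (default 0.05; flags
#'   `p <= alpha`).
#' @param transform Transform policy passed to [fit_model()].
#' @return List with data frames `descriptives`, `associations`,
#'   `phenotype_comparison`.
#' @export
build_report_tables <- function(data,
                                exposures = ASSOCIATION_EXPOSURES,
                                outcomes = ASSOCIATION_OUTCOMES,
                                alpha = 0.05,
                                transform = "auto") {
  exposures <- intersect(exposures, names(data))
  outcomes <- intersect(outcomes, names(data))
  covars <- names(MODEL_COVARIATES)
  model_of <- setNames(paste0("model_", 0:3), covars)

  desc_vars <- unique(c("age", outcomes, exposures))
  desc_vars <- intersect(desc_vars, names(data))
  descriptives <- do.call(rbind, lapply(desc_vars, function(v) {
    x <- data[[v]]
    by_sex <- function(s) {
      xs <- x[data$sex == s & !is.na(x)]
      c(mean = mean(xs), sd = stats::sd(xs), n = length(xs))
    }
    f <- if ("sex" %in% names(data)) by_sex("female") else c(NA, NA, 0)
    m <- if ("sex" %in% names(data)) by_sex("male") else c(NA, NA, 0)
    p <- tryCatch(sex_ttest(x, data$sex)$p, error = function(e) NA_real_)
    data.frame(variable = v, mean_all = mean(x, na.rm = TRUE),
               sd_all = stats::sd(x, na.rm = TRUE),
               n_all = sum(!is.na(x)),
               mean_men = m[["mean"]], sd_men = m[["sd"]],
               mean_women = f[["mean"]], sd_women = f[["sd"]],
               p_sex = p, sig_sex = !is.na(p) & p <= alpha)
  }))

  cells <- expand.grid(exposure = exposures, outcome = outcomes,
                       covariate = covars, stringsAsFactors = FALSE)
  associations <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    ex <- cells$exposure[i]; oc <- cells$outcome[i]; cv <- cells$covariate[i]
    res <- tryCatch(
      suppressWarnings(fit_model(data, oc, ex, cv, transform = transform,
                                 alpha = alpha)),
      error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(exposure = ex, outcome = oc, model = model_of[[cv]],
                        covariate = cv, f_stat = NA_real_, df1 = NA_integer_,
                        df2 = NA_integer_, p_value = NA_real_,
                        adj_r2 = NA_real_, beta_std = NA_real_, n_used = 0L,
                        significant = FALSE))
    }
    data.frame(exposure = ex, outcome = oc, model = model_of[[cv]],
               covariate = cv, f_stat = res$f_stat, df1 = res$df1,
               df2 = res$df2, p_value = res$p_value, adj_r2 = res$adj_r2,
               beta_std = res$beta_std, n_used = res$n_used,
               significant = res$p_value <= alpha)
  }))
  if (!is.null(associations)) rownames(associations) <- NULL

  phen <- NULL
  if ("phenotype" %in% names(data)) {
    phen <- do.call(rbind, lapply(intersect(exposures, names(data)),
                                  function(ex) {
      do.call(rbind, lapply(covars, function(cv) {
        res <- tryCatch(phenotype_anova(data, ex, cv),
                        error = function(e) NULL)
        if (is.null(res)) {
          return(data.frame(outcome = ex, model = model_of[[cv]],
                            covariate = cv, f_stat = NA_real_,
                            df1 = NA_integer_, df2 = NA_integer_,
                            p_value = NA_real_, n_used = 0L))
        }
        data.frame(outcome = ex, model = model_of[[cv]], covariate = cv,
                   f_stat = res$f_stat, df1 = res$df1, df2 = res$df2,
                   p_value = res$p_value, n_used = res$n_used)
      }))
    }))
    if (!is.null(phen)) rownames(phen) <- NULL
  }

  list(descriptives = descriptives, associations = associations,
       phenotype_comparison = phen)
}
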