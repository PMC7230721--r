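# Independent oracles and fixture builders. The oracles deliberately avoid
# the package's code paths: the steady-state oracle is a naive exhaustive
# loop with its own CV arithmetic, and the OLS oracle solves the normal
# equations directly.

# Build an epoch_series object directly from per-epoch values.
make_epoch_series <- function(vo2, vco2 = vo2 * 0.8, ve = vo2 / 10,
                              epoch_s = 30, missing = rep(FALSE, length(vo2))) {
  n <- length(vo2)
  out <- data.frame(epoch = seq_len(n), start_s = (seq_len(n) - 1) * epoch_s,
                    vo2 = vo2, vco2 = vco2, ve = ve, rer = vco2 / vo2,
                    n_samples = ifelse(missing, 0L, 1L), missing = missing)
  out$vo2[missing] <- NA_real_
  out$vco2[missing] <- NA_real_
  out$ve[missing] <- NA_real_
  out$rer[missing] <- NA_real_
  attr(out, "epoch_s") <- epoch_s
  attr(out, "duration_s") <- n * epoch_s
  attr(out, "participant_id") <- "fixture"
  class(out) <- c("epoch_series", "data.frame")
  out
}

# Exhaustive naive steady-state search: scans every epoch-aligned start,
# recomputes CVs from first principles, keeps the strict minimum of the
# mean CV among qualifying windows (earliest on ties). Returns the start_s
# of the winner or NULL.
naive_most_stable_start <- function(series, discard_s = 300, window_s = 300,
                                    cv_max = 10) {
  epoch_s <- attr(series, "epoch_s")
  w <- window_s / epoch_s
  cv <- function(x) {
    m <- sum(x) / length(x)
    100 * sqrt(sum((x - m)^2) / (length(x) - 1)) / m
  }
  best_start <- NULL
  best_score <- Inf
  for (i in seq_len(nrow(series) - w + 1)) {
    if (series$start_s[i] < discard_s) next
    sl <- series[i:(i + w - 1), ]
    if (any(sl$missing)) next
    cvs <- c(cv(sl$vo2), cv(sl$vco2), cv(sl$ve), cv(sl$rer))
    if (!all(cvs < cv_max)) next
    score <- mean(cvs)
    if (score < best_score) {
      best_score <- score
      best_start <- series$start_s[i]
    }
  }
  best_start
}

# Random epoch series with a mix of stable and unstable stretches.
random_epoch_series <- function(n_epochs = 60, epoch_s = 30) {
  base_vo2 <- runif(1, 180, 320)
  rer <- runif(1, 0.75, 0.95)
  # piecewise noise level so the argmin moves around and some windows fail
  k <- sample(2:4, 1)
  bounds <- sort(c(0, runif(k - 1), 1))
  lev <- runif(k, 0.005, 0.18)
  pos <- (seq_len(n_epochs) - 0.5) / n_epochs
  sig <- lev[findInterval(pos, bounds, rightmost.closed = TRUE)]
  vo2 <- base_vo2 * (1 + rnorm(n_epochs, 0, sig))
  vco2 <- base_vo2 * rer * (1 + rnorm(n_epochs, 0, sig))
  ve <- base_vo2 / 10 * (1 + rnorm(n_epochs, 0, sig))
  vo2 <- pmax(vo2, 1); vco2 <- pmax(vco2, 1); ve <- pmax(ve, 0.1)
  make_epoch_series(vo2, vco2, ve, epoch_s)
}

# Normal-equations OLS oracle. X: predictor matrix without intercept.
naive_ols <- function(y, X) {
  X <- as.matrix(X)
  Xd <- cbind(1, X)
  xtx <- crossprod(Xd)
  b <- solve(xtx, crossprod(Xd, y))
  res <- y - Xd %*% b
  n <- length(y)
  df2 <- n - ncol(Xd)
  sigma2 <- sum(res^2) / df2
  se <- sqrt(diag(sigma2 * solve(xtx)))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(beta = unname(drop(b)), se = unname(se), df2 = df2, r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / df2)
}

# Cohort with metabolic outputs computed directly from the planted truth
# (no breath-level simulation) — a fast analysis-stage fixture.
synth_analysis_table <- function(n, seed, effect_rer_insulin = 0.33) {
  co <- simulate_cohort(cohort_sim_config(n = n, seed = seed,
                                          effect_rer_insulin = effect_rer_insulin))
  win <- data.frame(mean_vo2 = co$truth$vo2_star * 1000,
                    mean_vco2 = co$truth$vco2_star * 1000,
                    mean_rer = co$truth$rer_true)
  cbind(derive_indices(co$participants), compute_metabolics(win))
}

# Small constant trace builder.
const_trace <- function(vo2 = 250, vco2 = 200, ve = 7, dt = 5,
                        duration = 1800, id = "const") {
  t <- seq(dt, duration - dt / 2, by = dt)
  gas_trace(t, rep(vo2, length(t)), rep(vco2, length(t)),
            rep(ve, length(t)), id, duration_s = duration)
}
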