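# Steady-state selection: discard an initial transient, scan fixed-length
# windows of epoch means, screen each window's coefficient of variation in
# VO2, VCO2, VE and RER, and keep the most stable window that meets the
# criteria. No randomness anywhere in this module.

#' Steady-state selection criteria
#'
#' @param discard_initial_s Seconds discarded at the start of the recording
#'   (default 300, i.e. the first 5 min).
#' @param window_s Candidate window length in seconds (default 300). Both
#'   `discard_initial_s` and `window_s` must be whole multiples of the epoch
#'   length used upstream.
#' @param cv_max_pct CV threshold in percent applied to all four screened
#'   series (default 10).
#' @return A `steady_state_criteria` list.
#' @export
steady_state_criteria <- function(discard_initial_s = 300, window_s = 300,
                                  cv_max_pct = 10.0) {
  stopifnot(discard_initial_s >= 0, window_s > 0, cv_max_pct > 0)
  structure(list(discard_initial_s = discard_initial_s, window_s = window_s,
                 cv_max_pct = cv_max_pct,
                 variables = c("vo2", "vco2", "ve", "rer")),
            class = "steady_state_criteria")
}

#' Coefficient of variation, percent
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation. Scale
#' invariant: `cv_percent(k * x) == cv_percent(x)` for any `k > 0`.
#'
#' @param values Numeric vector, at least 2 values, positive mean.
#' @return CV in percent.
#' @export
#' @examples
#' cv_percent(c(90, 110)) # 14.1421...
cv_percent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    stop("insufficient data: need >= 2 values for a CV", call. = FALSE)
  }
  m <- mean(values)
  if (m <= 0) stop("domain error: CV undefined for mean <= 0", call. = FALSE)
  100 * stats::sd(values) / m
}

#' Enumerate candidate steady-state windows
#'
#' One window per epoch-aligned start from `discard_initial_s` up to
#' `span - window_s`, step one epoch. Windows that overlap a missing epoch
#' are omitted. For each window the CV (percent) of the epoch-mean VO2,
#' VCO2, VE and RER series is computed, together with the window means; the
#' composite `stability` score is the plain mean of the four CVs and
#' `meets_criteria` is true iff all four CVs are strictly below
#' `cv_max_pct`.
#'
#' @param series An [epoch_trace()] result.
#' @param criteria A [steady_state_criteria()].
#' @return Data frame (class `ss_windows`) with one row per candidate
#'   window: `start_s`, `end_s`, `cv_vo2`, `cv_vco2`, `cv_ve`, `cv_rer`,
#'   `stability`, `mean_vo2`, `mean_vco2`, `mean_ve`, `mean_rer`,
#'   `meets_criteria`.
#' @export
enumerate_windows <- function(series, criteria = steady_state_criteria()) {
  stopifnot(inherits(series, "epoch_series"))
  epoch_s <- attr(series, "epoch_s")
  if (criteria$window_s %% epoch_s != 0 ||
      criteria$discard_initial_s %% epoch_s != 0) {
    stop("window_s and discard_initial_s must be multiples of epoch_s",
         call. = FALSE)
  }
  span <- nrow(series) * epoch_s
  if (span < criteria$discard_initial_s + criteria$window_s) {
    stop("too-short error: recording shorter than discard + window",
         call. = FALSE)
  }
  w <- criteria$window_s %/% epoch_s           # epochs per window
  first <- criteria$discard_initial_s %/% epoch_s + 1L
  starts <- seq.int(first, nrow(series) - w + 1L)
  rows <- lapply(starts, function(i) {
    sl <- series[i:(i + w - 1L), ]
    if (any(sl$missing)) return(NULL)
    cvs <- c(cv_percent(sl$vo2), cv_percent(sl$vco2),
             cv_percent(sl$ve), cv_percent(sl$rer))
    data.frame(start_s = sl$start_s[1L],
               end_s = sl$start_s[1L] + criteria$window_s,
               cv_vo2 = cvs[1L], cv_vco2 = cvs[2L], cv_ve = cvs[3L],
               cv_rer = cvs[4L],
               stability = mean(cvs),
               mean_vo2 = mean(sl$vo2), mean_vco2 = mean(sl$vco2),
               mean_ve = mean(sl$ve),
               mean_rer = mean(sl$vco2) / mean(sl$vo2),
               meets_criteria = all(cvs < criteria$cv_max_pct))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      cv_vo2 = numeric(0), cv_vco2 = numeric(0),
                      cv_ve = numeric(0), cv_rer = numeric(0),
                      stability = numeric(0), mean_vo2 = numeric(0),
                      mean_vco2 = numeric(0), mean_ve = numeric(0),
                      mean_rer = numeric(0), meets_criteria = logical(0))
  }
  rownames(out) <- NULL
  attr(out, "criteria") <- criteria
  class(out) <- c("ss_windows", "data.frame")
  out
}

#' Select the most stable steady-state window
#'
#' Among the windows meeting the CV criteria, returns the one with minimum
#' `stability` (mean of the four CVs); ties break to the earliest start.
#' When no window meets the criteria, returns `NULL` — the no-valid-window
#' signal, which excludes the participant from calorimetry outputs.
#'
#' @param windows An [enumerate_windows()] result (non-empty).
#' @return A one-row data frame, or `NULL` if no window qualifies.
#' @export
select_most_stable <- function(windows) {
  if (is.null(windows) || nrow(windows) == 0L) {
    stop("precondition error: empty window sequence", call. = FALSE)
  }
  ok <- windows[windows$meets_criteria, , drop = FALSE]
  if (nrow(ok) == 0L) return(NULL)
  ok <- ok[order(ok$stability, ok$start_s), , drop = FALSE]
  out <- ok[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' RER validity of a selected window
#'
#' Basal respiratory exchange ratios outside the physiological range exclude
#' a participant from substrate-oxidation outputs (BMR is kept). Bounds are
#' inclusive: exclusion applies only strictly below `lo` or strictly above
#' `hi`.
#'
#' @param window A selected window (one row, with `mean_rer`), or a bare
#'   numeric mean RER.
#' @param lo,hi Inclusive validity bounds (defaults 0.7 and 1.0).
#' @return Logical flag, `TRUE` when the mean RER is within bounds.
#' @export
rer_validity <- function(window, lo = 0.7, hi = 1.0) {
  rer <- if (is.numeric(window)) window else window$mean_rer
  rer >= lo & rer <= hi
}
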