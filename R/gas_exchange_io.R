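# Reading, validating, epoching and writing gas-exchange recordings and
# participant tables. All times are seconds from recording start; epochs are
# half-open [start, end). Gas units: VO2/VCO2 mL/min, VE L/min.

#' Trace file dialect
#'
#' Column mapping for delimited gas-exchange exports. The default matches the
#' package's own CSV layout; metabolic-cart exports with other headers are
#' adapted by renaming here rather than rewriting files.
#'
#' @param time,vo2,vco2,ve Column names holding time (s), oxygen uptake
#'   (mL/min), carbon-dioxide output (mL/min) and minute ventilation (L/min).
#' @param sep Field separator.
#' @return A `trace_dialect` list.
#' @export
#' @examples
#' trace_dialect()
trace_dialect <- function(time = "t_s", vo2 = "vo2_ml_min",
                          vco2 = "vco2_ml_min", ve = "ve_l_min", sep = ",") {
  structure(list(time = time, vo2 = vo2, vco2 = vco2, ve = ve, sep = sep),
            class = "trace_dialect")
}

#' Construct a gas-exchange trace
#'
#' @param t Time of each sample, seconds from recording start (strictly
#'   increasing, non-negative).
#' @param vo2,vco2 Oxygen uptake and carbon-dioxide output, mL/min (> 0).
#' @param ve Minute ventilation, L/min (> 0).
#' @param participant_id Opaque identifier.
#' @param duration_s Total recorded span; defaults to `ceiling(max(t))`.
#'   Must be at least the last sample time.
#' @return A `gas_trace`: data frame with columns `t`, `vo2`, `vco2`, `ve`
#'   plus attributes `participant_id` and `duration_s`.
#' @export
gas_trace <- function(t, vo2, vco2, ve, participant_id = "unknown",
                      duration_s = NULL) {
  if (length(t) < 2L) {
    stop("empty trace: need at least 2 valid samples", call. = FALSE)
  }
  if (any(t < 0)) stop("sample times must be non-negative", call. = FALSE)
  if (any(diff(t) <= 0)) {
    stop("ordering error: sample times must be strictly increasing",
         call. = FALSE)
  }
  if (any(vo2 <= 0) || any(vco2 <= 0) || any(ve <= 0)) {
    stop("gas values must be positive", call. = FALSE)
  }
  if (is.null(duration_s)) duration_s <- ceiling(max(t))
  if (duration_s < max(t)) {
    stop("duration_s shorter than last sample time", call. = FALSE)
  }
  out <- data.frame(t = as.numeric(t), vo2 = as.numeric(vo2),
                    vco2 = as.numeric(vco2), ve = as.numeric(ve))
  attr(out, "participant_id") <- as.character(participant_id)
  attr(out, "duration_s") <- as.numeric(duration_s)
  class(out) <- c("gas_trace", "data.frame")
  out
}

#' Read a gas-exchange trace from delimited text
#'
#' Rows with non-positive VO2, VCO2 or VE are dropped and counted (reported
#' as a message and in the `n_dropped` attribute); a file must retain at
#' least two valid samples.
#'
#' @param path CSV file path.
#' @param dialect A [trace_dialect()] naming the columns.
#' @param participant_id Identifier; defaults to the file name sans extension.
#' @param duration_s Optional recorded span override (s).
#' @return A [gas_trace()] with attribute `n_dropped`.
#' @export
read_trace <- function(path, dialect = trace_dialect(),
                       participant_id = NULL, duration_s = NULL) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = dialect$sep, check.names = FALSE)
  need <- unlist(dialect[c("time", "vo2", "vco2", "ve")])
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  if (is.null(participant_id)) {
    participant_id <- sub("\\.[^.]*$", "", basename(path))
  }
  d <- data.frame(t = as.numeric(raw[[dialect$time]]),
                  vo2 = as.numeric(raw[[dialect$vo2]]),
                  vco2 = as.numeric(raw[[dialect$vco2]]),
                  ve = as.numeric(raw[[dialect$ve]]))
  bad <- !stats::complete.cases(d) | d$vo2 <= 0 | d$vco2 <= 0 | d$ve <= 0
  n_dropped <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  if (nrow(d) < 2L) {
    stop("empty-trace error: fewer than 2 valid samples in ", path,
         call. = FALSE)
  }
  if (any(diff(d$t) <= 0)) {
    stop("ordering error: non-monotone time column in ", path, call. = FALSE)
  }
  if (n_dropped > 0) {
    message(sprintf("read_trace: dropped %d invalid sample(s) from %s",
                    n_dropped, basename(path)))
  }
  tr <- gas_trace(d$t, d$vo2, d$vco2, d$ve, participant_id, duration_s)
  attr(tr, "n_dropped") <- n_dropped
  tr
}

#' Write a gas-exchange trace
#'
#' Inverse of [read_trace()]: retained samples round-trip bit-identically in
#' the value columns.
#'
#' @param trace A `gas_trace`.
#' @param path Output CSV path.
#' @param dialect Column naming, see [trace_dialect()].
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, dialect = trace_dialect()) {
  stopifnot(inherits(trace, "gas_trace"))
  out <- data.frame(trace$t, trace$vo2, trace$vco2, trace$ve)
  names(out) <- unlist(dialect[c("time", "vo2", "vco2", "ve")])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average a trace into fixed epochs
#'
#' Epochs tile `[0, duration_s)` half-open; each epoch value is the
#' arithmetic mean of the samples with `start <= t < end`. The per-epoch RER
#' is the ratio of epoch-mean VCO2 to epoch-mean VO2 (not the mean of
#' breath-level ratios). Epochs containing no samples are kept as rows with
#' `missing = TRUE` and are excluded by downstream window enumeration.
#'
#' @param trace A [gas_trace()].
#' @param epoch_s Epoch length in seconds (> 0); default 30.
#' @return An `epoch_series`: data frame with columns `epoch`, `start_s`,
#'   `vo2`, `vco2`, `ve`, `rer`, `n_samples`, `missing`, and attributes
#'   `epoch_s`, `duration_s`, `participant_id`.
#' @export
epoch_trace <- function(trace, epoch_s = 30) {
  stopifnot(inherits(trace, "gas_trace"))
  if (epoch_s <= 0) stop("epoch_s must be positive", call. = FALSE)
  duration_s <- attr(trace, "duration_s")
  n_epochs <- floor(duration_s / epoch_s)
  if (n_epochs < 1L) stop("empty-epoch error: trace shorter than one epoch",
                          call. = FALSE)
  idx <- floor(trace$t / epoch_s) + 1L      # 1-based epoch index
  keep <- idx >= 1L & idx <= n_epochs       # beyond-span samples ignored
  idx <- idx[keep]
  f <- factor(idx, levels = seq_len(n_epochs))
  n_samples <- as.integer(table(f))
  mean_by <- function(x) {
    s <- rowsum(x[keep], f)[, 1L]
    ifelse(n_samples > 0L, s / n_samples, NA_real_)
  }
  vo2 <- mean_by(trace$vo2)
  vco2 <- mean_by(trace$vco2)
  ve <- mean_by(trace$ve)
  if (all(n_samples == 0L)) {
    stop("empty-epoch error: all epochs missing", call. = FALSE)
  }
  out <- data.frame(epoch = seq_len(n_epochs),
                    start_s = (seq_len(n_epochs) - 1L) * epoch_s,
                    vo2 = vo2, vco2 = vco2, ve = ve,
                    rer = vco2 / vo2,
                    n_samples = n_samples,
                    missing = n_samples == 0L)
  rownames(out) <- NULL
  attr(out, "epoch_s") <- epoch_s
  attr(out, "duration_s") <- duration_s
  attr(out, "participant_id") <- attr(trace, "participant_id")
  class(out) <- c("epoch_series", "data.frame")
  out
}

#' Read a participant table
#'
#' Delimited text with a header; mandatory columns `id`, `sex`, `age`. Sex
#' must code male/female (case-insensitive `male`/`female`/`m`/`f`). Unknown
#' columns are preserved pass-through; blank numeric cells become `NA` and
#' propagate as missing downstream (analyses use pairwise-complete rows).
#' Units are assumed mg/dL (blood panel), UI/mL (insulin), mm Hg, kg, cm,
#' m (height), years.
#'
#' @param path CSV file path.
#' @return A data frame, one row per participant, `sex` a factor with levels
#'   `female`, `male`.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop("participant file not found: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "sex", "age"), names(d))
  if (length(miss)) {
    stop("format error: missing mandatory column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  sx <- tolower(trimws(as.character(d$sex)))
  sx[sx == "m"] <- "male"
  sx[sx == "f"] <- "female"
  if (!all(sx %in% c("male", "female"))) {
    bad <- unique(d$sex[!sx %in% c("male", "female")])
    stop("format error: sex value(s) outside {male, female}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  d$sex <- factor(sx, levels = c("female", "male"))
  d$id <- as.character(d$id)
  d
}

#' Write a participant table
#' @param participants Data frame as returned by [read_participants()] or
#'   [derive_indices()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
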