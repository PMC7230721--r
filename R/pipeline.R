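# End-to-end orchestration: ingest -> steady state -> stoichiometry ->
# clinical indices -> association reports, as one configured, logged run.

#' Pipeline run configuration
#'
#' @param traces_dir Directory of trace CSVs named `<id>.csv` (may be
#'   missing/empty: calorimetry stages are then skipped with a warning).
#' @param participants_file Participant CSV (see [read_participants()]).
#' @param out_dir Output directory for the artifact bundle.
#' @param epoch_s Epoch length, seconds.
#' @param criteria A [steady_state_criteria()].
#' @param stoich A [stoichiometry_config()].
#' @param transform Transform policy for [fit_model()].
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @param dialect Trace file [trace_dialect()].
#' @return A `run_config` list.
#' @export
run_config <- function(traces_dir = NULL, participants_file, out_dir,
                       epoch_s = 30,
                       criteria = steady_state_criteria(),
                       stoich = stoichiometry_config(),
                       transform = "auto", alpha = 0.05, seed = 20200423,
                       dialect = trace_dialect()) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(traces_dir = traces_dir,
                 participants_file = participants_file, out_dir = out_dir,
                 epoch_s = epoch_s, criteria = criteria, stoich = stoich,
                 transform = transform, alpha = alpha,
                 seed = as.integer(seed), dialect = dialect),
            class = "run_config")
}

#' Process one trace through steady-state selection and stoichiometry
#'
#' @param trace A [gas_trace()].
#' @param epoch_s Epoch length (s).
#' @param criteria A [steady_state_criteria()].
#' @param stoich A [stoichiometry_config()].
#' @return One-row data frame with the metabolic outputs, the selected
#'   window bounds, and a `status` of `ok`, `rer_out_of_range` or
#'   `no_valid_window` (metabolic fields `NA` for the latter).
#' @export
process_trace <- function(trace, epoch_s = 30,
                          criteria = steady_state_criteria(),
                          stoich = stoichiometry_config()) {
  id <- attr(trace, "participant_id")
  series <- epoch_trace(trace, epoch_s)
  windows <- enumerate_windows(series, criteria)
  sel <- if (nrow(windows)) select_most_stable(windows) else NULL
  if (is.null(sel)) {
    return(data.frame(id = id, status = "no_valid_window",
                      window_start_s = NA_real_, window_end_s = NA_real_,
                      bmr_kcal_d = NA_real_, bfox_g_min = NA_real_,
                      bfox_pct_bmr = NA_real_, bchox_g_min = NA_real_,
                      bchox_pct_bmr = NA_real_, mean_rer = NA_real_,
                      oxidation_valid = FALSE))
  }
  met <- compute_metabolics(sel, stoich)
  data.frame(id = id,
             status = if (met$oxidation_valid) "ok" else "rer_out_of_range",
             window_start_s = sel$start_s, window_end_s = sel$end_s, met)
}

#' Run the full pipeline
#'
#' Reads the participant table; processes every trace (steady-state
#' selection, Weir/Frayn stoichiometry) with per-participant exclusion
#' logging; RER-out-of-range participants keep their BMR but lose the
#' substrate-oxidation outputs; derives clinical indices and phenotypes;
#' fits the association grid and the phenotype comparison; writes the
#' bundle (`metabolics.csv`, `indices.csv`, `exclusions.csv`,
#' `table1_descriptives.csv`, `associations.csv`,
#' `phenotype_comparison.csv`, `manifest.json`) to `cfg$out_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with all in-memory tables plus the per-stage
#'   participant log.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  participants <- read_participants(cfg$participants_file)

  metabolics <- NULL
  exclusions <- data.frame(participant_id = character(0),
                           reason = character(0), mean_rer = numeric(0))
  trace_files <- character(0)
  if (!is.null(cfg$traces_dir) && dir.exists(cfg$traces_dir)) {
    trace_files <- list.files(cfg$traces_dir, pattern = "\\.csv$",
                              full.names = TRUE)
  }
  if (length(trace_files) == 0L) {
    warning("no traces found: calorimetry stages skipped", call. = FALSE)
  } else {
    rows <- lapply(trace_files, function(f) {
      tr <- read_trace(f, cfg$dialect)
      process_trace(tr, cfg$epoch_s, cfg$criteria, cfg$stoich)
    })
    metabolics <- do.call(rbind, rows)
    excl <- metabolics[metabolics$status != "ok", , drop = FALSE]
    if (nrow(excl)) {
      exclusions <- data.frame(participant_id = excl$id,
                               reason = excl$status,
                               mean_rer = excl$mean_rer)
    }
    # RER exclusion removes oxidation outputs but keeps BMR
    bad <- metabolics$status == "rer_out_of_range"
    metabolics[bad, c("bfox_g_min", "bfox_pct_bmr",
                      "bchox_g_min", "bchox_pct_bmr")] <- NA_real_
  }

  merged <- participants
  if (!is.null(metabolics)) {
    merged <- merge(participants,
                    metabolics[, setdiff(names(metabolics), "status")],
                    by = "id", all.x = TRUE, sort = FALSE)
  }
  indices <- derive_indices(merged)
  reports <- build_report_tables(indices, alpha = cfg$alpha,
                                 transform = cfg$transform)

  w <- function(x, f) if (!is.null(x)) {
    utils::write.csv(x, file.path(cfg$out_dir, f), row.names = FALSE)
  }
  w(metabolics, "metabolics.csv")
  w(indices, "indices.csv")
  w(exclusions, "exclusions.csv")
  w(reports$descriptives, "table1_descriptives.csv")
  w(reports$associations, "associations.csv")
  w(reports$phenotype_comparison, "phenotype_comparison.csv")

  manifest <- list(
    package = "calorflex",
    version = as.character(utils::packageVersion("calorflex")),
    seed = cfg$seed, epoch_s = cfg$epoch_s,
    criteria = unclass(cfg$criteria), stoich = unclass(cfg$stoich),
    transform = cfg$transform, alpha = cfg$alpha,
    n_participants = nrow(participants),
    n_traces = length(trace_files),
    n_analyzed = if (is.null(metabolics)) 0L else
      sum(metabolics$status == "ok"),
    n_excluded = nrow(exclusions))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(participants = participants, metabolics = metabolics,
                 exclusions = exclusions, indices = indices,
                 reports = reports, manifest = manifest))
}
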