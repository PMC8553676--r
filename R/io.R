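#' Write and read a single recording as tabular text
#'
#' A recording is stored as a two-column CSV (`time_s`, `amplitude_uV`,
#' one sample per row) with a JSON metadata sidecar (same path with
#' `.json` appended) holding check size, reversal rate, sampling rate,
#' segment length and ground-truth fields.
#'
#' @param recording a `vep_recording`
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "vep_recording"))
  n <- length(recording$samples)
  df <- data.frame(time_s = (seq_len(n) - 1) / recording$sampling_rate,
                   amplitude_uV = recording$samples)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- recording[setdiff(names(recording), "samples")]
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @return `read_recording()` returns a `vep_recording`
#' @export
read_recording <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  df <- utils::read.csv(path)
  if (!all(c("time_s", "amplitude_uV") %in% names(df)))
    stop("recording file must have columns time_s, amplitude_uV")
  rec <- c(list(samples = df$amplitude_uV), meta)
  rec$blink_segments <- as.integer(rec$blink_segments %||% integer(0))
  structure(rec, class = "vep_recording")
}

#' Persist a synthetic cohort as a directory tree
#'
#' Writes one CSV per recording under
#' `dir/participant_XX/<condition>/check_<size>.csv` (with JSON
#' sidecars) plus the cohort-level `ground_truth.csv`.  Only available
#' for cohorts generated at `"recording"` fidelity.
#'
#' @param cohort a [generate_cohort()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vep_cohort"))
  if (cohort$fidelity != "recording")
    stop("only recording-fidelity cohorts carry raw time series")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$participants)) {
    part <- cohort$participants[[i]]
    for (cn in names(part$conditions)) {
      d <- file.path(dir, sprintf("participant_%02d", i), cn)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (rec in part$conditions[[cn]]$data) {
        write_recording(rec, file.path(
          d, sprintf("check_%s.csv", gsub("[.]", "p", rec$check_size))))
      }
    }
  }
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Persist the tables of a study run
#'
#' Writes `ground_truth.csv`, `responses.csv`, `estimates.csv`,
#' `comparisons.csv`, `config.json` and `run_log.txt` into `dir`.  Each
#' table is plain UTF-8 CSV with a header row, so any stage can be
#' re-run from the persisted intermediates (see [curve_from_table()]).
#'
#' @param results a [run_study()] result
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_study_results <- function(results, dir) {
  stopifnot(inherits(results, "study_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("ground_truth", "responses", "estimates", "comparisons")) {
    utils::write.csv(results[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  cfg <- results$config
  cfg$stimulus <- cfg$stimulus[c("check_sizes", "reversal_rate",
                                 "segment_length", "n_segments",
                                 "sampling_rate", "sf_convention")]
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(results$log, file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Write a per-check-size response table
#'
#' One row per check size, tidy CSV, suitable for external inspection
#' and for re-entry via [curve_from_table()].
#'
#' @param curve a `tuning_curve` (or the `responses` table of a run)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_responses <- function(curve, path) {
  df <- if (inherits(curve, "tuning_curve")) as.data.frame(curve) else curve
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
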