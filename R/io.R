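#' Write a landmark recording to CSV
#'
#' The standard pose-tracker layout: one row per (frame, landmark) with
#' columns `frame, landmark, x, y, confidence`. Missing coordinates are
#' written as empty fields.
#'
#' @param rec A `landmark_recording`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(rec, path) {
  write.csv(rec$landmarks, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a landmark recording from CSV
#'
#' @param path CSV with columns `frame, landmark, x, y, confidence`.
#' @param fs Sampling rate of the recording (30 or 60 Hz).
#' @param hand,subject_id,session_id Metadata.
#' @param segment Optional `c(start, end)` task-segment annotation in
#'   frames; `NULL` leaves trimming to the preprocessing auto-trim.
#' @return A `landmark_recording`.
#' @export
read_landmark_csv <- function(path, fs = 30, hand = "dominant",
                              subject_id = "S1", session_id = 1L,
                              segment = NULL) {
  lm <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "landmark", "x", "y", "confidence")
  if (!all(need %in% names(lm))) {
    tapkin_error(sprintf("%s: missing column(s) %s", path,
                         paste(setdiff(need, names(lm)), collapse = ", ")),
                 "tapkin_io_error")
  }
  structure(list(fs = fs, hand = hand, subject_id = subject_id,
                 session_id = session_id, segment = segment,
                 landmarks = lm[need]),
            class = "landmark_recording")
}

#' Write a cohort to a directory
#'
#' Lays out the cohort as plain text: one landmark CSV and one
#' ground-truth JSON sidecar per recording under `recordings/` and
#' `truth/`, a per-recording `manifest.csv` (with the sampling rate),
#' and a per-session `sessions.csv` with the clinical labels.
#'
#' @param cohort A `cohort_dataset` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "recordings"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  for (id in names(cohort$recordings)) {
    write_landmark_csv(cohort$recordings[[id]],
                       file.path(dir, "recordings", paste0(id, ".csv")))
    tr <- cohort$truths[[id]]
    jsonlite::write_json(
      list(periods = tr$periods, peak_amps = tr$peak_amps,
           cycle_starts = tr$cycle_starts, severity = tr$severity,
           outlier_frames = tr$outlier_frames,
           dropout_frames = tr$dropout_frames),
      file.path(dir, "truth", paste0(id, ".json")),
      auto_unbox = TRUE, digits = NA)
  }
  man <- cohort$manifest
  man$fs <- vapply(man$recording_id,
                   function(id) cohort$recordings[[id]]$fs, numeric(1))
  man$file <- file.path("recordings", paste0(man$recording_id, ".csv"))
  write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$sessions, file.path(dir, "sessions.csv"),
            row.names = FALSE)
  invisible(dir)
}

#' Write a tapping signal to CSV with a QC sidecar
#'
#' @param sig A `tapping_signal`.
#' @param path Output CSV path (`t, amplitude, velocity, acceleration,
#'   jerk`); the QC counters go to `<path>.qc.json`.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(sig, path) {
  write.csv(data.frame(t = sig$t, amplitude = sig$amplitude,
                       velocity = sig$velocity,
                       acceleration = sig$acceleration, jerk = sig$jerk),
            path, row.names = FALSE)
  jsonlite::write_json(sig$qc, paste0(path, ".qc.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write a feature table with its inventory manifest
#'
#' @param features Matrix (rows = assessments) carrying a `manifest`
#'   attribute, as assembled by [cohort_features()].
#' @param path Output CSV path; the manifest goes to
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(assessment = rownames(features), features,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  man <- attr(features, "manifest")
  if (!is.null(man)) {
    jsonlite::write_json(man, paste0(path, ".manifest.json"),
                         auto_unbox = TRUE)
  }
  invisible(path)
}
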