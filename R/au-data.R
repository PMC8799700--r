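# Core data types and file I/O: framewise AU recordings, BIDS-style event
# tables, dyad rosters and 20x20 causality matrices.

#' Default facial action-unit channel manifest
#'
#' The 20 AU channels tracked by the automated facial-feature extractor, in
#' cohort order. Channel order is fixed at the cohort level so that causality
#' matrices are comparable across dyads. "Smirk" has no FACS code and is
#' given the placeholder AU99.
#'
#' @return character vector of 20 channel labels.
#' @export
default_au_labels <- function() {
  c("AU01_inner_brow_raise", "AU02_brow_raise", "AU04_brow_furrow",
    "AU05_eye_widen", "AU06_cheek_raise", "AU07_lid_tighten",
    "AU09_nose_wrinkle", "AU10_upper_lip_raise", "AU12_lip_corner_pull",
    "AU14_dimpler", "AU15_lip_corner_depress", "AU17_chin_raise",
    "AU18_lip_pucker", "AU20_lip_stretch", "AU24_lip_press",
    "AU25_mouth_open", "AU26_jaw_drop", "AU28_lip_suck",
    "AU43_eye_closure", "AU99_smirk")
}

#' Recognised experimental conditions
#' @return character vector of condition labels.
#' @export
au_conditions <- function() {
  c("anticipation_pain", "anticipation_nopain",
    "anticipation_treat", "anticipation_notreat",
    "pain_moderate", "pain_innocuous", "rating", "rest")
}

#' Construct a framewise AU recording
#'
#' A recording holds one subject's framewise activations of the 20 AU
#' channels at a fixed sampling rate (protocol value 20 frames/s). Frame
#' indices are implicit: row `i` is frame `first_frame + i - 1`, and frames
#' are gap-free by construction.
#'
#' @param values numeric matrix, frames x 20.
#' @param subject_id subject identifier.
#' @param role `"patient"` or `"clinician"`.
#' @param sampling_rate_hz positive sampling rate in frames per second.
#' @param au_labels cohort AU channel manifest (length 20).
#' @param first_frame integer index of the first frame (default 0).
#' @return an object of class `au_recording`.
#' @export
au_recording <- function(values, subject_id, role = c("patient", "clinician"),
                         sampling_rate_hz = 20,
                         au_labels = default_au_labels(), first_frame = 0L) {
  role <- match.arg(role)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(au_labels) != 20L) {
    stopf("schema error: `au_labels` must name exactly 20 AU channels, got %d",
          length(au_labels))
  }
  if (ncol(values) != 20L) {
    stopf("schema error: AU recordings carry exactly 20 channels, got %d",
          ncol(values))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stopf("data error: non-finite AU value at frame %d (channel %s)",
          as.integer(first_frame) + bad[[1L]] - 1L, au_labels[bad[[2L]]])
  }
  if (!is.numeric(sampling_rate_hz) || length(sampling_rate_hz) != 1L ||
      sampling_rate_hz <= 0) {
    stop("`sampling_rate_hz` must be a single positive number")
  }
  colnames(values) <- au_labels
  structure(
    list(subject_id = as.character(subject_id), role = role,
         sampling_rate_hz = sampling_rate_hz, values = values,
         au_labels = au_labels, first_frame = as.integer(first_frame)),
    class = "au_recording"
  )
}

n_frames <- function(rec) nrow(rec$values)

#' @export
print.au_recording <- function(x, ...) {
  cat(sprintf("<au_recording> %s (%s): %d frames x %d AU channels @ %g Hz (%.1f s)\n",
              x$subject_id, x$role, n_frames(x), ncol(x$values),
              x$sampling_rate_hz, n_frames(x) / x$sampling_rate_hz))
  invisible(x)
}

#' Read a framewise AU recording from CSV
#'
#' Expects columns `frame`, `time_s` and exactly the 20 cohort AU columns;
#' channel order is normalised to `au_labels`. Frames must be strictly
#' increasing and gap-free; values must be finite.
#'
#' @param path CSV file path.
#' @inheritParams au_recording
#' @return an `au_recording`.
#' @export
read_au_recording <- function(path, subject_id,
                              role = c("patient", "clinician"),
                              sampling_rate_hz = 20,
                              au_labels = default_au_labels()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("frame", "time_s") %in% names(df))) {
    stop("schema error: AU CSV must have `frame` and `time_s` columns")
  }
  have <- setdiff(names(df), c("frame", "time_s"))
  missing <- setdiff(au_labels, have)
  extra <- setdiff(have, au_labels)
  if (length(missing) || length(extra)) {
    stopf("schema error: AU columns do not match the cohort manifest (missing: %s; extra: %s)",
          paste(missing, collapse = ", ") %0% "none",
          paste(extra, collapse = ", ") %0% "none")
  }
  fr <- df$frame
  if (nrow(df) == 0L) stop("data error: empty AU recording")
  if (any(diff(fr) != 1)) {
    i <- which(diff(fr) != 1)[1L]
    stopf("data error: frame indices must be strictly increasing and gap-free (break after frame %s)",
          format(fr[i]))
  }
  vals <- as.matrix(df[au_labels])
  if (!all(is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)[1L, ]
    stopf("data error: non-finite AU value at frame %s (channel %s)",
          format(fr[bad[[1L]]]), au_labels[bad[[2L]]])
  }
  au_recording(vals, subject_id, match.arg(role), sampling_rate_hz,
               au_labels, first_frame = fr[1L])
}

`%0%` <- function(x, alt) if (nzchar(x)) x else alt

#' Write an AU recording to CSV at full precision
#'
#' Values are written with 17 significant digits so that
#' `read_au_recording()` recovers them bit-identically.
#'
#' @param rec an `au_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_au_recording <- function(rec, path) {
  stopifnot(inherits(rec, "au_recording"))
  frame <- rec$first_frame + seq_len(n_frames(rec)) - 1L
  df <- data.frame(frame = frame, time_s = frame / rec$sampling_rate_hz,
                   rec$values, check.names = FALSE)
  write_precise_table(df, path)
  invisible(path)
}

#' Construct and validate an event table
#'
#' BIDS-events-style block annotations: one row per event with onset and
#' duration in seconds, a condition label, and trial/run indices. Events
#' within a run must not overlap; anticipation durations must lie within
#' the protocol bounds (default 6-12 s); trial indices are unique within a
#' run for each condition (a trial's rest/anticipation/stimulus/rating rows
#' share the trial index).
#'
#' @param onset event onsets in seconds (>= 0).
#' @param duration event durations in seconds (> 0).
#' @param condition condition labels, from [au_conditions()].
#' @param trial_index integer trial index within the run.
#' @param run_index integer run index.
#' @param anticipation_bounds allowed anticipation duration range in seconds.
#' @return a `data.frame` of class `event_table`.
#' @export
event_table <- function(onset, duration, condition, trial_index,
                        run_index = 1L, anticipation_bounds = c(6, 12)) {
  df <- data.frame(onset = as.numeric(onset), duration = as.numeric(duration),
                   condition = as.character(condition),
                   trial_index = as.integer(trial_index),
                   run_index = as.integer(run_index))
  validate_event_table(df, anticipation_bounds)
}

validate_event_table <- function(df, anticipation_bounds = c(6, 12)) {
  need <- c("onset", "duration", "condition", "trial_index", "run_index")
  if (!all(need %in% names(df))) {
    stopf("schema error: event table needs columns %s", paste(need, collapse = ", "))
  }
  if (any(df$onset < 0) || any(df$duration <= 0)) {
    stop("data error: onsets must be >= 0 and durations > 0")
  }
  bad <- setdiff(unique(df$condition), au_conditions())
  if (length(bad)) stopf("data error: unknown condition(s): %s", paste(bad, collapse = ", "))
  ant <- grepl("^anticipation", df$condition)
  eps <- 1e-9
  if (any(df$duration[ant] < anticipation_bounds[1] - eps |
          df$duration[ant] > anticipation_bounds[2] + eps)) {
    stopf("data error: anticipation durations must lie in [%g, %g] s",
          anticipation_bounds[1], anticipation_bounds[2])
  }
  for (r in unique(df$run_index)) {
    e <- df[df$run_index == r, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1 && any(e$onset[-1] < (e$onset + e$duration)[-nrow(e)] - eps)) {
      stopf("data error: overlapping events in run %d", r)
    }
    dup <- duplicated(e[c("condition", "trial_index")])
    if (any(dup)) {
      stopf("data error: duplicate trial index for condition %s in run %d",
            e$condition[dup][1L], r)
    }
  }
  df <- df[order(df$run_index, df$onset), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' Read / write BIDS-style event tables (TSV)
#' @param path TSV file path.
#' @param anticipation_bounds allowed anticipation duration range in seconds.
#' @return `read_events()` returns an `event_table`.
#' @export
read_events <- function(path, anticipation_bounds = c(6, 12)) {
  validate_event_table(utils::read.delim(path), anticipation_bounds)
}

#' @rdname read_events
#' @param events an `event_table`.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_table"))
  write_precise_table(as.data.frame(events), path, sep = "\t")
  invisible(path)
}

#' Construct a dyad roster
#'
#' One row per dyad; `is_real = FALSE` marks pseudo-dyads (pairings of a
#' patient and a clinician who never interacted, used for the empirical
#' null).
#'
#' @param dyad_id,patient_id,clinician_id identifiers.
#' @param is_real logical, real or pseudo pairing.
#' @return a `data.frame` of class `dyad_roster`.
#' @export
dyad_roster <- function(dyad_id, patient_id, clinician_id, is_real = TRUE) {
  df <- data.frame(dyad_id = as.character(dyad_id),
                   patient_id = as.character(patient_id),
                   clinician_id = as.character(clinician_id),
                   is_real = as.logical(is_real))
  if (anyDuplicated(df$dyad_id)) stop("data error: duplicated dyad ids")
  dup <- duplicated(df[c("patient_id", "clinician_id")])
  if (any(dup)) stop("data error: duplicated patient/clinician pairing")
  class(df) <- c("dyad_roster", "data.frame")
  df
}

#' @rdname dyad_roster
#' @param path CSV file path.
#' @export
read_roster <- function(path) {
  df <- utils::read.csv(path)
  dyad_roster(df$dyad_id, df$patient_id, df$clinician_id, df$is_real)
}

#' @rdname dyad_roster
#' @param roster a `dyad_roster`.
#' @export
write_roster <- function(roster, path) {
  stopifnot(inherits(roster, "dyad_roster"))
  utils::write.table(as.data.frame(roster), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a labelled square causality matrix (CSV)
#'
#' Rows index the source AU and columns the target AU. Writing uses 17
#' significant digits so reading is an exact inverse for finite values.
#'
#' @param m square numeric matrix (or a `gc_matrix` object).
#' @param path CSV file path.
#' @param labels channel labels for both dimensions; defaults to the row
#'   names of `m`.
#' @return `read_gc_values()` returns a labelled numeric matrix.
#' @export
write_gc_values <- function(m, path, labels = NULL) {
  if (inherits(m, "gc_matrix")) m <- m$values
  m <- as.matrix(m)
  labels <- labels %||% rownames(m) %||% default_au_labels()
  if (nrow(m) != length(labels) || ncol(m) != length(labels)) {
    stopf("shape error: expected a %d x %d matrix, got %d x %d",
          length(labels), length(labels), nrow(m), ncol(m))
  }
  dimnames(m) <- list(labels, labels)
  df <- data.frame(source = labels, m, check.names = FALSE)
  write_precise_table(df, path)
  invisible(path)
}

#' @rdname write_gc_values
#' @export
read_gc_values <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  labels <- df[[1L]]
  m <- as.matrix(df[-1L])
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m) || !identical(colnames(m), as.character(labels))) {
    stop("shape error: matrix CSV must be square with matching row/column labels")
  }
  rownames(m) <- labels
  m
}
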