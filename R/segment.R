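# Block segmentation: cut time-aligned patient/clinician AU segments out of
# continuous recordings using the event table.

slice_frames <- function(rec, onset, duration) {
  rate <- rec$sampling_rate_hz
  i0 <- round(onset * rate)
  i1 <- round((onset + duration) * rate)
  if (i0 < rec$first_frame || i1 > rec$first_frame + n_frames(rec)) {
    stopf("bounds error: event [%g, %g) s exceeds recording of %d frames",
          onset, onset + duration, n_frames(rec))
  }
  rec$values[(i0 - rec$first_frame + 1L):(i1 - rec$first_frame), , drop = FALSE]
}

#' Segment a dyad's recordings into time-aligned blocks
#'
#' Extracts one `block_series` per event matching `conditions`. Event
#' windows are half-open `[onset, onset + duration)` in seconds, mapped to
#' frames by rounding, so consecutive events never share a frame. Blocks
#' are ordered by run and onset and numbered consecutively.
#'
#' For pseudo-dyads, whose members ran under their own protocol timing, pass
#' the clinician's own events as `clinician_events`: blocks are then paired
#' by block index and truncated to the shorter member's frame count.
#'
#' @param patient,clinician `au_recording` objects sharing a sampling rate.
#' @param events the dyad's `event_table` (the patient's, for pseudo-dyads).
#' @param conditions conditions to extract (default: the treatment-paradigm
#'   anticipation blocks).
#' @param dyad_id optional dyad identifier stamped on each block.
#' @param clinician_events optional separate `event_table` for the clinician.
#' @return list of `block_series`, each with equal-length
#'   `patient_segment` / `clinician_segment` frame x 20 matrices.
#' @export
segment_blocks <- function(patient, clinician, events,
                           conditions = c("anticipation_treat",
                                          "anticipation_notreat"),
                           dyad_id = NULL, clinician_events = NULL) {
  stopifnot(inherits(patient, "au_recording"),
            inherits(clinician, "au_recording"))
  if (patient$sampling_rate_hz != clinician$sampling_rate_hz) {
    stop("alignment error: patient and clinician sampling rates differ")
  }
  pe <- events[events$condition %in% conditions, , drop = FALSE]
  pe <- pe[order(pe$run_index, pe$onset), , drop = FALSE]
  if (nrow(pe) == 0L) stop("empty-input error: no events match `conditions`")
  truncate <- !is.null(clinician_events)
  if (truncate) {
    ce <- clinician_events[clinician_events$condition %in% conditions, , drop = FALSE]
    ce <- ce[order(ce$run_index, ce$onset), , drop = FALSE]
    if (nrow(ce) != nrow(pe)) {
      stop("alignment error: members have different numbers of matching blocks")
    }
  } else {
    ce <- pe
  }
  blocks <- vector("list", nrow(pe))
  for (b in seq_len(nrow(pe))) {
    ps <- slice_frames(patient, pe$onset[b], pe$duration[b])
    cs <- slice_frames(clinician, ce$onset[b], ce$duration[b])
    n <- min(nrow(ps), nrow(cs))
    if (truncate) {
      ps <- ps[seq_len(n), , drop = FALSE]
      cs <- cs[seq_len(n), , drop = FALSE]
    } else if (nrow(ps) != nrow(cs)) {
      stop("alignment error: unequal member frame counts for a shared event")
    }
    blocks[[b]] <- structure(
      list(dyad_id = dyad_id, condition = pe$condition[b], block_index = b,
           patient_segment = ps, clinician_segment = cs, n_frames = n),
      class = "block_series")
  }
  blocks
}

#' @export
print.block_series <- function(x, ...) {
  cat(sprintf("<block_series> %s block %d (%s): %d frames x %d channels per member\n",
              x$dyad_id %||% "dyad", x$block_index, x$condition, x$n_frames,
              ncol(x$patient_segment)))
  invisible(x)
}
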