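# Cohort-level simulation and on-disk datasets: a full synthetic study
# (AU streams, pain sessions, trial betas, behaviour, roster, ground
# truth) that exercises every reader and every downstream stage.

#' Simulate a complete dyad cohort in memory
#'
#' Generates `n_dyads` patient-clinician dyads. Each dyad's planted
#' coupling gains are multiplied by a per-dyad scale drawn uniformly from
#' `gain_scale_range`, so facial-causality strength varies across the
#' cohort; the dyad's scalar facial score (the mean realised gain) then
#' drives the planted cross-brain coupling and behavioural scores.
#'
#' @param n_dyads number of real dyads (>= 2).
#' @param au_params a [dyad_sim_params()] template (per-dyad seeds are
#'   derived from `seed`).
#' @param pain_params a [pain_sim_params()] template, or `NULL` to skip
#'   pain sessions.
#' @param brain_params a [brain_sim_params()] template, or `NULL` to skip
#'   brain/behaviour data.
#' @param gain_scale_range per-dyad uniform range multiplying the planted
#'   coupling gains.
#' @param seed global cohort seed.
#' @return an object of class `dyad_cohort`: `roster`, per-dyad data
#'   (`dyads`), index tables by member id, and a per-dyad `truth` table.
#' @export
simulate_cohort <- function(n_dyads, au_params = dyad_sim_params(),
                            pain_params = pain_sim_params(),
                            brain_params = brain_sim_params(),
                            gain_scale_range = c(0.4, 1.6), seed = 1L) {
  if (n_dyads < 2L) stop("insufficient-data error: need >= 2 dyads")
  pid <- sprintf("P%02d", seq_len(n_dyads))
  cid <- sprintf("C%02d", seq_len(n_dyads))
  did <- sprintf("D%02d", seq_len(n_dyads))
  roster <- dyad_roster(did, pid, cid, is_real = TRUE)
  dyads <- vector("list", n_dyads)
  names(dyads) <- did
  truth_rows <- vector("list", n_dyads)
  for (d in seq_len(n_dyads)) {
    set.seed(derive_seed(seed, "gain-scale", d))
    sc <- stats::runif(1, gain_scale_range[1], gain_scale_range[2])
    ap <- au_params
    ap$seed <- derive_seed(seed, "au", d)
    if (!is.null(ap$coupling_edges) && nrow(ap$coupling_edges)) {
      ap$coupling_edges$gain <- ap$coupling_edges$gain * sc
    }
    dy <- generate_dyad_au(ap, patient_id = pid[d], clinician_id = cid[d])
    score <- dy$truth$coupling_strength
    entry <- list(dyad_id = did[d], patient = dy$patient,
                  clinician = dy$clinician, events = dy$events,
                  truth = dy$truth, gain_scale = sc)
    if (!is.null(pain_params)) {
      pp <- pain_params
      pp$seed <- derive_seed(seed, "pain", d)
      entry$pain <- generate_pain_session(pp, subject_id = pid[d])
    }
    if (!is.null(brain_params)) {
      entry$brain <- generate_dyad_brain(
        brain_params, facial_score = score, dyad_id = did[d],
        patient_id = pid[d], clinician_id = cid[d],
        seed = derive_seed(seed, "brain", d))
    }
    dyads[[d]] <- entry
    truth_rows[[d]] <- data.frame(
      dyad_id = did[d], gain_scale = sc, facial_score = score,
      rho = if (!is.null(entry$brain)) entry$brain$truth$rho else NA_real_)
  }
  truth <- do.call(rbind, truth_rows)
  behavior <- if (!is.null(brain_params)) {
    do.call(rbind, lapply(dyads, function(e) e$brain$behavior))
  } else NULL
  if (!is.null(behavior)) rownames(behavior) <- NULL
  structure(list(roster = roster, dyads = dyads, truth = truth,
                 behavior = behavior, seed = as.integer(seed),
                 gain_scale_range = gain_scale_range),
            class = "dyad_cohort")
}

#' @export
print.dyad_cohort <- function(x, ...) {
  e <- x$dyads[[1L]]
  cat(sprintf("<dyad_cohort> %d real dyads (seed %d)%s%s\n",
              nrow(x$roster), x$seed,
              if (!is.null(e$pain)) ", with pain sessions" else "",
              if (!is.null(e$brain)) ", with trial betas + behaviour" else ""))
  invisible(x)
}

cohort_member <- function(cohort, id, role) {
  for (e in cohort$dyads) {
    if (role == "patient" && e$patient$subject_id == id) {
      return(list(rec = e$patient, events = e$events))
    }
    if (role == "clinician" && e$clinician$subject_id == id) {
      return(list(rec = e$clinician, events = e$events))
    }
  }
  stopf("data error: %s %s not found in cohort", role, id)
}

#' Blocks for any (real or pseudo) dyad of a cohort
#'
#' Real dyads share one event table; pseudo-dyad members keep their own
#' protocol timing, so their blocks are paired by block index and truncated
#' to the shorter member.
#'
#' @param cohort a `dyad_cohort`.
#' @param patient_id,clinician_id member identifiers.
#' @param conditions conditions to extract.
#' @return list of `block_series`.
#' @export
cohort_blocks <- function(cohort, patient_id, clinician_id,
                          conditions = c("anticipation_treat",
                                         "anticipation_notreat")) {
  pat <- cohort_member(cohort, patient_id, "patient")
  cli <- cohort_member(cohort, clinician_id, "clinician")
  real <- any(cohort$roster$patient_id == patient_id &
                cohort$roster$clinician_id == clinician_id &
                cohort$roster$is_real)
  if (real) {
    segment_blocks(pat$rec, cli$rec, pat$events, conditions,
                   dyad_id = paste0(patient_id, "_", clinician_id))
  } else {
    segment_blocks(pat$rec, cli$rec, pat$events, conditions,
                   dyad_id = paste0("pseudo_", patient_id, "_x_", clinician_id),
                   clinician_events = cli$events)
  }
}

#' ESGC matrices for every dyad of a roster
#'
#' Computes the directed 20 x 20 ESGC matrix for each roster row (real or
#' pseudo), with the same reservoir parameters and seeds for both, as the
#' empirical-null construction requires.
#'
#' @param cohort a `dyad_cohort`.
#' @param roster a `dyad_roster` (e.g. the real roster or the output of
#'   [enumerate_pseudo_dyads()]).
#' @param direction causality direction.
#' @param p [reservoir_params()].
#' @param conditions block conditions.
#' @return list of `gc_matrix`, one per roster row.
#' @export
cohort_gc_matrices <- function(cohort, roster,
                               direction = "patient_to_clinician",
                               p = reservoir_params(),
                               conditions = c("anticipation_treat",
                                              "anticipation_notreat")) {
  lapply(seq_len(nrow(roster)), function(i) {
    blocks <- cohort_blocks(cohort, roster$patient_id[i],
                            roster$clinician_id[i], conditions)
    m <- esgc_matrix(blocks, direction, p)
    m$dyad_id <- roster$dyad_id[i]
    m
  })
}

#' Write a simulated cohort to disk / read it back
#'
#' `build_cohort()` simulates a cohort and writes every artefact as plain
#' text: per-subject AU CSVs and event TSVs for the treatment session, the
#' patient pain session, per-subject trial-beta CSVs, `roster.csv`,
#' `behavior.csv`, a `truth.json` with the planted ground truth and a
#' `params.json` echo. `load_cohort()` reads the dataset back through the
#' package readers.
#'
#' @param dir output directory.
#' @param n_dyads number of real dyads.
#' @param overwrite allow writing into an existing non-empty directory.
#' @inheritParams simulate_cohort
#' @return `build_cohort()` returns the in-memory cohort invisibly;
#'   `load_cohort()` returns a `dyad_cohort`.
#' @export
build_cohort <- function(dir, n_dyads, au_params = dyad_sim_params(),
                         pain_params = pain_sim_params(),
                         brain_params = brain_sim_params(),
                         gain_scale_range = c(0.4, 1.6), seed = 1L,
                         overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stopf("refusing to write into non-empty directory %s (set overwrite = TRUE)", dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(n_dyads, au_params, pain_params, brain_params,
                            gain_scale_range, seed)
  write_roster(cohort$roster, file.path(dir, "roster.csv"))
  if (!is.null(cohort$behavior)) {
    write_precise_table(cohort$behavior, file.path(dir, "behavior.csv"))
  }
  truth <- list(cohort_seed = cohort$seed,
                gain_scale_range = cohort$gain_scale_range,
                dyads = cohort$truth,
                edges = lapply(cohort$dyads, function(e) e$truth$edges))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  params_echo <- list(n_dyads = n_dyads, seed = seed,
                      au_params = unclass(au_params),
                      pain_params = if (!is.null(pain_params)) unclass(pain_params),
                      brain_params = if (!is.null(brain_params)) {
                        bp <- unclass(brain_params)
                        bp$roi_definitions <- lapply(bp$roi_definitions, as.integer)
                        bp
                      },
                      gain_scale_range = gain_scale_range)
  jsonlite::write_json(params_echo, file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (e in cohort$dyads) {
    pid <- e$patient$subject_id
    cid <- e$clinician$subject_id
    write_au_recording(e$patient, file.path(dir, sprintf("au_treatment_%s.csv", pid)))
    write_au_recording(e$clinician, file.path(dir, sprintf("au_treatment_%s.csv", cid)))
    write_events(e$events, file.path(dir, sprintf("events_treatment_%s.tsv", e$dyad_id)))
    if (!is.null(e$pain)) {
      write_au_recording(e$pain$patient, file.path(dir, sprintf("au_pain_%s.csv", pid)))
      write_events(e$pain$events, file.path(dir, sprintf("events_pain_%s.tsv", pid)))
    }
    if (!is.null(e$brain)) {
      write_betas <- function(bs, path) {
        df <- data.frame(parcel = rownames(bs$betas), bs$betas,
                         check.names = FALSE)
        colnames(df)[-1L] <- sprintf("trial_%02d", seq_len(ncol(bs$betas)))
        write_precise_table(df, path)
      }
      write_betas(e$brain$patient, file.path(dir, sprintf("betas_%s.csv", pid)))
      write_betas(e$brain$clinician, file.path(dir, sprintf("betas_%s.csv", cid)))
      trials <- data.frame(trial = seq_along(e$brain$patient$trial_conditions),
                           condition = e$brain$patient$trial_conditions,
                           run = e$brain$patient$trial_runs)
      utils::write.table(trials, file.path(dir, sprintf("trials_%s.csv", e$dyad_id)),
                         sep = ",", row.names = FALSE, quote = FALSE)
    }
  }
  invisible(cohort)
}

#' @rdname build_cohort
#' @export
load_cohort <- function(dir) {
  roster <- read_roster(file.path(dir, "roster.csv"))
  truth_json <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  behavior_path <- file.path(dir, "behavior.csv")
  behavior <- if (file.exists(behavior_path)) utils::read.csv(behavior_path)
  dyads <- vector("list", nrow(roster))
  names(dyads) <- roster$dyad_id
  for (i in seq_len(nrow(roster))) {
    pid <- roster$patient_id[i]
    cid <- roster$clinician_id[i]
    did <- roster$dyad_id[i]
    entry <- list(
      dyad_id = did,
      patient = read_au_recording(file.path(dir, sprintf("au_treatment_%s.csv", pid)),
                                  pid, "patient"),
      clinician = read_au_recording(file.path(dir, sprintf("au_treatment_%s.csv", cid)),
                                    cid, "clinician"),
      events = read_events(file.path(dir, sprintf("events_treatment_%s.tsv", did))))
    pain_path <- file.path(dir, sprintf("au_pain_%s.csv", pid))
    if (file.exists(pain_path)) {
      entry$pain <- list(
        patient = read_au_recording(pain_path, pid, "patient"),
        events = read_events(file.path(dir, sprintf("events_pain_%s.tsv", pid))))
    }
    beta_path <- file.path(dir, sprintf("betas_%s.csv", pid))
    if (file.exists(beta_path)) {
      trials <- utils::read.csv(file.path(dir, sprintf("trials_%s.csv", did)))
      read_betas <- function(path, id) {
        df <- utils::read.csv(path, check.names = FALSE)
        m <- as.matrix(df[-1L])
        rownames(m) <- df[[1L]]
        new_beta_series(m, trials$condition, trials$run, id)
      }
      entry$brain <- list(patient = read_betas(beta_path, pid),
                          clinician = read_betas(file.path(dir, sprintf("betas_%s.csv", cid)), cid))
    }
    dyads[[i]] <- entry
  }
  structure(list(roster = roster, dyads = dyads,
                 truth = truth_json$dyads, behavior = behavior,
                 seed = truth_json$cohort_seed,
                 gain_scale_range = truth_json$gain_scale_range),
            class = "dyad_cohort")
}
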