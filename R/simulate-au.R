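# Synthetic dyadic AU streams with known ground truth.
#
# Each AU channel evolves as a stationary AR(1); a planted directed coupling
# adds gain * f(lagged source value) to the target channel's innovation,
# by default only inside anticipation blocks (where causality is estimated).
# The model is deliberately minimal: it carries the lagged directed
# dependence the ESGC stage must detect, nothing more.

#' Parameters for the dyadic AU generator
#'
#' @param n_aus number of AU channels per member (fixed at 20 by the cohort
#'   manifest).
#' @param sampling_rate_hz video sampling rate (protocol value 20 frames/s).
#' @param n_blocks anticipation blocks per dyad (protocol value 12,
#'   implied by `n_runs * trials_per_run`).
#' @param block_duration_range_s anticipation block duration bounds in
#'   seconds (protocol value 6-12 s, pseudorandomised).
#' @param coupling_edges data frame of planted directed couplings (see
#'   [coupling_edge()]); `NULL` for an uncoupled (null) dyad.
#' @param ar_coef per-channel AR(1) coefficient in `[0, 1)`.
#' @param noise_sd innovation standard deviation. The default 0.6 with
#'   `ar_coef = 0.8` gives unit marginal variance.
#' @param nonlinearity coupling transfer function applied to the lagged
#'   source value.
#' @param coupling_window `"anticipation"` restricts the planted coupling to
#'   anticipation blocks; `"all"` applies it throughout the session.
#' @param n_runs,trials_per_run session structure (2 runs x 6 trials).
#' @param rest_duration_range_s,stim_duration_s,rating_duration_s timing of
#'   the rest/stimulus/rating phases flanking each anticipation block.
#' @param seed integer seed; the generator is a pure function of
#'   parameters + seed.
#' @return a list of class `dyad_sim_params`.
#' @export
dyad_sim_params <- function(n_aus = 20L, sampling_rate_hz = 20,
                            n_blocks = 12L,
                            block_duration_range_s = c(6, 12),
                            coupling_edges = default_coupling_edges(),
                            ar_coef = 0.8, noise_sd = 0.6,
                            nonlinearity = c("tanh", "logistic", "linear"),
                            coupling_window = c("anticipation", "all"),
                            n_runs = 2L, trials_per_run = 6L,
                            rest_duration_range_s = c(10, 14),
                            stim_duration_s = 14, rating_duration_s = 7,
                            seed = 1L) {
  nonlinearity <- match.arg(nonlinearity)
  coupling_window <- match.arg(coupling_window)
  if (abs(ar_coef) >= 1) {
    stop("parameter error: |ar_coef| must be < 1 for stationarity")
  }
  if (noise_sd <= 0) stop("parameter error: noise_sd must be positive")
  if (!is.null(coupling_edges) && nrow(coupling_edges)) {
    if (any(coupling_edges$lag_frames < 1)) {
      stop("parameter error: coupling lag_frames must be >= 1")
    }
    if (any(coupling_edges$source_au > n_aus | coupling_edges$target_au > n_aus)) {
      stop("parameter error: coupling edge AU index out of range")
    }
  }
  structure(list(n_aus = as.integer(n_aus), sampling_rate_hz = sampling_rate_hz,
                 n_blocks = as.integer(n_blocks),
                 block_duration_range_s = block_duration_range_s,
                 coupling_edges = coupling_edges, ar_coef = ar_coef,
                 noise_sd = noise_sd, nonlinearity = nonlinearity,
                 coupling_window = coupling_window,
                 n_runs = as.integer(n_runs),
                 trials_per_run = as.integer(trials_per_run),
                 rest_duration_range_s = rest_duration_range_s,
                 stim_duration_s = stim_duration_s,
                 rating_duration_s = rating_duration_s,
                 seed = as.integer(seed)),
            class = "dyad_sim_params")
}

#' Describe one planted directed coupling edge
#'
#' @param source_role,target_role `"patient"` or `"clinician"`.
#' @param source_au,target_au AU channel index (1-20).
#' @param gain coupling gain applied to the transformed lagged source value.
#' @param lag_frames coupling lag in frames (>= 1).
#' @return one-row data frame; rbind rows to build an edge list.
#' @export
coupling_edge <- function(source_role, source_au, target_role, target_au,
                          gain, lag_frames) {
  stopifnot(source_role %in% c("patient", "clinician"),
            target_role %in% c("patient", "clinician"))
  data.frame(source_role = source_role, source_au = as.integer(source_au),
             target_role = target_role, target_au = as.integer(target_au),
             gain = as.numeric(gain), lag_frames = as.integer(lag_frames))
}

#' @rdname coupling_edge
#' @details `default_coupling_edges()` plants the canonical leader-follower
#'   pattern: patient lip suck (AU28) drives clinician eye closure (AU43)
#'   and lid tightening (AU7).
#' @export
default_coupling_edges <- function() {
  rbind(coupling_edge("patient", 18L, "clinician", 19L, gain = 1.2, lag_frames = 4L),
        coupling_edge("patient", 18L, "clinician", 6L, gain = 1.0, lag_frames = 6L))
}

# Build one session's event table: per trial rest -> anticipation ->
# stimulus -> rating, durations snapped to the frame grid so the
# n_frames = round(duration * rate) invariant is exact.
build_session_events <- function(n_runs, run_conditions, rate, rest_range,
                                 ant_range, stim_s, rating_s, ant_map,
                                 stim_map) {
  snap <- function(x) round(x * rate) / rate
  rows <- list()
  t <- 0
  for (r in seq_len(n_runs)) {
    conds <- run_conditions[[r]]
    for (tr in seq_along(conds)) {
      add <- function(d, cond) {
        rows[[length(rows) + 1L]] <<- data.frame(
          onset = t, duration = d, condition = cond,
          trial_index = tr, run_index = r)
        t <<- t + d
      }
      add(snap(stats::runif(1, rest_range[1], rest_range[2])), "rest")
      add(snap(stats::runif(1, ant_range[1], ant_range[2])), ant_map[[conds[tr]]])
      add(snap(stim_s), stim_map[[conds[tr]]])
      add(snap(rating_s), "rating")
    }
  }
  validate_event_table(do.call(rbind, rows), anticipation_bounds = ant_range)
}

treatment_session_events <- function(p) {
  # 12 trials across 2 runs: 4 verum + 4 sham (treat cue) and 4 no
  # treatment (no-treat cue), pseudorandomised within run
  per_run <- lapply(seq_len(p$n_runs), function(r) {
    sample(c(rep("treat", round(2 * p$trials_per_run / 3)),
             rep("notreat", p$trials_per_run - round(2 * p$trials_per_run / 3))))
  })
  build_session_events(p$n_runs, per_run, p$sampling_rate_hz,
                       p$rest_duration_range_s, p$block_duration_range_s,
                       p$stim_duration_s, p$rating_duration_s,
                       ant_map = list(treat = "anticipation_treat",
                                      notreat = "anticipation_notreat"),
                       stim_map = list(treat = "pain_moderate",
                                       notreat = "pain_moderate"))
}

nonlin_fun <- function(name) {
  switch(name,
         tanh = tanh,
         logistic = function(x) 1 / (1 + exp(-x)) - 0.5,
         linear = identity)
}

# Generate all 2 * n_aus channels. Nodes 1..n are patient AUs, n+1..2n
# clinician AUs. If the planted edge graph is acyclic the channels are
# generated in topological order with a vectorised recursive filter;
# otherwise a frame-by-frame loop with identical semantics is used.
simulate_channels <- function(p, n_frames_total, mask) {
  n <- p$n_aus
  nv <- 2L * n
  f <- nonlin_fun(p$nonlinearity)
  edges <- p$coupling_edges
  if (is.null(edges)) edges <- default_coupling_edges()[0, ]
  node <- function(role, au) as.integer(ifelse(role == "patient", au, n + au))
  esrc <- node(edges$source_role, edges$source_au)
  etgt <- node(edges$target_role, edges$target_au)
  E <- matrix(stats::rnorm(n_frames_total * nv, sd = p$noise_sd),
              n_frames_total, nv)
  X <- matrix(0, n_frames_total, nv)
  ord <- topo_order(nv, esrc, etgt)
  maskv <- if (p$coupling_window == "anticipation") as.numeric(mask) else 1
  if (!is.null(ord)) {
    for (v in ord) {
      u <- E[, v]
      for (e in which(etgt == v)) {
        s <- X[, esrc[e]]
        lag <- edges$lag_frames[e]
        drive <- c(rep(0, lag), f(s[seq_len(n_frames_total - lag)]))
        u <- u + edges$gain[e] * drive * maskv
      }
      X[, v] <- as.numeric(stats::filter(u, p$ar_coef, method = "recursive"))
    }
  } else {
    maskv <- rep(maskv, length.out = n_frames_total)
    for (t in seq_len(n_frames_total)) {
      x <- E[t, ] + if (t > 1) p$ar_coef * X[t - 1L, ] else 0
      for (e in seq_along(esrc)) {
        lag <- edges$lag_frames[e]
        if (t > lag) {
          x[etgt[e]] <- x[etgt[e]] +
            edges$gain[e] * f(X[t - lag, esrc[e]]) * maskv[t]
        }
      }
      X[t, ] <- x
    }
  }
  X
}

topo_order <- function(nv, esrc, etgt) {
  indeg <- tabulate(etgt, nv)
  ord <- integer(0)
  queue <- which(indeg == 0L)
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    ord <- c(ord, v)
    out <- which(esrc == v)
    for (e in out) {
      indeg[etgt[e]] <- indeg[etgt[e]] - 1L
      if (indeg[etgt[e]] == 0L) queue <- c(queue, etgt[e])
    }
  }
  if (length(ord) == nv) ord else NULL
}

anticipation_mask <- function(events, rate, n_frames_total) {
  mask <- logical(n_frames_total)
  ant <- events[grepl("^anticipation", events$condition), , drop = FALSE]
  for (b in seq_len(nrow(ant))) {
    i0 <- round(ant$onset[b] * rate)
    i1 <- round((ant$onset[b] + ant$duration[b]) * rate)
    mask[(i0 + 1L):i1] <- TRUE
  }
  mask
}

#' Generate one dyad's coupled AU streams
#'
#' Simulates the pain/treatment session for one patient-clinician dyad:
#' a pseudorandomised event table (12 anticipation blocks of 6-12 s across
#' two runs, each flanked by rest, stimulus and rating phases) and both
#' members' 20-channel AU streams. Every channel is AR(1); planted coupling
#' edges add `gain * f(source lagged by lag_frames)` to the target
#' innovation, by default only inside anticipation blocks. Output is a pure
#' function of parameters + seed.
#'
#' @param p a [dyad_sim_params()] object.
#' @param patient_id,clinician_id subject identifiers.
#' @return list with `patient` and `clinician` (`au_recording`), `events`
#'   (`event_table`) and `truth` (planted edges and the dyad's scalar
#'   coupling strength, the mean planted gain).
#' @export
generate_dyad_au <- function(p = dyad_sim_params(), patient_id = "patient",
                             clinician_id = "clinician") {
  stopifnot(inherits(p, "dyad_sim_params"))
  set.seed(p$seed)
  events <- treatment_session_events(p)
  total_s <- max(events$onset + events$duration)
  nf <- round(total_s * p$sampling_rate_hz)
  mask <- anticipation_mask(events, p$sampling_rate_hz, nf)
  X <- simulate_channels(p, nf, mask)
  edges <- p$coupling_edges
  strength <- if (!is.null(edges) && nrow(edges)) mean(edges$gain) else 0
  list(patient = au_recording(X[, seq_len(p$n_aus)], patient_id, "patient",
                              p$sampling_rate_hz),
       clinician = au_recording(X[, p$n_aus + seq_len(p$n_aus)], clinician_id,
                                "clinician", p$sampling_rate_hz),
       events = events,
       truth = list(edges = edges, coupling_strength = strength,
                    seed = p$seed))
}

#' Parameters for the pain-session generator
#'
#' @param discriminative_aus data frame with columns `au` (channel index)
#'   and `shift` (mean activation shift, in marginal sd units, during
#'   moderate-pain stimulation). Defaults plant the pain-expression
#'   signature on AU28 (lip suck), AU43 (eye closure), AU7 (lid tighten)
#'   and AU4 (brow furrow).
#' @param n_trials_per_condition trials per condition per run (protocol:
#'   3 moderate pain + 3 innocuous per run, two runs).
#' @param trial_sd between-trial variability of the planted shift.
#' @inheritParams dyad_sim_params
#' @return a list of class `pain_sim_params`.
#' @export
pain_sim_params <- function(n_aus = 20L, sampling_rate_hz = 20,
                            n_runs = 2L, n_trials_per_condition = 3L,
                            discriminative_aus = data.frame(
                              au = c(18L, 19L, 6L, 3L),
                              shift = c(1.5, 1.2, 1.0, 0.8)),
                            trial_sd = 0.3, ar_coef = 0.8, noise_sd = 0.6,
                            block_duration_range_s = c(6, 12),
                            rest_duration_range_s = c(10, 14),
                            stim_duration_s = 14, rating_duration_s = 7,
                            seed = 1L) {
  if (abs(ar_coef) >= 1) {
    stop("parameter error: |ar_coef| must be < 1 for stationarity")
  }
  if (!is.null(discriminative_aus) && nrow(discriminative_aus)) {
    if (!all(is.finite(discriminative_aus$shift))) {
      stop("parameter error: pain shifts must be finite")
    }
  }
  structure(list(n_aus = as.integer(n_aus), sampling_rate_hz = sampling_rate_hz,
                 n_runs = as.integer(n_runs),
                 n_trials_per_condition = as.integer(n_trials_per_condition),
                 discriminative_aus = discriminative_aus, trial_sd = trial_sd,
                 ar_coef = ar_coef, noise_sd = noise_sd,
                 block_duration_range_s = block_duration_range_s,
                 rest_duration_range_s = rest_duration_range_s,
                 stim_duration_s = stim_duration_s,
                 rating_duration_s = rating_duration_s,
                 seed = as.integer(seed)),
            class = "pain_sim_params")
}

#' Generate one patient's pain-MRI session
#'
#' Simulates the pain paradigm: per run, `n_trials_per_condition` moderate
#' pain and as many innocuous pressure trials in pseudorandom order. During
#' moderate-pain stimulation the discriminative AUs are shifted by their
#' planted `shift` (plus per-trial noise); all other channels are identical
#' in distribution across conditions.
#'
#' @param p a [pain_sim_params()] object.
#' @param subject_id patient identifier.
#' @return list with `patient` (`au_recording`), `events` (`event_table`)
#'   and `truth` (per-block condition labels and the planted shift table).
#' @export
generate_pain_session <- function(p = pain_sim_params(),
                                  subject_id = "patient") {
  stopifnot(inherits(p, "pain_sim_params"))
  set.seed(p$seed)
  per_run <- lapply(seq_len(p$n_runs), function(r) {
    sample(rep(c("pain", "nopain"), each = p$n_trials_per_condition))
  })
  events <- build_session_events(
    p$n_runs, per_run, p$sampling_rate_hz, p$rest_duration_range_s,
    p$block_duration_range_s, p$stim_duration_s, p$rating_duration_s,
    ant_map = list(pain = "anticipation_pain", nopain = "anticipation_nopain"),
    stim_map = list(pain = "pain_moderate", nopain = "pain_innocuous"))
  total_s <- max(events$onset + events$duration)
  nf <- round(total_s * p$sampling_rate_hz)
  X <- matrix(stats::rnorm(nf * p$n_aus, sd = p$noise_sd), nf, p$n_aus)
  X <- apply(X, 2L, function(u) {
    as.numeric(stats::filter(u, p$ar_coef, method = "recursive"))
  })
  pain_ev <- events[events$condition == "pain_moderate", , drop = FALSE]
  disc <- p$discriminative_aus
  for (b in seq_len(nrow(pain_ev))) {
    i0 <- round(pain_ev$onset[b] * p$sampling_rate_hz)
    i1 <- round((pain_ev$onset[b] + pain_ev$duration[b]) * p$sampling_rate_hz)
    rows <- (i0 + 1L):i1
    for (k in seq_len(nrow(disc))) {
      X[rows, disc$au[k]] <- X[rows, disc$au[k]] +
        disc$shift[k] + stats::rnorm(1, sd = p$trial_sd)
    }
  }
  stim <- events[events$condition %in% c("pain_moderate", "pain_innocuous"), ,
                 drop = FALSE]
  labels <- data.frame(run_index = stim$run_index,
                       trial_index = stim$trial_index,
                       condition = ifelse(stim$condition == "pain_moderate",
                                          "pain", "innocuous"))
  list(patient = au_recording(X, subject_id, "patient", p$sampling_rate_hz),
       events = events,
       truth = list(block_labels = labels, discriminative_aus = disc,
                    seed = p$seed))
}
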