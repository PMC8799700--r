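# Synthetic dyadic brain and behaviour data: trial-wise parcel beta series
# whose cross-brain coupling covaries with the dyad's facial-causality
# score, plus bounded behavioural instrument scores.

#' Parameters for the dyadic brain/behaviour generator
#'
#' @param n_parcels parcels per subject.
#' @param roi_definitions named list of disjoint parcel index sets. The
#'   planted cross-brain link connects `clinician_aIns` (clinician anterior
#'   insula) with `patient_m_pIns` (patient mid/posterior insula).
#' @param n_trials trials per subject (protocol value 12: one anticipation
#'   beta per trial across both runs).
#' @param concordance_gain slope mapping a dyad's facial-causality score to
#'   the latent cross-brain coupling before squashing.
#' @param squash squashing function keeping the implied trial-wise
#'   correlation inside (-1, 1); `"none"` errors if the raw value falls
#'   outside.
#' @param roi_noise_sd parcel-level noise sd around the shared ROI latent.
#' @param behavior_link list with `care_slope`, `negexp_slope`, `care_sd`,
#'   `negexp_sd`: behavioural scores are linear in the dyad's true
#'   cross-brain coupling plus rater noise, then clamped to instrument
#'   ranges (CARE totals 9-45 per rater; Berkeley subscales to their
#'   item-sum ranges).
#' @param emit_bold also emit raw parcel BOLD (trial boxcars convolved with
#'   the double-gamma HRF plus noise) so the beta-series stage can be
#'   exercised end to end. Default off: betas are emitted directly.
#' @param tr_s repetition time in seconds for emitted BOLD.
#' @param bold_noise_sd additive noise sd for emitted BOLD.
#' @param seed integer seed.
#' @return a list of class `brain_sim_params`.
#' @export
brain_sim_params <- function(n_parcels = 50L,
                             roi_definitions = list(
                               clinician_aIns = 1:3, patient_m_pIns = 4:6,
                               vlPFC = 7:9, TPJ = 10:12),
                             n_trials = 12L, concordance_gain = 1.0,
                             squash = c("tanh", "none"), roi_noise_sd = 0.15,
                             behavior_link = list(care_slope = 10,
                                                  negexp_slope = 18,
                                                  care_sd = 1.5, negexp_sd = 2),
                             emit_bold = FALSE, tr_s = 1.25,
                             bold_noise_sd = 0.5, seed = 1L) {
  squash <- match.arg(squash)
  idx <- unlist(roi_definitions)
  if (!length(roi_definitions) || any(idx < 1 | idx > n_parcels)) {
    stop("parameter error: ROI parcel indices out of range")
  }
  if (anyDuplicated(idx)) stop("parameter error: ROI sets must be disjoint")
  structure(list(n_parcels = as.integer(n_parcels),
                 roi_definitions = roi_definitions,
                 n_trials = as.integer(n_trials),
                 concordance_gain = concordance_gain, squash = squash,
                 roi_noise_sd = roi_noise_sd, behavior_link = behavior_link,
                 emit_bold = emit_bold, tr_s = tr_s,
                 bold_noise_sd = bold_noise_sd, seed = as.integer(seed)),
            class = "brain_sim_params")
}

#' Generate one dyad's trial beta series and behavioural scores
#'
#' The clinician's anterior-insula parcels share a per-trial latent
#' `g ~ N(0, 1)`; the patient's mid/posterior-insula parcels are generated
#' as `rho * g + sqrt(1 - rho^2) * noise` with
#' `rho = squash(concordance_gain * facial_score)`, so the planted
#' trial-wise cross-brain correlation equals `rho`. All remaining parcels
#' are independent noise. CARE (patient- and clinician-rated totals) and
#' Berkeley expressivity subscales are linear in `rho` plus noise, clamped
#' to their instrument ranges.
#'
#' @param p a [brain_sim_params()] object.
#' @param facial_score the dyad's scalar facial-causality score (finite).
#' @param dyad_id,patient_id,clinician_id identifiers.
#' @param seed integer seed (defaults to `p$seed`).
#' @return list with `patient` / `clinician` beta series, `behavior` (one
#'   row), `truth` (`rho` and generating coefficients), `events`, and -
#'   when `emit_bold` - raw `bold` matrices per member.
#' @export
generate_dyad_brain <- function(p = brain_sim_params(), facial_score,
                                dyad_id = "dyad", patient_id = "patient",
                                clinician_id = "clinician", seed = p$seed) {
  stopifnot(inherits(p, "brain_sim_params"), is.finite(facial_score))
  set.seed(seed)
  raw <- p$concordance_gain * facial_score
  rho <- switch(p$squash, tanh = tanh(raw), none = raw)
  if (abs(rho) >= 1) {
    stop("parameter error: requested trial-beta correlation outside (-1, 1)")
  }
  nt <- p$n_trials
  np <- p$n_parcels
  g <- stats::rnorm(nt)
  noise_mat <- function() matrix(stats::rnorm(np * nt), np, nt)
  cli <- noise_mat()
  pat <- noise_mat()
  for (j in p$roi_definitions$clinician_aIns) {
    cli[j, ] <- g + stats::rnorm(nt, sd = p$roi_noise_sd)
  }
  for (j in p$roi_definitions$patient_m_pIns) {
    pat[j, ] <- rho * g + sqrt(1 - rho^2) * stats::rnorm(nt)
  }
  conds <- sample(rep(c("anticipation_treat", "anticipation_notreat"),
                      times = c(round(2 * nt / 3), nt - round(2 * nt / 3))))
  runs <- rep(1:2, each = nt / 2)
  rownames(cli) <- rownames(pat) <- sprintf("parcel_%02d", seq_len(np))
  bl <- p$behavior_link
  care_p <- clamp(33 + bl$care_slope * rho + stats::rnorm(1, sd = bl$care_sd), 9, 45)
  care_c <- clamp(31 + bl$care_slope * rho + stats::rnorm(1, sd = bl$care_sd), 9, 45)
  behavior <- data.frame(
    dyad_id = dyad_id,
    care_patient = care_p, care_clinician = care_c,
    care_dyad = (care_p + care_c) / 2,
    negative_expressivity = clamp(18 + bl$negexp_slope * rho +
                                    stats::rnorm(1, sd = bl$negexp_sd), 6, 42),
    positive_expressivity = clamp(stats::rnorm(1, 18, 3), 4, 28),
    impulse_strength = clamp(stats::rnorm(1, 24, 4), 6, 42))
  out <- list(
    patient = new_beta_series(pat, conds, runs, patient_id),
    clinician = new_beta_series(cli, conds, runs, clinician_id),
    behavior = behavior,
    truth = list(rho = rho, facial_score = facial_score,
                 concordance_gain = p$concordance_gain,
                 behavior_link = bl, seed = seed))
  if (p$emit_bold) {
    ev <- bold_trial_events(nt, runs, conds, seed = derive_seed(seed, "ev"))
    n_vols <- ceiling((max(ev$onset + ev$duration) + 20) / p$tr_s)
    X <- bs_design(ev, n_vols, p$tr_s)$X
    make_bold <- function(B) {
      ant_cols <- seq_len(nt)
      mu <- X[, ant_cols, drop = FALSE] %*% t(B)
      t(mu) + matrix(stats::rnorm(np * n_vols, sd = p$bold_noise_sd), np, n_vols)
    }
    out$bold <- list(patient = make_bold(pat), clinician = make_bold(cli))
    out$events <- ev
    out$tr_s <- p$tr_s
  }
  out
}

# minimal trial timing for emitted BOLD: rest / anticipation / stimulus /
# rating per trial, anticipation durations on the 6-12 s protocol range
bold_trial_events <- function(n_trials, runs, conds, seed) {
  set.seed(seed)
  rows <- list()
  t <- 0
  per_run <- split(seq_len(n_trials), runs)
  for (r in seq_along(per_run)) {
    for (tr in seq_along(per_run[[r]])) {
      i <- per_run[[r]][tr]
      add <- function(d, cond) {
        rows[[length(rows) + 1L]] <<- data.frame(
          onset = t, duration = d, condition = cond,
          trial_index = tr, run_index = r)
        t <<- t + d
      }
      add(stats::runif(1, 10, 14), "rest")
      add(stats::runif(1, 6, 12), conds[i])
      add(14, "pain_moderate")
      add(7, "rating")
    }
  }
  validate_event_table(do.call(rbind, rows))
}
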