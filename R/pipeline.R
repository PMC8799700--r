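# End-to-end orchestration: simulate -> classify -> esgc -> infer ->
# concord, with a single global seed from which every stage, dyad and
# reservoir derives its own sub-seed, and a consolidated JSON report.

#' Build a pipeline configuration
#'
#' Returns the default configuration as a named list; override fields via
#' `...`. Unknown keys are rejected, so typos cannot silently disable a
#' stage.
#'
#' @param ... overrides for any default field: `n_dyads`, `seed`,
#'   `out_dir`, `stages` (named logical list), `au_params`, `pain_params`,
#'   `brain_params`, `reservoir`, `gain_scale_range`, `alpha`,
#'   `pseudo_cap`, `conditions`, `classifier` (list of `k`, `nrounds`,
#'   `max_depth`, `eta`, `threshold`), `source_au`, `log_level`.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    n_dyads = 6L, seed = 1L, out_dir = NULL,
    stages = list(simulate = TRUE, classify = TRUE, esgc = TRUE,
                  infer = TRUE, concord = TRUE),
    au_params = dyad_sim_params(), pain_params = pain_sim_params(),
    brain_params = brain_sim_params(), reservoir = reservoir_params(),
    gain_scale_range = c(0.4, 1.6), alpha = 0.05, pseudo_cap = 30L,
    conditions = c("anticipation_treat", "anticipation_notreat"),
    classifier = list(k = 5L, nrounds = 200L, max_depth = 3L, eta = 0.1,
                      threshold = 0.5),
    source_au = "AU28_lip_suck", log_level = "info")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    stopf("config error: unknown key(s): %s", paste(unknown, collapse = ", "))
  }
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  structure(cfg, class = "pipeline_config")
}

read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

plog <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message(sprintf(...))
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Executes the enabled stages in dependency order: `simulate` builds the
#' cohort, `classify` fits the grouped-CV pain classifier plus SHAP
#' ranking over all patients' pain sessions, `esgc` computes both directed
#' 20 x 20 causality matrices per dyad, `infer` contrasts them with the
#' pseudo-dyad empirical null (Mann-Whitney + BH-FDR) and extracts the AU28
#' row score, and `concord` regresses patient-parcel cross-brain
#' concordance on that score and correlates dyad-level insula concordance
#' with CARE and negative expressivity. A stage whose inputs were not
#' produced raises a dependency error naming the stage.
#'
#' @param config a [pipeline_config()], or a path to a YAML/JSON file with
#'   the same fields.
#' @return an object of class `pipeline_report`; if `out_dir` is set, the
#'   report (JSON), per-dyad matrices (CSV) and the config echo are also
#'   written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- config$stages
  report <- list(seed = config$seed, stages_run = names(which(unlist(stages))),
                 timing_s = list())
  t_stage <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    v <- force(expr)
    list(value = v, elapsed = proc.time()[["elapsed"]] - t0)
  }
  if (!isTRUE(stages$simulate)) {
    stop("dependency error: stage `simulate` must be enabled (no external cohort support)")
  }
  plog(config, "simulate: %d dyads (seed %d)", config$n_dyads, config$seed)
  st <- t_stage(simulate_cohort(config$n_dyads, config$au_params,
                                config$pain_params, config$brain_params,
                                config$gain_scale_range, config$seed))
  cohort <- st$value
  report$timing_s$simulate <- st$elapsed

  if (isTRUE(stages$classify)) {
    if (is.null(config$pain_params)) {
      stop("dependency error: stage `classify` needs pain sessions (pain_params is NULL)")
    }
    plog(config, "classify: grouped-CV XGBoost over %d patients", config$n_dyads)
    st <- t_stage({
      frames <- do.call(rbind, lapply(cohort$dyads, function(e) {
        assemble_frames(e$pain$patient, e$pain$events)
      }))
      rownames(frames) <- NULL
      class(frames) <- c("frame_table", "data.frame")
      cl <- config$classifier
      fit <- pain_classifier(frames, k = cl$k, nrounds = cl$nrounds,
                             max_depth = cl$max_depth, eta = cl$eta,
                             threshold = cl$threshold,
                             seed = derive_seed(config$seed, "classify"))
      list(fit = fit, shap = rank_shap(fit, frames))
    })
    report$timing_s$classify <- st$elapsed
    report$classifier <- list(
      auc = st$value$fit$auc, precision = st$value$fit$precision,
      recall = st$value$fit$recall, cv_scheme = st$value$fit$cv_scheme,
      threshold = st$value$fit$threshold,
      shap_ranking = st$value$shap)
    classifier_fit <- st$value
  }

  gc_real <- NULL
  if (isTRUE(stages$esgc)) {
    plog(config, "esgc: 2 x %d real-dyad matrices", config$n_dyads)
    rp <- config$reservoir
    rp$seed <- derive_seed(config$seed, "esgc")
    st <- t_stage(list(
      p2c = cohort_gc_matrices(cohort, cohort$roster, "patient_to_clinician",
                               rp, config$conditions),
      c2p = cohort_gc_matrices(cohort, cohort$roster, "clinician_to_patient",
                               rp, config$conditions)))
    gc_real <- st$value
    report$timing_s$esgc <- st$elapsed
    report$esgc <- list(
      n_matrices = 2L * config$n_dyads,
      median_gc_p2c = stats::median(vapply(gc_real$p2c, function(m)
        stats::median(m$values, na.rm = TRUE), 0)))
  }

  links <- NULL
  if (isTRUE(stages$infer)) {
    if (is.null(gc_real)) {
      stop("dependency error: stage `infer` requires stage `esgc`")
    }
    plog(config, "infer: pseudo-dyad null (cap %d) + Mann-Whitney + BH-FDR",
         config$pseudo_cap)
    rp <- config$reservoir
    rp$seed <- derive_seed(config$seed, "esgc")
    st <- t_stage({
      pseudo <- enumerate_pseudo_dyads(cohort$roster, cap = config$pseudo_cap,
                                       seed = derive_seed(config$seed, "infer"))
      null_p2c <- cohort_gc_matrices(cohort, pseudo, "patient_to_clinician",
                                     rp, config$conditions)
      null_c2p <- cohort_gc_matrices(cohort, pseudo, "clinician_to_patient",
                                     rp, config$conditions)
      sig_p2c <- gc_group_test(gc_real$p2c, null_p2c, alpha = config$alpha)
      sig_c2p <- gc_group_test(gc_real$c2p, null_c2p, alpha = config$alpha)
      list(pseudo = pseudo, sig_p2c = sig_p2c, sig_c2p = sig_c2p,
           links = summarize_links(sig_p2c, sig_c2p, gc_real$p2c,
                                   source_au = config$source_au))
    })
    links <- st$value$links
    sig <- st$value
    report$timing_s$infer <- st$elapsed
    report$inference <- list(
      n_pseudo = nrow(st$value$pseudo),
      n_links_patient_to_clinician = links$n_links_patient_to_clinician,
      n_links_clinician_to_patient = links$n_links_clinician_to_patient,
      au_row_score = as.list(links$au_row_score))
  }

  if (isTRUE(stages$concord)) {
    if (is.null(links)) {
      stop("dependency error: stage `concord` requires stage `infer` (AU28 score)")
    }
    if (is.null(config$brain_params)) {
      stop("dependency error: stage `concord` needs trial betas (brain_params is NULL)")
    }
    plog(config, "concord: cross-brain regression on the %s score",
         config$source_au)
    st <- t_stage({
      rois <- config$brain_params$roi_definitions
      coeffs <- t(vapply(cohort$dyads, function(e) {
        pv <- partner_roi_vector(e$brain$clinician, rois$clinician_aIns)
        dyad_concordance(e$brain$patient, pv)
      }, numeric(config$brain_params$n_parcels)))
      score <- links$au_row_score[cohort$roster$dyad_id]
      grp <- group_regression(coeffs, score, alpha = config$alpha)
      scalar <- vapply(cohort$dyads, function(e) {
        pv <- partner_roi_vector(e$brain$clinician, rois$clinician_aIns)
        ov <- partner_roi_vector(e$brain$patient, rois$patient_m_pIns)
        stats::cor(pv, ov)
      }, 0)
      list(grp = grp, scalar = scalar,
           care = behavior_correlation(scalar, cohort$behavior$care_dyad),
           negexp = behavior_correlation(scalar,
                                         cohort$behavior$negative_expressivity))
    })
    report$timing_s$concord <- st$elapsed
    report$concordance <- list(
      n_significant_parcels = sum(st$value$grp$table$significant),
      significant_parcels = st$value$grp$table$parcel[st$value$grp$table$significant],
      care = unclass(st$value$care), negexp = unclass(st$value$negexp))
    concord_fit <- st$value
  }

  report$config <- config_echo(config)
  out <- structure(list(report = report, cohort = cohort,
                        classifier = if (exists("classifier_fit", inherits = FALSE)) classifier_fit,
                        gc = gc_real,
                        inference = if (!is.null(links)) sig,
                        concordance = if (exists("concord_fit", inherits = FALSE)) concord_fit),
                   class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    if (!is.null(gc_real)) {
      for (m in c(gc_real$p2c, gc_real$c2p)) {
        write_gc_values(m, file.path(config$out_dir,
                                     sprintf("gc_%s_%s.csv", m$dyad_id, m$direction)))
      }
    }
  }
  out
}

config_echo <- function(config) {
  e <- unclass(config)
  e$au_params <- unclass(e$au_params)
  e$pain_params <- if (!is.null(e$pain_params)) unclass(e$pain_params)
  if (!is.null(e$brain_params)) {
    bp <- unclass(e$brain_params)
    bp$roi_definitions <- lapply(bp$roi_definitions, as.integer)
    e$brain_params <- bp
  }
  e$reservoir <- unclass(e$reservoir)
  e
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pipeline_report> seed %d; stages: %s\n", r$seed,
              paste(r$stages_run, collapse = ", ")))
  if (!is.null(r$classifier)) {
    cat(sprintf("  classifier: AUC %.3f, precision %.3f, recall %.3f\n",
                r$classifier$auc, r$classifier$precision, r$classifier$recall))
  }
  if (!is.null(r$inference)) {
    cat(sprintf("  links: %d patient->clinician, %d clinician->patient (of 400 each)\n",
                r$inference$n_links_patient_to_clinician,
                r$inference$n_links_clinician_to_patient))
  }
  if (!is.null(r$concordance)) {
    cat(sprintf("  concordance: %d significant parcels; CARE r %.3f (p %.3g); neg. expressivity r %.3f (p %.3g)\n",
                r$concordance$n_significant_parcels, r$concordance$care$r,
                r$concordance$care$p, r$concordance$negexp$r,
                r$concordance$negexp$p))
  }
  invisible(x)
}
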