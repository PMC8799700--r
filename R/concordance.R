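# Trial-wise beta-series estimation and cross-brain concordance analysis:
# per-parcel GLM betas for each anticipation trial, regression of one
# partner's trial betas on the other's ROI trial vector, a group-level
# regression against the facial-causality score, and behavioural
# correlations. Parcel-level OLS with BH-FDR across parcels plays the
# inferential role of a voxelwise mixed-effects map with cluster
# correction, at desk scale.

#' Canonical double-gamma haemodynamic response function
#'
#' `h(t) = dgamma(t; 6, 1) - dgamma(t; 16, 1) / 6`, peak normalised to 1.
#'
#' @param t time in seconds (>= 0; negative times return 0).
#' @param peak_shape,undershoot_shape gamma shape parameters (rate 1).
#' @param undershoot_ratio relative undershoot amplitude.
#' @return numeric vector of HRF values.
#' @export
double_gamma_hrf <- function(t, peak_shape = 6, undershoot_shape = 16,
                             undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_shape, rate = 1)
  h[t < 0] <- 0
  h / max(h)
}

new_beta_series <- function(betas, trial_conditions, trial_runs, subject_id) {
  betas <- as.matrix(betas)
  if (!all(is.finite(betas))) stop("data error: non-finite trial betas")
  colnames(betas) <- sprintf("trial_%02d", seq_len(ncol(betas)))
  structure(list(subject_id = as.character(subject_id), betas = betas,
                 trial_conditions = trial_conditions,
                 trial_runs = trial_runs),
            class = "beta_series")
}

#' @export
print.beta_series <- function(x, ...) {
  cat(sprintf("<beta_series> %s: %d parcels x %d trials\n", x$subject_id,
              nrow(x$betas), ncol(x$betas)))
  invisible(x)
}

# Design matrix: one boxcar-convolved-HRF regressor per anticipation trial,
# pooled pain and rating nuisance regressors, and an intercept.
bs_design <- function(events, n_vols, tr_s, dt = 0.1) {
  end_s <- n_vols * tr_s
  grid <- seq(0, end_s + 32, by = dt)
  kern <- double_gamma_hrf(seq(0, 32, by = dt))
  scan_t <- (seq_len(n_vols) - 1) * tr_s
  reg <- function(ev) {
    box <- numeric(length(grid))
    for (i in seq_len(nrow(ev))) {
      box <- box + as.numeric(grid >= ev$onset[i] &
                                grid < ev$onset[i] + ev$duration[i])
    }
    v <- stats::convolve(box, rev(kern), type = "open")[seq_along(grid)] * dt
    stats::approx(grid, v, xout = scan_t)$y
  }
  ant <- events[grepl("^anticipation", events$condition), , drop = FALSE]
  ant <- ant[order(ant$run_index, ant$onset), , drop = FALSE]
  if (nrow(ant) == 0L) stop("empty-input error: no anticipation events")
  X <- vapply(seq_len(nrow(ant)), function(i) reg(ant[i, , drop = FALSE]),
              numeric(n_vols))
  colnames(X) <- sprintf("trial_%02d", seq_len(nrow(ant)))
  nuis <- NULL
  pain <- events[events$condition %in% c("pain_moderate", "pain_innocuous"), ,
                 drop = FALSE]
  if (nrow(pain)) nuis <- cbind(nuis, pain = reg(pain))
  rating <- events[events$condition == "rating", , drop = FALSE]
  if (nrow(rating)) nuis <- cbind(nuis, rating = reg(rating))
  X <- cbind(X, nuis, intercept = 1)
  list(X = X, ant = ant, n_trials = nrow(ant))
}

#' Estimate a trial-wise beta series from parcel BOLD
#'
#' Ordinary-least-squares GLM per parcel with one regressor of interest per
#' anticipation trial (boxcar convolved with the double-gamma HRF) plus
#' pooled pain and rating nuisance regressors and an intercept. For the
#' pain/treatment protocol (two runs of six trials) this yields 12 trial
#' betas per parcel.
#'
#' @param bold numeric matrix, parcels x volumes.
#' @param events the session `event_table` (onsets relative to scan start).
#' @param tr_s repetition time in seconds.
#' @param subject_id subject identifier.
#' @return a `beta_series` (parcels x trials matrix with per-trial
#'   condition and run labels).
#' @export
beta_series <- function(bold, events, tr_s = 1.25, subject_id = "subject") {
  bold <- as.matrix(bold)
  d <- bs_design(events, ncol(bold), tr_s)
  qrX <- qr(d$X)
  if (qrX$rank < ncol(d$X)) {
    dropped <- colnames(d$X)[qrX$pivot[(qrX$rank + 1L):ncol(d$X)]]
    stopf("design error: rank-deficient design; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  fit <- stats::lm.fit(d$X, t(bold))
  co <- fit$coefficients
  betas <- t(co[seq_len(d$n_trials), , drop = FALSE])
  if (!is.null(rownames(bold))) rownames(betas) <- rownames(bold)
  new_beta_series(betas, d$ant$condition, d$ant$run_index, subject_id)
}

#' Define a region of interest as a parcel index set
#' @param name ROI name (e.g. `"clinician_aIns"`).
#' @param parcels integer parcel indices (non-empty).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(name, parcels) {
  parcels <- as.integer(parcels)
  if (!length(parcels)) stop("ROI error: empty parcel set")
  structure(list(name = name, parcels = parcels), class = "roi_spec")
}

#' Partner ROI trial vector
#'
#' Per-trial mean beta over the ROI parcels, z-scored across trials. A
#' zero-variance mean series is returned as an all-`NA` vector flagged
#' degenerate.
#'
#' @param bs a `beta_series`.
#' @param roi an [roi_spec()] (or integer parcel indices).
#' @return z-scored numeric trial vector (possibly flagged `degenerate`).
#' @export
partner_roi_vector <- function(bs, roi) {
  stopifnot(inherits(bs, "beta_series"))
  parcels <- if (inherits(roi, "roi_spec")) roi$parcels else as.integer(roi)
  if (!length(parcels) || any(parcels < 1 | parcels > nrow(bs$betas))) {
    stop("ROI error: parcel indices outside the beta matrix")
  }
  v <- colMeans(bs$betas[parcels, , drop = FALSE])
  zscore(v)
}

#' Per-parcel cross-brain concordance coefficients
#'
#' For every parcel, the standardised slope of the subject's own z-scored
#' trial betas regressed on the partner's ROI trial vector - which equals
#' the Pearson correlation across trials. Zero-variance parcels yield `NA`.
#'
#' @param own the subject's `beta_series`.
#' @param partner_vec the partner's z-scored ROI trial vector from
#'   [partner_roi_vector()].
#' @return named numeric vector of per-parcel coefficients.
#' @export
dyad_concordance <- function(own, partner_vec) {
  stopifnot(inherits(own, "beta_series"))
  if (is_degenerate(partner_vec) || any(!is.finite(partner_vec))) {
    stop("degenerate error: partner ROI vector has zero variance")
  }
  if (length(partner_vec) != ncol(own$betas)) {
    stop("data error: partner vector length does not match trial count")
  }
  zx <- partner_vec
  sxx <- sum(zx^2)
  out <- apply(own$betas, 1L, function(y) {
    zy <- zscore(y)
    if (is_degenerate(zy)) return(NA_real_)
    sum(zx * zy) / sxx
  })
  out
}

#' Group regression of concordance on the facial-causality score
#'
#' Per parcel, OLS of the per-dyad concordance coefficients on the z-scored
#' between-dyad regressor (the patient AU28 -> clinician causality score),
#' with two-sided t tests and Benjamini-Hochberg FDR across parcels.
#'
#' @param coeffs numeric matrix, dyads x parcels, of concordance
#'   coefficients.
#' @param score per-dyad regressor (length `nrow(coeffs)`, variance > 0).
#' @param alpha FDR level.
#' @return object of class `concordance_group` with a per-parcel table
#'   (`slope`, `t`, `p`, `q`, `significant`).
#' @export
group_regression <- function(coeffs, score, alpha = 0.05) {
  coeffs <- as.matrix(coeffs)
  n <- nrow(coeffs)
  if (n < 3) stop("insufficient-data error: need >= 3 dyads")
  if (length(score) != n) stop("data error: regressor length mismatch")
  z <- zscore(score)
  if (is_degenerate(z)) stop("degenerate-regressor error: score has zero variance")
  X <- cbind(1, z)
  res <- apply(coeffs, 2L, function(y) {
    ok <- is.finite(y)
    if (sum(ok) < 3) return(c(NA, NA, NA))
    fit <- stats::lm.fit(X[ok, , drop = FALSE], y[ok])
    df <- sum(ok) - 2L
    s2 <- sum(fit$residuals^2) / df
    xtx_inv <- chol2inv(chol(crossprod(X[ok, , drop = FALSE])))
    se <- sqrt(s2 * xtx_inv[2L, 2L])
    tval <- fit$coefficients[2L] / se
    c(fit$coefficients[2L], tval, 2 * stats::pt(-abs(tval), df))
  })
  tab <- data.frame(parcel = colnames(coeffs) %||%
                      sprintf("parcel_%02d", seq_len(ncol(coeffs))),
                    slope = res[1L, ], t = res[2L, ], p = res[3L, ])
  tab$q <- stats::p.adjust(tab$p, method = "BH")
  tab$significant <- !is.na(tab$q) & tab$q <= alpha
  structure(list(table = tab, alpha = alpha, n_dyads = n),
            class = "concordance_group")
}

#' @export
print.concordance_group <- function(x, ...) {
  sig <- x$table[x$table$significant, ]
  cat(sprintf("<concordance_group> %d dyads, %d parcels; %d significant at FDR %g\n",
              x$n_dyads, nrow(x$table), nrow(sig), x$alpha))
  if (nrow(sig)) print(utils::head(sig[order(sig$p), ], 10), row.names = FALSE)
  invisible(x)
}

#' Correlate dyad-level concordance with a behavioural score
#'
#' Pearson correlation with a two-sided t-based p value. The CARE dyad
#' score is conventionally the mean of the patient-rated and
#' clinician-rated totals.
#'
#' @param concordance per-dyad scalar concordance for a named ROI pair.
#' @param scores per-dyad behavioural scores (same length, n >= 3).
#' @return list of class `behavior_cor` with `r`, `p`, `n`.
#' @export
behavior_correlation <- function(concordance, scores) {
  ok <- is.finite(concordance) & is.finite(scores)
  x <- concordance[ok]
  y <- scores[ok]
  if (length(x) < 3) stop("insufficient-data error: need >= 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("degenerate error: zero variance in a behavioural correlation input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "behavior_cor")
}

#' @export
print.behavior_cor <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.4g (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}
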