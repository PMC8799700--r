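# Echo-state Granger causality (ESGC).
#
# A directed causality strength F(source -> target) is the log ratio of
# held-out prediction errors of two echo-state models of the target's next
# frame: a restricted model driven by the target's own past only, and a
# full model driven jointly by target and source. Readouts are linear,
# ridge-regularised, and assessed by leave-one-block-out cross-validation
# over the (nonconsecutive) anticipation blocks, so nonlinear readout
# overfitting does not inflate the statistic. Estimates are averaged over
# several independent reservoir realisations and may be negative; negative
# values are retained so the pseudo-dyad null stays unbiased for rank-based
# inference.

#' Echo-state reservoir parameters
#'
#' @param n_units reservoir size.
#' @param spectral_radius spectral radius the recurrent weight matrix is
#'   rescaled to (< 1, enforcing the echo-state property).
#' @param input_scale scale of the uniform input weights.
#' @param input_bias scale of the per-unit constant bias inside the tanh
#'   activation. A nonzero bias breaks the odd symmetry of the tanh
#'   reservoir, without which even-order nonlinear couplings (e.g. a
#'   squared lagged source) are invisible to the readout.
#' @param leak_rate leaky-integrator rate in `[0, 1]`.
#' @param ridge_lambda ridge penalty on the linear readout (the intercept
#'   is not penalised).
#' @param washout_frames states discarded at the start of every block.
#' @param n_reservoirs independent reservoir realisations averaged.
#' @param seed integer seed; reservoir weights are a pure function of
#'   seed + realisation index.
#' @return a list of class `reservoir_params`.
#' @export
reservoir_params <- function(n_units = 100L, spectral_radius = 0.9,
                             input_scale = 1.0, input_bias = 0.5,
                             leak_rate = 0.3, ridge_lambda = 1e-2,
                             washout_frames = 10L, n_reservoirs = 5L,
                             seed = 1L) {
  if (spectral_radius <= 0 || spectral_radius >= 1) {
    stop("parameter error: spectral_radius must lie in (0, 1)")
  }
  if (leak_rate < 0 || leak_rate > 1) {
    stop("parameter error: leak_rate must lie in [0, 1]")
  }
  if (ridge_lambda < 0) stop("parameter error: ridge_lambda must be >= 0")
  structure(list(n_units = as.integer(n_units),
                 spectral_radius = spectral_radius,
                 input_scale = input_scale, input_bias = input_bias,
                 leak_rate = leak_rate, ridge_lambda = ridge_lambda,
                 washout_frames = as.integer(washout_frames),
                 n_reservoirs = as.integer(n_reservoirs),
                 seed = as.integer(seed)),
            class = "reservoir_params")
}

# Recurrent weights are shared between the restricted and full models of a
# reservoir realisation (variance reduction); input weights are drawn
# independently for each input dimensionality.
esn_weights <- function(p, reservoir_index) {
  set.seed(derive_seed(p$seed, "esn-weights", reservoir_index))
  W <- matrix(stats::rnorm(p$n_units^2), p$n_units, p$n_units)
  sr <- max(Mod(eigen(W, only.values = TRUE)$values))
  W <- W * (p$spectral_radius / sr)
  win1 <- matrix(stats::runif(p$n_units, -1, 1) * p$input_scale, ncol = 1)
  win2 <- matrix(stats::runif(p$n_units * 2, -1, 1) * p$input_scale, ncol = 2)
  bias <- stats::runif(p$n_units, -1, 1) * p$input_bias
  list(W = W, win1 = win1, win2 = win2, bias = bias)
}

#' Run an echo-state reservoir over an input series
#'
#' `s_t = (1 - leak) s_{t-1} + leak tanh(W s_{t-1} + W_in u_t + b)` with
#' zero initial state; `b` is the per-unit input bias (see
#' [reservoir_params()]). The state is reset at every block start, so
#' states of a block never depend on other blocks. Deterministic given
#' seed + reservoir index.
#'
#' @param u input series: numeric vector or frames x d matrix with
#'   d in \{1, 2\}.
#' @param p a [reservoir_params()] object.
#' @param reservoir_index which reservoir realisation to use.
#' @return frames x `n_units` state matrix.
#' @export
esn_states <- function(u, p = reservoir_params(), reservoir_index = 1L) {
  u <- as.matrix(u)
  if (!ncol(u) %in% 1:2) stop("input dimensionality must be 1 or 2")
  if (!all(is.finite(u))) stop("data error: non-finite input values")
  w <- esn_weights(p, reservoir_index)
  win <- if (ncol(u) == 1L) w$win1 else w$win2
  .esn_states_cpp(u, w$W, win, w$bias, p$leak_rate)
}

# z-score a per-block series list using statistics pooled over all blocks;
# returns NULL for zero-variance series (flagged-missing downstream)
zscore_blocks <- function(blocks) {
  all <- unlist(blocks, use.names = FALSE)
  s <- stats::sd(all)
  if (!is.finite(s) || s == 0) return(NULL)
  m <- mean(all)
  lapply(blocks, function(x) (x - m) / s)
}

check_blocks <- function(source, target, p) {
  if (is.numeric(source)) source <- list(source)
  if (is.numeric(target)) target <- list(target)
  if (length(source) != length(target)) {
    stop("alignment error: source and target block counts differ")
  }
  if (length(target) < 2L) {
    stop("bounds error: leave-one-block-out needs at least 2 blocks")
  }
  len_s <- lengths(source)
  len_t <- lengths(target)
  if (!all(len_s == len_t)) {
    stop("alignment error: source and target blocks have unequal lengths")
  }
  if (any(len_t < p$washout_frames + 3L)) {
    stop("bounds error: every block must be longer than washout + 2 frames")
  }
  list(source = source, target = target)
}

cv_mse <- function(inputs, targets, w, win, p) {
  .esgc_cv_mse_cpp(inputs, targets, w$W, win, w$bias, p$leak_rate,
                   p$ridge_lambda, p$washout_frames)
}

esgc_from_series <- function(src_z, tgt_z, weights, p) {
  restricted <- lapply(tgt_z, function(x) matrix(x, ncol = 1))
  full <- Map(function(tg, sr) cbind(tg, sr), tgt_z, src_z)
  per <- vapply(seq_len(p$n_reservoirs), function(r) {
    w <- weights[[r]]
    mr <- cv_mse(restricted, tgt_z, w, w$win1, p)
    mf <- cv_mse(full, tgt_z, w, w$win2, p)
    c(gc = log(mr[1] / mf[1]), mse_r = mr[1], mse_f = mf[1], n = mr[2])
  }, numeric(4))
  list(gc = mean(per["gc", ]), mse_restricted = mean(per["mse_r", ]),
       mse_full = mean(per["mse_f", ]), n_frames_used = per["n", 1L],
       per_reservoir = per["gc", ])
}

#' Echo-state Granger causality between two block-structured series
#'
#' Fits the restricted (target-only) and full (target + source) echo-state
#' models and returns the log ratio of their pooled leave-one-block-out
#' held-out MSEs, averaged over `n_reservoirs` reservoir realisations.
#' Both series are z-scored with pooled all-block statistics, making the
#' estimate exactly invariant to positive rescaling of either input.
#' A zero-variance source or target yields a flagged-missing estimate.
#'
#' @param source,target per-block series: lists of equal-length numeric
#'   vectors (one entry per block), time-aligned across members.
#' @param p a [reservoir_params()] object.
#' @return an object of class `esgc` with `gc_strength`
#'   (`= log(mse_restricted / mse_full)`, not clipped), the pooled MSEs,
#'   `n_frames_used` and per-reservoir estimates.
#' @examples
#' set.seed(1)
#' blocks <- replicate(4, rnorm(80), simplify = FALSE)
#' target <- lapply(blocks, function(x) 0.8 * c(0, x[-length(x)]) + rnorm(80))
#' esgc(blocks, target, reservoir_params(n_units = 20, n_reservoirs = 2))
#' @export
esgc <- function(source, target, p = reservoir_params()) {
  bl <- check_blocks(source, target, p)
  src_z <- zscore_blocks(bl$source)
  tgt_z <- zscore_blocks(bl$target)
  if (is.null(src_z) || is.null(tgt_z)) {
    return(structure(list(gc_strength = NA_real_, mse_restricted = NA_real_,
                          mse_full = NA_real_, n_frames_used = 0L,
                          per_reservoir = rep(NA_real_, p$n_reservoirs),
                          flag = "zero_variance", params = p),
                     class = "esgc"))
  }
  weights <- lapply(seq_len(p$n_reservoirs), function(r) esn_weights(p, r))
  est <- esgc_from_series(src_z, tgt_z, weights, p)
  structure(list(gc_strength = est$gc, mse_restricted = est$mse_restricted,
                 mse_full = est$mse_full, n_frames_used = est$n_frames_used,
                 per_reservoir = est$per_reservoir, flag = NULL, params = p),
            class = "esgc")
}

#' @export
print.esgc <- function(x, ...) {
  if (!is.null(x$flag)) {
    cat(sprintf("<esgc> flagged missing (%s)\n", x$flag))
    return(invisible(x))
  }
  cat(sprintf("<esgc> gc_strength = %.4f (held-out MSE restricted %.4f / full %.4f, %d frames, %d reservoirs)\n",
              x$gc_strength, x$mse_restricted, x$mse_full,
              as.integer(x$n_frames_used), length(x$per_reservoir)))
  invisible(x)
}

#' Directed 20 x 20 ESGC matrix for one dyad
#'
#' Entry `(i, j)` is the bivariate ESGC strength from AU `i` of the source
#' member to AU `j` of the target member, giving 400 estimates per
#' direction. Reservoir realisations are shared across cells (restricted
#' models are fitted once per target channel), and the whole matrix is
#' deterministic given the reservoir seed.
#'
#' @param blocks list of `block_series` for one dyad and paradigm (from
#'   [segment_blocks()]).
#' @param direction `"patient_to_clinician"` or `"clinician_to_patient"`.
#' @param p a [reservoir_params()] object.
#' @param paradigm label stored on the result (e.g. `"anticipation"`).
#' @return an object of class `gc_matrix` with a labelled 20 x 20 `values`
#'   matrix (source AU in rows, target AU in columns); zero-variance
#'   channels yield `NA` rows/columns.
#' @export
esgc_matrix <- function(blocks, direction = c("patient_to_clinician",
                                              "clinician_to_patient"),
                        p = reservoir_params(), paradigm = "anticipation") {
  direction <- match.arg(direction)
  if (!length(blocks)) stop("empty-input error: no blocks supplied")
  stopifnot(all(vapply(blocks, inherits, TRUE, "block_series")))
  src_member <- if (direction == "patient_to_clinician") "patient_segment" else "clinician_segment"
  tgt_member <- if (direction == "patient_to_clinician") "clinician_segment" else "patient_segment"
  S <- lapply(blocks, `[[`, src_member)
  Tg <- lapply(blocks, `[[`, tgt_member)
  labels <- colnames(S[[1L]]) %||% default_au_labels()
  nau <- length(labels)
  lens <- vapply(Tg, nrow, 0L)
  if (any(lens < p$washout_frames + 3L)) {
    stop("bounds error: every block must be longer than washout + 2 frames")
  }
  if (length(blocks) < 2L) {
    stop("bounds error: leave-one-block-out needs at least 2 blocks")
  }
  # standardise every channel with pooled all-block statistics; flag
  # zero-variance channels and zero-fill them so the grid call can skip them
  standardise_member <- function(mats) {
    ok <- logical(nau)
    out <- lapply(mats, function(m) m)
    for (ch in seq_len(nau)) {
      z <- zscore_blocks(lapply(mats, function(m) m[, ch]))
      ok[ch] <- !is.null(z)
      for (b in seq_along(out)) {
        out[[b]][, ch] <- if (ok[ch]) z[[b]] else 0
      }
    }
    list(blocks = out, ok = ok)
  }
  src <- standardise_member(S)
  tgt <- standardise_member(Tg)
  acc <- matrix(0, nau, nau)
  for (r in seq_len(p$n_reservoirs)) {
    w <- esn_weights(p, r)
    grid <- .esgc_grid_cpp(src$blocks, tgt$blocks, w$W, w$win1, w$win2,
                           w$bias, p$leak_rate, p$ridge_lambda,
                           p$washout_frames, src$ok, tgt$ok)
    acc <- acc + log(matrix(grid$mse_restricted, nau, nau, byrow = TRUE) /
                       grid$mse_full)
  }
  vals <- acc / p$n_reservoirs
  dimnames(vals) <- list(labels, labels)
  structure(list(values = vals, dyad_id = blocks[[1L]]$dyad_id,
                 direction = direction, paradigm = paradigm,
                 n_blocks = length(blocks), params = p),
            class = "gc_matrix")
}

#' @export
print.gc_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<gc_matrix> %s, %s (%s paradigm): %d x %d, %d blocks\n",
              x$dyad_id %||% "dyad", gsub("_", " ", x$direction), x$paradigm,
              nrow(v), ncol(v), x$n_blocks))
  cat(sprintf("  gc_strength: median %.4f, max %.4f at [%s -> %s], %d missing\n",
              stats::median(v, na.rm = TRUE), max(v, na.rm = TRUE),
              rownames(v)[which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1L, 1L]],
              colnames(v)[which(v == max(v, na.rm = TRUE), arr.ind = TRUE)[1L, 2L]],
              sum(is.na(v))))
  invisible(x)
}

#' @export
plot.gc_matrix <- function(x, main = NULL, ...) {
  v <- x$values
  graphics::image(seq_len(ncol(v)), seq_len(nrow(v)), t(v)[, rev(seq_len(nrow(v)))],
                  axes = FALSE, xlab = "target AU", ylab = "source AU",
                  main = main %||% sprintf("%s (%s)", gsub("_", " ", x$direction),
                                           x$paradigm), ...)
  graphics::axis(1, seq_len(ncol(v)), sub("_.*", "", colnames(v)), las = 2,
                 cex.axis = 0.6)
  graphics::axis(2, seq_len(nrow(v)), sub("_.*", "", rev(rownames(v))), las = 2,
                 cex.axis = 0.6)
  invisible(x)
}

#' Classical linear Granger causality (validation reference)
#'
#' Log ratio of the residual variance of an AR(p) model of the target alone
#' to that of the model augmented with the source's lags, fitted by OLS.
#' Used as an independent linear oracle against which the echo-state
#' estimator is validated.
#'
#' @param source,target numeric series of equal length.
#' @param order AR model order p.
#' @return log variance-ratio Granger causality (a single number).
#' @export
linear_gc <- function(source, target, order = 1L) {
  n <- length(target)
  stopifnot(length(source) == n, order >= 1L)
  if (n < 5L * order + 5L) stop("bounds error: series too short for the model order")
  idx <- (order + 1L):n
  lagmat <- function(x) {
    vapply(seq_len(order), function(l) x[idx - l], numeric(length(idx)))
  }
  y <- target[idx]
  Xr <- cbind(1, lagmat(target))
  Xf <- cbind(Xr, lagmat(source))
  if (qr(Xf)$rank < ncol(Xf)) stop("numeric error: singular design")
  rss <- function(X) sum(stats::lm.fit(X, y)$residuals^2)
  log(rss(Xr) / rss(Xf))
}
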