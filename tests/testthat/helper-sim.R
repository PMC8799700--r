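# shared helpers: small parameter presets and oracle implementations used
# across test files

# reservoir small enough for grid-scale experiments
tiny_reservoir <- function(n_units = 15L, ...) {
  reservoir_params(n_units = n_units, n_reservoirs = 1L, seed = 7L, ...)
}

# session timing compressed outside the anticipation blocks (the blocks
# themselves keep the 6-12 s protocol range)
fast_au_params <- function(...) {
  dyad_sim_params(rest_duration_range_s = c(2, 3), stim_duration_s = 2,
                  rating_duration_s = 1, ...)
}

fast_pain_params <- function(...) {
  pain_sim_params(rest_duration_range_s = c(2, 3), rating_duration_s = 1, ...)
}

# blockwise VAR(1) driver: y_t = coupling * x_{t-1} + e_t
var_blocks <- function(n_blocks, n_frames, coupling = 0.8, seed = 1) {
  set.seed(seed)
  x <- replicate(n_blocks, rnorm(n_frames), simplify = FALSE)
  y <- lapply(x, function(v) {
    coupling * c(0, v[-n_frames]) + rnorm(n_frames)
  })
  list(x = x, y = y)
}

# brute-force one-sided Mann-Whitney p by enumerating all rank subsets:
# p = P(rank sum of the first sample >= observed) under exchangeability
exact_mw_p <- function(real, null) {
  k <- length(real)
  pooled <- c(real, null)
  r <- rank(pooled)
  obs <- sum(r[seq_len(k)])
  subsets <- utils::combn(length(pooled), k)
  sums <- colSums(matrix(r[subsets], nrow = k))
  mean(sums >= obs)
}

# brute-force Benjamini-Hochberg step-up significance decision
bh_oracle <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  k <- which(p[o] <= alpha * seq_len(m) / m)
  sig <- logical(m)
  if (length(k)) sig[o[seq_len(max(k))]] <- TRUE
  sig
}

# standard ROI layout used by the brain generator defaults
default_rois <- function() brain_sim_params()$roi_definitions
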