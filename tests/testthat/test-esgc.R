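# Echo-state network states, pairwise ESGC and the linear GC reference

test_that("reservoir states honour the update equation's fixed points", {
  p0 <- reservoir_params(n_units = 12, input_bias = 0, seed = 2)
  z <- matrix(0, 50, 1)
  expect_equal(esn_states(z, p0), matrix(0, 50, 12))
  # leak 0 freezes the state at its (zero) initial value for any input
  pl <- reservoir_params(n_units = 12, leak_rate = 0, seed = 2)
  expect_equal(esn_states(matrix(rnorm(50), 50, 1), pl), matrix(0, 50, 12))
  u <- matrix(rnorm(100), 50, 2)
  p <- reservoir_params(n_units = 12, seed = 2)
  expect_identical(esn_states(u, p, 3), esn_states(u, p, 3))
  expect_false(identical(esn_states(u, p, 1), esn_states(u, p, 2)))
  expect_error(esn_states(matrix(0, 5, 3), p), "dimensionality")
  expect_error(esn_states(matrix(NaN, 5, 1), p), "non-finite")
})

test_that("gc_strength is exactly scale invariant and block-order invariant", {
  d <- var_blocks(6, 120, coupling = 0.6, seed = 3)
  p <- tiny_reservoir()
  base <- esgc(d$x, d$y, p)
  expect_equal(base$gc_strength, log(base$mse_restricted / base$mse_full))
  scaled <- esgc(lapply(d$x, `*`, 5), lapply(d$y, `*`, 0.02), p)
  expect_equal(scaled$gc_strength, base$gc_strength, tolerance = 1e-10)
  perm <- sample(6)
  shuffled <- esgc(d$x[perm], d$y[perm], p)
  expect_equal(shuffled$gc_strength, base$gc_strength, tolerance = 1e-10)
})

test_that("degenerate and malformed series are flagged or rejected", {
  d <- var_blocks(4, 60, seed = 5)
  p <- tiny_reservoir()
  flat <- lapply(d$x, function(v) rep(1, length(v)))
  est <- esgc(flat, d$y, p)
  expect_true(is.na(est$gc_strength))
  expect_equal(est$flag, "zero_variance")
  expect_error(esgc(d$x[1], d$y[1], p), "2 blocks")
  expect_error(esgc(d$x, lapply(d$y, head, 10), p), "unequal lengths")
  short <- lapply(1:4, function(i) rnorm(12))
  expect_error(esgc(short, short, p), "washout")
})

test_that("a source that copies the target cannot hurt prediction", {
  set.seed(6)
  y <- replicate(8, as.numeric(stats::filter(rnorm(150), 0.7, "recursive")),
                 simplify = FALSE)
  est <- esgc(y, y, tiny_reservoir())
  expect_gt(est$gc_strength, -0.05)
})

test_that("linear GC reference matches its closed-form oracle values", {
  set.seed(8)
  x <- rnorm(2e4)
  y <- rnorm(2e4)
  expect_lt(abs(linear_gc(x, y, 1)), 0.01)           # independent noise
  y2 <- 0.8 * c(0, x[-2e4]) + rnorm(2e4)
  expect_equal(linear_gc(x, y2, 1), log(1.64), tolerance = 0.03)
  # innovations already explained by the restricted model add nothing
  e <- rnorm(2e4)
  ar <- as.numeric(stats::filter(e, 0.9, "recursive"))
  expect_lt(abs(linear_gc(e, ar, 1)), 0.01)
  expect_error(linear_gc(rep(1, 1000), rnorm(1000), 1), "singular")
})

test_that("ESGC agrees with linear GC on linear data across replicates", {
  p <- tiny_reservoir(n_units = 20L)
  thr <- 0.05
  hits <- sapply(1:50, function(r) {
    d <- var_blocks(8, 150, coupling = 0.5, seed = 1000 + r)
    e <- esgc(d$x, d$y, p)$gc_strength
    l <- linear_gc(unlist(d$x), unlist(d$y), 1)
    (e > thr) == (l > thr) && sign(e) == sign(l)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("ESGC detects an even nonlinear coupling that linear GC misses", {
  p <- reservoir_params(n_units = 30, n_reservoirs = 2, seed = 3)
  res <- sapply(1:10, function(r) {
    set.seed(2000 + r)
    x <- replicate(8, rnorm(150), simplify = FALSE)
    # zero linear cross-correlation by even symmetry
    y <- lapply(x, function(v) {
      0.8 * (c(0, v[-150])^2 - 1) / sqrt(2) + 0.6 * rnorm(150)
    })
    c(e = esgc(x, y, p)$gc_strength,
      l = linear_gc(unlist(x), unlist(y), 1))
  })
  expect_true(all(res["e", ] > 0.1))
  expect_true(all(abs(res["l", ]) < 0.05))
})

test_that("the dyad matrix is a 20 x 20 grid consistent with pairwise calls", {
  dy <- generate_dyad_au(fast_au_params(seed = 51))
  blocks <- segment_blocks(dy$patient, dy$clinician, dy$events, dyad_id = "D")
  p <- tiny_reservoir()
  m <- esgc_matrix(blocks, "patient_to_clinician", p)
  expect_equal(dim(m$values), c(20L, 20L))
  expect_identical(rownames(m$values), default_au_labels())
  pair <- esgc(lapply(blocks, function(b) b$patient_segment[, 18]),
               lapply(blocks, function(b) b$clinician_segment[, 19]), p)
  expect_equal(m$values[18, 19], pair$gc_strength, tolerance = 1e-12)

  # zero-variance channel is flagged missing, not fabricated
  for (i in seq_along(blocks)) blocks[[i]]$clinician_segment[, 4] <- 2
  m2 <- esgc_matrix(blocks, "patient_to_clinician", p)
  expect_true(all(is.na(m2$values[, 4])))
  expect_false(anyNA(m2$values[, -4]))
  expect_error(esgc_matrix(list(), "patient_to_clinician", p), "empty-input")
})
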