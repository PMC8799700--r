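# Synthetic dyad, pain-session, brain and cohort generators

test_that("generators are pure functions of params + seed", {
  p <- fast_au_params(seed = 21)
  a <- generate_dyad_au(p)
  b <- generate_dyad_au(p)
  expect_identical(a$patient$values, b$patient$values)
  expect_identical(a$clinician$values, b$clinician$values)
  expect_identical(as.data.frame(a$events), as.data.frame(b$events))
  c <- generate_dyad_au(fast_au_params(seed = 22))
  expect_false(identical(a$patient$values, c$patient$values))
})

test_that("uncoupled members are statistically independent", {
  p <- fast_au_params(coupling_edges = NULL, seed = 4)
  dy <- generate_dyad_au(p)
  n <- nrow(dy$patient$values)
  ccs <- sapply(1:20, function(ch) {
    cor(dy$patient$values[, ch], dy$clinician$values[, ch])
  })
  # AR(1) with coef 0.8 has ~9 effective frames per independent draw
  expect_lt(max(abs(ccs)), 6 / sqrt(n / 9))
})

test_that("a planted edge shows up at its lag in the cross-correlogram", {
  # innovation-level coupling filtered through AR(1) keeps its
  # cross-correlogram peak at the planted lag only while ar < 0.618
  # (golden-ratio bound of a^2 + a - 1 < 0); use a moderate ar here
  edges <- coupling_edge("patient", 18, "clinician", 19, gain = 1.0,
                         lag_frames = 5)
  p <- fast_au_params(coupling_edges = edges, coupling_window = "all",
                      ar_coef = 0.5, seed = 8)
  dy <- generate_dyad_au(p)
  src <- dy$patient$values[, 18]
  tgt <- dy$clinician$values[, 19]
  n <- length(src)
  cc <- sapply(0:15, function(l) cor(src[1:(n - l)], tgt[(1 + l):n]))
  expect_equal(which.max(cc) - 1L, 5L)
})

test_that("frame-loop and filter generation paths agree exactly", {
  # a zero-gain 2-cycle forces the sequential path without changing the model
  edges <- rbind(coupling_edge("patient", 18, "clinician", 19, 1.0, 5),
                 coupling_edge("patient", 1, "clinician", 1, 0, 2),
                 coupling_edge("clinician", 1, "patient", 1, 0, 2))
  acyclic <- fast_au_params(coupling_edges = edges[1, ], seed = 13)
  cyclic <- fast_au_params(coupling_edges = edges, seed = 13)
  a <- generate_dyad_au(acyclic)
  b <- generate_dyad_au(cyclic)
  expect_equal(b$patient$values, a$patient$values, tolerance = 1e-12)
  expect_equal(b$clinician$values, a$clinician$values, tolerance = 1e-12)
})

test_that("unstable or malformed simulation parameters are rejected", {
  expect_error(dyad_sim_params(ar_coef = 1), "stationarity")
  expect_error(dyad_sim_params(
    coupling_edges = coupling_edge("patient", 1, "clinician", 2, 1, 0)),
    "lag_frames")
  expect_error(pain_sim_params(discriminative_aus = data.frame(au = 18, shift = Inf)),
               "finite")
})

test_that("pain sessions carry the planted discriminative shifts", {
  p <- fast_pain_params(seed = 31)
  s <- generate_pain_session(p)
  stim <- s$events[s$events$condition %in% c("pain_moderate", "pain_innocuous"), ]
  expect_equal(nrow(stim), 12L)  # 3 + 3 per run, two runs
  expect_equal(sum(stim$condition == "pain_moderate"), 6L)
  frames <- assemble_frames(s$patient, s$events)
  d28 <- mean(frames$AU28_lip_suck[frames$label == 1]) -
    mean(frames$AU28_lip_suck[frames$label == 0])
  expect_equal(d28, 1.5, tolerance = 0.45)
  # non-discriminative channel: no condition difference beyond noise
  d12 <- mean(frames$AU12_lip_corner_pull[frames$label == 1]) -
    mean(frames$AU12_lip_corner_pull[frames$label == 0])
  expect_lt(abs(d12), 0.45)

  null <- generate_pain_session(fast_pain_params(
    discriminative_aus = data.frame(au = 18L, shift = 0), seed = 32))
  nf <- assemble_frames(null$patient, null$events)
  d0 <- mean(nf$AU28_lip_suck[nf$label == 1]) - mean(nf$AU28_lip_suck[nf$label == 0])
  expect_lt(abs(d0), 0.45)
})

test_that("brain generator plants the requested cross-brain correlation", {
  rois <- default_rois()
  # zero gain: concordance centred at zero across dyads
  cc0 <- sapply(1:30, function(d) {
    g <- generate_dyad_brain(brain_sim_params(concordance_gain = 0),
                             facial_score = 1, seed = 500 + d)
    expect_equal(g$truth$rho, 0)
    cor(colMeans(g$clinician$betas[rois$clinician_aIns, ]),
        colMeans(g$patient$betas[rois$patient_m_pIns, ]))
  })
  expect_lt(abs(mean(cc0)), 0.12)

  # noiseless behaviour link: scores are an exact linear function of rho
  bp <- brain_sim_params(behavior_link = list(care_slope = 10, negexp_slope = 18,
                                              care_sd = 0, negexp_sd = 0))
  scores <- seq(0.2, 1.2, length.out = 8)
  beh <- t(sapply(seq_along(scores), function(i) {
    g <- generate_dyad_brain(bp, facial_score = scores[i], seed = 600 + i)
    c(rho = g$truth$rho, negexp = g$behavior$negative_expressivity)
  }))
  expect_equal(cor(beh[, "negexp"], beh[, "rho"]), 1, tolerance = 1e-12)

  expect_error(generate_dyad_brain(brain_sim_params(squash = "none"),
                                   facial_score = 5, seed = 1),
               "outside")
  expect_error(brain_sim_params(roi_definitions = list(a = 1:3, b = 3:5)),
               "disjoint")
})

test_that("emitted BOLD reproduces the generating betas through the GLM", {
  bp <- brain_sim_params(emit_bold = TRUE, bold_noise_sd = 0)
  g <- generate_dyad_brain(bp, facial_score = 0.8, seed = 77)
  bs <- beta_series(g$bold$patient, g$events, tr_s = g$tr_s)
  expect_equal(ncol(bs$betas), 12L)
  expect_equal(unname(bs$betas), unname(g$patient$betas), tolerance = 1e-8)
})

test_that("cohorts write to disk, reload exactly and are byte-reproducible", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  co <- build_cohort(file.path(dir1, "c"), n_dyads = 3,
                     au_params = fast_au_params(),
                     pain_params = fast_pain_params(), seed = 9)
  expect_equal(nrow(co$roster), 3L)
  expect_true(all(co$roster$is_real))

  back <- load_cohort(file.path(dir1, "c"))
  expect_identical(back$dyads$D01$patient$values, co$dyads$D01$patient$values)
  expect_identical(back$dyads$D02$brain$patient$betas,
                   co$dyads$D02$brain$patient$betas)
  expect_equal(as.data.frame(back$dyads$D03$events),
               as.data.frame(co$dyads$D03$events))

  build_cohort(file.path(dir2, "c"), n_dyads = 3,
               au_params = fast_au_params(),
               pain_params = fast_pain_params(), seed = 9)
  f1 <- list.files(file.path(dir1, "c"), full.names = TRUE)
  f2 <- list.files(file.path(dir2, "c"), full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_true(all(mapply(function(a, b) {
    identical(readBin(a, "raw", file.size(a)), readBin(b, "raw", file.size(b)))
  }, f1, f2)))

  expect_error(build_cohort(file.path(dir1, "c"), n_dyads = 2), "refusing")
})
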