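# Beta-series GLM, cross-brain concordance and behavioural correlations

test_that("the trial GLM recovers known betas from noiseless BOLD", {
  g <- generate_dyad_brain(brain_sim_params(emit_bold = TRUE,
                                            bold_noise_sd = 0),
                           facial_score = 0.5, seed = 70)
  bs <- beta_series(g$bold$clinician, g$events, tr_s = g$tr_s,
                    subject_id = "C01")
  expect_equal(dim(bs$betas), c(50L, 12L))     # two runs x six trials
  expect_equal(unname(bs$betas), unname(g$clinician$betas), tolerance = 1e-8)
  expect_equal(sort(unique(bs$trial_runs)), c(1L, 2L))

  # pure-noise BOLD: trial betas centred at zero
  set.seed(71)
  noise <- matrix(rnorm(length(g$bold$clinician)), nrow(g$bold$clinician))
  b0 <- beta_series(noise, g$events, tr_s = g$tr_s)
  expect_lt(abs(mean(b0$betas)), 0.1)

  # duplicated trial regressors are named in the rank-deficiency error
  ev <- as.data.frame(g$events)
  dup <- ev[grepl("anticipation", ev$condition), ][1, ]
  expect_error(beta_series(noise, rbind(ev, dup), tr_s = g$tr_s),
               "design error.*trial")
})

test_that("partner ROI vectors are z-scored trial means with degenerate flags", {
  set.seed(72)
  B <- matrix(rnorm(10 * 12), 10, 12)
  bs <- dyadcomm:::new_beta_series(B, rep("anticipation_treat", 12),
                                   rep(1:2, each = 6), "S")
  one <- partner_roi_vector(bs, roi_spec("seed", 4))
  expect_equal(unname(one), (B[4, ] - mean(B[4, ])) / sd(B[4, ]))
  expect_equal(sd(one), 1)

  flat <- dyadcomm:::new_beta_series(matrix(1, 3, 12), rep("rest", 12),
                                     rep(1, 12), "S")
  v <- partner_roi_vector(flat, roi_spec("seed", 1))
  expect_true(all(is.na(v)) && isTRUE(attr(v, "degenerate")))

  # opposite parcels cancel to a constant zero mean
  B2 <- rbind(B[1, ], -B[1, ])
  canc <- dyadcomm:::new_beta_series(B2, rep("rest", 12), rep(1, 12), "S")
  expect_true(isTRUE(attr(partner_roi_vector(canc, roi_spec("r", 1:2)),
                          "degenerate")))
  expect_error(partner_roi_vector(bs, roi_spec("r", 99)), "ROI error")
})

test_that("concordance coefficients equal the Pearson correlation closed form", {
  set.seed(73)
  B <- matrix(rnorm(25 * 12), 25, 12)
  own <- dyadcomm:::new_beta_series(B, rep("anticipation_treat", 12),
                                    rep(1:2, each = 6), "S")
  pv <- partner_roi_vector(own, roi_spec("seed", 1:3))
  cc <- dyad_concordance(own, pv)
  oracle <- apply(B, 1, function(y) cor(y, pv))
  expect_equal(unname(cc), unname(oracle), tolerance = 1e-12)

  same <- dyadcomm:::new_beta_series(rbind(pv, pv), rep("rest", 12),
                                     rep(1, 12), "S")
  expect_equal(unname(dyad_concordance(same, pv)), c(1, 1), tolerance = 1e-12)
  anti <- dyadcomm:::new_beta_series(rbind(-pv), rep("rest", 12), rep(1, 12), "S")
  expect_equal(unname(dyad_concordance(anti, pv)), -1, tolerance = 1e-12)

  flatrow <- dyadcomm:::new_beta_series(rbind(pv, rep(2, 12)), rep("rest", 12),
                                        rep(1, 12), "S")
  expect_true(is.na(dyad_concordance(flatrow, pv)[2]))
  degenerate <- structure(rep(NA_real_, 12), degenerate = TRUE)
  expect_error(dyad_concordance(own, degenerate), "degenerate")
})

test_that("group regression recovers slopes and controls its false positives", {
  set.seed(74)
  score <- rnorm(30)
  z <- (score - mean(score)) / sd(score)
  coeffs <- sapply(1:8, function(j) 0.5 * z)   # noiseless planted slope
  grp <- group_regression(coeffs, score)
  expect_equal(unname(grp$table$slope), rep(0.5, 8), tolerance = 1e-10)
  expect_true(all(grp$table$significant))

  # score-independent coefficients: BH keeps the discovery fraction near 0
  frac <- sapply(1:30, function(r) {
    set.seed(800 + r)
    mean(group_regression(matrix(rnorm(20 * 30), 20, 30),
                          rnorm(20))$table$significant)
  })
  expect_lte(mean(frac), 0.05 + 0.02)

  expect_error(group_regression(coeffs, rep(1, 30)), "degenerate-regressor")
  expect_error(group_regression(coeffs[1:2, ], score[1:2]), ">= 3")
})

test_that("behavioural correlations use the two-sided Pearson test", {
  x <- c(0.1, 0.3, 0.2, 0.6, 0.45, 0.8)
  exact <- behavior_correlation(x, 2 * x + 1)
  expect_equal(exact$r, 1, tolerance = 1e-12)
  inv <- behavior_correlation(x, -x)
  expect_equal(inv$r, -1, tolerance = 1e-12)
  set.seed(75)
  a <- rnorm(20)
  b <- 0.5 * a + rnorm(20)
  ref <- cor.test(a, b)
  got <- behavior_correlation(a, b)
  expect_equal(got$r, unname(ref$estimate))
  expect_equal(got$p, ref$p.value)
  expect_error(behavior_correlation(x, rep(3, 6)), "degenerate")
  expect_error(behavior_correlation(x[1:2], x[1:2]), ">= 3")
})

test_that("permuting dyad labels destroys the planted behaviour correlation", {
  co <- simulate_cohort(30, au_params = fast_au_params(), pain_params = NULL,
                        brain_params = brain_sim_params(), seed = 76)
  rois <- default_rois()
  scalar <- sapply(co$dyads, function(e) {
    cor(partner_roi_vector(e$brain$clinician, rois$clinician_aIns),
        partner_roi_vector(e$brain$patient, rois$patient_m_pIns))
  })
  linked <- behavior_correlation(scalar, co$behavior$negative_expressivity)
  expect_gt(linked$r, 0.3)
  set.seed(77)
  perm_r <- sapply(1:50, function(i) {
    behavior_correlation(scalar,
                         sample(co$behavior$negative_expressivity))$r
  })
  expect_lt(abs(mean(perm_r)), 0.1)
})
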