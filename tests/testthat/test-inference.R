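# Pseudo-dyad enumeration, the Mann-Whitney cell test and BH-FDR

test_that("pseudo-dyad enumeration yields all n(n-1) mismatched pairings", {
  r2 <- dyad_roster(c("D1", "D2"), c("P1", "P2"), c("C1", "C2"))
  ps2 <- enumerate_pseudo_dyads(r2)
  expect_equal(nrow(ps2), 2L)
  expect_false(any(ps2$is_real))

  n <- 40
  r40 <- dyad_roster(sprintf("D%02d", 1:n), sprintf("P%02d", 1:n),
                     sprintf("C%02d", 1:n))
  ps40 <- enumerate_pseudo_dyads(r40)
  expect_equal(nrow(ps40), 40 * 39)
  real_keys <- paste(r40$patient_id, r40$clinician_id)
  expect_false(any(paste(ps40$patient_id, ps40$clinician_id) %in% real_keys))

  cap1 <- enumerate_pseudo_dyads(r40, cap = 100, seed = 5)
  cap2 <- enumerate_pseudo_dyads(r40, cap = 100, seed = 5)
  expect_equal(nrow(cap1), 100L)
  expect_identical(cap1, cap2)
  expect_false(identical(cap1, enumerate_pseudo_dyads(r40, cap = 100, seed = 6)))

  expect_error(enumerate_pseudo_dyads(r2[1, ]), "insufficient-data")
})

test_that("cell test reproduces exact rank-permutation probabilities", {
  expect_equal(cell_test(c(3, 4, 5), c(0, 1, 2)), 1 / 20)
  expect_equal(cell_test(c(0, 1, 2), c(3, 4, 5)), 1)  # reversed extreme
  expect_gte(cell_test(c(1, 2, 3), c(1, 2, 3)), 0.5)
  deg <- cell_test(rep(2, 4), rep(2, 5))
  expect_equal(as.numeric(deg), 1)
  expect_true(attr(deg, "degenerate"))
  expect_error(cell_test(numeric(0), 1:3), "empty-input")
  expect_error(cell_test(c(1, NA), 1:3), "non-finite")

  # brute-force enumeration oracle over random tie-free small samples
  set.seed(14)
  for (case in 1:25) {
    n <- sample(1:8, 1)
    m <- sample(2:8, 1)
    real <- runif(n)
    null <- runif(m)
    expect_equal(cell_test(real, null), exact_mw_p(real, null),
                 tolerance = 1e-12)
  }
})

test_that("BH correction follows the step-up convention over the grid", {
  s <- fdr_correct(matrix(c(0.01, 0.02, 0.03, 0.5), 2, 2), alpha = 0.05)
  expect_equal(sum(s$significant), 3L)
  expect_equal(s$m, 4L)
  expect_true(all(s$q >= s$p))
  expect_equal(sum(fdr_correct(matrix(1, 20, 20))$significant), 0L)
  # boundary: a single p at alpha / m is significant under step-up <=
  p <- matrix(1, 20, 20)
  p[7, 3] <- 0.05 / 400
  sb <- fdr_correct(p)
  expect_true(sb$significant[7, 3])
  expect_equal(sum(sb$significant), 1L)
  expect_error(fdr_correct(matrix(c(0.5, 1.2), 1, 2)), "\\[0, 1\\]")

  # brute-force step-up oracle on random grids, including NA cells
  set.seed(15)
  for (case in 1:200) {
    g <- matrix(runif(400)^sample(1:4, 1), 20, 20)
    if (case %% 5 == 0) g[sample(400, 13)] <- NA
    got <- fdr_correct(g, alpha = 0.05)
    ok <- !is.na(g)
    expect_identical(got$significant[ok], bh_oracle(g[ok], 0.05))
    expect_equal(got$m, sum(ok))
  }
})

test_that("group test + link summary wire the grids together coherently", {
  set.seed(16)
  labels <- default_au_labels()
  mk <- function(shift) {
    m <- matrix(rnorm(400, sd = 0.05), 20, 20,
                dimnames = list(labels, labels))
    m[18, 19] <- m[18, 19] + shift
    m
  }
  real <- lapply(1:6, function(i) mk(1))
  null <- lapply(1:15, function(i) mk(0))
  sig <- gc_group_test(real, null)
  expect_equal(dim(sig$p), c(20L, 20L))
  expect_equal(sig$m, 400L)
  expect_true(sig$significant[18, 19])
  expect_equal(sig$n_real, 6L)
  expect_equal(sig$n_null, 15L)

  links <- summarize_links(sig, gc_p2c = real)
  expect_equal(links$n_links_patient_to_clinician, sum(sig$significant))
  expect_equal(sum(links$out_degree), sum(sig$significant))
  expect_equal(sum(links$in_degree), sum(sig$significant))
  expect_length(links$au_row_score, 6L)
  expect_equal(unname(links$au_row_score[1]), mean(real[[1]][18, ]))

  # a constant AU28 row averages to itself; an empty grid has zero degrees
  flat <- matrix(0.2, 20, 20, dimnames = list(labels, labels))
  empty <- fdr_correct(matrix(1, 20, 20,
                              dimnames = list(labels, labels)))
  l0 <- summarize_links(empty, gc_p2c = list(flat))
  expect_equal(unname(l0$au_row_score), 0.2)
  expect_true(all(l0$out_degree == 0) && all(l0$in_degree == 0))

  # a synthetic grid with 59 surviving cells is counted as such
  p59 <- matrix(1, 20, 20)
  p59[sample(400, 59)] <- 1e-6
  expect_equal(summarize_links(fdr_correct(p59))$n_links_patient_to_clinician,
               59L)
})
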