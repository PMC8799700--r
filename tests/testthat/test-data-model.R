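# Data types, readers/writers and block segmentation

test_that("AU recordings round-trip through CSV bit-identically", {
  set.seed(11)
  vals <- matrix(rnorm(240 * 20), 240, 20)
  rec <- au_recording(vals, "P01", "patient")
  path <- withr::local_tempfile(fileext = ".csv")
  write_au_recording(rec, path)
  back <- read_au_recording(path, "P01", "patient")
  expect_identical(back$values, rec$values)
  expect_equal(nrow(back$values), 240L)
  expect_identical(back$au_labels, default_au_labels())
})

test_that("AU readers reject malformed inputs instead of coercing", {
  expect_error(au_recording(matrix(0, 10, 19), "x", "patient"), "schema")
  bad <- matrix(0, 10, 20)
  bad[4, 2] <- NaN
  expect_error(au_recording(bad, "x", "patient"), "frame 3")

  rec <- au_recording(matrix(rnorm(200), 10, 20), "P01", "patient")
  path <- withr::local_tempfile(fileext = ".csv")
  write_au_recording(rec, path)
  df <- read.csv(path, check.names = FALSE)

  p1 <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[-3], p1, row.names = FALSE)  # drop one AU column
  expect_error(read_au_recording(p1, "P01", "patient"), "schema")

  p2 <- withr::local_tempfile(fileext = ".csv")
  df2 <- df
  df2$extra_channel <- 0
  write.csv(df2, p2, row.names = FALSE)
  expect_error(read_au_recording(p2, "P01", "patient"), "schema")

  p3 <- withr::local_tempfile(fileext = ".csv")
  df3 <- df
  df3$frame[5] <- 99L  # gap
  write.csv(df3, p3, row.names = FALSE)
  expect_error(read_au_recording(p3, "P01", "patient"), "gap-free")
})

test_that("event tables validate protocol structure", {
  ev <- event_table(onset = c(0, 12, 20), duration = c(10, 8, 14),
                    condition = c("rest", "anticipation_treat", "pain_moderate"),
                    trial_index = 1L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events(ev, path)
  expect_equal(read_events(path), ev)

  expect_error(event_table(c(0, 5), c(10, 8), c("rest", "anticipation_treat"),
                           1:2), "overlap")
  expect_error(event_table(0, 10, "coffee_break", 1L), "unknown condition")
  expect_error(event_table(0, 4, "anticipation_treat", 1L),
               "anticipation durations")
  expect_error(event_table(c(0, 20), c(10, 8), c("rest", "rest"), c(1L, 1L)),
               "duplicate trial")
})

test_that("rosters and causality matrices round-trip", {
  r <- dyad_roster(c("D1", "D2"), c("P1", "P2"), c("C1", "C2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_roster(r, path)
  expect_equal(read_roster(path), r)
  expect_error(dyad_roster(c("D1", "D2"), c("P1", "P1"), c("C1", "C1")),
               "duplicated")

  set.seed(2)
  m <- matrix(rnorm(400), 20, 20, dimnames = list(default_au_labels(),
                                                  default_au_labels()))
  mp <- withr::local_tempfile(fileext = ".csv")
  write_gc_values(m, mp)
  expect_identical(read_gc_values(mp), m)

  z <- matrix(0, 20, 20, dimnames = dimnames(m))
  zp <- withr::local_tempfile(fileext = ".csv")
  write_gc_values(z, zp)
  expect_identical(read_gc_values(zp), z)

  expect_error(write_gc_values(m[-1, ], mp), "shape")
})

test_that("segmentation maps seconds to frames by the rounding convention", {
  vals <- matrix(seq_len(4000 * 20), 4000, 20)  # values encode frame index
  pat <- au_recording(vals, "P", "patient")
  cli <- au_recording(vals, "C", "clinician")
  ev <- event_table(onset = c(0, 10, 30, 50),
                    duration = c(10, 6, 12, 9.95),
                    condition = c("rest", "anticipation_treat",
                                  "anticipation_notreat", "anticipation_treat"),
                    trial_index = 1:4)
  blocks <- segment_blocks(pat, cli, ev, dyad_id = "D")
  expect_length(blocks, 3L)
  expect_equal(sapply(blocks, `[[`, "n_frames"), c(120L, 240L, 199L))
  expect_equal(sapply(blocks, function(b) round(b$n_frames)),
               round(c(6, 12, 9.95) * 20))
  # half-open windows never duplicate a frame across non-overlapping events
  taken <- unlist(lapply(blocks, function(b) b$patient_segment[, 1]))
  expect_false(any(duplicated(taken)))

  short <- au_recording(vals[1:100, ], "P", "patient")
  expect_error(segment_blocks(short, cli, ev), "bounds")
  slow <- au_recording(vals, "C", "clinician", sampling_rate_hz = 10)
  expect_error(segment_blocks(pat, slow, ev), "alignment")
  expect_error(segment_blocks(pat, cli, ev, conditions = "rating"),
               "empty-input")
})

test_that("a full treatment session yields the 12 protocol anticipation blocks", {
  dy <- generate_dyad_au(fast_au_params(seed = 3))
  blocks <- segment_blocks(dy$patient, dy$clinician, dy$events, dyad_id = "D")
  expect_length(blocks, 12L)
  for (b in blocks) {
    expect_equal(nrow(b$patient_segment), b$n_frames)
    expect_equal(nrow(b$clinician_segment), b$n_frames)
    expect_gte(b$n_frames, 6 * 20)
    expect_lte(b$n_frames, 12 * 20)
  }
})
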