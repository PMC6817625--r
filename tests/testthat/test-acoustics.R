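test_that("semitone transform hits the reference, octaves, and worked values", {
  expect_identical(hz_to_semitone(440), 0)
  expect_equal(hz_to_semitone(220), -12)
  expect_equal(hz_to_semitone(880), 12)
  # 12*log2(92.47/440), value frozen from an independent evaluation
  expect_equal(hz_to_semitone(92.47), -27.00535, tolerance = 1e-6)
  # octave law and transposition, over random frequencies
  set.seed(11)
  f <- runif(50, 60, 1000)
  expect_equal(hz_to_semitone(2 * f) - hz_to_semitone(f), rep(12, 50))
  expect_equal(hz_to_semitone(f, reference_hz = 100),
               12 * log2(f / 100))
  expect_equal(semitone_to_hz(hz_to_semitone(f)), f)
  expect_error(hz_to_semitone(0), "positive")
  expect_error(hz_to_semitone(c(100, -3)), "positive")
  expect_error(hz_to_semitone(NaN), "positive")
})

test_that("note labelling reproduces the printed Hz-note pairs", {
  expect_identical(semitone_to_note_label(0), "A4")
  hz <- c(92.47, 177.70, 164.10, 253.10, 103.60, 208.50, 168.5, 348.20)
  labels <- c("F#2", "F3", "E3", "B3", "G#2", "G#3", "E3", "F4")
  expect_identical(semitone_to_note_label(hz_to_semitone(hz)), labels)
  # exact halves round away from zero; octave increments at C
  expect_identical(semitone_to_note_label(0.5), "A#4")
  expect_identical(semitone_to_note_label(-0.5), "G#4")
  expect_identical(semitone_to_note_label(-9), "C4")
  expect_identical(semitone_to_note_label(-10), "B3")
  expect_error(semitone_to_note_label(Inf), "finite")
})

test_that("F0 range is a log ratio, transposition invariant", {
  expect_equal(f0_range_semitones(100, 200), 12)
  expect_equal(f0_range_semitones(123.4, 123.4), 0)
  expect_equal(f0_range_semitones(92.47, 177.70), 11.30857, tolerance = 1e-5)
  set.seed(21)
  a <- runif(30, 80, 200); b <- a * runif(30, 1, 3); k <- runif(30, 0.1, 10)
  expect_equal(f0_range_semitones(k * a, k * b), f0_range_semitones(a, b))
  expect_error(f0_range_semitones(200, 100), ">=")
})

test_that("delta-F closed form equals a generic through-origin regression", {
  expect_equal(estimate_delta_f(c(500, 1500, 2500, 3500)), 1000)
  expect_equal(estimate_delta_f(c(450, 1450, 2450, 3450)), 20600 / 21)
  x <- (2 * 1:4 - 1) / 2
  set.seed(31)
  for (i in 1:25) {
    f <- sort(runif(4, 300, 5000))
    if (any(diff(f) <= 0)) next
    oracle <- unname(coef(lm(f ~ 0 + x)))
    expect_equal(estimate_delta_f(f), oracle, tolerance = 1e-9)
  }
  expect_error(estimate_delta_f(c(500, 1500, 2500)), "exactly 4")
  expect_error(estimate_delta_f(c(500, 400, 2500, 3500)), "increasing")
  expect_error(estimate_delta_f(c(-500, 1500, 2500, 3500)), "positive")
})

test_that("VTL conversion and uniform-tube round trip", {
  expect_equal(vtl_from_delta_f(1000), 16.75)
  expect_equal(vtl_from_delta_f(20600 / 21), 17.07524, tolerance = 1e-5)
  # synthesize formants of a tube of length L, recover L exactly
  for (L in c(12, 14.27, 16.75, 17.44)) {
    df <- 33500 / (2 * L)
    expect_equal(vtl_from_delta_f(estimate_delta_f((2 * 1:4 - 1) / 2 * df)), L)
  }
  # decreasing in delta-F
  expect_true(vtl_from_delta_f(1100) < vtl_from_delta_f(1000))
  expect_error(vtl_from_delta_f(0), "positive")
})

test_that("vocal profiles average per-recording transforms", {
  one <- make_records(mean_f0 = 110, min_f0 = 90, max_f0 = 180,
                      delta_f = 1000)
  p1 <- build_vocal_profile(one)
  expect_equal(p1$mean_f0_st, hz_to_semitone(110))
  expect_equal(p1$f0_range_st, f0_range_semitones(90, 180))
  expect_equal(p1$vtl_cm, 16.75)
  expect_identical(p1$n_recordings, 1L)

  # two records with semitone means -20 and -22 average to -21
  two <- make_records(mean_f0 = semitone_to_hz(c(-20, -22)))
  expect_equal(build_vocal_profile(two)$mean_f0_st, -21)

  # 3-record set vs. hand-computed means
  r3 <- make_records(mean_f0 = c(100, 120, 140), min_f0 = c(80, 90, 100),
                     max_f0 = c(150, 200, 260),
                     delta_f = c(950, 1000, 1050))
  p3 <- build_vocal_profile(r3)
  expect_equal(p3$mean_f0_st,
               mean(12 * log2(c(100, 120, 140) / 440)))
  expect_equal(p3$f0_range_st,
               mean(12 * log2(c(150, 200, 260) / c(80, 90, 100))))
  expect_equal(p3$delta_f_hz, 1000)
  expect_equal(p3$vtl_cm, 33500 / 2000)
  # convex order: averaging per-recording VTLs gives a larger value
  p3b <- build_vocal_profile(r3, vtl_from = "mean_vtl")
  expect_true(p3b$vtl_cm > p3$vtl_cm)

  expect_error(build_vocal_profile(r3[0, ]), "non-empty")
  mixed <- rbind(make_records(person = "a"), make_records(person = "b"))
  expect_error(build_vocal_profile(mixed), "single person")
  mixed_d <- rbind(make_records(display = "speech"),
                   make_records(display = "singing"))
  expect_error(build_vocal_profile(mixed_d), "one display")
})

test_that("record validation rejects malformed tables", {
  r <- make_records()
  bad <- r; bad$min_f0_hz[1] <- bad$max_f0_hz[1] + 1
  expect_error(validate_acoustic_records(bad), "min <= mean <= max")
  bad2 <- r; bad2$f2_hz[2] <- bad2$f1_hz[2] - 1
  expect_error(validate_acoustic_records(bad2), "increasing")
  bad3 <- r; bad3$recording_id[2] <- bad3$recording_id[1]
  expect_error(validate_acoustic_records(bad3), "duplicate")
  bad4 <- r; bad4$display[1] <- "humming"
  expect_error(validate_acoustic_records(bad4), "display")
})

test_that("modulation indices are absolute, symmetric differences", {
  sp <- build_vocal_profile(make_records(display = "speech",
                                         mean_f0 = semitone_to_hz(-22.37)))
  si <- build_vocal_profile(make_records(display = "singing",
                                         mean_f0 = semitone_to_hz(-20.07)))
  m <- modulation_indices(sp, si)
  expect_equal(m$abs_df0_st, 2.30, tolerance = 1e-10)
  # symmetry in argument order
  m2 <- modulation_indices(si, sp)
  expect_equal(m[-1], m2[-1])
  # identical profiles give all-zero indices
  sp2 <- sp; sp2$display <- "singing"
  m0 <- modulation_indices(sp, sp2)
  expect_equal(unlist(m0[-1]), c(abs_df0_st = 0, abs_drange_st = 0,
                                 abs_dvtl_cm = 0))
  other <- sp; other$person_id <- "someone_else"; other$display <- "singing"
  expect_error(modulation_indices(sp, other), "different persons")
  expect_error(modulation_indices(sp, sp), "one profile per display")
})

test_that("profiles table groups by person and display", {
  recs <- rbind(
    make_records(person = "a", display = "speech"),
    make_records(person = "a", display = "singing",
                 mean_f0 = c(130, 150)),
    make_records(person = "b", display = "speech", mean_f0 = 100)
  )
  prof <- build_vocal_profiles(recs)
  expect_identical(nrow(prof), 3L)
  expect_identical(prof$person_id, c("a", "a", "b"))
  expect_setequal(prof$n_recordings, c(2L, 2L, 1L))
})
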