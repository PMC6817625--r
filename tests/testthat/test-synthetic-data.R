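test_that("default calibration carries the published summaries", {
  calib <- default_calibration()
  men <- calib$groups[calib$groups$sex == "M", ]
  # group-size-weighted male speech F0 mean reproduces the printed total
  expect_equal(sum(men$f0_speech_mean * men$n) / sum(men$n), -22.37,
               tolerance = 0.005)
  expect_equal(calib$cross_display$M[["f0"]], 0.800)
  expect_equal(calib$cross_display$F[["f0"]], 0.607)
  expect_equal(calib$cross_display$M[["vtl"]], 0.808)
  expect_equal(calib$cross_display$M[["attract"]], 0.720)
  expect_true(all(as.matrix(calib$groups[grep("_sd$",
    names(calib$groups))]) > 0))
  expect_equal(calib$rating$target_alpha, 0.79)
  # the per-sex correlation matrices are valid after (possible) repair
  for (s in c("M", "F")) {
    R <- voxpath:::calibration_correlation(calib, s)$mat
    expect_true(min(eigen(R, symmetric = TRUE)$values) > 0)
    expect_equal(unname(diag(R)), rep(1, 10))
  }
})

test_that("generated group means converge to the calibration", {
  calib <- default_calibration()
  co <- generate_cohort(calib, seed = 61, sexes = "M", n_total = c(M = 10000))
  men <- calib$groups[calib$groups$sex == "M", ]
  target_mean <- sum(men$f0_speech_mean * men$n) / sum(men$n)
  expect_equal(mean(co$speech_f0_st), target_mean, tolerance = 0.05)
  target_vtl <- sum(men$vtl_speech_mean * men$n) / sum(men$n)
  expect_equal(mean(co$speech_vtl_cm), target_vtl, tolerance = 0.05)
  # determinism: same seed, identical table
  co2 <- generate_cohort(calib, seed = 61, sexes = "M",
                         n_total = c(M = 10000))
  expect_identical(co, co2)
})

test_that("zeroed correlation targets give independent displays", {
  calib <- default_calibration()
  calib$cross_display$M[] <- 0
  # body-size links also bridge the two displays; zero them too so the
  # speech and singing blocks are fully independent
  calib$extra_correlations[c("f0_vtl_cross", "weight_vtl", "height_vtl")] <- 0
  co <- generate_cohort(calib, seed = 67, sexes = "M", n_total = c(M = 6000))
  # within one country (pooling countries re-introduces a small mixture
  # correlation through the different group means)
  br <- co[co$country == "BR", ]
  expect_equal(cor(br$speech_f0_st, br$singing_f0_st), 0, tolerance = 0.05)
  expect_equal(cor(br$speech_range_st, br$singing_range_st), 0,
               tolerance = 0.05)
  expect_equal(cor(br$speech_vtl_cm, br$singing_vtl_cm), 0, tolerance = 0.05)
})

test_that("cohort schema and bounds hold", {
  co <- generate_cohort(default_calibration(), seed = 71)
  expect_identical(nrow(co), 152L)  # 40 + 33 + 44 + 35
  expect_true(all(co$liking_to_sing %in% 1:10))
  expect_true(all(co$soi_total >= 9 & co$soi_total <= 81))
  expect_true(all(is.finite(co$wsr[co$sex == "M"])))
  expect_true(all(is.finite(co$whr[co$sex == "F"])))
  expect_false(anyDuplicated(co$person_id) > 0)
})

test_that("rating matrices hit the alpha target and the noiseless limit", {
  set.seed(73)
  true <- rnorm(80, 3.5, 0.7)
  # calibrated case: alpha 0.79, 46 raters, 80 targets
  alphas <- vapply(1:10, function(i) {
    m <- generate_rating_matrix(true, n_raters = 46, target_alpha = 0.79,
                                seed = 1000 + i)
    cronbach_alpha(m)
  }, numeric(1))
  expect_gt(mean(alphas), 0.74)
  expect_lt(mean(alphas), 0.84)
  # near-noiseless limit: alpha close to 1, means reproduce ordering
  m <- generate_rating_matrix(true, n_raters = 20, target_alpha = 0.985,
                              seed = 5)
  expect_gt(cronbach_alpha(m), 0.95)
  expect_gt(cor(aggregate_target_means(m), true), 0.97)
  # determinism
  m2 <- generate_rating_matrix(true, n_raters = 20, target_alpha = 0.985,
                               seed = 5)
  expect_identical(m$scores, m2$scores)
  expect_error(generate_rating_matrix(true, 1, 0.8, seed = 1), "raters")
  expect_error(generate_rating_matrix(true, 10, 1.2, seed = 1), "target_alpha")
  expect_error(generate_rating_matrix(rep(3, 5), 10, 0.8, seed = 1),
               "variance")
})

test_that("simulate_study produces a coherent, reproducible bundle", {
  calib <- small_calibration(n_per_group = 6L, raters = 3L)
  s1 <- simulate_study(calib, seed = 77)
  expect_identical(nrow(s1$cohort), 24L)
  # two recordings per person per display
  expect_identical(nrow(s1$recordings), 24L * 4L)
  expect_silent(validate_acoustic_records(s1$recordings))
  # recordings reproduce the cohort's profiles approximately
  prof <- build_vocal_profiles(s1$recordings)
  merged <- merge(prof[prof$display == "speech", ],
                  s1$cohort[c("person_id", "speech_f0_st", "speech_vtl_cm")])
  expect_gt(cor(merged$mean_f0_st, merged$speech_f0_st), 0.9)
  expect_gt(cor(merged$vtl_cm, merged$speech_vtl_cm), 0.8)
  # ratings cover every target in both displays
  expect_setequal(unique(s1$ratings$target_id), s1$cohort$person_id)
  # full determinism from the master seed
  s2 <- simulate_study(calib, seed = 77)
  expect_identical(s1, s2)
})
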