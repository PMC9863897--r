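test_that("spec validation rejects degenerate cohorts", {
  expect_error(cohort_spec(n_subjects = 1), "at least 2 subjects")
  expect_error(cohort_spec(coupling = 1.2), "coupling")
  expect_error(cohort_spec(thermal_fs = 5), "100 samples")
  expect_error(cohort_spec(rest_window_s = 8), "at least 10 s")
  expect_error(cohort_spec(noise_sd = -0.1), "noise_sd")
  expect_error(cohort_spec(fatigue_slope = 0.3), "band center")
})

test_that("default design: 10 subjects x 5 series = 50 recordings", {
  cohort <- generate_cohort(cohort_spec(seed = 2, with_patches = FALSE))
  expect_identical(nrow(cohort$recordings), 50L)
  expect_identical(nrow(cohort$ground_truth), 50L)
  expect_identical(length(unique(cohort$recordings$subject_id)), 10L)
  # every series has 3 ROIs and at least 10 s of post-exercise signal
  for (k in seq_len(nrow(cohort$recordings))) {
    rois <- cohort$recordings$thermal_rois[[k]]
    expect_identical(rois$roi_id, 1:3)
    tail_len <- length(rois$mean_trace[[1]]) -
      cohort$recordings$exercise_end_index[k] + 1L
    expect_gte(tail_len, 100L)
  }
})

test_that("identical seeds give identical cohorts, on disk byte-for-byte", {
  s <- cohort_spec(n_subjects = 2, n_series = 2, seed = 33)
  c1 <- generate_cohort(s)
  c2 <- generate_cohort(s)
  expect_identical(c1$recordings$emg, c2$recordings$emg)
  expect_identical(c1$ground_truth, c2$ground_truth)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(c1, d1)
  write_cohort(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e7),
                     readBin(file.path(d2, f), "raw", 2e7))
  }
})

test_that("generator self-consistency: measured ARV/MDF match latent truth", {
  cohort <- generate_cohort(cohort_spec(seed = 4, with_patches = FALSE))
  tg <- emg_targets(cohort)
  merged <- merge(tg, cohort$ground_truth)
  expect_lt(max(abs(merged$arv - merged$true_arv) / merged$true_arv), 0.05)
  expect_lt(max(abs(merged$mdf - merged$true_mdf) / merged$true_mdf), 0.05)
})

test_that("coupling controls the thermal-EMG association", {
  # coupling 1, no noise: MeanTemp deterministically tracks true ARV
  c1 <- generate_cohort(cohort_spec(coupling = 1, noise_sd = 0, seed = 5,
                                    with_patches = FALSE))
  tab1 <- thermal_feature_table(c1)
  m <- merge(tab1[tab1$roi_id == 1, ], c1$ground_truth)
  expect_gt(cor(m$mean_temp, m$true_arv), 0.999)
  # coupling 0: association centered at zero (averaged over seeds)
  rs <- vapply(6:10, function(sd) {
    c0 <- generate_cohort(cohort_spec(coupling = 0, seed = sd,
                                      with_patches = FALSE))
    t0 <- thermal_feature_table(c0)
    m0 <- merge(t0[t0$roi_id == 1, ], c0$ground_truth)
    cor(m0$mean_temp, m0$true_arv)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("cohort round trip is lossless and errors are specific", {
  cohort <- generate_cohort(cohort_spec(n_subjects = 2, n_series = 2, seed = 11))
  d <- withr::local_tempdir()
  write_cohort(cohort, d)
  back <- read_cohort(d)
  expect_identical(back$recordings$emg, cohort$recordings$emg)
  expect_identical(lapply(back$recordings$thermal_rois, `[[`, "mean_trace"),
                   lapply(cohort$recordings$thermal_rois, `[[`, "mean_trace"))
  expect_identical(lapply(back$recordings$thermal_rois, `[[`, "patch_frames"),
                   lapply(cohort$recordings$thermal_rois, `[[`, "patch_frames"))
  expect_identical(back$ground_truth$true_arv, cohort$ground_truth$true_arv)
  expect_identical(back$recordings$exercise_end_index,
                   cohort$recordings$exercise_end_index)
  # empty directory: explicit empty-cohort error
  expect_error(read_cohort(withr::local_tempdir()), "manifest.json not found")
  # missing ROI trace: validation error naming subject/series/ROI
  unlink(file.path(d, "S02_series1_roi2_thermal.csv"))
  expect_error(read_cohort(d), "S02 series 1 ROI 2")
})
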