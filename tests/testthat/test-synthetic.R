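test_that("block intensity profiles hit their defining knots exactly", {
  p <- block_profile(13.57, 0.7, 106, noise_sd_s = 0)
  expect_equal(block_intensity(0, p), 0)
  expect_equal(block_intensity(13.57, p), 0.7, tolerance = 1e-9)
  expect_equal(block_intensity(106, p), 0.15, tolerance = 1e-9)
  expect_lt(block_intensity(106.5, p), 0.15)  # crossing is downward
  g <- block_intensity(seq(0, 400, by = 0.25), p)
  expect_true(all(g >= 0 & g <= 1))
  expect_true(all(diff(g[seq(0, 400, by = 0.25) >= 13.57]) <= 1e-12))

  # dip-and-rebound profile pins dip and threshold crossing
  pd <- block_profile(12.1, 0.931, 285, release_dip = c(92.8, 0.565),
                      rebound = TRUE, noise_sd_s = 0)
  expect_equal(block_intensity(92.8, pd), 0.565, tolerance = 1e-9)
  expect_equal(block_intensity(285, pd), 0.15, tolerance = 1e-9)
  expect_gt(block_intensity(270, pd), 0.15)   # still blocked at the horizon
  expect_gt(block_intensity(pd$rebound_time_min, pd),
            block_intensity(92.8, pd))        # re-deepening after the dip

  expect_error(block_profile(100, 0.7, 90), "onset_min < duration_min")
  expect_error(block_profile(10, 0.7, 100, rebound = TRUE), "release_dip")
})

test_that("cohort generation is deterministic and honors its spec", {
  c1 <- generate_cohort(cohort_spec(seed = 42))
  c2 <- generate_cohort(cohort_spec(seed = 42))
  expect_identical(c1, c2)
  expect_equal(nrow(c1), 24)
  expect_equal(as.vector(table(c1$condition)), c(12L, 12L))
  expect_true(all(c1$baseline_latency_s <= 15))
  expect_true(all(c1$baseline_latency_s >= 0))
  # glucose lands on the diagnostic side under the default truncation
  expect_true(all(classify_glycemic_status(c1$glucose_mmol_L) ==
                    ifelse(c1$condition == "dm_pn", "diabetic", "nondiabetic")))

  # zero-variance spec collapses every control baseline onto the mean
  c0 <- generate_cohort(cohort_spec(
    baseline_sd_s = c(control = 0, dm_pn = 0), repeat_sd_s = 0, seed = 1))
  expect_true(all(c0$baseline_latency_s[c0$condition == "control"] == 6.4))
  expect_true(all(c0$baseline_latency_s[c0$condition == "dm_pn"] == 11.9))
})

test_that("baseline draws follow the condition's normal distribution", {
  # Monte-Carlo check of the generating distribution: a large cohort with the
  # censoring ceiling moved out of the way recovers the neuropathic mean
  # within 3 standard errors
  spec <- cohort_spec(n_per_arm = 2500, cutoff_s = 1000, repeat_sd_s = 0,
                      seed = 99)
  coh <- generate_cohort(spec)
  b <- coh$baseline_latency_s[coh$condition == "dm_pn"]
  expect_equal(length(b), 5000)
  expect_lt(abs(mean(b) - 11.9), 3 * 3.4 / sqrt(5000))
  b0 <- coh$baseline_latency_s[coh$condition == "control"]
  expect_lt(abs(mean(b0) - 6.4), 3.1 * 2.8 / sqrt(5000))
})

test_that("trajectories respect baseline, censoring and the clamp", {
  m <- list(mouse_id = "m1", baseline_latency_s = 6.4)
  p <- block_profile(10, 1, 110, noise_sd_s = 0)
  tr <- generate_trajectory(m, p, c(0, 10, 50, 109.99, 110, 200), cutoff_s = 15)
  expect_equal(tr$latency_s[1], 6.4)                       # baseline at t = 0
  expect_equal(compute_mpe(6.4, tr$latency_s[1], 15), 0)
  expect_equal(tr$latency_s[2], 15)                        # full block censors
  expect_true(tr$censored[2])
  expect_equal(compute_mpe(6.4, tr$latency_s[2], 15), 100)
  # %MPE crosses the 15% threshold exactly at the profile duration
  expect_gt(compute_mpe(6.4, tr$latency_s[4], 15), 15)
  expect_equal(compute_mpe(6.4, tr$latency_s[5], 15), 15, tolerance = 1e-6)

  # heavy noise never escapes [0, cutoff]
  set.seed(4)
  pn <- block_profile(10, 0.9, 110, noise_sd_s = 5)
  tr <- generate_trajectory(m, pn, seq(0, 260, by = 1.5), cutoff_s = 15)
  expect_true(all(tr$latency_s >= 0 & tr$latency_s <= 15))
  expect_identical(tr$censored, tr$latency_s == 15)
})

test_that("full study generation is seeded, scheduled and filtered", {
  s1 <- generate_study(seed = 2)
  s2 <- generate_study(seed = 2)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$cohort), 24)
  # neuropathic baselines reaching the cut-off were generated and excluded
  ex <- s1$cohort[s1$cohort$status == "excluded", ]
  expect_gt(nrow(ex), 0)
  expect_true(all(ex$condition == "dm_pn"))
  expect_true(all(ex$baseline_latency_s >= 15))
  # measurements only for included mice, on the BIBD grid
  inc <- s1$cohort$mouse_id[s1$cohort$status == "included"]
  expect_setequal(unique(s1$measurements$mouse_id), inc)
  expect_true(all(s1$measurements$t_min %% 1.5 == 0))
  expect_true(all(s1$measurements$latency_s >= 0 &
                    s1$measurements$latency_s <= 15))
  # each included mouse is measured once per window
  cnt <- table(s1$measurements$mouse_id)
  expect_true(all(cnt == 20))
})

test_that("study files round-trip through disk", {
  dir <- withr::local_tempdir()
  st <- generate_study(seed = 3)
  write_study(st, dir)
  expect_true(all(file.exists(file.path(
    dir, c("cohort.csv", "measurements.csv", "schedule.csv", "truth.json")))))
  coh <- utils::read.csv(file.path(dir, "cohort.csv"))
  expect_equal(nrow(coh), 24)
  expect_equal(coh$baseline_latency_s, st$cohort$baseline_latency_s,
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$arm_profiles$control.BH$duration_min, 106)
})
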