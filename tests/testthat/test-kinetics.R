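test_that("interval summaries average within half-open 13.5-min windows", {
  spec <- design_spec()
  mpe <- tibble::tibble(t_min = c(1, 5, 9, 13.5, 20), # 13.5 goes to window 1
                        mpe_pct = c(0, 50, 100, 80, 60))
  s <- summarize_intervals(mpe, spec)
  expect_equal(nrow(s), 20)
  expect_equal(s$midpoint_min, 0:19 * 13.5 + 6.75)
  expect_equal(s$mean_mpe_pct[1], 50)
  expect_equal(s$sd_mpe_pct[1], 50)   # sample SD of {0, 50, 100}
  expect_equal(s$n[2], 2L)
  expect_equal(s$mean_mpe_pct[2], 70)
  # empty windows keep their place with n = 0 and missing mean
  expect_true(all(s$n[3:20] == 0))
  expect_true(all(is.na(s$mean_mpe_pct[3:20])))
  # constant scores give SD 0
  s2 <- summarize_intervals(tibble::tibble(t_min = c(1, 2), mpe_pct = c(50, 50)),
                            spec)
  expect_equal(s2$sd_mpe_pct[1], 0)
  expect_error(summarize_intervals(tibble::tibble(t_min = 270, mpe_pct = 1),
                                   spec), "total_min")
})

test_that("interval summaries support precision weights", {
  spec <- design_spec()
  mpe <- tibble::tibble(t_min = c(1, 2), mpe_pct = c(0, 90))
  s <- summarize_intervals(mpe, spec, weights = c(1, 2))
  expect_equal(s$mean_mpe_pct[1], 60)
  expect_error(summarize_intervals(mpe, spec, weights = c(1, -1)), "weights")
})

test_that("cubic fit recovers exact cubics and matches the normal-equation oracle", {
  f <- function(t) 2 + t - 0.5 * t^2 + 0.01 * t^3
  d <- tibble::tibble(midpoint_min = seq(0.5, 12, length.out = 10),
                      mean_mpe_pct = f(seq(0.5, 12, length.out = 10)), n = 1L)
  fit <- fit_cubic(d)
  expect_equal(fit$coefficients, c(2, 1, -0.5, 0.01), tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(predict(fit, 7), f(7), tolerance = 1e-8)

  # brute-force normal-equation solve as independent oracle
  set.seed(31)
  for (i in 1:20) {
    k <- sample(5:12, 1)
    t <- sort(stats::runif(k, 0, 10))
    y <- stats::runif(k, 0, 100)
    X <- cbind(1, t, t^2, t^3)
    beta <- solve(crossprod(X), crossprod(X, y))
    fit <- fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = y, n = 1L))
    expect_equal(fit$coefficients, as.numeric(beta), tolerance = 1e-8)
    # R^2 against its definition
    r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
    expect_equal(fit$r_squared, r2, tolerance = 1e-8)
  }
})

test_that("cubic fit handles degenerate inputs", {
  d <- tibble::tibble(midpoint_min = 0:19 * 13.5 + 6.75,
                      mean_mpe_pct = rep(40, 20), n = 1L)
  expect_warning(fit <- fit_cubic(d), "zero-variance")
  expect_equal(fit$coefficients, c(40, 0, 0, 0), tolerance = 1e-10)
  expect_equal(fit$r_squared, 0)
  expect_error(fit_cubic(d[1:3, ]), "underdetermined cubic")
  # windows with n = 0 are not usable points
  d$n[5:20] <- 0L
  expect_equal(suppressWarnings(fit_cubic(d))$domain, c(6.75, 6.75 + 3 * 13.5))
})

test_that("R^2 is invariant to affine rescaling of time", {
  set.seed(8)
  t <- 0:19 * 13.5 + 6.75
  y <- 60 * exp(-t / 90) + stats::rnorm(20, 0, 5)
  d1 <- tibble::tibble(midpoint_min = t, mean_mpe_pct = y, n = 1L)
  d2 <- tibble::tibble(midpoint_min = 3 * t - 40, mean_mpe_pct = y, n = 1L)
  expect_equal(fit_cubic(d1)$r_squared, fit_cubic(d2)$r_squared,
               tolerance = 1e-8)
})

test_that("landmarks of an analytic cubic are found and classified", {
  # f(t) = t^3 - 6 t^2 + 9 t has f' = 3 (t - 1)(t - 3)
  f <- function(t) t^3 - 6 * t^2 + 9 * t
  t <- seq(0, 3.5, length.out = 12)
  fit <- fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = f(t), n = 1L))
  lm_ <- extract_landmarks(fit)
  peak <- lm_[lm_$kind == "onset_peak", ]
  expect_equal(peak$t_min, 1, tolerance = 1e-6)
  expect_equal(peak$mpe_pct, 4, tolerance = 1e-6)
  expect_false(peak$at_boundary)
  rel <- lm_[lm_$kind == "release_local_min", ]
  expect_equal(rel$t_min, 3, tolerance = 1e-6)
  expect_equal(rel$mpe_pct, 0, tolerance = 1e-6)

  # strictly increasing cubic: global max at the domain end, no interior points
  t <- seq(0.5, 3, length.out = 8)
  fit <- fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = t^3, n = 1L))
  lm_ <- extract_landmarks(fit)
  expect_equal(nrow(lm_), 1)
  expect_equal(lm_$t_min, 3, tolerance = 1e-6)
  expect_true(lm_$at_boundary)
})

test_that("landmark extraction agrees with a dense-grid scan", {
  set.seed(77)
  for (i in 1:25) {
    t <- seq(0, 30, length.out = 15)
    y <- stats::rnorm(1, 50, 20) + stats::rnorm(1, 0, 3) * t +
      stats::rnorm(1, 0, 0.3) * t^2 + stats::rnorm(1, 0, 0.02) * t^3 +
      stats::rnorm(15, 0, 4)
    fit <- fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = y, n = 1L))
    grid <- seq(0, 30, by = 1e-3)
    fg <- predict(fit, grid)
    lm_ <- extract_landmarks(fit)
    peak <- lm_[lm_$kind == "onset_peak", ]
    expect_lte(abs(peak$t_min - grid[which.max(fg)]), 1e-3)
    expect_equal(peak$mpe_pct, max(fg), tolerance = 1e-6)
  }
})

test_that("block duration on the fitted curve finds the sustained crossing", {
  # cubic strictly above 15% before t = 106 and below afterwards on [0, 270]
  f <- function(t) 15 + 2e-5 * (106 - t) * (t + 50) * (400 - t)
  t <- 0:19 * 13.5 + 6.75
  fit <- fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = f(t), n = 1L))
  d <- block_duration(fit, threshold_pct = 15)
  expect_s3_class(d, "block_duration")
  expect_equal(d$status, "ok")
  expect_equal(d$duration_min, 106, tolerance = 1e-6)

  # still above threshold at the end of the domain: censored
  g <- function(t) 20 + 0.05 * t
  fit <- fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = g(t), n = 1L))
  d <- block_duration(fit, 15)
  expect_equal(d$status, "censored_above_total")
  expect_true(is.na(d$duration_min))

  # peak never reaches the threshold
  fit <- suppressWarnings(
    fit_cubic(tibble::tibble(midpoint_min = t, mean_mpe_pct = rep(10, 20),
                             n = 1L)))
  expect_error(block_duration(fit, 15), "no block established")
})

test_that("block duration on interval means interpolates the crossing", {
  t <- 0:7 * 13.5 + 6.75
  m <- c(0, 40, 80, 60, 40, 20, 10, 5)
  s <- tibble::tibble(midpoint_min = t, mean_mpe_pct = m, n = 6L)
  d <- block_duration(s, 15, smooth = "none")
  # last window above 15% is 20 at t = 74.25; linear crossing 6.75 min later
  expect_equal(d$duration_min, 81)
  expect_equal(d$onset$t_min, t[3])

  # exactly linear decay: plain and refined isotonic paths agree exactly
  m2 <- c(95, 85, 75, 65, 55, 45, 35, 25, 15, 5, rep(0, 10))
  s2 <- tibble::tibble(midpoint_min = 0:19 * 13.5 + 6.75, mean_mpe_pct = m2,
                       n = 6L)
  d_none <- block_duration(s2, 15, smooth = "none")
  d_iso <- block_duration(s2, 15, smooth = "isotonic")
  expect_equal(d_none$duration_min, d_iso$duration_min, tolerance = 1e-9)

  # a spurious late re-block forces the plain crossing later, the isotonic
  # smoother restores the main release
  m3 <- c(80, 70, 50, 30, 10, 17, 5, 3, rep(0, 12))
  s3 <- tibble::tibble(midpoint_min = 0:19 * 13.5 + 6.75, mean_mpe_pct = m3,
                       n = 6L)
  expect_gt(block_duration(s3, 15, smooth = "none")$duration_min,
            block_duration(s3, 15, smooth = "isotonic")$duration_min)

  # means still above threshold at the last window: censored
  s4 <- tibble::tibble(midpoint_min = 0:19 * 13.5 + 6.75,
                       mean_mpe_pct = seq(90, 52, by = -2), n = 6L)
  expect_equal(block_duration(s4, 15)$status, "censored_above_total")
  # no block at all
  s5 <- tibble::tibble(midpoint_min = t, mean_mpe_pct = rep(5, 8), n = 6L)
  expect_error(block_duration(s5, 15), "no block established")
})

test_that("estimated duration is monotone in the generator's true duration", {
  set.seed(12)
  durations <- c(60, 90, 120, 150)
  est <- vapply(durations, function(dur) {
    prof <- block_profile(13.57, 0.7, dur, noise_sd_s = 0)
    estimate_arm_duration(prof)$duration_min
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("multi-segment fits recover piecewise-cubic time courses", {
  # two different cubics joined at t = 135; one global cubic cannot fit both
  f1 <- function(t) 80 - 0.4 * t + 0.002 * t^2
  f2 <- function(t) 10 + 0.3 * (t - 135) - 0.001 * (t - 135)^2
  t <- 0:19 * 13.5 + 6.75
  y <- ifelse(t < 135, f1(t), f2(t))
  s <- tibble::tibble(midpoint_min = t, mean_mpe_pct = y, n = 6L)
  segs <- fit_cubic_segments(s, breaks = 135)
  expect_length(segs, 2)
  expect_lt(segs[[1]]$domain[2], 135)
  expect_equal(segs[[1]]$fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(segs[[2]]$fit$r_squared, 1, tolerance = 1e-9)
  expect_lt(fit_cubic(s)$r_squared, 0.999)  # single cubic cannot be exact
  expect_equal(predict(segs[[2]]$fit, 200), f2(200), tolerance = 1e-6)
  expect_error(fit_cubic_segments(s, breaks = c(30, 20)), "strictly")
})
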