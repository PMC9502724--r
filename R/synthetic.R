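#' Block intensity profile for trajectory simulation
#'
#' Describes the latent intensity of a sensory block as a fraction of the
#' baseline-to-cutoff latency gap: a rise from 0 to `peak_intensity` at
#' `onset_min`, an optional mid-course partial release (`release_dip`) with
#' optional re-deepening (`rebound`), then a decay calibrated so the
#' intensity crosses 0.15 (the diminished-block threshold on the intensity
#' scale) exactly at `duration_min`. Segments are joined with cosine easing,
#' giving a smooth, phenomenological shape rather than a mechanistic
#' pharmacokinetic model; single-release profiles emulate plain bupivacaine
#' kinetics, dip-plus-rebound profiles the bimodal release of the liposomal
#' formulation.
#'
#' @param onset_min Minutes from injection to peak intensity.
#' @param peak_intensity Peak intensity in (0, 1\].
#' @param duration_min Minutes from injection until the intensity decays
#'   below 0.15; may exceed the study horizon (the block is then censored).
#' @param release_dip Optional `c(t_min, intensity)` for a partial mid-course
#'   release, strictly between `onset_min` and `duration_min`.
#' @param rebound If `TRUE` (requires `release_dip`), the intensity
#'   re-deepens after the dip before the final decay.
#' @param rebound_time_min,rebound_intensity Optional rebound knot; default
#'   to the midpoint of dip and duration, and 90% of `peak_intensity`.
#' @param noise_sd_s SD (seconds) of additive Gaussian observation noise on
#'   the latency scale.
#'
#' @return An object of class `"block_profile"`.
#' @examples
#' block_profile(13.57, 0.70, 106)
#' @export
block_profile <- function(onset_min, peak_intensity, duration_min,
                          release_dip = NULL, rebound = FALSE,
                          rebound_time_min = NULL, rebound_intensity = NULL,
                          noise_sd_s = 0.5) {
  stopifnot(onset_min > 0, onset_min < duration_min,
            peak_intensity > 0, peak_intensity <= 1, noise_sd_s >= 0)
  if (!is.null(release_dip)) {
    stopifnot(length(release_dip) == 2,
              release_dip[1] > onset_min, release_dip[1] < duration_min,
              release_dip[2] > 0, release_dip[2] <= peak_intensity)
  } else if (rebound) {
    stop("rebound requires a release_dip", call. = FALSE)
  }
  if (rebound) {
    if (is.null(rebound_time_min)) {
      rebound_time_min <- (release_dip[1] + duration_min) / 2
    }
    if (is.null(rebound_intensity)) rebound_intensity <- 0.9 * peak_intensity
    stopifnot(rebound_time_min > release_dip[1],
              rebound_time_min < duration_min,
              rebound_intensity > 0, rebound_intensity <= 1)
  }
  structure(list(onset_min = onset_min, peak_intensity = peak_intensity,
                 duration_min = duration_min, release_dip = release_dip,
                 rebound = rebound, rebound_time_min = rebound_time_min,
                 rebound_intensity = rebound_intensity,
                 noise_sd_s = noise_sd_s),
            class = "block_profile")
}

# cosine easing between (t0, v0) and (t1, v1); constant outside
ease <- function(t, t0, t1, v0, v1) {
  u <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
  v0 + (v1 - v0) * (1 - cos(pi * u)) / 2
}

#' Evaluate a block intensity profile
#'
#' Returns the noise-free latent intensity `g(t)` of a [block_profile()] as
#' a fraction of the baseline-to-cutoff gap. By construction `g` crosses
#' `threshold_frac` (default 0.15) downward exactly at the profile's
#' `duration_min`, provided the segment it decays from starts above the
#' threshold.
#'
#' @param t Times in minutes (vectorized).
#' @param profile A [block_profile()].
#' @param threshold_frac Intensity value pinned at `duration_min`.
#' @return Intensities in \[0, 1\].
#' @export
block_intensity <- function(t, profile, threshold_frac = 0.15) {
  stopifnot(inherits(profile, "block_profile"))
  p <- profile
  # knot the final decay starts from
  if (is.null(p$release_dip)) {
    ts <- p$onset_min; vs <- p$peak_intensity
  } else if (p$rebound) {
    ts <- p$rebound_time_min; vs <- p$rebound_intensity
  } else {
    ts <- p$release_dip[1]; vs <- p$release_dip[2]
  }
  # end of the decay, placed so g(duration_min) == threshold_frac
  if (vs > threshold_frac) {
    u <- acos(2 * threshold_frac / vs - 1) / pi
    t_end <- ts + (p$duration_min - ts) / u
  } else {
    t_end <- p$duration_min
  }
  g <- numeric(length(t))
  seg <- function(lo, hi) t >= lo & t < hi
  g[seg(0, p$onset_min)] <- ease(t[seg(0, p$onset_min)], 0, p$onset_min,
                                 0, p$peak_intensity)
  if (!is.null(p$release_dip)) {
    td <- p$release_dip[1]; vd <- p$release_dip[2]
    i <- seg(p$onset_min, td)
    g[i] <- ease(t[i], p$onset_min, td, p$peak_intensity, vd)
    if (p$rebound) {
      i <- seg(td, p$rebound_time_min)
      g[i] <- ease(t[i], td, p$rebound_time_min, vd, p$rebound_intensity)
    }
  } else if (p$onset_min < ts) {
    i <- seg(p$onset_min, ts)
    g[i] <- ease(t[i], p$onset_min, ts, p$peak_intensity, vs)
  }
  i <- seg(ts, t_end)
  g[i] <- ease(t[i], ts, t_end, vs, 0)
  g[t < 0 | t >= t_end] <- 0
  g
}

#' Synthetic cohort specification
#'
#' Parameters of the simulated study population: per-condition normal
#' distributions for plantar and tail-flick baseline latency, fasting
#' glucose and body weight, with defaults matching the summary statistics of
#' the emulated study (control plantar baseline 6.4 s, SD 2.8; neuropathic
#' 11.9 s, SD 3.4; glucose 7.6/0.9 vs 24.6/5.4 mmol/L; post-induction weight
#' 28.5/2.2 vs 21.3/2.4 g; tail flick 1.9/0.4 vs 2.2/0.4 s).
#'
#' @param n_per_arm Mice per (condition x treatment) arm.
#' @param baseline_mean_s,baseline_sd_s Named numeric vectors
#'   (`control`, `dm_pn`): plantar baseline distribution in seconds.
#' @param tail_flick_mean_s,tail_flick_sd_s Tail-flick baseline distribution.
#' @param glucose_mean,glucose_sd Fasting glucose distribution (mmol/L).
#' @param weight_mean_g,weight_sd_g Body-weight distribution (g).
#' @param cutoff_s,tail_flick_cutoff_s Assay cut-offs (latency draws are
#'   censored there).
#' @param repeat_sd_s Within-mouse SD of the three baseline repeats.
#' @param truncate_glucose If `TRUE` (default), glucose draws are resampled
#'   onto the diagnostic side of the condition's threshold (> 23 mmol/L for
#'   `dm_pn`, < 8 for `control`), emulating a cohort whose diabetic status
#'   was confirmed before enrollment.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#'
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_arm = 6,
                        baseline_mean_s = c(control = 6.4, dm_pn = 11.9),
                        baseline_sd_s = c(control = 2.8, dm_pn = 3.4),
                        tail_flick_mean_s = c(control = 1.9, dm_pn = 2.2),
                        tail_flick_sd_s = c(control = 0.4, dm_pn = 0.4),
                        glucose_mean = c(control = 7.6, dm_pn = 24.6),
                        glucose_sd = c(control = 0.9, dm_pn = 5.4),
                        weight_mean_g = c(control = 28.5, dm_pn = 21.3),
                        weight_sd_g = c(control = 2.2, dm_pn = 2.4),
                        cutoff_s = 15, tail_flick_cutoff_s = 4,
                        repeat_sd_s = 0.4, truncate_glucose = TRUE,
                        seed = NULL) {
  conds <- c("control", "dm_pn")
  for (v in list(baseline_mean_s, baseline_sd_s, tail_flick_mean_s,
                 tail_flick_sd_s, glucose_mean, glucose_sd,
                 weight_mean_g, weight_sd_g)) {
    stopifnot(all(conds %in% names(v)))
  }
  stopifnot(n_per_arm >= 1, cutoff_s > 0, tail_flick_cutoff_s > 0,
            repeat_sd_s >= 0,
            all(baseline_sd_s >= 0), all(glucose_sd >= 0),
            all(weight_sd_g >= 0), all(tail_flick_sd_s >= 0))
  structure(list(
    n_per_arm = as.integer(n_per_arm),
    baseline_mean_s = baseline_mean_s, baseline_sd_s = baseline_sd_s,
    tail_flick_mean_s = tail_flick_mean_s, tail_flick_sd_s = tail_flick_sd_s,
    glucose_mean = glucose_mean, glucose_sd = glucose_sd,
    weight_mean_g = weight_mean_g, weight_sd_g = weight_sd_g,
    cutoff_s = cutoff_s, tail_flick_cutoff_s = tail_flick_cutoff_s,
    repeat_sd_s = repeat_sd_s, truncate_glucose = truncate_glucose,
    seed = seed
  ), class = "cohort_spec")
}

# draw from N(mean, sd) with optional one-sided truncation, by rejection
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(mean, n))
  out <- stats::rnorm(n, mean, sd)
  bad <- out <= lower | out >= upper
  while (any(bad)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- out <= lower | out >= upper
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws one mouse table for the four study arms (condition control/dm_pn x
#' treatment BH/LB). Plantar baselines are drawn per mouse from the
#' condition's normal distribution, expanded into three within-mouse repeats,
#' clamped to `[0, cutoff_s]` (a repeat that reaches the cut-off is recorded
#' at the cut-off, exactly as a censored reading would be), and summarized
#' with [trimmed_baseline()]. Draws at or above the cut-off are deliberately
#' retained - in the neuropathic arms they occur at a realistic rate and give
#' the downstream exclusion filter work to do. Glucose is drawn per condition
#' (truncated to the diagnostic side by default, see [cohort_spec()]).
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per mouse: `mouse_id`, `condition`,
#'   `treatment`, `glucose_mmol_L`, `weight_g`, `baseline_rep1_s` ...
#'   `baseline_rep3_s`, `baseline_latency_s` (trimmed), `tail_flick_latency_s`,
#'   `status`, `exclusion_reason`. Deterministic given `spec$seed`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  arms <- expand.grid(condition = c("control", "dm_pn"),
                      treatment = c("BH", "LB"),
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(arms))
  for (k in seq_len(nrow(arms))) {
    cond <- arms$condition[k]; trt <- arms$treatment[k]
    n <- spec$n_per_arm
    latent <- rnorm_trunc(n, spec$baseline_mean_s[[cond]],
                          spec$baseline_sd_s[[cond]], lower = 0)
    reps <- matrix(pmin(pmax(
      rep(latent, each = 3) + stats::rnorm(3 * n, 0, spec$repeat_sd_s),
      0), spec$cutoff_s), nrow = 3)
    tf <- pmin(rnorm_trunc(n, spec$tail_flick_mean_s[[cond]],
                           spec$tail_flick_sd_s[[cond]], lower = 0),
               spec$tail_flick_cutoff_s)
    glu <- if (spec$truncate_glucose) {
      if (cond == "dm_pn") {
        rnorm_trunc(n, spec$glucose_mean[[cond]], spec$glucose_sd[[cond]],
                    lower = 23)
      } else {
        rnorm_trunc(n, spec$glucose_mean[[cond]], spec$glucose_sd[[cond]],
                    lower = 0, upper = 8)
      }
    } else {
      rnorm_trunc(n, spec$glucose_mean[[cond]], spec$glucose_sd[[cond]],
                  lower = 0)
    }
    wt <- rnorm_trunc(n, spec$weight_mean_g[[cond]], spec$weight_sd_g[[cond]],
                      lower = 0)
    rows[[k]] <- tibble::tibble(
      mouse_id = sprintf("%s-%s-%02d", ifelse(cond == "control", "C", "D"),
                         trt, seq_len(n)),
      condition = cond, treatment = trt,
      glucose_mmol_L = glu, weight_g = wt,
      baseline_rep1_s = reps[1, ], baseline_rep2_s = reps[2, ],
      baseline_rep3_s = reps[3, ],
      baseline_latency_s = apply(reps, 2, trimmed_baseline),
      tail_flick_latency_s = tf,
      status = "candidate", exclusion_reason = NA_character_
    )
  }
  dplyr::bind_rows(rows)
}

#' Simulate a censored latency trajectory for one mouse
#'
#' Latency at time `t` is
#' `clamp(baseline + g(t) * (cutoff - baseline) + noise, 0, cutoff)`, where
#' `g` is the profile's latent intensity; the `censored` flag is set whenever
#' the clamp binds at the cut-off. With zero noise the %MPE of the trajectory
#' equals `100 * g(t)` exactly.
#'
#' @param mouse A one-row data frame (or list) with `mouse_id` and
#'   `baseline_latency_s` (must be below `cutoff_s`).
#' @param profile A [block_profile()].
#' @param schedule_times Sorted measurement times in minutes.
#' @param cutoff_s Assay cut-off in seconds.
#' @return A tibble with columns `mouse_id`, `t_min`, `latency_s`, `censored`.
#' @export
generate_trajectory <- function(mouse, profile, schedule_times,
                                cutoff_s = 15) {
  stopifnot(inherits(profile, "block_profile"))
  b <- mouse$baseline_latency_s
  stopifnot(length(b) == 1, b >= 0, b < cutoff_s,
            !is.unsorted(schedule_times), all(schedule_times >= 0))
  g <- block_intensity(schedule_times, profile)
  lat <- b + g * (cutoff_s - b)
  if (profile$noise_sd_s > 0) {
    lat <- lat + stats::rnorm(length(lat), 0, profile$noise_sd_s)
  }
  lat <- pmin(pmax(lat, 0), cutoff_s)
  tibble::tibble(mouse_id = mouse$mouse_id, t_min = schedule_times,
                 latency_s = lat, censored = lat >= cutoff_s - 1e-12)
}

#' Default per-arm block profiles
#'
#' Phenomenological profiles for the four study arms, keyed
#' `"<condition>.<treatment>"`: plain bupivacaine (BH) arms are
#' single-release with onsets near 13-14 min and durations of 106 min
#' (control) and 117.1 min (neuropathic); liposomal bupivacaine (LB) in
#' controls is single-release with full peak effect and 118-min duration,
#' while in the neuropathic arm it shows a partial release (dip to intensity
#' 0.565 at 92.8 min) followed by a rebound, with the final decay crossing
#' the diminished threshold only after the 270-min study horizon.
#'
#' @param noise_sd_s Observation noise SD in seconds, applied to all arms.
#' @return Named list of [block_profile()] objects.
#' @export
default_arm_profiles <- function(noise_sd_s = 0.5) {
  list(
    control.BH = block_profile(13.57, 0.700, 106, noise_sd_s = noise_sd_s),
    dm_pn.BH   = block_profile(13.20, 0.585, 117.1, noise_sd_s = noise_sd_s),
    control.LB = block_profile(14.80, 1.000, 118, noise_sd_s = noise_sd_s),
    dm_pn.LB   = block_profile(12.10, 0.931, 285,
                               release_dip = c(92.8, 0.565), rebound = TRUE,
                               noise_sd_s = noise_sd_s)
  )
}

#' Generate a complete synthetic study
#'
#' End-to-end simulator: draws a cohort, applies the sensory exclusion
#' filter, schedules the included mice of each arm on the balanced
#' incomplete block grid, and simulates a censored latency trajectory per
#' mouse. All randomness flows through a single seeded generator, so
#' identical seeds give identical studies.
#'
#' @param arm_profiles Named list of [block_profile()]s keyed
#'   `"<condition>.<treatment>"`; see [default_arm_profiles()].
#' @param cohort A [cohort_spec()] (its own `seed` is ignored here).
#' @param design A [design_spec()] whose `n_mice_per_group` is adapted per
#'   arm to the number of included mice.
#' @param seed Integer seed for the whole study.
#'
#' @return A list with `cohort` (all mice, with inclusion status),
#'   `measurements` (`mouse_id`, `t_min`, `latency_s`, `censored` for
#'   included mice only), `schedule`, and `truth` (the arm profiles and
#'   seed, for parameter-recovery checks).
#' @export
generate_study <- function(arm_profiles = default_arm_profiles(),
                           cohort = cohort_spec(),
                           design = design_spec(), seed = 1) {
  set.seed(seed)
  cohort$seed <- NULL
  coh <- generate_cohort(cohort)
  parts <- apply_sensory_exclusions(coh, assay_config("plantar"))
  coh_all <- dplyr::bind_rows(parts$included, parts$excluded)
  coh_all <- coh_all[order(coh_all$mouse_id), , drop = FALSE]
  meas <- list(); sched <- list()
  for (key in names(arm_profiles)) {
    cond_trt <- strsplit(key, ".", fixed = TRUE)[[1]]
    ids <- parts$included$mouse_id[
      parts$included$condition == cond_trt[1] &
        parts$included$treatment == cond_trt[2]]
    if (length(ids) < 1) next
    ds <- design_spec(length(ids), design$slot_spacing_min,
                      design$window_min, design$total_min, seed = NULL)
    sc <- generate_schedule(ds, ids)
    sched[[key]] <- dplyr::mutate(sc, condition = cond_trt[1],
                                  treatment = cond_trt[2])
    for (id in ids) {
      mouse <- parts$included[parts$included$mouse_id == id, ]
      times <- sc$slot_time_min[sc$mouse_id == id]
      meas[[id]] <- generate_trajectory(mouse, arm_profiles[[key]], times,
                                        cutoff_s = cohort$cutoff_s)
    }
  }
  list(cohort = coh_all,
       measurements = dplyr::bind_rows(meas),
       schedule = dplyr::bind_rows(sched),
       truth = list(arm_profiles = arm_profiles, seed = seed))
}

#' Write a synthetic study to disk
#'
#' Emits `cohort.csv`, `measurements.csv`, `schedule.csv` and `truth.json`
#' (the true profile parameters, for recovery tests) into a directory.
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(study$cohort, file.path(dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(study$measurements, file.path(dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(study$schedule, file.path(dir, "schedule.csv"),
                   row.names = FALSE)
  truth <- lapply(study$truth$arm_profiles, function(p) {
    p <- unclass(p)
    p[!vapply(p, is.null, logical(1))]
  })
  jsonlite::write_json(list(seed = study$truth$seed, arm_profiles = truth),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
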