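# Shared fixture builders; everything is generated in code at test time.

# cohort of n mice with given trimmed baselines
make_cohort <- function(baselines, condition = "dm_pn", treatment = "BH") {
  tibble::tibble(
    mouse_id = sprintf("m%02d", seq_along(baselines)),
    condition = condition,
    treatment = treatment,
    baseline_latency_s = baselines
  )
}

# %MPE table of one simulated arm: n mice on the default BIBD grid, latency
# trajectories from `profile`, scored against each mouse's own baseline.
# Baselines are drawn from the control condition (mean 6.4, SD 2.8 s),
# censored at the cut-off; mice at the cut-off are dropped, as the exclusion
# filter would do.
simulate_arm_mpe <- function(profile, n = 6, cutoff = 15,
                             baseline_mean = 6.4, baseline_sd = 2.8) {
  b <- numeric(0)
  while (length(b) < n) {
    d <- stats::rnorm(n, baseline_mean, baseline_sd)
    b <- c(b, d[d > 0])
  }
  b <- pmin(b[1:n], cutoff)
  keep <- b < cutoff
  ids <- sprintf("m%02d", seq_len(n))[keep]
  b <- b[keep]
  sch <- generate_schedule(design_spec(length(ids), seed = NULL), ids)
  dplyr::bind_rows(lapply(seq_along(ids), function(i) {
    times <- sch$slot_time_min[sch$mouse_id == ids[i]]
    tr <- generate_trajectory(
      list(mouse_id = ids[i], baseline_latency_s = b[i]), profile, times,
      cutoff_s = cutoff)
    tibble::tibble(
      mouse_id = ids[i], t_min = tr$t_min,
      mpe_pct = compute_mpe(b[i], tr$latency_s, cutoff),
      baseline_latency_s = b[i])
  }))
}

# duration estimate for one simulated single-release arm, using the
# precision-weighted isotonic estimator (the pipeline default)
estimate_arm_duration <- function(profile, n = 6, cutoff = 15) {
  mpe <- simulate_arm_mpe(profile, n = n, cutoff = cutoff)
  wsumm <- summarize_intervals(
    mpe, design_spec(), weights = (cutoff - mpe$baseline_latency_s)^2)
  block_duration(wsumm, 15, smooth = "isotonic")
}

# exhaustive pairwise concordance AUC (independent oracle for ROC)
auc_by_pairs <- function(pos, neg) {
  mean(outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q)))
}
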