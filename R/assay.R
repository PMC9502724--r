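#' Assay configuration for thermal-latency testing
#'
#' Bundles the constants of a radiant-heat withdrawal assay: the censoring
#' ceiling ("cut-off") after which the stimulus is removed to prevent tissue
#' damage and secondary hyperalgesia, and the nominal infrared intensity of
#' the heat source. The plantar (hind-paw) assay uses a 15 s cut-off at 50%
#' intensity; the tail-flick assay a 4 s cut-off at 40% intensity.
#'
#' @param assay Either `"plantar"` or `"tail_flick"`.
#'
#' @return An object of class `"assay_config"`: a list with elements
#'   `assay_name`, `cutoff_s` (seconds) and `intensity_pct`.
#' @examples
#' assay_config("plantar")$cutoff_s
#' assay_config("tail_flick")$cutoff_s
#' @export
assay_config <- function(assay = c("plantar", "tail_flick")) {
  assay <- match.arg(assay)
  cfg <- switch(assay,
    plantar    = list(assay_name = "plantar", cutoff_s = 15, intensity_pct = 50),
    tail_flick = list(assay_name = "tail_flick", cutoff_s = 4, intensity_pct = 40)
  )
  structure(cfg, class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf("<assay_config> %s: cut-off %g s, intensity %g%%\n",
              x$assay_name, x$cutoff_s, x$intensity_pct))
  invisible(x)
}

#' Trimmed mean of repeated baseline latencies
#'
#' Baseline (pre-injection) latency is measured as repeated heat-stimulus
#' trials (the protocol uses three repeats at 5-minute intervals). The
#' summary value is the mean of the repeats that lie within one sample
#' standard deviation of the mean of all repeats; the boundary is inclusive,
#' so with two or more repeats at least one value always survives the trim.
#' The trim is applied once, not iterated.
#'
#' @param latencies Numeric vector of latency repeats in seconds
#'   (length >= 2, finite, non-negative).
#'
#' @return The trimmed mean, in seconds.
#' @examples
#' trimmed_baseline(c(4, 6, 20)) # 20 is > 1 SD from the mean and is dropped
#' trimmed_baseline(c(6.1, 6.7, 6.4))
#' @export
trimmed_baseline <- function(latencies) {
  if (length(latencies) < 2) {
    stop("insufficient baseline repeats (need at least 2 values)", call. = FALSE)
  }
  if (!is.numeric(latencies) || !all(is.finite(latencies)) || any(latencies < 0)) {
    stop("baseline latencies must be finite non-negative numbers", call. = FALSE)
  }
  m <- mean(latencies)
  s <- stats::sd(latencies)
  # inclusive boundary, with a relative guard against floating-point ties
  keep <- abs(latencies - m) <= s * (1 + 1e-10) + 1e-12
  stopifnot("all baseline values trimmed" = any(keep))
  mean(latencies[keep])
}

#' Percent maximal possible effect (%MPE)
#'
#' Normalizes a post-injection latency against the animal's own baseline and
#' the assay cut-off:
#' \deqn{\%MPE = 100 \times \frac{post - pre}{cutoff - pre}}
#' A censored post-injection reading (latency at the cut-off) therefore maps
#' to 100%. Raw values are clamped to \[0, 100\]: readings in the
#' hyperalgesic direction (post < pre) are scored as 0, since the score is
#' interpreted as block intensity.
#'
#' @param pre Baseline latency in seconds (must be strictly below `cutoff`;
#'   animals at or above the cut-off are excluded upstream).
#' @param post Post-injection latency in seconds, in `[0, cutoff]`.
#' @param cutoff Assay cut-off in seconds.
#'
#' @return Numeric vector of %MPE values in \[0, 100\]. Arguments are
#'   recycled to a common length.
#' @examples
#' compute_mpe(6.4, 15, 15)  # censored reading: full effect
#' compute_mpe(5, 10, 15)    # halfway between baseline and cut-off
#' @export
compute_mpe <- function(pre, post, cutoff) {
  n <- max(length(pre), length(post), length(cutoff))
  pre <- rep_len(pre, n); post <- rep_len(post, n); cutoff <- rep_len(cutoff, n)
  if (any(!is.finite(pre)) || any(!is.finite(post)) || any(!is.finite(cutoff))) {
    stop("latencies and cutoff must be finite", call. = FALSE)
  }
  if (any(pre >= cutoff)) {
    stop("baseline at or above cutoff - animal must be excluded upstream",
         call. = FALSE)
  }
  if (any(pre < 0) || any(post < 0) || any(post > cutoff + 1e-9)) {
    stop("latencies must satisfy 0 <= pre < cutoff and 0 <= post <= cutoff",
         call. = FALSE)
  }
  pmin(pmax(100 * (post - pre) / (cutoff - pre), 0), 100)
}

#' Classify glycemic status from fasting glucose
#'
#' Applies the study inclusion thresholds for streptozotocin-induced type 1
#' diabetes: fasting glucose above 23 mmol/L is diabetic, below 8 mmol/L is
#' non-diabetic. Both inequalities are strict; values in the \[8, 23\] gap are
#' flagged `"indeterminate"` and belong to neither study arm.
#'
#' @param fasting_glucose_mmol_L Numeric vector of fasting glucose
#'   concentrations in mmol/L (finite, non-negative).
#'
#' @return Character vector with values `"diabetic"`, `"nondiabetic"` or
#'   `"indeterminate"`.
#' @examples
#' classify_glycemic_status(c(25.3, 7.6, 23))
#' @export
classify_glycemic_status <- function(fasting_glucose_mmol_L) {
  g <- fasting_glucose_mmol_L
  if (!is.numeric(g) || any(!is.finite(g)) || any(g < 0)) {
    stop("fasting glucose must be finite and non-negative", call. = FALSE)
  }
  ifelse(g > 23, "diabetic", ifelse(g < 8, "nondiabetic", "indeterminate"))
}

#' Exclude animals whose neuropathy reaches the assay cut-off
#'
#' An animal whose trimmed baseline latency is at or above the cut-off has a
#' non-positive %MPE denominator and a degree of neuropathy that the assay
#' cannot quantify; such records are moved to the excluded set with reason
#' `"neuropathy >= cutoff"`. The partition is exhaustive and disjoint.
#'
#' @param cohort A data frame with at least columns `mouse_id` and
#'   `baseline_latency_s`. A `status`/`exclusion_reason` pair is added or
#'   updated in place.
#' @param config An [assay_config()] providing the cut-off.
#'
#' @return A list with tibbles `included` and `excluded`.
#' @examples
#' coh <- tibble::tibble(mouse_id = c("m1", "m2"), baseline_latency_s = c(6, 15))
#' apply_sensory_exclusions(coh, assay_config("plantar"))$excluded
#' @export
apply_sensory_exclusions <- function(cohort, config = assay_config("plantar")) {
  stopifnot(is.data.frame(cohort),
            all(c("mouse_id", "baseline_latency_s") %in% names(cohort)))
  cohort <- tibble::as_tibble(cohort)
  if (!"status" %in% names(cohort)) cohort$status <- "included"
  if (!"exclusion_reason" %in% names(cohort)) cohort$exclusion_reason <- NA_character_
  out <- cohort$baseline_latency_s >= config$cutoff_s
  cohort$status[out] <- "excluded"
  cohort$exclusion_reason[out] <- "neuropathy >= cutoff"
  cohort$status[!out & cohort$status != "excluded"] <- "included"
  list(included = cohort[cohort$status == "included", , drop = FALSE],
       excluded = cohort[cohort$status == "excluded", , drop = FALSE])
}

#' Per-measurement %MPE table
#'
#' Joins post-injection latency measurements to each animal's trimmed
#' baseline and scores every reading as %MPE. Only animals present in the
#' cohort table are scored; the cohort should already have been filtered with
#' [apply_sensory_exclusions()].
#'
#' @param measurements Data frame with columns `mouse_id`, `t_min`,
#'   `latency_s`.
#' @param cohort Data frame with columns `mouse_id`, `baseline_latency_s`.
#' @param config An [assay_config()].
#'
#' @return A tibble with columns `mouse_id`, `t_min`, `mpe_pct` and
#'   `baseline_latency_s` (kept so downstream steps can form
#'   precision weights; see [summarize_intervals()]).
#' @export
compute_mpe_table <- function(measurements, cohort,
                              config = assay_config("plantar")) {
  stopifnot(all(c("mouse_id", "t_min", "latency_s") %in% names(measurements)),
            all(c("mouse_id", "baseline_latency_s") %in% names(cohort)))
  base <- cohort[, c("mouse_id", "baseline_latency_s")]
  m <- dplyr::inner_join(tibble::as_tibble(measurements), base, by = "mouse_id")
  tibble::tibble(
    mouse_id = m$mouse_id,
    t_min = m$t_min,
    mpe_pct = compute_mpe(m$baseline_latency_s, m$latency_s, config$cutoff_s),
    baseline_latency_s = m$baseline_latency_s
  )
}
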