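#' Pipeline configuration
#'
#' Collects every analysis choice the end-to-end pipeline depends on, so a
#' report is a pure function of (inputs, config).
#'
#' @param assay An [assay_config()]; only the plantar assay feeds the
#'   block-duration pipeline.
#' @param design A [design_spec()] describing the measurement grid.
#' @param mpe_threshold_pct Diminished-block threshold in %MPE, in (0, 100).
#' @param fit_mode How block duration is located: `"cubic"` (crossing of the
#'   fitted cubic), `"piecewise"` (piecewise-linear interval means) or
#'   `"isotonic"` (monotone-smoothed interval means; default, see the
#'   methods vignette for the rationale).
#' @param roc_aggregation Observation unit for the ROC models:
#'   `"window-mean"` (default: one score per scheduling window, i.e. 20
#'   values per arm under the default grid), `"measurement"` or
#'   `"mouse-mean"`.
#' @param t_test_variant `"pooled"` or `"welch"` for cohort contrasts.
#' @param output_dir If non-`NULL`, [run_pipeline()] writes `report.json`
#'   and CSV tables there.
#'
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(assay = assay_config("plantar"),
                            design = design_spec(),
                            mpe_threshold_pct = 15,
                            fit_mode = c("isotonic", "piecewise", "cubic"),
                            roc_aggregation = c("window-mean", "measurement",
                                                "mouse-mean"),
                            t_test_variant = c("pooled", "welch"),
                            output_dir = NULL) {
  stopifnot(inherits(assay, "assay_config"), inherits(design, "design_spec"),
            mpe_threshold_pct > 0, mpe_threshold_pct < 100)
  structure(list(
    assay = assay, design = design,
    mpe_threshold_pct = mpe_threshold_pct,
    fit_mode = match.arg(fit_mode),
    roc_aggregation = match.arg(roc_aggregation),
    t_test_variant = match.arg(t_test_variant),
    output_dir = output_dir
  ), class = "pipeline_config")
}

read_table_checked <- function(x, required, what) {
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop(sprintf("%s file not found: %s", what, x),
                              call. = FALSE)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x) || nrow(x) == 0) {
    stop(sprintf("schema error: %s table is empty", what), call. = FALSE)
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("schema error: %s table lacks column(s) %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  tibble::as_tibble(x)
}

arm_scores <- function(mpe, cohort, aggregation, spec) {
  # one score vector per aggregation unit, within one study arm
  switch(aggregation,
    "measurement" = mpe$mpe_pct,
    "window-mean" = {
      s <- summarize_intervals(mpe, spec)
      s$mean_mpe_pct[s$n > 0]
    },
    "mouse-mean" = {
      vapply(split(mpe$mpe_pct, mpe$mouse_id), mean, numeric(1))
    })
}

#' Run the full nerve-block analysis pipeline
#'
#' Orchestrates the analysis end-to-end: schema validation, glycemic and
#' sensory exclusions, per-measurement %MPE scoring, per-arm interval
#' summaries, cubic fits with landmark extraction, block-duration estimation
#' (with censoring at the study horizon), the two pairs of ROC models with
#' their chi-squared area contrasts, and cohort-characteristic t-tests.
#'
#' The ROC models mirror the study's design: the *treatment-wise* pair fits
#' one model per anesthetic discriminating neuropathy condition from %MPE
#' (positive class `dm_pn`), the *condition-wise* pair one model per
#' condition discriminating anesthetic (positive class `LB`), each pair
#' compared with [compare_auc()].
#'
#' @param cohort Cohort table or CSV path; requires columns `mouse_id`,
#'   `condition`, `treatment`, `glucose_mmol_L` and either
#'   `baseline_latency_s` or the three `baseline_rep*_s` columns.
#' @param measurements Measurement table or CSV path with `mouse_id`,
#'   `t_min`, `latency_s`.
#' @param config A [pipeline_config()].
#'
#' @return An object of class `"study_report"`: a list with `exclusions`,
#'   `arms` (per-arm summaries, fit, landmarks, duration), `roc`,
#'   `comparisons`, `cohort_tests`, and the `config` in effect. Written to
#'   `config$output_dir` as JSON/CSV when that is set.
#' @export
run_pipeline <- function(cohort, measurements, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- read_table_checked(
    cohort, c("mouse_id", "condition", "treatment", "glucose_mmol_L"),
    "cohort")
  measurements <- read_table_checked(
    measurements, c("mouse_id", "t_min", "latency_s"), "measurements")

  if (!"baseline_latency_s" %in% names(cohort)) {
    reps <- paste0("baseline_rep", 1:3, "_s")
    if (!all(reps %in% names(cohort))) {
      stop("schema error: cohort table needs baseline_latency_s or baseline repeat columns",
           call. = FALSE)
    }
    cohort$baseline_latency_s <- apply(
      as.matrix(cohort[, reps]), 1, trimmed_baseline)
  }

  # glycemic consistency filter, then sensory (cut-off) filter
  cohort$glycemic_status <- classify_glycemic_status(cohort$glucose_mmol_L)
  expected <- ifelse(cohort$condition == "dm_pn", "diabetic", "nondiabetic")
  bad_gly <- cohort$glycemic_status != expected
  cohort$status <- ifelse(bad_gly, "excluded", "included")
  cohort$exclusion_reason <- ifelse(
    bad_gly, paste0("glycemic status ", cohort$glycemic_status,
                    " inconsistent with condition"), NA_character_)
  parts <- apply_sensory_exclusions(cohort[!bad_gly, , drop = FALSE],
                                    config$assay)
  included <- parts$included
  excluded <- dplyr::bind_rows(cohort[bad_gly, , drop = FALSE],
                               parts$excluded)

  mpe <- compute_mpe_table(measurements, included, config$assay)
  mpe <- dplyr::inner_join(
    mpe, included[, c("mouse_id", "condition", "treatment")], by = "mouse_id")

  arm_keys <- unique(paste(included$condition, included$treatment, sep = "."))
  arms <- list()
  for (key in sort(arm_keys)) {
    ct <- strsplit(key, ".", fixed = TRUE)[[1]]
    m <- mpe[mpe$condition == ct[1] & mpe$treatment == ct[2], , drop = FALSE]
    if (nrow(m) == 0) next
    summ <- summarize_intervals(m, config$design)
    fit <- tryCatch(fit_cubic(summ), error = function(e) {
      stop(sprintf("arm %s: %s", key, conditionMessage(e)), call. = FALSE)
    })
    dur <- switch(config$fit_mode,
      cubic = block_duration(fit, config$mpe_threshold_pct),
      piecewise = block_duration(summ, config$mpe_threshold_pct,
                                 smooth = "none"),
      isotonic = {
        # precision-weighted means: latency noise scales %MPE noise by
        # 1 / (cutoff - baseline)
        wsumm <- summarize_intervals(
          m, config$design,
          weights = (config$assay$cutoff_s - m$baseline_latency_s)^2)
        block_duration(wsumm, config$mpe_threshold_pct, smooth = "isotonic")
      })
    arms[[key]] <- list(condition = ct[1], treatment = ct[2],
                        n_mice = sum(included$condition == ct[1] &
                                       included$treatment == ct[2]),
                        summaries = summ, fit = fit,
                        landmarks = extract_landmarks(fit), duration = dur)
  }

  # ROC models: condition discrimination within each treatment, and
  # treatment discrimination within each condition
  roc <- list(); comparisons <- list()
  mk_scores <- function(rows, label_col) {
    keys <- unique(paste(rows$condition, rows$treatment, sep = "."))
    parts <- lapply(keys, function(k) {
      ct <- strsplit(k, ".", fixed = TRUE)[[1]]
      sub <- rows[rows$condition == ct[1] & rows$treatment == ct[2], ]
      tibble::tibble(score = arm_scores(sub, NULL, config$roc_aggregation,
                                        config$design),
                     label = sub[[label_col]][1])
    })
    dplyr::bind_rows(parts)
  }
  trts <- intersect(c("BH", "LB"), unique(mpe$treatment))
  if (length(trts) && length(unique(mpe$condition)) == 2) {
    for (trt in trts) {
      sc <- mk_scores(mpe[mpe$treatment == trt, ], "condition")
      roc[[paste0("condition_given_", trt)]] <-
        roc_from_scores(sc$score, sc$label, positive_label = "dm_pn")
    }
    if (length(trts) == 2) {
      comparisons$treatment_models <- compare_auc(
        roc[["condition_given_BH"]], roc[["condition_given_LB"]])
    }
  }
  conds <- intersect(c("control", "dm_pn"), unique(mpe$condition))
  if (length(conds) && length(unique(mpe$treatment)) == 2) {
    for (cond in conds) {
      sc <- mk_scores(mpe[mpe$condition == cond, ], "treatment")
      roc[[paste0("treatment_given_", cond)]] <-
        roc_from_scores(sc$score, sc$label, positive_label = "LB")
    }
    if (length(conds) == 2) {
      comparisons$condition_models <- compare_auc(
        roc[["treatment_given_control"]], roc[["treatment_given_dm_pn"]])
    }
  }

  # cohort-characteristic contrasts, control vs dm_pn, over all candidates
  cohort_tests <- list()
  covars <- c(plantar_baseline = "baseline_latency_s",
              tail_flick = "tail_flick_latency_s",
              weight = "weight_g", glucose = "glucose_mmol_L")
  for (nm in names(covars)) {
    col <- covars[[nm]]
    if (!col %in% names(cohort)) next
    x <- cohort[[col]][cohort$condition == "dm_pn"]
    y <- cohort[[col]][cohort$condition == "control"]
    if (length(x) >= 2 && length(y) >= 2) {
      tt <- t_test_from_raw(x, y, variant = config$t_test_variant)
      tt$label <- significance_label(tt$p_value)
      cohort_tests[[nm]] <- tt
    }
  }

  report <- structure(list(
    exclusions = excluded[, intersect(
      c("mouse_id", "condition", "treatment", "status", "exclusion_reason"),
      names(excluded))],
    n_included = nrow(included),
    arms = arms, roc = roc, comparisons = comparisons,
    cohort_tests = cohort_tests, config = config
  ), class = "study_report")
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  included mice: %d (excluded: %d)\n",
              x$n_included, nrow(x$exclusions)))
  for (key in names(x$arms)) {
    a <- x$arms[[key]]
    d <- a$duration
    dtxt <- if (d$status == "ok") sprintf("%.1f min", d$duration_min) else
      "censored above horizon"
    cat(sprintf("  %-12s n = %d, onset %.1f min @ %.1f%% MPE, duration %s (R^2 %.2f)\n",
                key, a$n_mice, a$landmarks$t_min[1], a$landmarks$mpe_pct[1],
                dtxt, a$fit$r_squared))
  }
  for (nm in names(x$roc)) {
    cat(sprintf("  ROC %-24s AUC %.3f (SE %.3f)\n", nm, x$roc[[nm]]$auc,
                x$roc[[nm]]$se))
  }
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat(sprintf("  contrast %-17s chi2(1) = %.2f, p = %.3g\n", nm, cc$chi2,
                cc$p_value))
  }
  invisible(x)
}

report_to_list <- function(report) {
  num <- function(z) if (is.numeric(z)) signif(z, 6) else z
  arms <- lapply(report$arms, function(a) list(
    condition = a$condition, treatment = a$treatment, n_mice = a$n_mice,
    coefficients = num(a$fit$coefficients), domain = num(a$fit$domain),
    r_squared = num(a$fit$r_squared),
    landmarks = lapply(seq_len(nrow(a$landmarks)), function(i) list(
      kind = a$landmarks$kind[i], t_min = num(a$landmarks$t_min[i]),
      mpe_pct = num(a$landmarks$mpe_pct[i]),
      at_boundary = a$landmarks$at_boundary[i])),
    duration = list(status = a$duration$status,
                    duration_min = num(a$duration$duration_min),
                    threshold_pct = a$duration$threshold_pct,
                    method = a$duration$method)))
  roc <- lapply(report$roc, function(r) list(
    auc = num(r$auc), se = num(r$se), n_pos = r$n_pos, n_neg = r$n_neg,
    positive_label = r$positive_label, se_method = r$se_method))
  comparisons <- lapply(report$comparisons, function(cc) list(
    auc_1 = num(cc$auc_1), auc_2 = num(cc$auc_2), chi2 = num(cc$chi2),
    df = cc$df, p_value = num(cc$p_value)))
  tests <- lapply(report$cohort_tests, function(tt) list(
    t = num(tt$t), df = num(tt$df), p_value = num(tt$p_value),
    group_means = num(tt$group_means), group_sds = num(tt$group_sds),
    group_ns = tt$group_ns, variant = tt$variant, label = tt$label))
  list(
    n_included = report$n_included,
    exclusions = report$exclusions,
    arms = arms, roc = roc, comparisons = comparisons,
    cohort_tests = tests,
    config = list(assay = report$config$assay$assay_name,
                  cutoff_s = report$config$assay$cutoff_s,
                  mpe_threshold_pct = report$config$mpe_threshold_pct,
                  fit_mode = report$config$fit_mode,
                  roc_aggregation = report$config$roc_aggregation,
                  t_test_variant = report$config$t_test_variant))
}

#' Write a study report to disk
#'
#' Serializes a [run_pipeline()] report as `report.json` (floats at six
#' significant digits, stable key order, so re-runs on identical inputs are
#' byte-identical) plus per-arm interval summaries and ROC points as CSV.
#'
#' @param report A `"study_report"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(report_to_list(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  for (key in names(report$arms)) {
    utils::write.csv(report$arms[[key]]$summaries,
                     file.path(dir, paste0("summaries_", key, ".csv")),
                     row.names = FALSE)
  }
  for (nm in names(report$roc)) {
    utils::write.csv(report$roc[[nm]]$points,
                     file.path(dir, paste0("roc_", nm, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}
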