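#' ROC curve from %MPE scores
#'
#' Builds a receiver operating characteristic curve for discriminating two
#' classes (e.g. neuropathy condition, or anesthetic treatment) from %MPE
#' scores. Thresholds are swept over the distinct score values ("predict
#' positive when score >= threshold"), with tied scores grouped at a single
#' threshold, so the curve starts at (0, 0) and ends at (1, 1). The area
#' under the curve is computed by point-to-point trapezoidal integration,
#' which for this construction equals the tie-corrected Mann-Whitney
#' statistic `U / (n_pos * n_neg)`.
#'
#' The standard error defaults to the distribution-free Hanley-McNeil
#' formula with `Q1 = A / (2 - A)` and `Q2 = 2 A^2 / (1 + A)`; a
#' nonparametric bootstrap (stratified by class, using the current RNG
#' state) is available as an alternative.
#'
#' @param scores Numeric scores (typically %MPE values).
#' @param labels Class labels, same length as `scores`; exactly two distinct
#'   classes must both be present.
#' @param positive_label The label treated as positive (higher scores are
#'   expected for this class).
#' @param se_method `"hanley_mcneil"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `se_method = "bootstrap"`.
#'
#' @return An object of class `"roc_result"`: `points` (tibble with
#'   `threshold`, `fpr`, `tpr`), `auc`, `se`, `n_pos`, `n_neg`,
#'   `positive_label`, `se_method`.
#' @examples
#' roc_from_scores(c(3, 5, 7, 2, 4, 6),
#'                 rep(c("a", "b"), each = 3), positive_label = "a")$auc
#' @export
roc_from_scores <- function(scores, labels, positive_label,
                            se_method = c("hanley_mcneil", "bootstrap"),
                            n_boot = 2000) {
  se_method <- match.arg(se_method)
  stopifnot(length(scores) == length(labels), is.numeric(scores),
            all(is.finite(scores)))
  is_pos <- labels == positive_label
  pos <- scores[is_pos]
  neg <- scores[!is_pos]
  if (!length(pos) || !length(neg)) {
    stop("degenerate ROC (both classes must be present)", call. = FALSE)
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(c) mean(pos >= c), numeric(1))
  fpr <- vapply(thr, function(c) mean(neg >= c), numeric(1))
  points <- tibble::tibble(threshold = c(Inf, thr),
                           fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) *
               (utils::head(points$tpr, -1) + utils::tail(points$tpr, -1)) / 2)
  auc_of <- function(p, n) {
    # tie-corrected Mann-Whitney, used for bootstrap resamples
    r <- rank(c(p, n))
    (sum(r[seq_along(p)]) - length(p) * (length(p) + 1) / 2) /
      (length(p) * length(n))
  }
  se <- switch(se_method,
    hanley_mcneil = {
      A <- auc
      q1 <- A / (2 - A)
      q2 <- 2 * A^2 / (1 + A)
      np <- length(pos); nn <- length(neg)
      sqrt(pmax(0, (A * (1 - A) + (np - 1) * (q1 - A^2) +
                      (nn - 1) * (q2 - A^2)) / (np * nn)))
    },
    bootstrap = {
      reps <- vapply(seq_len(n_boot), function(i) {
        auc_of(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
      }, numeric(1))
      stats::sd(reps)
    })
  structure(list(points = points, auc = auc, se = se,
                 n_pos = length(pos), n_neg = length(neg),
                 positive_label = positive_label, se_method = se_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.3f (SE %.3f, %s), %d pos / %d neg, positive = %s\n",
              x$auc, x$se, x$se_method, x$n_pos, x$n_neg, x$positive_label))
  invisible(x)
}

#' Chi-squared comparison of two independent ROC areas
#'
#' Contrasts the areas under two ROC curves built from independent samples
#' (disjoint study arms) with the one-degree-of-freedom statistic
#' \deqn{\chi^2 = (A_1 - A_2)^2 / (SE_1^2 + SE_2^2),}
#' referring it to the upper tail of the chi-squared distribution.
#'
#' @param r1,r2 `"roc_result"` objects from independent samples.
#'
#' @return An object of class `"auc_comparison"`: `auc_1`, `auc_2`, `se_1`,
#'   `se_2`, `chi2`, `df` (always 1) and `p_value`.
#' @export
compare_auc <- function(r1, r2) {
  stopifnot(inherits(r1, "roc_result"), inherits(r2, "roc_result"))
  d <- r1$auc - r2$auc
  v <- r1$se^2 + r2$se^2
  if (v == 0) {
    if (d == 0) {
      chi2 <- 0
      p <- 1
    } else {
      warning("both standard errors are zero with unequal AUCs; p-value at machine floor",
              call. = FALSE)
      chi2 <- Inf
      p <- .Machine$double.xmin
    }
  } else {
    chi2 <- d^2 / v
    p <- max(stats::pchisq(chi2, df = 1, lower.tail = FALSE),
             .Machine$double.xmin)
  }
  structure(list(auc_1 = r1$auc, auc_2 = r2$auc, se_1 = r1$se, se_2 = r2$se,
                 chi2 = chi2, df = 1L, p_value = p),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("<auc_comparison> AUC %.3f vs %.3f: chi2(1) = %.3g, p = %.4g\n",
              x$auc_1, x$auc_2, x$chi2, x$p_value))
  invisible(x)
}

#' Two-sample independent t-test from summary statistics
#'
#' Closed-form two-sided t-test from group means, SDs and sizes, as used to
#' contrast cohort characteristics (latency, weight, glucose) between
#' conditions when only summary statistics are available. The default is the
#' classical pooled-variance test; Welch's unequal-variance form is
#' available via `variant = "welch"` (with equal group sizes and equal SDs
#' the two coincide).
#'
#' @param m1,sd1,n1 Mean, sample SD and size of group 1.
#' @param m2,sd2,n2 Mean, sample SD and size of group 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#'
#' @return An object of class `"block_t_test"`: `t`, `df`, `p_value`
#'   (two-sided), `group_means`, `group_sds`, `group_ns`, `variant`.
#' @examples
#' t_test_from_summary(11.9, 3.4, 12, 6.4, 2.8, 12) # plantar latency contrast
#' @export
t_test_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                                variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, sd1 >= 0, sd2 >= 0)
  if (sd1 == 0 && sd2 == 0) {
    if (m1 == m2) {
      t <- 0; df <- n1 + n2 - 2; p <- 1
    } else {
      warning("zero variance in both groups with unequal means; p-value at machine floor",
              call. = FALSE)
      t <- sign(m1 - m2) * Inf; df <- n1 + n2 - 2; p <- .Machine$double.xmin
    }
  } else if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
    t <- (m1 - m2) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(t = t, df = df, p_value = max(p, .Machine$double.xmin),
                 group_means = c(m1, m2), group_sds = c(sd1, sd2),
                 group_ns = c(n1, n2), variant = variant),
            class = "block_t_test")
}

#' Two-sample independent t-test from raw samples
#'
#' Raw-data twin of [t_test_from_summary()]: computes each sample's mean, SD
#' and size and delegates to the closed form, so the two entry points agree
#' exactly.
#'
#' @param sample1,sample2 Numeric vectors, each of length >= 2.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return See [t_test_from_summary()].
#' @export
t_test_from_raw <- function(sample1, sample2,
                            variant = c("pooled", "welch")) {
  stopifnot(length(sample1) >= 2, length(sample2) >= 2,
            all(is.finite(sample1)), all(is.finite(sample2)))
  t_test_from_summary(mean(sample1), stats::sd(sample1), length(sample1),
                      mean(sample2), stats::sd(sample2), length(sample2),
                      variant = variant)
}

#' @export
print.block_t_test <- function(x, ...) {
  cat(sprintf(
    "<block_t_test> %s: t = %.3f, df = %.4g, p = %.4g (means %.3g vs %.3g, n %d/%d)\n",
    x$variant, x$t, x$df, x$p_value, x$group_means[1], x$group_means[2],
    x$group_ns[1], x$group_ns[2]))
  invisible(x)
}

#' Significance tier label
#'
#' Maps a p-value to the study's two-tier reporting convention: significant
#' at p < 0.05, notably significant at p < 0.1, otherwise not significant.
#'
#' @param p A p-value (or vector of them).
#' @return Character vector of labels.
#' @export
significance_label <- function(p) {
  ifelse(p < 0.05, "significant",
         ifelse(p < 0.1, "notable", "not significant"))
}
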