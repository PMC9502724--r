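#' Per-window group summaries of %MPE
#'
#' Averages per-measurement %MPE scores within each scheduling window
#' (half-open intervals `[w * window_min, (w + 1) * window_min)`), producing
#' the group-level time course that the curve fit consumes. Empty windows are
#' reported with `n = 0` and missing mean/SD rather than dropped, so the
#' window grid is always complete.
#'
#' When `weights` are supplied the window mean is a weighted mean. The
#' intended use is precision weighting of %MPE values: additive latency
#' noise of SD `s` seconds maps to %MPE noise of SD
#' `100 s / (cutoff - baseline)`, so weights proportional to
#' `(cutoff - baseline)^2` give the efficient (inverse-variance) group
#' mean. The plain, unweighted mean remains the default.
#'
#' @param mpe_values Data frame with columns `t_min` and `mpe_pct`
#'   (a `mouse_id` column is allowed and ignored). All `t_min` must be
#'   below `spec$total_min`.
#' @param spec A [design_spec()] giving the window grid.
#' @param weights Optional non-negative weights, one per row of
#'   `mpe_values`.
#'
#' @return A tibble with columns `window_index`, `midpoint_min`,
#'   `mean_mpe_pct`, `sd_mpe_pct` (unweighted sample SD; `NA` when
#'   `n < 2`) and `n`.
#' @export
summarize_intervals <- function(mpe_values, spec = design_spec(),
                                weights = NULL) {
  stopifnot(all(c("t_min", "mpe_pct") %in% names(mpe_values)))
  t <- mpe_values$t_min
  y <- mpe_values$mpe_pct
  if (any(t < 0) || any(t >= spec$total_min)) {
    stop("all t_min must lie in [0, total_min)", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(y))
  stopifnot(length(weights) == length(y), all(weights >= 0),
            all(is.finite(weights)))
  win <- floor(t / spec$window_min)
  W <- spec$n_windows
  idx <- 0:(W - 1L)
  mean_w <- rep(NA_real_, W); sd_w <- rep(NA_real_, W); n_w <- integer(W)
  for (w in idx) {
    i <- win == w
    yi <- y[i]
    n_w[w + 1L] <- length(yi)
    if (length(yi)) {
      mean_w[w + 1L] <- stats::weighted.mean(yi, weights[i])
      sd_w[w + 1L] <- if (length(yi) >= 2) stats::sd(yi) else NA_real_
    }
  }
  tibble::tibble(
    window_index = idx,
    midpoint_min = idx * spec$window_min + spec$window_min / 2,
    mean_mpe_pct = mean_w,
    sd_mpe_pct = sd_w,
    n = n_w
  )
}

#' Fit a cubic polynomial to the %MPE time course
#'
#' Ordinary least-squares fit of the per-window mean %MPE on the window
#' midpoint time, using a third-order polynomial evaluated continuously over
#' the observed time range. The fit is unweighted: each window mean enters
#' with equal weight regardless of its within-window SD.
#'
#' @param summaries Output of [summarize_intervals()] (or any data frame with
#'   `midpoint_min`, `mean_mpe_pct` and `n`); windows with `n = 0` are
#'   dropped, and at least four usable windows are required.
#'
#' @return An object of class `"cubic_fit"`: coefficients `(a0, a1, a2, a3)`
#'   of `a0 + a1 t + a2 t^2 + a3 t^3` (%MPE vs minutes), the fitted `domain`
#'   `(t_lo, t_hi)`, `r_squared`, the data used, and the underlying
#'   [stats::lm] object. When the response has zero variance `r_squared` is
#'   defined as 0 (with a warning) so that it always lies in \[0, 1\].
#' @export
fit_cubic <- function(summaries) {
  stopifnot(all(c("midpoint_min", "mean_mpe_pct") %in% names(summaries)))
  d <- summaries[!is.na(summaries$mean_mpe_pct), , drop = FALSE]
  if ("n" %in% names(d)) d <- d[d$n >= 1, , drop = FALSE]
  if (nrow(d) < 4) stop("underdetermined cubic (need >= 4 windows)", call. = FALSE)
  model <- stats::lm(mean_mpe_pct ~ midpoint_min + I(midpoint_min^2) +
                       I(midpoint_min^3), data = d)
  coefs <- unname(stats::coef(model))
  coefs[is.na(coefs)] <- 0  # collinear higher orders (e.g. < 4 distinct times)
  res <- stats::resid(model)
  ss_tot <- sum((d$mean_mpe_pct - mean(d$mean_mpe_pct))^2)
  if (ss_tot > 0) {
    r2 <- 1 - sum(res^2) / ss_tot
  } else {
    warning("zero-variance response: R^2 defined as 0", call. = FALSE)
    r2 <- 0
  }
  structure(list(
    coefficients = coefs,
    domain = range(d$midpoint_min),
    r_squared = r2,
    data = tibble::as_tibble(d),
    model = model
  ), class = "cubic_fit")
}

#' @export
print.cubic_fit <- function(x, ...) {
  a <- x$coefficients
  cat(sprintf(
    "<cubic_fit> %.4g + %.4g t + %.4g t^2 + %.4g t^3 on [%g, %g] min, R^2 = %.3f\n",
    a[1], a[2], a[3], a[4], x$domain[1], x$domain[2], x$r_squared))
  invisible(x)
}

#' Evaluate a fitted cubic
#'
#' @param object A `"cubic_fit"`.
#' @param t Times in minutes.
#' @param ... Unused.
#' @return Fitted %MPE values at `t`.
#' @export
predict.cubic_fit <- function(object, t, ...) {
  a <- object$coefficients
  a[1] + a[2] * t + a[3] * t^2 + a[4] * t^3
}

#' Extract kinetic landmarks from a fitted cubic
#'
#' Locates the stationary points of the cubic by solving the derivative
#' quadratic analytically and classifies them by the second derivative. The
#' global maximum over the closed fit domain (endpoints included) is reported
#' as the block onset peak; an interior local minimum, when one exists, is
#' reported as a partial block release. Landmarks that fall on a domain
#' endpoint are flagged `at_boundary` (the true extremum may be censored by
#' the observation window).
#'
#' @param fit A `"cubic_fit"`.
#'
#' @return A tibble with columns `kind` (`"onset_peak"`,
#'   `"release_local_min"`), `t_min`, `mpe_pct`, `at_boundary`.
#' @export
extract_landmarks <- function(fit) {
  stopifnot(inherits(fit, "cubic_fit"))
  a <- fit$coefficients
  lo <- fit$domain[1]; hi <- fit$domain[2]
  # f'(t) = a1 + 2 a2 t + 3 a3 t^2
  qa <- 3 * a[4]; qb <- 2 * a[3]; qc <- a[2]
  crit <- numeric(0)
  if (abs(qa) > 0) {
    disc <- qb^2 - 4 * qa * qc
    if (disc >= 0) crit <- (-qb + c(-1, 1) * sqrt(disc)) / (2 * qa)
  } else if (abs(qb) > 0) {
    crit <- -qc / qb
  }
  eps <- 1e-9 * max(1, hi - lo)
  interior <- crit[crit > lo + eps & crit < hi - eps]
  f2 <- function(t) 2 * a[3] + 6 * a[4] * t

  cand_t <- c(lo, hi, interior)
  cand_y <- predict(fit, cand_t)
  peak_i <- which.max(cand_y)
  out <- tibble::tibble(
    kind = "onset_peak",
    t_min = cand_t[peak_i],
    mpe_pct = cand_y[peak_i],
    at_boundary = peak_i <= 2L
  )
  mins <- interior[f2(interior) > eps]
  if (length(mins)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      kind = "release_local_min",
      t_min = mins,
      mpe_pct = predict(fit, mins),
      at_boundary = FALSE
    ))
  }
  out
}

#' Estimate sensory block duration from a %MPE time course
#'
#' The block is considered diminished once the group %MPE falls below
#' `threshold_pct` (default 15%). The duration, measured from the injection
#' at `t = 0`, is the earliest time after the onset peak at which the curve
#' falls below the threshold and does not re-exceed it within the remaining
#' observation domain. If the curve is still at or above the threshold at the
#' end of the domain the block outlasted the study horizon and the result is
#' censored (`status = "censored_above_total"`).
#'
#' Two estimation paths are available. Passing a `"cubic_fit"` locates the
#' crossing on the fitted polynomial by analytic root-finding (with a
#' bisection fallback). Passing the interval summaries locates the crossing
#' on the sequence of window means joined piecewise-linearly; with
#' `smooth = "isotonic"` the post-peak means are first replaced by their
#' best-fitting non-increasing sequence (pool-adjacent-violators), a
#' shape-constrained smoother appropriate for single-release kinetics that
#' makes the crossing estimate robust to window-level noise around the
#' threshold, and the crossing is then refined by an ordinary
#' least-squares line through the three raw window means nearest the
#' isotonic crossing (local linear calibration; the refinement is kept
#' only when its slope is negative and its crossing stays within the span
#' of those windows).
#'
#' @param x A `"cubic_fit"` or a data frame of interval summaries from
#'   [summarize_intervals()].
#' @param threshold_pct Diminished-block threshold in %MPE (default 15). A
#'   value exactly at the threshold counts as diminished.
#' @param smooth For the interval-means path only: `"none"` or `"isotonic"`.
#' @param ... Passed between methods.
#'
#' @return An object of class `"block_duration"`: a list with `status`
#'   (`"ok"` or `"censored_above_total"`), `duration_min` (`NA` when
#'   censored), `threshold_pct`, `method`, and the onset landmark used.
#'   If the time course never reaches the threshold an error
#'   `"no block established"` is raised.
#' @export
block_duration <- function(x, threshold_pct = 15, ...) {
  UseMethod("block_duration")
}

new_block_duration <- function(status, duration, threshold, method, onset) {
  structure(list(status = status, duration_min = duration,
                 threshold_pct = threshold, method = method, onset = onset),
            class = "block_duration")
}

#' @export
print.block_duration <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<block_duration> %.2f min (threshold %g%% MPE, %s)\n",
                x$duration_min, x$threshold_pct, x$method))
  } else {
    cat(sprintf("<block_duration> censored above horizon (threshold %g%% MPE, %s)\n",
                x$threshold_pct, x$method))
  }
  invisible(x)
}

#' @rdname block_duration
#' @export
block_duration.cubic_fit <- function(x, threshold_pct = 15, ...) {
  lands <- extract_landmarks(x)
  onset <- lands[lands$kind == "onset_peak", ][1, ]
  if (onset$mpe_pct < threshold_pct) {
    stop("no block established (peak %MPE below threshold)", call. = FALSE)
  }
  a <- x$coefficients
  hi <- x$domain[2]
  t0 <- onset$t_min
  if (predict(x, hi) > threshold_pct) {
    return(new_block_duration("censored_above_total", NA_real_,
                              threshold_pct, "curve", onset))
  }
  # real roots of f(t) - threshold in (t0, hi]
  r <- polyroot(c(a[1] - threshold_pct, a[2], a[3], a[4]))
  r <- Re(r[abs(Im(r)) < 1e-7 * pmax(1, Mod(r))])
  r <- sort(r[r > t0 + 1e-9 & r <= hi + 1e-9])
  if (!length(r)) {
    # numerically missed crossing: fall back to bisection
    r <- stats::uniroot(function(t) predict(x, t) - threshold_pct,
                        c(t0, hi), tol = 1e-10)$root
  }
  # after the last root the sign is constant and f(hi) < threshold, so the
  # last root is the earliest time after which the curve stays below
  new_block_duration("ok", max(r), threshold_pct, "curve", onset)
}

#' @rdname block_duration
#' @export
block_duration.data.frame <- function(x, threshold_pct = 15,
                                      smooth = c("none", "isotonic"), ...) {
  smooth <- match.arg(smooth)
  stopifnot(all(c("midpoint_min", "mean_mpe_pct") %in% names(x)))
  d <- x[!is.na(x$mean_mpe_pct), , drop = FALSE]
  if (nrow(d) < 2) stop("need at least two non-empty windows", call. = FALSE)
  t <- d$midpoint_min
  y <- d$mean_mpe_pct
  peak_i <- which.max(y)
  if (y[peak_i] < threshold_pct) {
    stop("no block established (peak %MPE below threshold)", call. = FALSE)
  }
  onset <- tibble::tibble(kind = "onset_peak", t_min = t[peak_i],
                          mpe_pct = y[peak_i],
                          at_boundary = peak_i %in% c(1L, nrow(d)))
  tp <- t[peak_i:length(t)]
  yraw <- y[peak_i:length(y)]
  yp <- yraw
  if (smooth == "isotonic" && length(yp) >= 2) {
    yp <- -stats::isoreg(tp, -yp)$yf  # best non-increasing fit
  }
  method <- if (smooth == "isotonic") "means-isotonic" else "means"
  if (yp[length(yp)] > threshold_pct) {
    return(new_block_duration("censored_above_total", NA_real_,
                              threshold_pct, method, onset))
  }
  above <- which(yp > threshold_pct)         # a mean exactly at the
  if (!length(above)) {                      # threshold is already diminished
    return(new_block_duration("ok", tp[1L], threshold_pct, method, onset))
  }
  j <- max(above)                            # last window strictly above
  dur <- tp[j] + (tp[j + 1L] - tp[j]) *
    (yp[j] - threshold_pct) / (yp[j] - yp[j + 1L])
  if (smooth == "isotonic" && length(tp) >= 3) {
    # local linear calibration through the raw means around the crossing
    lo <- max(1L, j - 1L)
    hi <- min(length(tp), lo + 2L)
    lo <- max(1L, hi - 2L)
    sel <- lo:hi
    xs <- tp[sel]; ys <- yraw[sel]
    slope <- stats::cov(xs, ys) / stats::var(xs)
    if (is.finite(slope) && slope < 0) {
      cross <- mean(xs) + (threshold_pct - mean(ys)) / slope
      if (cross >= tp[lo] && cross <= tp[hi]) dur <- cross
    }
  }
  new_block_duration("ok", dur, threshold_pct, method, onset)
}

#' Multi-segment cubic fitting
#'
#' A single cubic cannot carry more than one interior release; time courses
#' with several partial releases (as extended-release formulations can show)
#' are better described by independent cubics over user-specified
#' sub-domains. Breakpoints are given in minutes; each segment must still
#' contain at least four usable windows. Landmarks are extracted per
#' segment.
#'
#' @param summaries Output of [summarize_intervals()].
#' @param breaks Numeric vector of interior breakpoints (minutes), strictly
#'   increasing, partitioning the window midpoints; windows are assigned to
#'   segments by half-open intervals `[b_k, b_{k+1})`.
#'
#' @return A list of segments, each a list with `domain`, `fit` (a
#'   `"cubic_fit"`) and `landmarks`.
#' @export
fit_cubic_segments <- function(summaries, breaks) {
  stopifnot(is.numeric(breaks), !is.unsorted(breaks, strictly = TRUE))
  edges <- c(-Inf, breaks, Inf)
  segs <- list()
  for (k in seq_len(length(edges) - 1L)) {
    d <- summaries[summaries$midpoint_min >= edges[k] &
                     summaries$midpoint_min < edges[k + 1L], , drop = FALSE]
    d <- d[!is.na(d$mean_mpe_pct), , drop = FALSE]
    if (nrow(d) == 0) next
    fit <- fit_cubic(d)
    segs[[length(segs) + 1L]] <- list(domain = fit$domain, fit = fit,
                                      landmarks = extract_landmarks(fit))
  }
  segs
}
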