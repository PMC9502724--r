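#' Balanced incomplete block measurement design
#'
#' Describes the sampling grid used to follow a group of mice through a
#' nerve-block time course: latency readings are taken every
#' `slot_spacing_min` minutes (the slot grid), each mouse is measured exactly
#' once per `window_min`-minute window, and the study runs for `total_min`
#' minutes. With the defaults (1.5 / 13.5 / 270) the grid holds
#' 270 / 1.5 = 180 measuring points of which a group of six mice occupies
#' 120 - hence an *incomplete* block design.
#'
#' @param n_mice_per_group Number of mice scheduled per group; at most
#'   `window_min / slot_spacing_min`.
#' @param slot_spacing_min Minutes between successive slots on the grid.
#' @param window_min Window length in minutes; must be an integer multiple of
#'   `slot_spacing_min`.
#' @param total_min Total follow-up in minutes; must be an integer multiple
#'   of `window_min`.
#' @param seed Integer seed used by [generate_schedule()], or `NULL` to use
#'   the current RNG state.
#'
#' @return An object of class `"design_spec"`.
#' @examples
#' design_spec(6)
#' @export
design_spec <- function(n_mice_per_group = 6, slot_spacing_min = 1.5,
                        window_min = 13.5, total_min = 270, seed = NULL) {
  stopifnot(n_mice_per_group >= 1, slot_spacing_min > 0,
            window_min > 0, total_min > 0)
  slots_per_window <- window_min / slot_spacing_min
  n_windows <- total_min / window_min
  if (abs(slots_per_window - round(slots_per_window)) > 1e-9) {
    stop("window_min must be an integer multiple of slot_spacing_min",
         call. = FALSE)
  }
  if (abs(n_windows - round(n_windows)) > 1e-9) {
    stop("total_min must be an integer multiple of window_min", call. = FALSE)
  }
  if (n_mice_per_group > round(slots_per_window)) {
    stop("more mice than slots per window", call. = FALSE)
  }
  structure(list(
    n_mice_per_group = as.integer(n_mice_per_group),
    slot_spacing_min = slot_spacing_min,
    window_min = window_min,
    total_min = total_min,
    slots_per_window = as.integer(round(slots_per_window)),
    n_windows = as.integer(round(n_windows)),
    seed = seed
  ), class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf(paste0("<design_spec> %d mice, %g-min slots, %g-min windows, ",
                     "%g min total (%d windows x %d slots)\n"),
              x$n_mice_per_group, x$slot_spacing_min, x$window_min,
              x$total_min, x$n_windows, x$slots_per_window))
  invisible(x)
}

#' Generate a balanced incomplete block measurement schedule
#'
#' Assigns each mouse to one slot per window. The slot occupied by a mouse
#' rotates by two slots from one window to the next (one slot when the window
#' holds fewer than four slots), starting from a seeded random permutation of
#' the mice over the slot grid. The two-slot rotation guarantees that the
#' same animal's consecutive measurements are always at least two slot
#' spacings apart, while the rotation walks every animal across the whole
#' grid over the course of the study.
#'
#' @param spec A [design_spec()].
#' @param mouse_ids Character vector of identifiers; its length must equal
#'   `spec$n_mice_per_group`.
#'
#' @return A tibble with columns `window_index` (0-based), `slot_time_min`
#'   and `mouse_id`, ordered by time. Deterministic given
#'   (`spec$seed`, order of `mouse_ids`).
#' @examples
#' sch <- generate_schedule(design_spec(6, seed = 1), paste0("m", 1:6))
#' nrow(sch) # 6 mice x 20 windows = 120 of the 180 grid points
#' @export
generate_schedule <- function(spec, mouse_ids) {
  stopifnot(inherits(spec, "design_spec"))
  n <- length(mouse_ids)
  if (n != spec$n_mice_per_group) {
    stop("length(mouse_ids) must equal spec$n_mice_per_group", call. = FALSE)
  }
  if (anyDuplicated(mouse_ids)) stop("mouse_ids must be unique", call. = FALSE)
  S <- spec$slots_per_window
  W <- spec$n_windows
  if (!is.null(spec$seed)) set.seed(spec$seed)
  base <- sample.int(S, n) - 1L            # distinct starting slots
  step <- if (S >= 4L) 2L else 1L
  w <- rep(0:(W - 1L), each = n)
  slot <- (rep(base, times = W) + step * w) %% S
  out <- tibble::tibble(
    window_index = w,
    slot_time_min = w * spec$window_min + slot * spec$slot_spacing_min,
    mouse_id = rep(mouse_ids, times = W)
  )
  out[order(out$slot_time_min), , drop = FALSE]
}

#' Validate a measurement schedule against its design
#'
#' Checks a schedule (for example one hand-edited after animal exclusions)
#' for slot collisions, off-grid times, window/time inconsistencies and
#' missing or duplicated mouse-window pairs. Violations are returned as
#' data, not raised as errors, and the check is idempotent.
#'
#' @param entries Data frame with columns `window_index`, `slot_time_min`,
#'   `mouse_id`.
#' @param spec A [design_spec()].
#'
#' @return A list with `ok` (logical) and `violations`, a tibble with
#'   columns `type` and `message`.
#' @export
validate_schedule <- function(entries, spec) {
  stopifnot(inherits(spec, "design_spec"),
            all(c("window_index", "slot_time_min", "mouse_id") %in%
                  names(entries)))
  v <- list()
  add <- function(type, msg) v[[length(v) + 1L]] <<- tibble::tibble(
    type = type, message = msg)

  off <- abs(entries$slot_time_min / spec$slot_spacing_min -
               round(entries$slot_time_min / spec$slot_spacing_min)) > 1e-9
  for (t in unique(entries$slot_time_min[off])) {
    add("off-grid", sprintf("t = %g min is not a multiple of %g",
                            t, spec$slot_spacing_min))
  }
  wrong_w <- floor(entries$slot_time_min / spec$window_min) !=
    entries$window_index
  for (i in which(wrong_w)) {
    add("window mismatch", sprintf("t = %g min recorded in window %d",
                                   entries$slot_time_min[i],
                                   entries$window_index[i]))
  }
  dup_t <- unique(entries$slot_time_min[duplicated(entries$slot_time_min)])
  for (t in dup_t) add("slot collision", sprintf("t = %g min used twice", t))

  mice <- unique(entries$mouse_id)
  tab <- table(factor(entries$mouse_id, levels = mice),
               factor(entries$window_index, levels = 0:(spec$n_windows - 1L)))
  for (i in seq_along(mice)) {
    miss <- colnames(tab)[tab[i, ] == 0]
    if (length(miss)) {
      add("missing pair", sprintf("mouse %s unmeasured in window(s) %s",
                                  mice[i], paste(miss, collapse = ", ")))
    }
    dup <- colnames(tab)[tab[i, ] > 1]
    if (length(dup)) {
      add("duplicate pair", sprintf("mouse %s measured twice in window(s) %s",
                                    mice[i], paste(dup, collapse = ", ")))
    }
  }
  violations <- if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(type = character(), message = character())
  list(ok = nrow(violations) == 0L, violations = violations)
}
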