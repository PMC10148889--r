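#' Event-locked analysis windows
#'
#' The two tasks use different windows.  Tube-test mode: baseline is the
#' second before onset (`[-1, 0]` s), traces span `[-1, +5]` s, and only
#' events from bouts lasting longer than 15 s are included (to avoid
#' handling-related signal changes at tube placement); there is no
#' refractory rule.  Open-field social-interaction mode: baseline is
#' `[-1.5, -1.0]` s, traces span `[-1.5, +5]` s, and events preceded by
#' another event within the last 3 s are excluded (the calcium sensor's slow
#' decay would contaminate the baseline).  Both modes quantify each event as
#' the mean of the baseline-shifted trace over `[0, 4]` s.
#'
#' @param mode `"tube"` or `"ofsi"`.
#' @param baseline,trace,amplitude Two-element windows in seconds relative
#'   to event onset.
#' @param refractory_s Minimum spacing to the previous event, s, or `NA` for
#'   no rule.
#' @param min_bout_s Minimum bout duration, s (strictly greater than), or
#'   `NA` for no rule.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(mode = c("tube", "ofsi"),
                        baseline = NULL, trace = NULL, amplitude = c(0, 4),
                        refractory_s = NULL, min_bout_s = NULL) {
  mode <- match.arg(mode)
  if (mode == "tube") {
    baseline <- baseline %||% c(-1, 0)
    trace <- trace %||% c(-1, 5)
    refractory_s <- refractory_s %||% NA_real_
    min_bout_s <- min_bout_s %||% 15
  } else {
    baseline <- baseline %||% c(-1.5, -1)
    trace <- trace %||% c(-1.5, 5)
    refractory_s <- refractory_s %||% 3
    min_bout_s <- min_bout_s %||% NA_real_
  }
  if (baseline[2L] > 0) abort("baseline window must precede event onset")
  if (amplitude[1L] < trace[1L] || amplitude[2L] > trace[2L]) {
    abort("amplitude window must lie within the trace window")
  }
  structure(list(mode = mode, baseline = baseline, trace = trace,
                 amplitude = amplitude, refractory_s = refractory_s,
                 min_bout_s = min_bout_s),
            class = "window_spec")
}

#' Extract event-locked trace segments and mean amplitudes
#'
#' Applies the inclusion rules of the chosen [window_spec()], samples the
#' dF/F trace around each included onset (nearest-sample alignment, no
#' resampling), subtracts each event's baseline-window mean so the segment
#' is zero-referenced to the pre-event baseline, and quantifies each event
#' as the mean of the shifted segment over the amplitude window.
#'
#' Exclusion reasons: `short_bout` (tube mode, bout not longer than
#' `min_bout_s`), `refractory` (a prior event within `refractory_s`), and
#' `window_out_of_range` (the trace window does not fit in the recording).
#'
#' @param trace A `dff_trace`.
#' @param events A data frame with column `onset_s` and optionally
#'   `bout_duration_s` (required in tube mode) plus any metadata columns,
#'   which are carried through.  The refractory rule is evaluated on onsets
#'   sorted in time within this table.
#' @param spec A [window_spec()].
#' @return A list of class `event_locked_set`: `events` (input metadata plus
#'   `included`, `reason`, `amplitude`), `matrix` (included events x
#'   timepoints, baseline-shifted), `rel_time_s`, and `spec`.
#' @export
extract_event_locked <- function(trace, events, spec = window_spec("tube")) {
  stopifnot(inherits(spec, "window_spec"))
  events <- tibble::as_tibble(events)
  if (!"onset_s" %in% names(events)) abort("events needs an onset_s column")
  fs <- attr(trace, "fs_hz")
  t0 <- trace$time_s[1L]
  n <- nrow(trace)
  events <- dplyr::arrange(events, .data$onset_s)
  m <- nrow(events)
  included <- rep(TRUE, m)
  reason <- rep(NA_character_, m)

  if (!is.na(spec$min_bout_s)) {
    if (!"bout_duration_s" %in% names(events)) {
      abort("tube mode needs a bout_duration_s column in events")
    }
    short <- !(events$bout_duration_s > spec$min_bout_s)
    reason[short] <- "short_bout"
    included[short] <- FALSE
  }
  if (!is.na(spec$refractory_s) && m > 1L) {
    gaps <- c(Inf, diff(events$onset_s))
    refr <- gaps <= spec$refractory_s
    refr[1L] <- FALSE
    hit <- refr & included
    reason[hit] <- "refractory"
    included[hit] <- FALSE
  }

  off <- round(spec$trace * fs)
  rel_idx <- seq.int(off[1L], off[2L])
  rel_time <- rel_idx / fs
  base_keep <- rel_time >= spec$baseline[1L] - 1e-9 &
    rel_time <= spec$baseline[2L] + 1e-9
  amp_keep <- rel_time >= spec$amplitude[1L] - 1e-9 &
    rel_time <= spec$amplitude[2L] + 1e-9

  onset_idx <- round((events$onset_s - t0) * fs) + 1L
  oob <- onset_idx + off[1L] < 1L | onset_idx + off[2L] > n
  hit <- oob & included
  reason[hit] <- "window_out_of_range"
  included[hit] <- FALSE

  keep <- which(included)
  mat <- matrix(numeric(0), nrow = 0L, ncol = length(rel_idx))
  amplitude <- rep(NA_real_, m)
  if (length(keep)) {
    mat <- t(vapply(keep, function(i) {
      seg <- trace$dff[onset_idx[i] + rel_idx]
      seg - mean(seg[base_keep])
    }, numeric(length(rel_idx))))
    amplitude[keep] <- rowMeans(mat[, amp_keep, drop = FALSE])
  } else {
    warn("no events pass the inclusion rules; empty event-locked set")
  }
  events$included <- included
  events$reason <- reason
  events$amplitude <- amplitude
  structure(list(events = events, matrix = mat, rel_time_s = rel_time,
                 spec = spec, fs_hz = fs),
            class = "event_locked_set")
}

#' @export
print.event_locked_set <- function(x, ...) {
  cat(sprintf("<event_locked_set> %s mode: %d/%d events included, window [%g, %g] s\n",
              x$spec$mode, sum(x$events$included), nrow(x$events),
              x$spec$trace[1L], x$spec$trace[2L]))
  invisible(x)
}

#' Group-average event-locked trace
#'
#' Pointwise mean and standard error across included events, optionally by a
#' grouping column of the event metadata.
#'
#' @param set An [extract_event_locked()] result.
#' @param by Optional name of a metadata column to average within.
#' @return A tibble: (`group`,) `rel_time_s`, `mean_dff`, `sem_dff`, `n`.
#' @export
event_locked_mean <- function(set, by = NULL) {
  stopifnot(inherits(set, "event_locked_set"))
  keep <- set$events$included
  groups <- if (is.null(by)) rep("all", sum(keep)) else set$events[[by]][keep]
  purrr::map_dfr(unique(groups), function(g) {
    m <- set$matrix[groups == g, , drop = FALSE]
    tibble::tibble(
      group = g,
      rel_time_s = set$rel_time_s,
      mean_dff = colMeans(m),
      sem_dff = apply(m, 2L, sd) / sqrt(nrow(m)),
      n = nrow(m)
    )
  })
}

#' Pre/post change around event onset
#'
#' Per included event, the mean of the baseline-shifted trace over
#' `[-1, 0)` s (pre) and `[0, +1]` s (post), with a paired two-sided t test
#' of post versus pre -- the test of whether signal changes at behavior
#' initiation.
#'
#' @param set An [extract_event_locked()] result whose trace window covers
#'   `[-1, +1]` s.
#' @return A list: `events` (per-event `pre_mean`, `post_mean`), `t`, `df`,
#'   `p` from the paired comparison (NA when fewer than 2 events).
#' @export
pre_post_change <- function(set) {
  stopifnot(inherits(set, "event_locked_set"))
  rt <- set$rel_time_s
  if (min(rt) > -1 + 1e-9 || max(rt) < 1 - 1e-9) {
    abort("trace window must cover [-1, +1] s")
  }
  pre_keep <- rt >= -1 - 1e-9 & rt < -1e-9
  post_keep <- rt >= -1e-9 & rt <= 1 + 1e-9
  m <- set$matrix
  pre <- rowMeans(m[, pre_keep, drop = FALSE])
  post <- rowMeans(m[, post_keep, drop = FALSE])
  ev <- set$events[set$events$included, , drop = FALSE]
  ev$pre_mean <- pre
  ev$post_mean <- post
  if (length(pre) >= 2L && var(post - pre) > 0) {
    tt <- t.test(post, pre, paired = TRUE)
    list(events = ev, t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
  } else {
    list(events = ev, t = NA_real_, df = NA_real_,
         p = if (length(pre) >= 2L) 1 else NA_real_)
  }
}
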