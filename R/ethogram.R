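#' Ethogram classification parameters
#'
#' Thresholds and post-processing windows for the rule-based tube-test
#' classifier.  The velocity and distance thresholds are conventions, not
#' published values: the original scoring procedure states only that nose and
#' tailbase velocities must exceed "a specified threshold".  All values are
#' exposed here so they can be tuned to a rig's calibration.
#'
#' @param v_push_cm_s Minimum signed velocity toward the partner, cm/s, for a
#'   push frame (default 2).
#' @param v_retreat_cm_s Maximum (negative) signed velocity for a retreat
#'   frame, cm/s (default -2).
#' @param d_min_retreat_cm Minimum cumulative backward displacement over a
#'   retreat epoch, cm (default 2); also the hold-ground bound for resist.
#' @param nose_overlap_cm Maximum nose-to-nose distance along the tube axis
#'   for the pair to count as overlapping, cm (default 1).
#' @param smooth_frames Width (odd) of the centred moving average applied to
#'   positions before differentiation (default 5).
#' @param min_event_s Minimum event duration, s (default 0.2).
#' @param merge_gap_s Epochs of the same predicate separated by less than
#'   this gap are merged, s (default 0.3).
#' @param confidence_min Keypoints below this likelihood are linearly
#'   interpolated (default 0.6); contiguous low-confidence gaps longer than
#'   `max_gap_s` invalidate the bout.
#' @param win_margin_cm How far the tailbase must exit the tube span for a
#'   loss call, cm (default 1).
#' @param max_gap_s Longest interpolable low-confidence gap, s (default 1).
#' @return A list of class `ethogram_config`.
#' @export
ethogram_config <- function(v_push_cm_s = 2, v_retreat_cm_s = -2,
                            d_min_retreat_cm = 2, nose_overlap_cm = 1,
                            smooth_frames = 5L, min_event_s = 0.2,
                            merge_gap_s = 0.3, confidence_min = 0.6,
                            win_margin_cm = 1, max_gap_s = 1) {
  if (!v_push_cm_s > 0) abort("v_push_cm_s must be > 0")
  if (!v_retreat_cm_s < 0) abort("v_retreat_cm_s must be < 0")
  if (smooth_frames < 1 || smooth_frames %% 2 == 0) {
    abort("smooth_frames must be odd and >= 1")
  }
  if (min(d_min_retreat_cm, nose_overlap_cm, min_event_s, merge_gap_s,
          win_margin_cm, max_gap_s) < 0) {
    abort("distances and windows must be >= 0")
  }
  structure(
    list(v_push_cm_s = v_push_cm_s, v_retreat_cm_s = v_retreat_cm_s,
         d_min_retreat_cm = d_min_retreat_cm, nose_overlap_cm = nose_overlap_cm,
         smooth_frames = as.integer(smooth_frames), min_event_s = min_event_s,
         merge_gap_s = merge_gap_s, confidence_min = confidence_min,
         win_margin_cm = win_margin_cm, max_gap_s = max_gap_s),
    class = "ethogram_config"
  )
}

behavior_labels <- c("body_push", "nose_push", "resist", "retreat")

#' Smoothed positions and signed keypoint velocities
#'
#' Low-confidence keypoints are linearly interpolated, positions are smoothed
#' with a centred moving average (shrinking at the edges), and velocities are
#' central differences scaled to cm/s.  Velocities are signed by each mouse's
#' `facing` so that positive always means motion toward the partner.
#'
#' @param bout A [tube_bout()].
#' @param config An [ethogram_config()].
#' @return A tibble with one row per mouse and frame: `mouse`, `frame`,
#'   `time_s`, smoothed `nose_x`, `tail_x` (absolute cm), and signed
#'   velocities `v_nose`, `v_tail` (cm/s toward the partner).
#' @export
compute_velocity <- function(bout, config = ethogram_config()) {
  stopifnot(inherits(bout, "tube_bout"))
  if (bout$n_frames <= config$smooth_frames) {
    abort("bout shorter than the smoothing window")
  }
  purrr::map_dfr(bout$mice, function(m) {
    tr <- bout_track(bout, m)
    nose <- interp_low_confidence(tr$nose_x, tr$conf_nose, config$confidence_min)
    tail <- interp_low_confidence(tr$tail_x, tr$conf_tail, config$confidence_min)
    nose_s <- moving_average(nose, config$smooth_frames)
    tail_s <- moving_average(tail, config$smooth_frames)
    f <- unname(bout$facing[m])
    tibble::tibble(
      mouse = m,
      frame = tr$frame,
      time_s = tr$frame / bout$fps,
      nose_x = nose_s,
      tail_x = tail_s,
      v_nose = f * central_diff(nose_s, bout$fps),
      v_tail = f * central_diff(tail_s, bout$fps)
    )
  })
}

# Run-length post-processing shared by all predicates: contiguous TRUE frames
# become epochs, epochs closer than merge_gap merge, epochs shorter than
# min_event_s drop.
epochs_from_mask <- function(mask, fps, config) {
  iv <- mask_to_intervals(mask)
  iv <- merge_intervals(iv, max_gap = config$merge_gap_s * fps)
  iv[(iv$end - iv$start) / fps >= config$min_event_s - 1e-9, , drop = FALSE]
}

# Retreat epochs for one mouse: tailbase velocity at or below the retreat
# threshold, merged, then filtered by cumulative backward displacement and
# minimum duration.  `s_tail` is the signed tail position (toward-partner
# positive).
retreat_epochs <- function(v_tail, s_tail, fps, config) {
  iv <- mask_to_intervals(v_tail <= config$v_retreat_cm_s)
  iv <- merge_intervals(iv, max_gap = config$merge_gap_s * fps)
  if (nrow(iv)) {
    disp <- s_tail[iv$start + 1L] - s_tail[iv$end]
    iv <- iv[disp >= config$d_min_retreat_cm - 1e-9, , drop = FALSE]
  }
  iv[(iv$end - iv$start) / fps >= config$min_event_s - 1e-9, , drop = FALSE]
}

empty_ethogram <- function(bout, skipped = FALSE, reason = NA_character_) {
  ev <- tibble::tibble(
    label = character(), actor = character(),
    start_frame = integer(), end_frame = integer(),
    start_s = numeric(), duration_s = numeric()
  )
  new_ethogram(ev, bout, skipped = skipped, reason = reason)
}

new_ethogram <- function(events, bout, skipped = FALSE, reason = NA_character_) {
  structure(events,
            class = c("cm_ethogram", class(tibble::tibble())),
            fps = bout$fps, duration_s = bout$duration_s,
            bout_id = bout$bout_id, mice = bout$mice,
            skipped = skipped, skip_reason = reason)
}

#' Classify tube-test behaviors from keypoint tracks
#'
#' Evaluates the rule-based predicates frame by frame and turns contiguous
#' runs into events.  For mouse `m` with partner `p`:
#'
#' * retreat(m): tailbase velocity at or below `v_retreat_cm_s` with
#'   cumulative backward displacement of at least `d_min_retreat_cm` over the
#'   epoch;
#' * body_push(m): nose and tailbase velocities at or above `v_push_cm_s`,
#'   noses within `nose_overlap_cm`, and `p` not in a retreat epoch;
#' * nose_push(m): as body_push but without the tailbase velocity criterion,
#'   and not already a body-push frame;
#' * resist(m): `p` performs a push event while `m`'s net tailbase
#'   displacement over that event stays below `d_min_retreat_cm` (holding
#'   ground) -- an interpretation, since the original scoring names resist
#'   without defining it.
#'
#' Runs merge across gaps shorter than `merge_gap_s` and events shorter than
#' `min_event_s` are dropped.  Bouts with a contiguous low-confidence gap
#' longer than `max_gap_s` are flagged and skipped (empty ethogram with a
#' reason attribute).
#'
#' @inheritParams compute_velocity
#' @return A tibble of class `cm_ethogram`: `label`, `actor`, `start_frame`,
#'   `end_frame` (half-open, 0-based), `start_s`, `duration_s`, sorted by
#'   start frame.
#' @export
classify_behaviors <- function(bout, config = ethogram_config()) {
  stopifnot(inherits(bout, "tube_bout"))
  max_gap_frames <- config$max_gap_s * bout$fps
  for (m in bout$mice) {
    tr <- bout_track(bout, m)
    if (longest_run(tr$conf_nose < config$confidence_min) > max_gap_frames ||
        longest_run(tr$conf_tail < config$confidence_min) > max_gap_frames) {
      warn(sprintf("bout %s: low-confidence gap > %g s for mouse %s; skipped",
                   bout$bout_id %||% "?", config$max_gap_s, m))
      return(empty_ethogram(bout, skipped = TRUE,
                            reason = "low_confidence_gap"))
    }
  }

  vel <- compute_velocity(bout, config)
  fps <- bout$fps
  a <- bout$mice[1]; b <- bout$mice[2]
  va <- dplyr::filter(vel, .data$mouse == a)
  vb <- dplyr::filter(vel, .data$mouse == b)
  sv <- list() # signed tail positions
  sv[[a]] <- unname(bout$facing[a]) * va$tail_x
  sv[[b]] <- unname(bout$facing[b]) * vb$tail_x
  vels <- list(); vels[[a]] <- va; vels[[b]] <- vb

  # stage 1: retreat epochs and per-frame retreat masks
  n <- bout$n_frames
  retreat_iv <- list()
  retreat_mask <- list()
  for (m in c(a, b)) {
    iv <- retreat_epochs(vels[[m]]$v_tail, sv[[m]], fps, config)
    retreat_iv[[m]] <- iv
    msk <- rep(FALSE, n)
    if (nrow(iv)) for (i in seq_len(nrow(iv))) {
      msk[(iv$start[i] + 1L):iv$end[i]] <- TRUE
    }
    retreat_mask[[m]] <- msk
  }

  overlap <- abs(va$nose_x - vb$nose_x) <= config$nose_overlap_cm

  # stage 2: push epochs given the partner's retreat mask
  push_iv <- list()
  events <- list()
  partner_of <- setNames(c(b, a), c(a, b))
  for (m in c(a, b)) {
    p <- partner_of[[m]]
    vm <- vels[[m]]
    body_mask <- vm$v_nose >= config$v_push_cm_s &
      vm$v_tail >= config$v_push_cm_s & overlap & !retreat_mask[[p]]
    nose_mask <- vm$v_nose >= config$v_push_cm_s & overlap &
      !retreat_mask[[p]] & !body_mask
    body_iv <- epochs_from_mask(body_mask, fps, config)
    nose_iv <- epochs_from_mask(nose_mask, fps, config)
    push_iv[[m]] <- dplyr::bind_rows(
      dplyr::mutate(body_iv, label = "body_push"),
      dplyr::mutate(nose_iv, label = "nose_push")
    )
    events[[length(events) + 1L]] <-
      dplyr::mutate(push_iv[[m]], actor = m)
    events[[length(events) + 1L]] <-
      dplyr::mutate(retreat_iv[[m]], label = "retreat", actor = m)
  }

  # stage 3: resist = holding ground under the partner's push
  for (m in c(a, b)) {
    p <- partner_of[[m]]
    iv <- push_iv[[p]]
    if (nrow(iv)) {
      net <- abs(sv[[m]][iv$end] - sv[[m]][iv$start + 1L])
      hold <- iv[net < config$d_min_retreat_cm, c("start", "end"), drop = FALSE]
      if (nrow(hold)) {
        events[[length(events) + 1L]] <-
          dplyr::mutate(hold, label = "resist", actor = m)
      }
    }
  }

  ev <- dplyr::bind_rows(events)
  if (nrow(ev) == 0L) return(empty_ethogram(bout))
  ev <- ev |>
    dplyr::mutate(
      start_frame = as.integer(.data$start),
      end_frame = as.integer(.data$end),
      start_s = .data$start / fps,
      duration_s = (.data$end - .data$start) / fps
    ) |>
    dplyr::select("label", "actor", "start_frame", "end_frame",
                  "start_s", "duration_s") |>
    dplyr::arrange(.data$start_frame, .data$actor, .data$label)
  new_ethogram(ev, bout)
}

#' Per-mouse behavior rates
#'
#' Rate of each behavior as event initiations per second, normalizing for
#' bout duration.
#'
#' @param ethogram A `cm_ethogram` from [classify_behaviors()].
#' @param bout The [tube_bout()] it came from.
#' @return A tibble with `mouse`, `label`, `n_events`, `rate_per_s` for every
#'   mouse-by-label combination (zeros included).
#' @export
behavior_rates <- function(ethogram, bout) {
  stopifnot(inherits(bout, "tube_bout"))
  if (!bout$duration_s > 0) abort("bout duration must be > 0")
  grid <- tidyr::expand_grid(mouse = bout$mice, label = behavior_labels)
  counts <- tibble::as_tibble(ethogram) |>
    dplyr::count(mouse = .data$actor, .data$label, name = "n_events")
  grid |>
    dplyr::left_join(counts, by = c("mouse", "label")) |>
    dplyr::mutate(
      n_events = dplyr::coalesce(.data$n_events, 0L),
      rate_per_s = .data$n_events / bout$duration_s
    )
}
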