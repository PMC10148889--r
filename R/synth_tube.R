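#' Script a synthetic tube-test bout
#'
#' Defines the choreography of a simulated bout: a list of labelled
#' episodes for the two mice, the frame rate, tube length and coordinate
#' noise.  Episodes of one actor must not overlap.
#'
#' @param episodes A data frame with columns `behavior` (one of
#'   `body_push`, `nose_push`, `resist`, `retreat`, `idle`), `actor`
#'   (`"A"` or `"B"`), `start_s` and `duration_s`.
#' @param duration_s Bout length, s.
#' @param fps Frames per second (default 30).
#' @param tube_length_cm Tube length, cm (default 30).
#' @param noise_sd_cm SD of i.i.d. Gaussian jitter added to every
#'   coordinate, cm (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `bout_script`.
#' @export
bout_script <- function(episodes, duration_s = 20, fps = 30,
                        tube_length_cm = 30, noise_sd_cm = 0.05, seed = 1L) {
  episodes <- tibble::as_tibble(episodes)
  if (nrow(episodes)) {
    ok_lab <- episodes$behavior %in% c(behavior_labels, "idle")
    if (!all(ok_lab)) abort("unknown behavior label in episodes")
    if (!all(episodes$actor %in% c("A", "B"))) abort("actor must be A or B")
    if (any(episodes$start_s < 0) ||
        any(episodes$start_s + episodes$duration_s > duration_s + 1e-9)) {
      abort("episodes must lie within [0, duration_s]")
    }
    for (act in unique(episodes$actor)) {
      ep <- episodes[episodes$actor == act, ]
      ep <- ep[order(ep$start_s), ]
      if (nrow(ep) > 1L) {
        ends <- ep$start_s + ep$duration_s
        if (any(ep$start_s[-1L] < ends[-nrow(ep)] - 1e-9)) {
          abort(paste0("overlapping episodes for actor ", act))
        }
      }
    }
  }
  if (!fps > 0) abort("fps must be > 0")
  if (!tube_length_cm > 0) abort("tube_length_cm must be > 0")
  structure(list(episodes = episodes, duration_s = duration_s, fps = fps,
                 tube_length_cm = tube_length_cm, noise_sd_cm = noise_sd_cm,
                 seed = as.integer(seed)),
            class = "bout_script")
}

# Kinematic constants of the simulator: scripted motion is fast enough that
# the default classifier thresholds (2 cm/s) fire with margin, approach and
# relax phases move below threshold (1 cm/s) so they stay silent.
SIM_PUSH_SPEED <- 3    # cm/s, push and retreat speed
SIM_SLOW_SPEED <- 1    # cm/s, sub-threshold approach/relax
SIM_RAMP_S <- 1.5      # approach/relax phase length
SIM_NOSE_GAP <- 2      # resting nose-to-nose distance, cm
SIM_CONTACT_GAP <- 0.5 # nose-to-nose distance during contact, cm
SIM_NOSE_PUSH_TAIL <- 0.5 # tailbase speed during a nose push, cm/s

#' Simulate a tube-test bout from a script
#'
#' Builds nose and tailbase tracks for both mice in tube coordinates.
#' Mouse A enters from the low-`x` end (`facing = +1`), B from the
#' high-`x` end (`facing = -1`).  During a scripted push, the actor's nose
#' (and, for a body push, tailbase) moves toward the partner at 3 cm/s while
#' the partner's nose gives way in contact and its tailbase holds ground;
#' during a retreat the actor backs away at 3 cm/s.  A sub-threshold
#' approach phase before each contact episode brings the noses within the
#' overlap tolerance, and a relax phase after it restores the resting gap,
#' both at 1 cm/s so they do not trigger the classifier.  Gaussian jitter of
#' `noise_sd_cm` is added to every coordinate; keypoint confidence is
#' emitted as 1.
#'
#' The returned truth table contains every scripted (non-idle) episode with
#' its exact frame span, plus the events implied by the contact kinematics
#' (the partner of a scripted push holds ground, i.e. resists; a scripted
#' resist implies a partner body push), flagged `scripted = FALSE`.
#'
#' @param script A [bout_script()].
#' @return A list: `bout` (a [tube_bout()]) and `truth` (tibble: `label`,
#'   `actor`, `start_frame`, `end_frame`, `start_s`, `duration_s`,
#'   `scripted`).
#' @export
simulate_tube_bout <- function(script) {
  stopifnot(inherits(script, "bout_script"))
  n <- round(script$duration_s * script$fps)
  fps <- script$fps
  t_mid <- (seq_len(n) - 0.5) / fps # frame-interval midpoints for integration
  L <- script$tube_length_cm

  # per-keypoint velocity profiles (cm/s, absolute x), built by superposing
  # episode segments; positions follow by integration
  vel <- list(nA = numeric(n), tA = numeric(n), nB = numeric(n), tB = numeric(n))
  add_seg <- function(key, from_s, to_s, v) {
    sel <- t_mid >= from_s & t_mid < to_s
    vel[[key]][sel] <<- vel[[key]][sel] + v
  }

  mid <- L / 2
  start_pos <- c(nA = mid - SIM_NOSE_GAP / 2, tA = mid - SIM_NOSE_GAP / 2 - 6,
                 nB = mid + SIM_NOSE_GAP / 2, tB = mid + SIM_NOSE_GAP / 2 + 6)

  # nominal nose gap at time t, from the segments laid so far
  gap_at <- function(t) {
    f <- min(n, max(0L, floor(t * fps)))
    nA <- start_pos[["nA"]] + sum(vel$nA[seq_len(f)]) / fps
    nB <- start_pos[["nB"]] + sum(vel$nB[seq_len(f)]) / fps
    nB - nA
  }
  # bring the pusher's nose from the current gap to contact gap by episode
  # start: a fast phase while the noses are apart (gap > overlap tolerance)
  # and a final sub-threshold phase for the last stretch
  add_approach <- function(nose_key, dir, t_start, prev_end) {
    g <- gap_at(t_start)
    if (g <= SIM_CONTACT_GAP + 1e-9) return(invisible())
    # final stretch (noses closer than 1.2 cm) at sub-threshold speed so the
    # push predicates stay silent once overlap begins
    slow_d <- min(g, 1.2) - SIM_CONTACT_GAP
    slow_t <- slow_d / SIM_SLOW_SPEED
    fast_d <- max(g - 1.2, 0)
    if (fast_d > 1e-9) {
      avail <- t_start - slow_t - prev_end - 0.1
      fast_t <- max(min(avail, fast_d / 2.5), 0.05)
      add_seg(nose_key, t_start - slow_t - fast_t, t_start - slow_t,
              dir * fast_d / fast_t)
    }
    add_seg(nose_key, t_start - slow_t, t_start, dir * slow_d / slow_t)
  }

  eps <- script$episodes
  if (nrow(eps)) eps <- eps[order(eps$start_s), , drop = FALSE]
  truth <- list()
  add_truth <- function(label, actor, s, d, scripted) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      label = label, actor = actor,
      start_frame = as.integer(round(s * fps)),
      end_frame = as.integer(round((s + d) * fps)),
      scripted = scripted
    )
  }

  prev_end <- 0
  if (nrow(eps)) for (i in seq_len(nrow(eps))) {
    beh <- eps$behavior[i]; act <- eps$actor[i]
    s <- eps$start_s[i]; d <- eps$duration_s[i]; e <- s + d
    if (beh == "idle") next
    # direction of "toward partner" in absolute x for the acting mouse
    dir_a <- if (act == "A") +1 else -1
    me_nose <- if (act == "A") "nA" else "nB"
    me_tail <- if (act == "A") "tA" else "tB"
    pa_nose <- if (act == "A") "nB" else "nA"
    pa_tail <- if (act == "A") "tB" else "tA"

    if (beh %in% c("body_push", "nose_push")) {
      add_approach(me_nose, dir_a, s, prev_end)
      add_seg(me_nose, s, e, dir_a * SIM_PUSH_SPEED)
      add_seg(pa_nose, s, e, dir_a * SIM_PUSH_SPEED) # partner nose gives way
      tail_v <- if (beh == "body_push") SIM_PUSH_SPEED else SIM_NOSE_PUSH_TAIL
      add_seg(me_tail, s, e, dir_a * tail_v)
      add_seg(me_nose, e, e + SIM_RAMP_S, -dir_a * SIM_SLOW_SPEED)
      add_truth(beh, act, s, d, TRUE)
      add_truth("resist", if (act == "A") "B" else "A", s, d, FALSE)
    } else if (beh == "retreat") {
      add_seg(me_nose, s, e, -dir_a * SIM_PUSH_SPEED)
      add_seg(me_tail, s, e, -dir_a * SIM_PUSH_SPEED)
      add_seg(me_nose, e, e + SIM_RAMP_S, dir_a * SIM_SLOW_SPEED)
      add_seg(me_tail, e, e + SIM_RAMP_S, dir_a * SIM_SLOW_SPEED)
      add_truth("retreat", act, s, d, TRUE)
    } else if (beh == "resist") {
      # the partner pushes; the actor holds ground with its tailbase
      dir_p <- -dir_a
      add_approach(pa_nose, dir_p, s, prev_end)
      add_seg(pa_nose, s, e, dir_p * SIM_PUSH_SPEED)
      add_seg(pa_tail, s, e, dir_p * SIM_PUSH_SPEED)
      add_seg(me_nose, s, e, dir_p * SIM_PUSH_SPEED) # actor's nose gives way
      add_seg(pa_nose, e, e + SIM_RAMP_S, -dir_p * SIM_SLOW_SPEED)
      add_truth("resist", act, s, d, TRUE)
      add_truth("body_push", if (act == "A") "B" else "A", s, d, FALSE)
    }
    prev_end <- e + SIM_RAMP_S
  }

  pos <- lapply(names(vel), function(k) {
    start_pos[[k]] + c(0, cumsum(vel[[k]] / fps))[seq_len(n)]
  })
  names(pos) <- names(vel)

  set.seed(script$seed)
  jitter <- function() rnorm(n, 0, script$noise_sd_cm)
  y0 <- 1.5
  tracks <- dplyr::bind_rows(
    tibble::tibble(mouse = "A", frame = 0:(n - 1L),
                   nose_x = pos$nA + jitter(), nose_y = y0 + jitter(),
                   tail_x = pos$tA + jitter(), tail_y = y0 + jitter(),
                   conf_nose = 1, conf_tail = 1),
    tibble::tibble(mouse = "B", frame = 0:(n - 1L),
                   nose_x = pos$nB + jitter(), nose_y = y0 + jitter(),
                   tail_x = pos$tB + jitter(), tail_y = y0 + jitter(),
                   conf_nose = 1, conf_tail = 1)
  )

  truth <- if (length(truth)) {
    dplyr::bind_rows(truth) |>
      dplyr::mutate(start_s = .data$start_frame / fps,
                    duration_s = (.data$end_frame - .data$start_frame) / fps) |>
      dplyr::arrange(.data$start_frame, .data$actor)
  } else {
    tibble::tibble(label = character(), actor = character(),
                   start_frame = integer(), end_frame = integer(),
                   scripted = logical(), start_s = numeric(),
                   duration_s = numeric())
  }

  list(
    bout = tube_bout(tracks, fps = fps, x0 = 0, x1 = L,
                     facing = c(A = 1, B = -1),
                     bout_id = paste0("sim-", script$seed)),
    truth = truth
  )
}
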