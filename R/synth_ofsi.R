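#' Behavioral profile for a simulated two-trial social-interaction session
#'
#' Requested zone occupancies for the two 150-s trials of the open-field
#' social-interaction test.  Built-in profiles emulate the three outcome
#' groups: `avoider` (susceptible-like; collapses interaction time and camps
#' in the corners once the partner is present), `approacher`
#' (resilient-like; maintains or increases interaction time) and `control`.
#'
#' @param label One of `"avoider"`, `"approacher"`, `"control"`.
#' @param mean_interaction_s,mean_corner_s Length-2 vectors: requested zone
#'   time, s, in trials 1 and 2; defaults depend on `label`.
#' @param n_entries Interaction-zone entries per trial (0 is substituted in
#'   a trial whose requested interaction time is 0).
#' @param entry_amp_dff Peak dF/F of the calcium transient locked to each
#'   trial-2 zone entry.
#' @param trial_s Trial length, s (default 150).
#' @param seed Integer seed.
#' @return A list of class `ofsi_profile`.
#' @export
ofsi_profile <- function(label = c("avoider", "approacher", "control"),
                         mean_interaction_s = NULL, mean_corner_s = NULL,
                         n_entries = NULL, entry_amp_dff = NULL,
                         trial_s = 150, seed = 1L) {
  label <- match.arg(label)
  defaults <- switch(label,
    avoider    = list(si = c(40, 8), corner = c(20, 70), entries = 4L, amp = 0.01),
    approacher = list(si = c(40, 65), corner = c(20, 10), entries = 6L, amp = 0.05),
    control    = list(si = c(40, 55), corner = c(20, 15), entries = 6L, amp = 0)
  )
  mean_interaction_s <- mean_interaction_s %||% defaults$si
  mean_corner_s <- mean_corner_s %||% defaults$corner
  n_entries <- n_entries %||% defaults$entries
  entry_amp_dff <- entry_amp_dff %||% defaults$amp
  if (any(mean_interaction_s < 0) || any(mean_corner_s < 0) ||
      any(mean_interaction_s > trial_s) || any(mean_corner_s > trial_s)) {
    abort("zone durations must lie in [0, trial length]")
  }
  if (n_entries < 0) abort("n_entries must be >= 0")
  structure(list(label = label, mean_interaction_s = mean_interaction_s,
                 mean_corner_s = mean_corner_s, n_entries = as.integer(n_entries),
                 entry_amp_dff = entry_amp_dff, trial_s = trial_s,
                 seed = as.integer(seed)),
            class = "ofsi_profile")
}

# Random walk confined to a rectangle, starting at `from`.  Confinement is
# by reflection: the free cumulative-sum walk is folded back into the
# rectangle, which keeps the walk inside while staying fully vectorized.
walk_in_rect <- function(n, from, rect, step_sd = 1.2, margin = 0.3) {
  reflect <- function(z, lo, hi) {
    r <- hi - lo
    y <- (z - lo) %% (2 * r)
    lo + ifelse(y <= r, y, 2 * r - y)
  }
  lo <- c(rect[1L] + margin, rect[3L] + margin)
  hi <- c(rect[2L] - margin, rect[4L] - margin)
  px <- min(max(from[1L], lo[1L]), hi[1L])
  py <- min(max(from[2L], lo[2L]), hi[2L])
  cbind(reflect(px + cumsum(rnorm(n, 0, step_sd)), lo[1L], hi[1L]),
        reflect(py + cumsum(rnorm(n, 0, step_sd)), lo[2L], hi[2L]))
}

# One trial: schedule corner and interaction visits inside a wander band so
# requested occupancies are met by frame count and every interaction visit
# is exactly one zone entry.
simulate_ofsi_trial <- function(inter_s, corner_s, n_entries, geom, fps,
                                trial_s) {
  n_total <- round(trial_s * fps)
  travel_frames <- round(0.5 * fps)
  band_gap <- 3
  band <- c(2, geom$width - 2,
            geom$corner1[4L] + band_gap, geom$interaction[3L] - band_gap)
  if (band[4L] <= band[3L]) abort("arena too small for a wander band")

  if (inter_s <= 0) n_entries <- 0L
  inter_frames <- round(inter_s * fps)
  if (n_entries == 0L && inter_frames > 0L) {
    abort("requested interaction time with zero entries is infeasible")
  }
  corner_frames <- round(corner_s * fps)
  n_corner <- if (corner_frames > 0L) 2L else 0L

  split_frames <- function(total, k) {
    if (k == 0L) return(integer(0))
    base <- total %/% k
    extra <- total - base * k
    base + c(rep(1L, extra), rep(0L, k - extra))
  }
  visit_rects <- c(rep(list(geom$interaction), n_entries),
                   list(geom$corner1, geom$corner2)[seq_len(n_corner)])
  visit_frames <- c(split_frames(inter_frames, n_entries),
                    split_frames(corner_frames, n_corner))
  n_visits <- length(visit_rects)
  is_interaction <- c(rep(TRUE, n_entries), rep(FALSE, n_corner))
  # interleave corner visits between interaction visits
  if (n_visits > 1L) {
    ord <- order(c(seq_len(n_entries),
                   if (n_corner) c(1.5, max(n_entries - 0.5, 0.5))))
    visit_rects <- visit_rects[ord]
    visit_frames <- visit_frames[ord]
    is_interaction <- is_interaction[ord]
  }

  overhead <- n_visits * 2L * travel_frames
  wander_total <- n_total - sum(visit_frames) - overhead
  if (wander_total < (n_visits + 1L) * fps %/% 2L) {
    abort("infeasible occupancy request: zone times exceed the trial length")
  }
  wander_frames <- split_frames(wander_total, n_visits + 1L)

  # entry/exit waypoints sit just outside/inside each zone's wall facing the
  # wander band
  waypoints <- function(rect) {
    cx <- mean(rect[1:2])
    if (rect[3L] >= band[4L]) { # zone above the band (interaction)
      list(out = c(cx, rect[3L] - 0.5), inn = c(cx, rect[3L] + 0.5),
           far = c(cx, rect[3L] - 5))
    } else {                    # zone below the band (corners)
      list(out = c(cx, rect[4L] + 0.5), inn = c(cx, rect[4L] - 0.5),
           far = c(cx, rect[4L] + 5))
    }
  }
  travel <- function(from, to, k) {
    s <- seq_len(k) / k
    cbind(from[1L] + s * (to[1L] - from[1L]),
          from[2L] + s * (to[2L] - from[2L]))
  }

  pos <- matrix(numeric(0), ncol = 2L)
  cur <- c(geom$width / 2, mean(band[3:4]))
  entry_frames <- integer(0)
  add <- function(m) pos <<- rbind(pos, m)
  add(walk_in_rect(wander_frames[1L], cur, band))
  cur <- pos[nrow(pos), ]
  for (v in seq_len(n_visits)) {
    wp <- waypoints(visit_rects[[v]])
    add(travel(cur, wp$out, travel_frames))
    if (is_interaction[v]) entry_frames <- c(entry_frames, nrow(pos) + 1L)
    inside <- walk_in_rect(visit_frames[v], wp$inn, visit_rects[[v]],
                           margin = 0.6)
    # first and last visit frames sit at the boundary waypoint, so the
    # inbound/outbound transits spend at most a frame or two in the zone
    inside[1L, ] <- wp$inn
    inside[nrow(inside), ] <- wp$inn
    add(inside)
    add(travel(wp$inn, wp$far, travel_frames))
    add(walk_in_rect(wander_frames[v + 1L], wp$far, band))
    cur <- pos[nrow(pos), ]
  }
  stopifnot(nrow(pos) == n_total)
  list(
    traj = tibble::tibble(time_s = (seq_len(n_total) - 1L) / fps,
                          x_cm = pos[, 1L], y_cm = pos[, 2L]),
    entry_times = (entry_frames - 1L) / fps
  )
}

#' Simulate a two-trial open-field social-interaction session
#'
#' Generates trajectories for both trials that realize the profile's
#' requested zone occupancies by frame count and its entry counts exactly:
#' zone visits are scheduled segments of a confined random walk, connected
#' by fast straight-line transits through a central band that touches no
#' zone, so occupancy is controlled and each scheduled interaction visit
#' produces exactly one outside-to-inside transition.
#'
#' @param profile An [ofsi_profile()].
#' @param geom An [arena_geometry()].
#' @param fps Frames per second (default 30).
#' @return A list: `trial1`, `trial2` (tibbles `time_s`, `x_cm`, `y_cm`),
#'   and `truth` with the scheduled interaction-zone entry times per trial.
#' @export
simulate_ofsi_session <- function(profile, geom = arena_geometry(), fps = 30) {
  stopifnot(inherits(profile, "ofsi_profile"))
  set.seed(profile$seed)
  t1 <- simulate_ofsi_trial(profile$mean_interaction_s[1L],
                            profile$mean_corner_s[1L], profile$n_entries,
                            geom, fps, profile$trial_s)
  t2 <- simulate_ofsi_trial(profile$mean_interaction_s[2L],
                            profile$mean_corner_s[2L], profile$n_entries,
                            geom, fps, profile$trial_s)
  list(trial1 = t1$traj, trial2 = t2$traj,
       truth = list(entries_t1 = t1$entry_times,
                    entries_t2 = t2$entry_times))
}
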