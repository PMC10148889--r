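#' Open-field social-interaction arena geometry
#'
#' The arena contains a perforated chamber (10 cm x 6.5 cm footprint)
#' centred at the far wall, a 24 cm x 14 cm interaction zone centred on the
#' chamber, and two corner zones (default 9 cm x 9 cm) in the corners of the
#' wall opposite the chamber.  Rectangles are given as
#' `c(xmin, xmax, ymin, ymax)` in cm; zone boundaries are closed (a centroid
#' on the boundary counts as inside).
#'
#' @param width,height Arena size, cm (default 44 x 44, the standard
#'   open-field box for this assay).
#' @param chamber,interaction Chamber footprint and interaction-zone
#'   rectangles; defaults follow the stated dimensions, placed at the far
#'   (high-`y`) wall.
#' @param corner_size Side of the square corner zones, cm (default 9; not a
#'   published value).
#' @return A list of class `arena_geometry` with rectangles `chamber`,
#'   `interaction`, `corner1`, `corner2`.
#' @export
arena_geometry <- function(width = 44, height = 44,
                           chamber = NULL, interaction = NULL,
                           corner_size = 9) {
  cx <- width / 2
  chamber <- chamber %||% c(cx - 5, cx + 5, height - 6.5, height)
  interaction <- interaction %||% c(cx - 12, cx + 12, height - 14, height)
  corner1 <- c(0, corner_size, 0, corner_size)
  corner2 <- c(width - corner_size, width, 0, corner_size)
  rects <- list(chamber = chamber, interaction = interaction,
                corner1 = corner1, corner2 = corner2)
  for (nm in names(rects)) {
    r <- rects[[nm]]
    if (r[1L] < 0 || r[2L] > width || r[3L] < 0 || r[4L] > height) {
      abort(paste0(nm, " rectangle extends outside the arena"))
    }
  }
  if (chamber[1L] < interaction[1L] - 1e-9 ||
      chamber[2L] > interaction[2L] + 1e-9 ||
      chamber[3L] < interaction[3L] - 1e-9 ||
      chamber[4L] > interaction[4L] + 1e-9) {
    abort("interaction zone must contain the chamber footprint")
  }
  structure(c(list(width = width, height = height), rects),
            class = "arena_geometry")
}

in_rect <- function(x, y, r) {
  x >= r[1L] & x <= r[2L] & y >= r[3L] & y <= r[4L]
}

# Entry onsets (times) for a point trajectory and a zone mask; an entry is
# an outside->inside transition, and starting inside counts as an entry at
# the first frame.
entries_from_mask <- function(inside, time_s) {
  onsets <- which(inside & !dplyr::lag(inside, default = FALSE))
  time_s[onsets]
}

#' Zone occupancy of an arena trajectory
#'
#' Per-frame point-in-rectangle membership of the centroid for the
#' interaction zone and the two corner zones (reported separately and
#' summed), plus entry counts and total path length.
#'
#' @param traj A data frame with `time_s`, `x_cm`, `y_cm` (one trial).
#' @param geom An [arena_geometry()].
#' @param fps Frames per second; inferred from `time_s` when omitted.
#' @return A tibble with one row per zone (`interaction`, `corner1`,
#'   `corner2`, `corners`): `duration_s`, `n_entries`, and the total
#'   `distance_cm` of the trajectory.
#' @export
compute_zone_occupancy <- function(traj, geom = arena_geometry(), fps = NULL) {
  traj <- tibble::as_tibble(traj)
  if (nrow(traj) == 0L) abort("empty trajectory")
  if (is.null(fps)) {
    fps <- if (nrow(traj) > 1L) 1 / (traj$time_s[2L] - traj$time_s[1L]) else 1
  }
  dist <- sum(sqrt(diff(traj$x_cm)^2 + diff(traj$y_cm)^2))
  one <- function(name, mask) {
    tibble::tibble(
      zone = name,
      duration_s = sum(mask) / fps,
      n_entries = length(entries_from_mask(mask, traj$time_s)),
      distance_cm = dist
    )
  }
  m_int <- in_rect(traj$x_cm, traj$y_cm, geom$interaction)
  m_c1 <- in_rect(traj$x_cm, traj$y_cm, geom$corner1)
  m_c2 <- in_rect(traj$x_cm, traj$y_cm, geom$corner2)
  dplyr::bind_rows(
    one("interaction", m_int),
    one("corner1", m_c1),
    one("corner2", m_c2),
    one("corners", m_c1 | m_c2)
  )
}

#' Zone-entry onset times
#'
#' Onset is the first frame of each outside-to-inside transition of the
#' centroid; a trajectory starting inside the zone counts as an entry at its
#' first frame.  Used both for subject entries in the open-field
#' social-interaction test and for partner approaches in the forced
#' interaction task.
#'
#' @param traj A data frame with `time_s`, `x_cm`, `y_cm`.
#' @param zone A rectangle `c(xmin, xmax, ymin, ymax)` or an
#'   [arena_geometry()] (its interaction zone is used).
#' @return Numeric vector of entry onset times, s.
#' @export
detect_zone_entries <- function(traj, zone = arena_geometry()) {
  traj <- tibble::as_tibble(traj)
  if (inherits(zone, "arena_geometry")) zone <- zone$interaction
  entries_from_mask(in_rect(traj$x_cm, traj$y_cm, zone), traj$time_s)
}

#' Composite social-avoidance score and susceptible/resilient labels
#'
#' For each scored (stressed) animal, four components are computed from
#' two-trial zone occupancies: the interaction-zone time ratio
#' (trial 2 / trial 1), the corner-zone time ratio (trial 2 / trial 1), the
#' trial-2 interaction-zone duration, and the trial-2 corner-zone duration.
#' Each component is z-scored across the scored cohort (sample sd, n-1);
#' the two interaction components are multiplied by -1 so that for all four
#' a positive value indicates avoidance.  The composite is the mean of the
#' four; animals above zero are classified susceptible, below zero
#' resilient (exactly zero: resilient with a tie flag).
#'
#' Only stressed animals enter the z-normalization cohort: the
#' classification applies to defeated animals, and controls would otherwise
#' shift the cohort mean.
#'
#' @param occupancy A data frame with one row per animal: `animal`,
#'   `si_t1`, `si_t2`, `corner_t1`, `corner_t2` (seconds; corner times summed
#'   over both corners), and optionally `scored` (logical; defaults to all).
#' @return A tibble of class `avoidance_result`: components, z-scores,
#'   `composite`, `label`, `tie_flag`, `excluded_reason`.
#' @export
social_avoidance_scores <- function(occupancy) {
  occ <- tibble::as_tibble(occupancy)
  need <- c("animal", "si_t1", "si_t2", "corner_t1", "corner_t2")
  miss <- setdiff(need, names(occ))
  if (length(miss)) abort(paste0("missing columns: ", paste(miss, collapse = ", ")))
  if (!"scored" %in% names(occ)) occ$scored <- TRUE

  occ$excluded_reason <- NA_character_
  zero_denom <- occ$scored & (occ$si_t1 <= 0 | occ$corner_t1 <= 0)
  if (any(zero_denom)) {
    warn(sprintf("%d animal(s) with zero trial-1 zone time excluded from scoring",
                 sum(zero_denom)))
    occ$excluded_reason[zero_denom] <- "zero_trial1_time"
  }
  use <- occ$scored & !zero_denom
  if (sum(use) < 2L) abort("need at least 2 scorable animals")

  occ$r_si <- ifelse(use, occ$si_t2 / occ$si_t1, NA_real_)
  occ$r_corner <- ifelse(use, occ$corner_t2 / occ$corner_t1, NA_real_)
  occ$d_si <- ifelse(use, occ$si_t2, NA_real_)
  occ$d_corner <- ifelse(use, occ$corner_t2, NA_real_)

  occ$z_si_ratio <- occ$z_corner_ratio <- occ$z_si_duration <-
    occ$z_corner_duration <- NA_real_
  occ$z_si_ratio[use] <- -zscore(occ$r_si[use], "interaction ratio")
  occ$z_corner_ratio[use] <- zscore(occ$r_corner[use], "corner ratio")
  occ$z_si_duration[use] <- -zscore(occ$d_si[use], "interaction duration")
  occ$z_corner_duration[use] <- zscore(occ$d_corner[use], "corner duration")
  occ$composite <- (occ$z_si_ratio + occ$z_corner_ratio +
                      occ$z_si_duration + occ$z_corner_duration) / 4
  occ$label <- dplyr::case_when(
    !use ~ NA_character_,
    occ$composite > 0 ~ "susceptible",
    TRUE ~ "resilient"
  )
  occ$tie_flag <- use & occ$composite == 0
  structure(occ, class = c("avoidance_result", class(tibble::tibble())))
}

#' Dominance call from the urine-marking assay
#'
#' In a divided chamber, the dominant mouse of a pair deposits more urine
#' marks over a greater territory.  A mouse is called dominant only if it
#' has strictly more deposits AND strictly greater marked area than its
#' partner; otherwise the pair is undetermined (such pairs are excluded
#' from downstream concordance tables).
#'
#' @param pair A data frame (or list) with one row per mouse of the pair:
#'   `mouse`, `n_deposits`, `area_cm2`.
#' @return A one-row tibble: `dominant` (mouse id or NA), `determined`.
#' @export
urine_marking_call <- function(pair) {
  pair <- tibble::as_tibble(pair)
  if (nrow(pair) != 2L) abort("a pair has exactly two mice")
  if (any(pair$n_deposits < 0) || any(pair$area_cm2 < 0)) {
    abort("counts and areas must be non-negative")
  }
  win1 <- pair$n_deposits[1L] > pair$n_deposits[2L] &&
    pair$area_cm2[1L] > pair$area_cm2[2L]
  win2 <- pair$n_deposits[2L] > pair$n_deposits[1L] &&
    pair$area_cm2[2L] > pair$area_cm2[1L]
  dom <- if (win1) pair$mouse[1L] else if (win2) pair$mouse[2L] else NA_character_
  tibble::tibble(dominant = dom, determined = !is.na(dom))
}

#' Concordance of tube-test and urine-marking dominance calls
#'
#' Builds the 2x2 contingency table of per-pair dominance calls from the two
#' assays (does the tube-test dominant mouse also win the urine-marking
#' call?) and tests association with Fisher's exact test.
#'
#' @param calls A data frame with one row per pair: `tube_dominant` and
#'   `urine_dominant` (mouse ids; pairs with an NA call are dropped), plus a
#'   reference mouse per pair in `mouse_a` defining which call counts as
#'   "A dominant".
#' @return A list: `table` (2x2), `odds_ratio`, `p` (two-sided).
#' @export
concordance_table <- function(calls) {
  calls <- tibble::as_tibble(calls)
  calls <- calls[!is.na(calls$tube_dominant) & !is.na(calls$urine_dominant), ]
  if (nrow(calls) < 1L) abort("need at least one pair with both calls")
  tube_a <- calls$tube_dominant == calls$mouse_a
  urine_a <- calls$urine_dominant == calls$mouse_a
  tab <- table(factor(tube_a, levels = c(TRUE, FALSE)),
               factor(urine_a, levels = c(TRUE, FALSE)),
               dnn = c("tube_a_dom", "urine_a_dom"))
  ft <- fisher_exact_2x2(matrix(as.integer(tab), 2L, 2L))
  list(table = tab, odds_ratio = ft$odds_ratio, p = ft$p)
}
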