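#' Assemble a pipeline run configuration
#'
#' A single configuration object governs a run; values can come from a YAML
#' file, with arguments overriding file entries.  Defaults embed the
#' analysis windows and exclusion rules of the two workflows and the
#' documented classifier conventions.
#'
#' @param yaml_path Optional YAML file of configuration entries.
#' @param ... Overrides: `seed`, `synthetic`, `output_dir`,
#'   `ethogram` (an [ethogram_config()]), `tube_windows`, `ofsi_windows`
#'   ([window_spec()]s), `geometry` (an [arena_geometry()]), and the
#'   synthetic design sizes (`n_cages`, `mice_per_cage`, `days`,
#'   `n_resilient`, `n_susceptible`, `n_control`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(yaml_path = NULL, ...) {
  cfg <- list(
    seed = 1L,
    synthetic = TRUE,
    output_dir = NULL,
    ethogram = ethogram_config(),
    tube_windows = window_spec("tube"),
    ofsi_windows = window_spec("ofsi"),
    geometry = arena_geometry(),
    n_cages = 2L, mice_per_cage = 4L, days = 5L,
    bout_duration_s = 20,
    n_resilient = 10L, n_susceptible = 10L, n_control = 10L,
    amp_effect = c(resilient = 0.05, susceptible = 0.01, control = 0),
    push_amp = c(subordinate = 0.05, dominant = 0.02)
  )
  if (!is.null(yaml_path)) {
    if (!file.exists(yaml_path)) abort(paste0("config file not found: ", yaml_path))
    from_file <- yaml::read_yaml(yaml_path)
    cfg[names(from_file)] <- from_file
  }
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "run_config")
}

new_manifest <- function(config, stages, exclusions, results_hash) {
  structure(list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("cagematch")),
    config = config,
    stage_counts = stages,
    exclusions = exclusions,
    results_hash = results_hash
  ), class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> seed %d, cagematch %s, hash %s\n",
              x$seed, x$package_version, x$results_hash))
  print(x$stage_counts)
  invisible(x)
}

# Scripted round-robin bout between a dominant and subordinate cage mate;
# the subordinate fully retreats (tailbase exits) at the end, deciding the
# win, and each push carries a photometry transient whose amplitude depends
# on the actor's status.
script_rr_bout <- function(dom_is_a, n_push_dom, n_push_sub, duration_s,
                           seed) {
  dom <- if (dom_is_a) "A" else "B"
  sub <- if (dom_is_a) "B" else "A"
  ep <- list()
  t <- 3
  for (i in seq_len(n_push_dom)) {
    ep[[length(ep) + 1L]] <- tibble::tibble(behavior = "body_push",
                                            actor = dom, start_s = t,
                                            duration_s = 1.2)
    t <- t + 4.5
  }
  for (i in seq_len(n_push_sub)) {
    ep[[length(ep) + 1L]] <- tibble::tibble(behavior = "body_push",
                                            actor = sub, start_s = t,
                                            duration_s = 1.2)
    t <- t + 4.5
  }
  # terminal full retreat: 5 s at 3 cm/s clears the tube end plus margin
  # even after the subordinate's own pushes advanced its tailbase
  ep[[length(ep) + 1L]] <- tibble::tibble(behavior = "retreat", actor = sub,
                                          start_s = duration_s - 5.5,
                                          duration_s = 5)
  bout_script(dplyr::bind_rows(ep), duration_s = duration_s, fps = 30,
              seed = seed)
}

#' Run the tube-test analysis workflow end to end
#'
#' Synthetic mode simulates round-robin cages with a fixed latent dominance
#' order (one upset on day 1, stable thereafter), classifies every bout,
#' computes behavior rates, outcomes, daily ranks and the stability day,
#' simulates a push-locked photometry recording per bout, extracts
#' tube-mode event-locked amplitudes and compares push-locked amplitudes of
#' subordinate versus dominant actors with Welch's t (rates) and the
#' mixed-effects model (amplitudes).
#'
#' @param config A [run_config()].
#' @return A list of class `tubetest_run`: `ethograms`, `rates`, `outcomes`,
#'   `ranks`, `stability`, `truth`, `amplitudes`, `rate_welch`, `amp_lmm`,
#'   `manifest`.
#' @export
run_tubetest_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!isTRUE(config$synthetic)) {
    abort("file-based runs need pose, photometry and bout metadata paths; see read_dlc_csv() and read_photometry_csv()")
  }
  set.seed(config$seed)
  n_mice <- config$mice_per_cage
  pairs <- utils::combn(n_mice, 2L)
  n_bouts_day <- ncol(pairs)
  seeds <- derive_seeds(config$n_cages * config$days * n_bouts_day * 2L)
  si <- 0L

  ethograms <- list(); rates <- list(); outcomes <- list(); truth <- list()
  amp_rows <- list(); exclusions <- list()
  for (cg in seq_len(config$n_cages)) {
    cage_id <- sprintf("cage%02d", cg)
    for (day in seq_len(config$days)) {
      for (p in seq_len(n_bouts_day)) {
        si <- si + 1L
        m1 <- pairs[1L, p]; m2 <- pairs[2L, p]
        # latent order = mouse index; day-1 upset between ranks 1 and 2
        dom_idx <- min(m1, m2); sub_idx <- max(m1, m2)
        if (day == 1L && dom_idx == 1L && sub_idx == 2L) {
          dom_idx <- 2L; sub_idx <- 1L
        }
        dom_is_a <- dom_idx < sub_idx
        n_push_dom <- sample(1:2, 1L)
        n_push_sub <- sample(0:1, 1L)
        script <- script_rr_bout(dom_is_a, n_push_dom, n_push_sub,
                                 config$bout_duration_s, seeds[si])
        sim <- simulate_tube_bout(script)
        bout <- sim$bout
        bout$cage_id <- cage_id
        bout$day <- day
        bout$bout_id <- sprintf("%s-d%d-%d", cage_id, day, p)
        id_of <- c(A = sprintf("%s-m%d", cage_id, m1),
                   B = sprintf("%s-m%d", cage_id, m2))
        if (!dom_is_a) { # dom scripted as B means min index rode B
          id_of <- c(A = sprintf("%s-m%d", cage_id, sub_idx),
                     B = sprintf("%s-m%d", cage_id, dom_idx))
        } else {
          id_of <- c(A = sprintf("%s-m%d", cage_id, dom_idx),
                     B = sprintf("%s-m%d", cage_id, sub_idx))
        }

        eth <- classify_behaviors(bout, config$ethogram)
        win <- detect_win(bout, config$ethogram)
        rt <- behavior_rates(eth, bout) |>
          dplyr::mutate(
            status = ifelse((.data$mouse == "A") == dom_is_a,
                            "dominant", "subordinate"),
            mouse = unname(id_of[.data$mouse]),
            cage_id = cage_id, day = day, bout_id = bout$bout_id
          )
        ethograms[[bout$bout_id]] <- eth
        rates[[bout$bout_id]] <- rt
        truth[[bout$bout_id]] <- dplyr::mutate(sim$truth,
                                               bout_id = bout$bout_id)
        outcomes[[bout$bout_id]] <- tibble::tibble(
          cage_id = cage_id, day = day, bout_id = bout$bout_id,
          winner = unname(id_of[win$winner]),
          loser = unname(id_of[win$loser]), flag = win$flag
        )

        # push-locked photometry for this bout
        pushes <- dplyr::filter(tibble::as_tibble(eth),
                                .data$label == "body_push")
        if (nrow(pushes)) {
          status <- ifelse((pushes$actor == "A") == dom_is_a,
                           "dominant", "subordinate")
          pp <- photo_sim_params(seed = seeds[si + length(seeds) / 2L])
          rec <- simulate_photometry(
            pushes$start_s, pp, duration_s = config$bout_duration_s,
            amp_per_event = config$push_amp[status]
          )
          trace <- isosbestic_normalize(rec$recording)
          qc <- qc_spread(trace)
          if (qc$qc_pass) {
            ev <- tibble::tibble(onset_s = pushes$start_s,
                                 bout_duration_s = bout$duration_s,
                                 mouse = unname(id_of[pushes$actor]),
                                 status = status)
            els <- suppressWarnings(
              extract_event_locked(trace, ev, config$tube_windows))
            amp_rows[[bout$bout_id]] <- els$events
            exc <- els$events[!els$events$included, ]
            if (nrow(exc)) {
              exclusions[[paste0(bout$bout_id, "-events")]] <- tibble::tibble(
                stage = "event_locked", record = bout$bout_id,
                reason = exc$reason
              )
            }
          } else {
            exclusions[[paste0(bout$bout_id, "-qc")]] <- tibble::tibble(
              stage = "photometry_qc", record = bout$bout_id,
              reason = "low_spread"
            )
          }
        }
      }
    }
  }

  outcomes <- dplyr::bind_rows(outcomes)
  rates <- dplyr::bind_rows(rates)
  ranks <- outcomes |>
    dplyr::group_by(.data$cage_id, .data$day) |>
    dplyr::group_modify(function(d, key) {
      mice <- sprintf("%s-m%d", key$cage_id, seq_len(n_mice))
      suppressWarnings(rank_cage(d, mice = mice))
    }) |>
    dplyr::ungroup()
  stability <- ranks |>
    dplyr::group_by(.data$cage_id) |>
    dplyr::summarise(stable_from_day = assess_stability(
      dplyr::pick("day", "mouse", "rank")), .groups = "drop")

  push_rates <- dplyr::filter(rates, .data$label == "body_push")
  rate_welch <- welch_t(
    push_rates$rate_per_s[push_rates$status == "dominant"],
    push_rates$rate_per_s[push_rates$status == "subordinate"]
  )
  amplitudes <- dplyr::bind_rows(amp_rows)
  amp_included <- dplyr::filter(amplitudes, .data$included)
  amp_lmm <- fit_group_lmm(amp_included, amplitude = "amplitude",
                           mouse = "mouse", group = "status",
                           ref = "dominant")

  results <- list(ethograms = ethograms, rates = rates, outcomes = outcomes,
                  ranks = ranks, stability = stability,
                  truth = dplyr::bind_rows(truth),
                  amplitudes = amplitudes,
                  rate_welch = rate_welch, amp_lmm = amp_lmm)
  stages <- tibble::tibble(
    stage = c("bouts", "events", "outcomes", "amplitude_events"),
    n = c(length(ethograms), sum(vapply(ethograms, nrow, integer(1))),
          nrow(outcomes), nrow(amplitudes))
  )
  results$manifest <- new_manifest(config, stages,
                                   dplyr::bind_rows(exclusions),
                                   rlang::hash(results))
  structure(results, class = "tubetest_run")
}

#' Run the social-defeat / open-field analysis workflow end to end
#'
#' Synthetic mode simulates a cohort ([simulate_cohort()]), computes
#' two-trial zone occupancies, the composite social-avoidance score with
#' susceptible/resilient labels over the stressed animals, detects trial-2
#' interaction-zone entries, normalizes each trial-2 recording
#' (sliding-median dF/F), applies QC, extracts entry-locked amplitudes
#' under the task's window rules (baseline `[-1.5, -1]` s, 3-s refractory)
#' and fits the mixed-effects group comparison against control.
#'
#' @param config A [run_config()].
#' @return A list of class `ofsi_run`: `animals`, `occupancy`, `avoidance`,
#'   `amplitudes`, `lmm`, `manifest`.  With an all-control cohort the
#'   scoring stage is skipped with a notice and `avoidance` is `NULL`.
#' @export
run_ofsi_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!isTRUE(config$synthetic)) {
    abort("file-based runs need trajectory and photometry paths; see read_photometry_csv()")
  }
  cohort <- simulate_cohort(config$n_resilient, config$n_susceptible,
                            config$n_control, amp_effect = config$amp_effect,
                            seed = config$seed, geom = config$geometry)
  animals <- cohort$animals
  exclusions <- list()

  occupancy <- purrr::map_dfr(animals$animal, function(id) {
    ses <- cohort$sessions[[id]]
    purrr::map_dfr(1:2, function(tr) {
      occ <- compute_zone_occupancy(ses[[paste0("trial", tr)]],
                                    config$geometry)
      tibble::tibble(
        animal = id, trial = tr,
        si_time = occ$duration_s[occ$zone == "interaction"],
        corner_time = occ$duration_s[occ$zone == "corners"],
        si_entries = occ$n_entries[occ$zone == "interaction"],
        distance_cm = occ$distance_cm[1L]
      )
    })
  })

  occ_wide <- occupancy |>
    tidyr::pivot_wider(id_cols = "animal", names_from = "trial",
                       values_from = c("si_time", "corner_time"),
                       names_sep = "_t") |>
    dplyr::rename(si_t1 = "si_time_t1", si_t2 = "si_time_t2",
                  corner_t1 = "corner_time_t1", corner_t2 = "corner_time_t2") |>
    dplyr::left_join(animals[, c("animal", "group", "stressed")],
                     by = "animal") |>
    dplyr::mutate(scored = .data$stressed)

  avoidance <- NULL
  if (any(occ_wide$scored)) {
    avoidance <- social_avoidance_scores(occ_wide)
  } else {
    inform("no stressed animals in cohort; avoidance scoring skipped")
  }

  amp_rows <- list()
  for (id in animals$animal) {
    rec <- cohort$recordings[[id]]$recording
    trace <- sliding_median_normalize(rec)
    qc <- qc_spread(trace)
    if (!qc$qc_pass) {
      exclusions[[id]] <- tibble::tibble(stage = "photometry_qc",
                                         record = id, reason = "low_spread")
      next
    }
    entries <- cohort$sessions[[id]]$truth$entries_t2
    if (!length(entries)) next
    ev <- tibble::tibble(onset_s = entries, animal = id,
                         group = animals$group[animals$animal == id])
    els <- suppressWarnings(
      extract_event_locked(trace, ev, config$ofsi_windows))
    amp_rows[[id]] <- els$events
    exc <- els$events[!els$events$included, ]
    if (nrow(exc)) {
      exclusions[[paste0(id, "-events")]] <- tibble::tibble(
        stage = "event_locked", record = id, reason = exc$reason)
    }
  }
  amplitudes <- dplyr::bind_rows(amp_rows)
  lmm <- NULL
  if (nrow(amplitudes)) {
    inc <- dplyr::filter(amplitudes, .data$included)
    if (length(unique(inc$group)) >= 2L) {
      lmm <- fit_group_lmm(inc, amplitude = "amplitude", mouse = "animal",
                           group = "group", ref = "control")
    }
  }

  results <- list(animals = animals, occupancy = occupancy,
                  avoidance = avoidance, amplitudes = amplitudes, lmm = lmm)
  stages <- tibble::tibble(
    stage = c("animals", "occupancy_rows", "entry_events"),
    n = c(nrow(animals), nrow(occupancy), nrow(amplitudes))
  )
  results$manifest <- new_manifest(config, stages,
                                   dplyr::bind_rows(exclusions),
                                   rlang::hash(results))
  structure(results, class = "ofsi_run")
}
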