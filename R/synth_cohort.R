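#' Simulate a chronic-defeat cohort with ground truth
#'
#' Generates, per animal, a two-trial open-field social-interaction session
#' (trajectory per trial) and a trial-2 photometry recording with a calcium
#' transient locked to every interaction-zone entry.  Entry transient
#' amplitudes are group-dependent (`amp_effect`) with an additional
#' per-animal Gaussian offset (`mouse_amp_sd`), giving the within-mouse
#' correlation structure that the mixed-model comparison is designed for.
#' Group behavioral profiles map resilient to the `approacher` trajectory
#' profile, susceptible to `avoider`, and control to `control`.
#'
#' @param n_resilient,n_susceptible,n_control Animals per group.
#' @param amp_effect Named numeric: entry-locked peak dF/F per group
#'   (defaults resilient 0.05, susceptible 0.01, control 0).
#' @param mouse_amp_sd SD of the per-animal amplitude offset (default
#'   0.005 dF/F).
#' @param seed Integer seed (drives all per-animal seeds).
#' @param geom An [arena_geometry()].
#' @param fps Trajectory frame rate (default 30).
#' @param photo_params Base [photo_sim_params()] for the recordings (its
#'   `transient_amp_dff` and `seed` are overridden per animal).
#' @return A list of class `cohort_dataset`: `animals` (tibble: `animal`,
#'   `group`, `stressed`, `true_amp`), `sessions` and `recordings` (named
#'   lists keyed by animal; each recording is a [simulate_photometry()]
#'   result for trial 2).
#' @export
simulate_cohort <- function(n_resilient, n_susceptible, n_control,
                            amp_effect = c(resilient = 0.05,
                                           susceptible = 0.01, control = 0),
                            mouse_amp_sd = 0.005, seed = 1L,
                            geom = arena_geometry(), fps = 30,
                            photo_params = photo_sim_params()) {
  if (min(n_resilient, n_susceptible, n_control) < 0) {
    abort("group counts must be >= 0")
  }
  groups <- rep(c("resilient", "susceptible", "control"),
                c(n_resilient, n_susceptible, n_control))
  n <- length(groups)
  if (n == 0L) {
    return(structure(list(animals = tibble::tibble(animal = character(),
                                                   group = character(),
                                                   stressed = logical(),
                                                   true_amp = numeric()),
                          sessions = list(), recordings = list()),
                     class = "cohort_dataset"))
  }
  set.seed(seed)
  seeds <- derive_seeds(2L * n)
  offsets <- rnorm(n, 0, mouse_amp_sd)
  profile_of <- c(resilient = "approacher", susceptible = "avoider",
                  control = "control")
  animals <- tibble::tibble(
    animal = sprintf("m%02d", seq_len(n)),
    group = groups,
    stressed = groups != "control",
    true_amp = unname(amp_effect[groups]) + offsets
  )
  sessions <- list()
  recordings <- list()
  for (i in seq_len(n)) {
    prof <- ofsi_profile(profile_of[[groups[i]]], seed = seeds[i])
    ses <- simulate_ofsi_session(prof, geom = geom, fps = fps)
    pp <- photo_params
    pp$seed <- seeds[n + i]
    rec <- simulate_photometry(ses$truth$entries_t2, pp,
                               duration_s = prof$trial_s,
                               amp_per_event = animals$true_amp[i])
    sessions[[animals$animal[i]]] <- ses
    recordings[[animals$animal[i]]] <- rec
  }
  structure(list(animals = animals, sessions = sessions,
                 recordings = recordings),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf("<cohort_dataset> %d animals (%s)\n", nrow(x$animals),
              paste(names(table(x$animals$group)),
                    table(x$animals$group), sep = ": ", collapse = ", ")))
  invisible(x)
}
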