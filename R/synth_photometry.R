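#' Photometry simulation parameters
#'
#' Parameters of the two-channel synthetic photometry model.  The signal
#' channel carries calcium transients (a GCaMP6s-like kernel,
#' `(1 - exp(-t/rise)) * exp(-t/decay)`, peak-normalized), a slow
#' photobleaching exponential, a shared low-frequency motion artifact and
#' white noise; the control (isosbestic) channel carries the same bleaching
#' and artifact (scaled by `artifact_gain_ratio`) plus independent noise,
#' but no transients.
#'
#' @param fs_hz Sampling rate, Hz (default 100).
#' @param transient_amp_dff Peak transient amplitude, fractional dF/F
#'   (default 0.05).
#' @param rise_tau_s,decay_tau_s Kernel time constants, s (defaults 0.2 and
#'   1.5, mimicking GCaMP6s kinetics -- the sensor is named, its kinetics
#'   are not, so these are conventions).
#' @param bleach_tau_s Photobleaching time constant, s (default 600).
#' @param artifact_amp Artifact SD as a fraction of baseline (default 0.02).
#' @param artifact_gain_ratio Artifact gain in the control channel relative
#'   to the signal channel (default 1).
#' @param artifact_smooth_s Gaussian smoothing SD shaping the artifact to
#'   below ~1 Hz, s (default 0.5).
#' @param noise_sd White-noise SD as a fraction of baseline (default 0.002).
#' @param baseline_f0 Baseline fluorescence, a.u. (default 100).
#' @param seed Integer seed.
#' @return A list of class `photo_sim_params`.
#' @export
photo_sim_params <- function(fs_hz = 100, transient_amp_dff = 0.05,
                             rise_tau_s = 0.2, decay_tau_s = 1.5,
                             bleach_tau_s = 600, artifact_amp = 0.02,
                             artifact_gain_ratio = 1, artifact_smooth_s = 0.5,
                             noise_sd = 0.002, baseline_f0 = 100, seed = 1L) {
  if (!fs_hz > 0) abort("fs_hz must be > 0")
  if (min(rise_tau_s, decay_tau_s, bleach_tau_s) <= 0) abort("taus must be > 0")
  if (!baseline_f0 > 0) abort("baseline_f0 must be > 0")
  if (transient_amp_dff < 0) abort("transient_amp_dff must be >= 0")
  structure(as.list(environment()), class = "photo_sim_params")
}

# Peak-normalized transient kernel evaluated at lag t >= 0.
transient_kernel <- function(t, rise_tau, decay_tau) {
  k <- (1 - exp(-t / rise_tau)) * exp(-t / decay_tau)
  t_peak <- rise_tau * log(1 + decay_tau / rise_tau)
  peak <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  k / peak
}

# Mean of the peak-normalized kernel over [0, upper] seconds: the expected
# mean-amplitude statistic per unit peak dF/F.
kernel_mean_amplitude <- function(rise_tau = 0.2, decay_tau = 1.5, upper = 4) {
  r <- 1 / decay_tau
  q <- 1 / decay_tau + 1 / rise_tau
  integral <- (1 - exp(-r * upper)) / r - (1 - exp(-q * upper)) / q
  t_peak <- rise_tau * log(1 + decay_tau / rise_tau)
  peak <- (1 - exp(-t_peak / rise_tau)) * exp(-t_peak / decay_tau)
  integral / peak / upper
}

#' Simulate a two-channel photometry recording
#'
#' Signal channel: `F0 * exp(-t/bleach_tau) * (1 + sum of transients +
#' artifact) + noise`; control channel: `F0 * exp(-t/bleach_tau) *
#' (1 + gain_ratio * artifact) + independent noise`.  Transients appear only
#' in the signal channel; the slow artifact is shared by both, so the
#' isosbestic regression can remove it.
#'
#' @param event_times_s Transient onset times, s, within `[0, duration_s]`.
#' @param params A [photo_sim_params()].
#' @param duration_s Recording length, s.
#' @param amp_per_event Optional per-event peak amplitudes (recycled);
#'   defaults to `params$transient_amp_dff`.
#' @return A list: `recording` (a [photometry_recording()]) and `truth`
#'   (list with `event_peaks_dff`, the `artifact` series and the clean
#'   `transient_sum`).
#' @export
simulate_photometry <- function(event_times_s, params = photo_sim_params(),
                                duration_s = 150, amp_per_event = NULL) {
  stopifnot(inherits(params, "photo_sim_params"))
  if (!duration_s > 0) abort("duration_s must be > 0")
  if (length(event_times_s) &&
      (min(event_times_s) < 0 || max(event_times_s) > duration_s)) {
    abort("event times must lie within [0, duration_s]")
  }
  fs <- params$fs_hz
  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1L) / fs
  amps <- if (is.null(amp_per_event)) {
    rep(params$transient_amp_dff, length(event_times_s))
  } else {
    rep_len(amp_per_event, length(event_times_s))
  }

  transients <- numeric(n)
  if (length(event_times_s)) {
    for (i in seq_along(event_times_s)) {
      lag <- t - event_times_s[i]
      on <- lag >= 0
      transients[on] <- transients[on] +
        amps[i] * transient_kernel(lag[on], params$rise_tau_s, params$decay_tau_s)
    }
  }

  set.seed(params$seed)
  artifact <- numeric(n)
  if (params$artifact_amp > 0) {
    raw <- rnorm(n)
    k <- round(params$artifact_smooth_s * fs)
    if (k > 0) {
      kern <- exp(-0.5 * ((-3 * k):(3 * k) / k)^2)
      kern <- kern / sum(kern)
      raw <- as.numeric(stats::filter(c(rev(raw[seq_len(3 * k)]), raw,
                                        rev(raw[n - seq_len(3 * k) + 1L])),
                                      kern, sides = 2))[3 * k + seq_len(n)]
    }
    artifact <- params$artifact_amp * raw / sd(raw)
  }

  bleach <- exp(-t / params$bleach_tau_s)
  f0 <- params$baseline_f0
  sig <- f0 * bleach * (1 + transients + artifact) +
    rnorm(n, 0, params$noise_sd * f0)
  ctl <- f0 * bleach * (1 + params$artifact_gain_ratio * artifact) +
    rnorm(n, 0, params$noise_sd * f0)

  list(
    recording = photometry_recording(t, sig, ctl, fs_hz = fs),
    truth = list(event_times_s = event_times_s, event_peaks_dff = amps,
                 artifact = artifact, transient_sum = transients)
  )
}
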