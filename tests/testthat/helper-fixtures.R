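# Fixture builders shared across test files.

# A tube bout from explicit position functions of time (seconds -> cm).
make_bout <- function(n_frames, fps = 30,
                      nose_a, tail_a, nose_b, tail_b,
                      facing = c(A = 1, B = -1), x0 = 0, x1 = 30) {
  tt <- (0:(n_frames - 1)) / fps
  f <- function(fun) if (is.function(fun)) fun(tt) else rep(fun, n_frames)
  tracks <- rbind(
    data.frame(mouse = "A", frame = 0:(n_frames - 1),
               nose_x = f(nose_a), nose_y = 1.5,
               tail_x = f(tail_a), tail_y = 1.5,
               conf_nose = 1, conf_tail = 1),
    data.frame(mouse = "B", frame = 0:(n_frames - 1),
               nose_x = f(nose_b), nose_y = 1.5,
               tail_x = f(tail_b), tail_y = 1.5,
               conf_nose = 1, conf_tail = 1)
  )
  tube_bout(tracks, fps = fps, x0 = x0, x1 = x1, facing = facing)
}

# A random bout script: 1-3 well-separated episodes with random labels.
random_script <- function(seed, noise_sd_cm = 0.05) {
  set.seed(seed)
  n_ep <- sample(1:3, 1)
  labs <- sample(c("body_push", "nose_push", "resist", "retreat"), n_ep,
                 replace = TRUE)
  actors <- sample(c("A", "B"), n_ep, replace = TRUE)
  starts <- 3 + (seq_len(n_ep) - 1) * 5.5 + runif(n_ep, 0, 0.5)
  durs <- runif(n_ep, 1, 1.8)
  duration <- max(starts + durs) + 4
  bout_script(data.frame(behavior = labs, actor = actors,
                         start_s = starts, duration_s = durs),
              duration_s = duration, noise_sd_cm = noise_sd_cm, seed = seed)
}

# dF/F trace object built directly from a numeric vector (for window and
# QC tests that do not need a simulated recording).
make_trace <- function(dff, fs = 100) {
  structure(
    tibble::tibble(time_s = (seq_along(dff) - 1) / fs, dff = dff),
    class = c("dff_trace", class(tibble::tibble())),
    fs_hz = fs, method = "sliding_median"
  )
}
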