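test_that("an idle script with zero noise yields stationary mice and no truth events", {
  sc <- bout_script(data.frame(behavior = "idle", actor = "A",
                               start_s = 0, duration_s = 10),
                    duration_s = 10, noise_sd_cm = 0, seed = 1)
  sim <- simulate_tube_bout(sc)
  expect_equal(nrow(sim$truth), 0)
  spreads <- tapply(sim$bout$tracks$nose_x, sim$bout$tracks$mouse, sd)
  expect_true(all(spreads == 0))
})

test_that("a scripted body push lands on the intended frames and satisfies the rule predicates", {
  sc <- bout_script(data.frame(behavior = "body_push", actor = "A",
                               start_s = 5, duration_s = 2),
                    duration_s = 20, fps = 30, noise_sd_cm = 0, seed = 2)
  sim <- simulate_tube_bout(sc)
  push <- sim$truth[sim$truth$label == "body_push", ]
  expect_equal(push$actor, "A")
  expect_equal(push$start_frame, 150L)
  expect_equal(push$end_frame, 210L)

  # frame-wise predicate oracle on the interior of the scripted span
  cfg <- ethogram_config()
  vel <- compute_velocity(sim$bout, cfg)
  va <- vel[vel$mouse == "A", ]
  vb <- vel[vel$mouse == "B", ]
  interior <- 156:204 # frames clear of the smoothing-induced transition
  expect_true(all(va$v_nose[interior + 1] >= cfg$v_push_cm_s))
  expect_true(all(va$v_tail[interior + 1] >= cfg$v_push_cm_s))
  expect_true(all(abs(va$nose_x - vb$nose_x)[interior + 1] <= cfg$nose_overlap_cm))
})

test_that("tube bout simulation is bit-identical under a fixed seed", {
  sc <- random_script(11)
  a <- simulate_tube_bout(sc)
  b <- simulate_tube_bout(sc)
  expect_identical(a$bout$tracks, b$bout$tracks)
  expect_false(identical(
    simulate_tube_bout(random_script(12))$bout$tracks, a$bout$tracks))
})

test_that("overlapping episodes for one actor are rejected", {
  expect_error(
    bout_script(data.frame(behavior = c("body_push", "retreat"),
                           actor = c("A", "A"),
                           start_s = c(5, 6), duration_s = c(2, 2)),
                duration_s = 20),
    "overlapping")
})

test_that("with no events, artifact or noise both channels are pure bleaching and dF/F is ~0", {
  pp <- photo_sim_params(artifact_amp = 0, noise_sd = 0, bleach_tau_s = 600,
                         seed = 1)
  sim <- simulate_photometry(numeric(0), pp, duration_s = 60)
  t <- sim$recording$time_s
  expect_equal(sim$recording$signal, pp$baseline_f0 * exp(-t / 600))
  expect_identical(sim$recording$signal, sim$recording$control)
  expect_lt(max(abs(isosbestic_normalize(sim$recording)$dff)), 1e-12)
  expect_lt(max(abs(sliding_median_normalize(sim$recording)$dff)), 0.005)
})

test_that("a single transient with no bleaching recovers the closed-form kernel peak", {
  pp <- photo_sim_params(artifact_amp = 0, noise_sd = 0, bleach_tau_s = 1e12,
                         transient_amp_dff = 0.05, seed = 1)
  sim <- simulate_photometry(10, pp, duration_s = 40)
  raw_dff <- sim$recording$signal / pp$baseline_f0 - 1
  # sampled maximum of the peak-normalized kernel at fs = 100
  lag <- seq(0, 30, by = 1 / pp$fs_hz)
  expected_peak <- 0.05 * max((1 - exp(-lag / 0.2)) * exp(-lag / 1.5)) /
    ((1 - exp(-0.2 * log(1 + 1.5 / 0.2) / 0.2)) *
       exp(-0.2 * log(1 + 1.5 / 0.2) / 1.5))
  expect_equal(max(raw_dff), expected_peak, tolerance = 1e-6)
  expect_equal(max(raw_dff), 0.05, tolerance = 1e-3)
})

test_that("the isosbestic regression removes a shared artifact that dominates the raw trace", {
  pp <- photo_sim_params(artifact_amp = 0.02, noise_sd = 0,
                         bleach_tau_s = 1e12, transient_amp_dff = 0, seed = 3)
  sim <- simulate_photometry(numeric(0), pp, duration_s = 120)
  raw_dff <- sim$recording$signal / mean(sim$recording$signal) - 1
  expect_gt(abs(cor(raw_dff, sim$truth$artifact)), 0.5)
  iso <- isosbestic_normalize(sim$recording)
  expect_lt(abs(cor(iso$dff, sim$truth$artifact)), 0.1)
})

test_that("with zero noise and artifact the injected transient mass matches the analytic kernel integral", {
  pp <- photo_sim_params(artifact_amp = 0, noise_sd = 0, bleach_tau_s = 600,
                         transient_amp_dff = 0.05, seed = 1)
  sim <- simulate_photometry(10, pp, duration_s = 60)
  # normalize against the known baseline (bleaching curve): what remains is
  # exactly the injected fractional modulation
  bleach <- pp$baseline_f0 * exp(-sim$recording$time_s / 600)
  dff <- sim$recording$signal / bleach - 1
  fs <- pp$fs_hz
  num <- sum(dff[(10 * fs):(40 * fs)]) / fs
  tp <- 0.2 * log(1 + 1.5 / 0.2)
  peak <- (1 - exp(-tp / 0.2)) * exp(-tp / 1.5)
  analytic <- 0.05 * (1.5 * (1 - exp(-30 / 1.5)) -
                        (1 - exp(-30 * (1 / 1.5 + 1 / 0.2))) / (1 / 1.5 + 1 / 0.2)) / peak
  expect_equal(num, analytic, tolerance = 0.01)
})

test_that("non-positive photometry duration and out-of-range events error", {
  expect_error(simulate_photometry(numeric(0), duration_s = 0), "duration")
  expect_error(simulate_photometry(200, duration_s = 100), "within")
})

test_that("ofsi trajectories realize requested occupancies within 5% and entry counts exactly", {
  prof <- ofsi_profile("approacher", mean_interaction_s = c(40, 60),
                       seed = 21)
  ses <- simulate_ofsi_session(prof)
  occ1 <- compute_zone_occupancy(ses$trial1)
  occ2 <- compute_zone_occupancy(ses$trial2)
  si1 <- occ1$duration_s[occ1$zone == "interaction"]
  si2 <- occ2$duration_s[occ2$zone == "interaction"]
  expect_lt(abs(si1 - 40) / 40, 0.05)
  expect_lt(abs(si2 - 60) / 60, 0.05)
  expect_equal(occ2$n_entries[occ2$zone == "interaction"], prof$n_entries)
  expect_equal(length(detect_zone_entries(ses$trial2)),
               length(ses$truth$entries_t2))
})

test_that("an avoider with zero trial-2 interaction time never enters the zone", {
  prof <- ofsi_profile("avoider", mean_interaction_s = c(40, 0), seed = 5)
  ses <- simulate_ofsi_session(prof)
  occ2 <- compute_zone_occupancy(ses$trial2)
  expect_equal(occ2$duration_s[occ2$zone == "interaction"], 0)
  expect_equal(length(detect_zone_entries(ses$trial2)), 0)
})

test_that("infeasible occupancy requests error", {
  prof <- ofsi_profile("control", mean_interaction_s = c(100, 40),
                       mean_corner_s = c(80, 10), seed = 1)
  expect_error(simulate_ofsi_session(prof), "infeasible")
})

test_that("an empty cohort is empty and a seeded cohort reproduces exactly", {
  empty <- simulate_cohort(0, 0, 0)
  expect_equal(nrow(empty$animals), 0)
  expect_length(empty$recordings, 0)

  a <- simulate_cohort(2, 2, 2, seed = 9)
  b <- simulate_cohort(2, 2, 2, seed = 9)
  expect_identical(rlang::hash(a), rlang::hash(b))
  expect_false(identical(rlang::hash(simulate_cohort(2, 2, 2, seed = 10)),
                         rlang::hash(a)))
})

test_that("scripted behaviors and zone entries are recoverable with onset error below 0.2 s", {
  # generator/analyzer closure at low noise
  for (seed in c(31, 32, 33)) {
    sc <- random_script(seed, noise_sd_cm = 0.1)
    sim <- simulate_tube_bout(sc)
    eth <- classify_behaviors(sim$bout)
    for (lab in unique(sim$truth$label)) {
      pr <- label_pr(list(eth), list(sim$truth), lab)
      expect_equal(unname(pr["recall"]), 1)
    }
  }
})
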