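test_that("velocity is zero for stationary tracks and exact for linear motion", {
  b <- make_bout(120, nose_a = 10, tail_a = 5, nose_b = 20, tail_b = 25)
  v <- compute_velocity(b)
  expect_true(all(v$v_nose == 0))
  expect_true(all(v$v_tail == 0))

  # x(t) = 5 + 3t toward the partner for A (facing +1)
  b2 <- make_bout(120, nose_a = function(t) 10 + 3 * t,
                  tail_a = function(t) 5 + 3 * t,
                  nose_b = 25, tail_b = 28)
  v2 <- compute_velocity(b2)
  va <- v2[v2$mouse == "A", ]
  interior <- 5:115
  expect_equal(va$v_nose[interior], rep(3, length(interior)), tolerance = 1e-10)

  # same motion with reversed facing flips the sign
  b3 <- make_bout(120, nose_a = function(t) 10 + 3 * t,
                  tail_a = function(t) 5 + 3 * t,
                  nose_b = 25, tail_b = 28, facing = c(A = -1, B = 1))
  v3 <- compute_velocity(b3)
  expect_equal(v3$v_nose[v3$mouse == "A"][interior],
               rep(-3, length(interior)), tolerance = 1e-10)
})

test_that("velocity errors on bouts shorter than the smoothing window", {
  b <- make_bout(4, nose_a = 10, tail_a = 5, nose_b = 20, tail_b = 25)
  expect_error(compute_velocity(b), "smoothing")
})

test_that("a fully stationary bout yields an empty ethogram", {
  b <- make_bout(300, nose_a = 10, tail_a = 5, nose_b = 20, tail_b = 25)
  eth <- classify_behaviors(b)
  expect_equal(nrow(eth), 0)
})

test_that("a scripted body push is recovered with the correct actor and onset", {
  sc <- bout_script(data.frame(behavior = "body_push", actor = "B",
                               start_s = 6, duration_s = 1.5),
                    duration_s = 18, noise_sd_cm = 0, seed = 4)
  sim <- simulate_tube_bout(sc)
  eth <- classify_behaviors(sim$bout)
  push <- eth[eth$label == "body_push", ]
  expect_equal(nrow(push), 1)
  expect_equal(push$actor, "B")
  expect_lt(abs(push$start_s - 6), 0.2)
})

test_that("a push is vetoed while the partner retreats, and the retreat is emitted", {
  # A advances (nose and tail >= threshold) with nose contact maintained,
  # while B's tailbase retreats at -3 cm/s for 1.5 s (4.5 cm >= minimum)
  fps <- 30
  n <- 300
  move <- function(t, v, s, e) v * pmin(pmax(t - s, 0), e - s)
  b <- make_bout(n, fps = fps,
                 nose_a = function(t) 12 + move(t, 3, 4, 5.5),
                 tail_a = function(t) 6 + move(t, 3, 4, 5.5),
                 nose_b = function(t) 12.5 + move(t, 3, 4, 5.5),
                 tail_b = function(t) 20 + move(t, 3, 4, 5.5))
  eth <- classify_behaviors(b)
  expect_equal(sum(eth$label %in% c("body_push", "nose_push") &
                     eth$actor == "A"), 0)
  retreat <- eth[eth$label == "retreat", ]
  expect_equal(retreat$actor, "B")
})

test_that("behavior rates are initiations per second with a complete mouse-by-label grid", {
  b <- make_bout(900, nose_a = 10, tail_a = 5, nose_b = 20, tail_b = 25) # 30 s
  empty <- classify_behaviors(b)
  r0 <- behavior_rates(empty, b)
  expect_equal(nrow(r0), 8)
  expect_true(all(r0$rate_per_s == 0))

  sc <- bout_script(data.frame(behavior = rep("body_push", 3), actor = "A",
                               start_s = c(4, 12, 20), duration_s = 1.2),
                    duration_s = 30, noise_sd_cm = 0, seed = 5)
  sim <- simulate_tube_bout(sc)
  eth <- classify_behaviors(sim$bout)
  r <- behavior_rates(eth, sim$bout)
  expect_equal(r$rate_per_s[r$mouse == "A" & r$label == "body_push"], 3 / 30)
  expect_equal(r$n_events, as.integer(r$rate_per_s * 30))
})

test_that("interval classification equals the frame-wise oracle on random bouts", {
  for (seed in c(101, 102, 103, 104, 105)) {
    sim <- simulate_tube_bout(random_script(seed))
    got <- as.data.frame(classify_behaviors(sim$bout))
    want <- oracle_classify(sim$bout)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("same-label events never overlap and body/nose push are mutually exclusive per frame", {
  for (seed in 201:205) {
    sim <- simulate_tube_bout(random_script(seed))
    eth <- as.data.frame(classify_behaviors(sim$bout))
    for (act in c("A", "B")) {
      for (lab in unique(eth$label)) {
        ev <- eth[eth$actor == act & eth$label == lab, ]
        if (nrow(ev) > 1) {
          ev <- ev[order(ev$start_frame), ]
          expect_true(all(ev$start_frame[-1] >= ev$end_frame[-nrow(ev)]))
        }
      }
      pushes <- eth[eth$actor == act & eth$label %in% c("body_push", "nose_push"), ]
      if (nrow(pushes) > 1) {
        frames <- unlist(mapply(seq, pushes$start_frame, pushes$end_frame - 1,
                                SIMPLIFY = FALSE))
        expect_false(anyDuplicated(frames) > 0)
      }
    }
  }
})

test_that("low-confidence gaps longer than the limit skip the bout with a reason", {
  tt <- (0:299) / 30
  tracks <- rbind(
    data.frame(mouse = "A", frame = 0:299, nose_x = 10, nose_y = 1.5,
               tail_x = 5, tail_y = 1.5,
               conf_nose = c(rep(0.1, 40), rep(1, 260)), conf_tail = 1),
    data.frame(mouse = "B", frame = 0:299, nose_x = 20, nose_y = 1.5,
               tail_x = 25, tail_y = 1.5, conf_nose = 1, conf_tail = 1)
  )
  b <- tube_bout(tracks, fps = 30)
  expect_warning(eth <- classify_behaviors(b), "skipped")
  expect_equal(nrow(eth), 0)
  expect_equal(attr(eth, "skip_reason"), "low_confidence_gap")
})

test_that("short low-confidence stretches are interpolated, not fatal", {
  conf <- rep(1, 300); conf[100:110] <- 0.2
  tracks <- rbind(
    data.frame(mouse = "A", frame = 0:299, nose_x = 10, nose_y = 1.5,
               tail_x = 5, tail_y = 1.5, conf_nose = conf, conf_tail = 1),
    data.frame(mouse = "B", frame = 0:299, nose_x = 20, nose_y = 1.5,
               tail_x = 25, tail_y = 1.5, conf_nose = 1, conf_tail = 1)
  )
  b <- tube_bout(tracks, fps = 30)
  eth <- classify_behaviors(b)
  expect_equal(nrow(eth), 0)
  expect_false(attr(eth, "skipped"))
})
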