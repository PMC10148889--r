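test_that("zone occupancy handles always-inside and never-inside trajectories", {
  geom <- arena_geometry()
  n <- 4500 # 150 s at 30 fps
  inside <- data.frame(time_s = (0:(n - 1)) / 30,
                       x_cm = 22, y_cm = 37)
  occ <- compute_zone_occupancy(inside, geom)
  expect_equal(occ$duration_s[occ$zone == "interaction"], 150)
  expect_equal(occ$n_entries[occ$zone == "interaction"], 1)

  outside <- data.frame(time_s = (0:(n - 1)) / 30, x_cm = 22, y_cm = 20)
  occ2 <- compute_zone_occupancy(outside, geom)
  expect_true(all(occ2$duration_s == 0))
  expect_true(all(occ2$n_entries == 0))
  expect_error(compute_zone_occupancy(inside[0, ], geom), "empty")
})

test_that("occupancy across zones and outside conserves the trial duration", {
  prof <- ofsi_profile("avoider", seed = 7)
  ses <- simulate_ofsi_session(prof)
  geom <- arena_geometry()
  occ <- compute_zone_occupancy(ses$trial2, geom)
  fps <- 30
  tr <- ses$trial2
  m_int <- tr$x_cm >= geom$interaction[1] & tr$x_cm <= geom$interaction[2] &
    tr$y_cm >= geom$interaction[3] & tr$y_cm <= geom$interaction[4]
  m_c1 <- tr$x_cm >= geom$corner1[1] & tr$x_cm <= geom$corner1[2] &
    tr$y_cm >= geom$corner1[3] & tr$y_cm <= geom$corner1[4]
  m_c2 <- tr$x_cm >= geom$corner2[1] & tr$x_cm <= geom$corner2[2] &
    tr$y_cm >= geom$corner2[3] & tr$y_cm <= geom$corner2[4]
  outside <- sum(!(m_int | m_c1 | m_c2)) / fps
  total <- occ$duration_s[occ$zone == "interaction"] +
    occ$duration_s[occ$zone == "corners"] + outside
  expect_equal(total, 150, tolerance = 1 / fps)
})

test_that("zone entries are onsets of outside-to-inside transitions", {
  zone <- c(0, 10, 0, 10)
  tr <- data.frame(time_s = (0:99) / 10,
                   x_cm = rep(c(5, 20, 5, 20), each = 25), y_cm = 5)
  ons <- detect_zone_entries(tr, zone)
  expect_equal(ons, c(0, 5)) # starts inside (t = 0) then re-enters at t = 5
  none <- detect_zone_entries(data.frame(time_s = 0:9, x_cm = 50, y_cm = 50),
                              zone)
  expect_length(none, 0)
})

test_that("a two-animal cohort z-scores to +/-1 with opposite labels and zero-sum composites", {
  occ <- data.frame(animal = c("avoid", "approach"),
                    si_t1 = c(40, 40), si_t2 = c(2, 70),
                    corner_t1 = c(20, 20), corner_t2 = c(80, 5))
  res <- social_avoidance_scores(occ)
  av <- res[res$animal == "avoid", ]
  ap <- res[res$animal == "approach", ]
  # n = 2: every z-score is +/- 1/sqrt(2)... with sample sd the z of the two
  # points are +/- 1/sqrt(2) * sqrt(2) = +/- 0.7071... * sqrt2; check signs
  expect_equal(abs(av$z_si_ratio), abs(ap$z_si_ratio))
  expect_gt(av$composite, 0)
  expect_lt(ap$composite, 0)
  expect_equal(av$composite + ap$composite, 0, tolerance = 1e-12)
  expect_equal(av$label, "susceptible")
  expect_equal(ap$label, "resilient")
})

test_that("an animal exactly at the cohort mean scores zero and is resilient with a tie flag", {
  occ <- data.frame(animal = c("a", "b", "mid"),
                    si_t1 = c(40, 40, 40), si_t2 = c(10, 70, 40),
                    corner_t1 = c(20, 20, 20), corner_t2 = c(60, 10, 35))
  res <- social_avoidance_scores(occ)
  mid <- res[res$animal == "mid", ]
  expect_equal(mid$composite, 0, tolerance = 1e-12)
  expect_equal(mid$label, "resilient")
  expect_true(mid$tie_flag)
})

test_that("component z-scores have mean zero and unit sd and swaps exchange composites", {
  set.seed(10)
  occ <- data.frame(animal = letters[1:8],
                    si_t1 = runif(8, 30, 50), si_t2 = runif(8, 5, 70),
                    corner_t1 = runif(8, 10, 30), corner_t2 = runif(8, 5, 70))
  res <- social_avoidance_scores(occ)
  for (col in c("z_si_ratio", "z_corner_ratio", "z_si_duration",
                "z_corner_duration")) {
    expect_lt(abs(mean(res[[col]])), 1e-9)
    expect_lt(abs(sd(res[[col]]) - 1), 1e-9)
  }
  swapped <- occ
  swapped[c(1, 2), -1] <- occ[c(2, 1), -1]
  res2 <- social_avoidance_scores(swapped)
  expect_equal(res2$composite[1], res$composite[2])
  expect_equal(res2$composite[2], res$composite[1])
  expect_equal(res2$composite[3:8], res$composite[3:8])
})

test_that("increasing trial-2 interaction time strictly decreases the composite", {
  set.seed(11)
  occ <- data.frame(animal = letters[1:6],
                    si_t1 = 40, si_t2 = c(10, 20, 30, 40, 50, 60),
                    corner_t1 = 20, corner_t2 = runif(6, 10, 50))
  res <- social_avoidance_scores(occ)
  # z parameters held fixed: bump one animal's trial-2 interaction time
  bumped <- occ
  bumped$si_t2[3] <- bumped$si_t2[3] + 5
  res2 <- social_avoidance_scores(bumped)
  # recompute animal 3's components against the ORIGINAL cohort parameters
  z1 <- (res$r_si - mean(res$r_si)) / sd(res$r_si)
  expect_gt(res$composite[3], {
    r_new <- bumped$si_t2[3] / bumped$si_t1[3]
    d_new <- bumped$si_t2[3]
    comp_new <- (-(r_new - mean(res$r_si)) / sd(res$r_si) +
                   res$z_corner_ratio[3] -
                   (d_new - mean(res$d_si)) / sd(res$d_si) +
                   res$z_corner_duration[3]) / 4
    comp_new
  })
})

test_that("zero trial-1 denominators exclude the animal with a warning", {
  occ <- data.frame(animal = c("a", "b", "c"),
                    si_t1 = c(0, 40, 40), si_t2 = c(10, 20, 60),
                    corner_t1 = c(20, 20, 20), corner_t2 = c(30, 40, 10))
  expect_warning(res <- social_avoidance_scores(occ), "zero trial-1")
  expect_equal(res$excluded_reason[1], "zero_trial1_time")
  expect_true(is.na(res$composite[1]))
  expect_false(any(is.na(res$composite[2:3])))
})

test_that("urine marking calls dominance only on strictly more deposits AND area", {
  clear <- data.frame(mouse = c("A", "B"), n_deposits = c(12, 3),
                      area_cm2 = c(30, 5))
  expect_equal(urine_marking_call(clear)$dominant, "A")

  conflict <- data.frame(mouse = c("A", "B"), n_deposits = c(12, 3),
                         area_cm2 = c(4, 5))
  expect_true(is.na(urine_marking_call(conflict)$dominant))

  tied <- data.frame(mouse = c("A", "B"), n_deposits = c(5, 5),
                     area_cm2 = c(30, 5))
  expect_false(urine_marking_call(tied)$determined)
})

test_that("tube/urine concordance builds the right table and exact p", {
  calls <- data.frame(mouse_a = paste0("a", 1:10),
                      tube_dominant = c(paste0("a", 1:5), paste0("b", 6:10)),
                      urine_dominant = c(paste0("a", 1:5), paste0("b", 6:10)))
  res <- concordance_table(calls)
  expect_equal(as.vector(res$table), c(5L, 0L, 0L, 5L))
  expect_equal(res$p, oracle_fisher_p(matrix(c(5, 0, 0, 5), 2)),
               tolerance = 1e-12)

  indep <- data.frame(mouse_a = paste0("a", 1:20),
                      tube_dominant = rep(c("dom_a", "dom_b"), each = 10),
                      urine_dominant = rep(c("dom_a", "dom_b", "dom_a", "dom_b"),
                                           each = 5))
  indep$tube_dominant <- ifelse(indep$tube_dominant == "dom_a",
                                indep$mouse_a, paste0("x", 1:20))
  indep$urine_dominant <- ifelse(indep$urine_dominant == "dom_a",
                                 indep$mouse_a, paste0("y", 1:20))
  res2 <- concordance_table(indep)
  expect_equal(res2$p, 1)
})
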