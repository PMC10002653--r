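test_that("identical seeds reproduce trajectories, turns and events exactly", {
  a <- simulate_experiment(2, 600, seed = 5)
  b <- simulate_experiment(2, 600, seed = 5)
  expect_identical(a$tracks, b$tracks)
  expect_identical(a$turns, b$turns)
  expect_identical(a$events, b$events)
})

test_that("adding animals does not perturb existing trajectories", {
  a <- simulate_experiment(1, 600, seed = 9)
  b <- simulate_experiment(3, 600, seed = 9)
  expect_identical(a$tracks, b$tracks[b$tracks$animal_id == 1, ])
})

test_that("run-mode displacement follows speed and turns barely translate", {
  p <- sim_params(heading_diffusion = 0, speed_decline_rate = 0,
                  base_speed = 0.4)
  # short run from the centre so the walls are never reached (clamping at a
  # wall shortens the step)
  s <- simulate_larva(200, p, seed = 3, ctrl_seed = 4,
                      start_xy = c(110, 110),
                      controller = robot_controller(enabled = FALSE))
  tr <- s$track
  step <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
  run2 <- tr$mode[-1] == "run" & tr$mode[-nrow(tr)] == "run"
  expect_true(all(abs(step[run2] - 0.4 * 0.1) < 1e-9))
  turn2 <- tr$mode[-1] == "turn"
  expect_true(all(step[turn2] <= 0.1 * 0.4 * 0.1 + 1e-9))
  # speeds stay at or above the configured floor at all times
  expect_true(all(tr$speed_mms >= 0))
  long <- simulate_larva(7200, sim_params(), seed = 3, ctrl_seed = 4)$track
  crawling <- long$mode == "run" & !long$dropped & is.na(long$event_id)
  expect_true(all(long$speed_mms[crawling] >= sim_params()$min_speed - 1e-12))
})

test_that("positions stay inside the arena and modes alternate run/turn", {
  s <- simulate_larva(3600, sim_params(), seed = 17, ctrl_seed = 18,
                      controller = robot_controller(enabled = FALSE))
  tr <- s$track
  expect_true(all(tr$x_mm >= 0 & tr$x_mm <= 220))
  expect_true(all(tr$y_mm >= 0 & tr$y_mm <= 220))
  r <- rle(tr$mode)
  expect_true(all(r$values[-1] != r$values[-length(r$values)]))
  # every logged turn matches a contiguous block of turn-mode frames
  for (k in seq_len(nrow(s$turns))) {
    blk <- tr$mode[s$turns$start_frame[k]:s$turns$end_frame[k]]
    expect_true(all(blk == "turn"))
  }
  # dropped-frame mask is false outside robot events
  expect_true(all(!tr$dropped[is.na(tr$event_id)]))
})

test_that("turn initiation matches the Poisson thinning closed form", {
  # lambda = 6/min, dt = 0.1 s -> per-step p = 1 - exp(-0.01) = 0.00995
  p <- sim_params(base_turn_rate = 6)
  s <- simulate_larva(7200, p, seed = 31, ctrl_seed = 32,
                      controller = robot_controller(enabled = FALSE))
  n_run <- sum(s$track$mode == "run")
  p_hat <- nrow(s$turns) / n_run
  p_exp <- 1 - exp(-6 * 0.1 / 60)
  expect_lt(abs(p_hat - p_exp) / p_exp, 0.15)   # ~700 events, Poisson error
})

test_that("left-turn fraction recovers the handedness bias", {
  p <- sim_params(handedness_bias = 0.8, base_turn_rate = 6)
  s <- simulate_larva(7200, p, seed = 41, ctrl_seed = 42,
                      controller = robot_controller(enabled = FALSE))
  n <- nrow(s$turns)
  lf <- mean(s$turns$direction == "left")
  expect_lt(abs(lf - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("turn sizes respect the truncated distribution bounds", {
  s <- simulate_larva(7200, sim_params(base_turn_rate = 6), seed = 51,
                      ctrl_seed = 52,
                      controller = robot_controller(enabled = FALSE))
  expect_true(all(s$turns$size_deg >= 20 & s$turns$size_deg <= 180))
})

test_that("klinokinesis drives net displacement toward the warm side", {
  fld <- thermal_field()
  dx <- vapply(1:4, function(i) {
    s <- simulate_larva(1800, sim_params(thermotaxis_gain = 2), field = fld,
                        seed = 60 + i, ctrl_seed = 80 + i,
                        controller = robot_controller(enabled = FALSE))
    tr <- s$track
    tr$x_mm[nrow(tr)] - tr$x_mm[1]
  }, numeric(1))
  expect_gt(mean(dx), 0)
})

test_that("retry ladder reaches near-certain success from p_first = 0.9", {
  set.seed(1)
  ok <- vapply(1:10000,
               function(i) larvawalk:::attempt_with_retries(0.9, 10L)$success,
               logical(1))
  expect_gte(mean(ok), 0.99)
  att <- vapply(1:2000,
                function(i) larvawalk:::attempt_with_retries(0.9, 10L)$attempts,
                integer(1))
  expect_lt(abs(mean(att == 1) - 0.9), 0.03)  # 90% first-try, as instrumented
})

test_that("every successful pickup is followed by a drop-off for that animal", {
  s <- simulate_experiment(3, 5400, seed = 77)
  ev <- s$events
  picks <- which(ev$type == "pickup" & ev$success)
  expect_gt(length(picks), 0)
  for (i in picks) {
    expect_lt(i, nrow(ev))
    expect_identical(ev$type[i + 1], "dropoff")
    expect_identical(ev$animal_id[i + 1], ev$animal_id[i])
    expect_identical(ev$frame[i + 1], ev$frame[i])
  }
  # drop-offs land near the arena centre
  drops <- ev[ev$type == "dropoff", ]
  expect_true(all(abs(drops$to_x_mm - 110) < 15))
  # manipulation frames are dropped; the animal reappears near the centre
  tr <- s$tracks[s$tracks$animal_id == ev$animal_id[picks[1]], ]
  eid <- ev$event_id[picks[1]]
  man <- which(!is.na(tr$event_id) & tr$event_id == eid)
  expect_true(all(tr$dropped[man]))
  after <- max(man) + 1L
  expect_lt(sqrt((tr$x_mm[after] - 110)^2 + (tr$y_mm[after] - 110)^2), 20)
})

test_that("failed pickups are logged and never lose the animal", {
  ctrl <- robot_controller(p_first_pickup = 0.01, p_boost = 0,
                          max_attempts = 2L)
  s <- simulate_larva(3600, sim_params(), seed = 91, ctrl_seed = 92,
                      controller = ctrl)
  ev <- s$events
  fails <- ev[ev$type == "pickup" & !ev$success, ]
  expect_gt(nrow(fails), 0)
  expect_true(all(fails$attempts == 2))
  expect_true(all(is.finite(s$track$x_mm)))
  expect_true(all(s$track$x_mm >= 0 & s$track$x_mm <= 220))
})

test_that("scheduled feeding inserts paused feed/rinse events", {
  ctrl <- robot_controller(feed_interval_s = 600, feed_duration_s = 30)
  s <- simulate_larva(1800, sim_params(), seed = 101, ctrl_seed = 102,
                      controller = ctrl)
  feeds <- s$events[s$events$type == "feed", ]
  expect_gte(nrow(feeds), 2)
  expect_true(all(s$events$type[match(feeds$event_id, s$events$event_id) + 1] ==
                    "rinse"))
  # trajectory pauses during feeding
  f1 <- feeds$frame[1]
  expect_equal(s$track$x_mm[f1], s$track$x_mm[f1 + 25])
  expect_equal(s$track$speed_mms[f1 + 10], 0)
})
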