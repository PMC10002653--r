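test_that("kinematics: constant velocity, circles, and stationary tracks", {
  tr <- straight_track(300, speed = 0.3)
  kin <- kinematics(tr)
  inner <- 10:290    # boxcar edge replication perturbs the first/last frames
  expect_equal(kin$speed_mms[inner], rep(0.3, length(inner)), tolerance = 1e-9)
  expect_equal(kin$heading_deg[inner], rep(0, length(inner)), tolerance = 1e-9)
  # circular path of radius 10 mm -> curvature 0.1 /mm within 2%
  R <- 10; v <- 0.3; n <- 2000
  t <- (seq_len(n) - 1) / 10
  circ <- data.frame(frame = seq_len(n), time_s = t,
                     x_mm = 110 + R * cos(v * t / R),
                     y_mm = 110 + R * sin(v * t / R))
  kc <- kinematics(circ)
  curv <- kc$curvature_per_mm[50:(n - 50)]
  expect_lt(max(abs(curv - 0.1) / 0.1), 0.02)
  # stationary: zero speed, curvature all missing
  still <- data.frame(frame = 1:100, time_s = (0:99) / 10,
                      x_mm = rep(50, 100), y_mm = rep(50, 100))
  ks <- kinematics(still)
  expect_true(all(ks$speed_mms == 0))
  expect_true(all(is.na(ks$curvature_per_mm)))
})

test_that("navigation index hits its exact extremes", {
  expect_equal(navigation_index(straight_track(600, 0.3, 0))$ni, 1)
  expect_equal(navigation_index(straight_track(600, 0.3, 180))$ni, -1)
  expect_equal(navigation_index(straight_track(600, 0.3, 90))$ni, 0)
})

test_that("navigation index is a ratio of means and respects its bounds", {
  # half the time at unit speed along +x, half along +y -> 0.5
  k <- data.frame(vx_mms = c(rep(1, 50), rep(0, 50)),
                  vy_mms = c(rep(0, 50), rep(1, 50)),
                  time_s = (0:99) / 10)
  expect_equal(navigation_index(k, window_min = NULL)$ni, 0.5)
  # bounds on arbitrary simulated windows
  s <- simulate_larva(1800, sim_params(), seed = 44, ctrl_seed = 45)
  ni <- navigation_index(kinematics(s$track))
  expect_true(all(abs(ni$windows$ni) <= 1 + 1e-12, na.rm = TRUE))
  expect_true(abs(ni$ni) <= 1)
  # all frames below v_min -> missing
  still <- data.frame(frame = 1:100, time_s = (0:99) / 10,
                      x_mm = rep(50, 100), y_mm = rep(50, 100))
  expect_true(is.na(navigation_index(still)$ni))
})

test_that("reflecting a trajectory across the gradient normal negates NI", {
  s <- simulate_larva(900, sim_params(thermotaxis_gain = 2),
                      field = thermal_field(), seed = 46, ctrl_seed = 47,
                      controller = robot_controller(enabled = FALSE))
  tr <- s$track
  mirrored <- tr
  mirrored$x_mm <- 220 - tr$x_mm
  expect_equal(navigation_index(kinematics(mirrored))$ni,
               -navigation_index(kinematics(tr))$ni, tolerance = 1e-9)
})

test_that("turn statistics and handedness summaries", {
  expect_equal(handedness(10, 0), 1)
  expect_equal(handedness(0, 10), -1)
  expect_equal(handedness(6, 4), 0.2)
  expect_true(is.na(handedness(0, 0)))
  seg <- data.frame(animal_id = 1, state = c("run", "turn", "run", "turn", "run"),
                    start_frame = c(1, 101, 121, 301, 321),
                    end_frame = c(100, 120, 300, 320, 600),
                    start_s = c(0, 10, 12, 30, 32),
                    end_s = c(10, 12, 30, 32, 60),
                    direction = c(NA, "left", NA, "left", NA),
                    turn_size_deg = c(NA, 60, NA, 90, NA))
  ts <- turn_statistics(seg, window_min = 1, total_time_s = 60)
  expect_identical(ts$summary$n_total, 2L)
  expect_equal(ts$summary$handedness, 1)
  expect_equal(sum(ts$series$n_turns), 2L)
  # turn rate normalizes by run time within the bin: both turns fall in the
  # first minute, which holds 10 + 18 + 28 = 56 s of run time
  expect_equal(ts$series$turn_rate_per_min[1], 2 / (56 / 60))
})

test_that("peri-event averaging detects an injected transient only", {
  set.seed(21)
  fr <- 10; n <- 48000                      # 80 min at 10 Hz
  t_s <- (seq_len(n) - 1) / fr
  ev <- c(600, 1500, 2400, 3300, 4200)      # seconds, well inside the series
  v <- rnorm(n, 0.3, 0.05)
  for (e in ev) {
    i <- e * fr
    v[(i + 1):(i + 90 * fr)] <- v[(i + 1):(i + 90 * fr)] + 0.1
  }
  pe <- peri_event_average(data.frame(time_s = t_s, value = v), ev)
  expect_identical(pe$n_events, 5L)
  expect_true(all(pe$minute_tests$significant[1:2]))
  expect_gt(pe$minute_tests$mean_post[1], pe$pre_mean + 0.05)
  expect_true(pe$returns_to_baseline)
  # constant input: no significant minutes, pre mean equals post mean
  pc <- peri_event_average(data.frame(time_s = t_s, value = rep(0.3, n)), ev)
  expect_true(all(!pc$minute_tests$significant))
  expect_equal(pc$pre_mean, 0.3)
  # events too close to the boundary are skipped and counted
  pb <- peri_event_average(data.frame(time_s = t_s, value = v), c(10, 600))
  expect_identical(pb$n_skipped, 1L)
  expect_identical(pb$n_events, 1L)
})

test_that("stitching glues sub-paths rigidly and preserves length", {
  # two straight 10 mm sub-paths split by a manipulation
  t1 <- straight_track(101, speed = 1, heading_deg = 0, start = c(50, 50))
  t2 <- straight_track(101, speed = 1, heading_deg = 0, start = c(110, 110))
  t2$frame <- t2$frame + 110
  gap <- t1[rep(101, 9), ]
  gap$frame <- 102:110
  gap$dropped <- TRUE
  t1$dropped <- FALSE; t2$dropped <- FALSE
  tr <- rbind(t1, gap, t2)
  st <- stitch_trajectory(tr)
  expect_equal(st$length_m, 0.020, tolerance = 1e-9)
  expect_identical(st$n_stitches, 1L)
  # the stitched path is continuous at the joint
  jump <- sqrt(diff(st$path$x_mm)^2 + diff(st$path$y_mm)^2)
  expect_lt(max(jump), 0.11)
  # no events -> identity
  plain <- straight_track(100); plain$dropped <- FALSE
  sp <- stitch_trajectory(plain)
  expect_equal(sp$path$x_mm, plain$x_mm)
  expect_identical(sp$n_stitches, 0L)
  # path length is invariant under the stitching translations
  sim <- simulate_larva(3600, sim_params(), seed = 55, ctrl_seed = 56)
  ssim <- stitch_trajectory(sim$track)
  keep <- which(!sim$track$dropped)
  seglen <- sqrt(diff(sim$track$x_mm[keep])^2 + diff(sim$track$y_mm[keep])^2)
  raw <- sum(seglen[diff(keep) == 1]) / 1000
  expect_equal(ssim$length_m, raw, tolerance = 1e-9)
})

test_that("binned population summaries treat the animal as the unit", {
  df <- rbind(data.frame(animal_id = 1, time_s = 0:599, value = 0.2),
              data.frame(animal_id = 2, time_s = 0:599, value = 0.4))
  out <- binned_population_summary(df, bin_min = 5)
  expect_equal(out$mean, rep(0.3, 2))
  expect_equal(out$sd, rep(stats::sd(c(0.2, 0.4)), 2))   # ~0.1414
  # identical animals -> zero sd
  df2 <- df; df2$value <- 0.25
  expect_true(all(binned_population_summary(df2, 5)$sd == 0))
  # single-animal bins are missing
  df3 <- rbind(data.frame(animal_id = 1, time_s = 0:599, value = 0.2),
               data.frame(animal_id = 2, time_s = 0:299, value = 0.4))
  out3 <- binned_population_summary(df3, 5)
  expect_true(is.na(out3$mean[2]))
})

test_that("speed declines at the configured rate in the first hour", {
  sim <- simulate_experiment(3, 2 * 3600, seed = 66)
  rows <- lapply(1:3, function(id) {
    tt <- sim$tracks[sim$tracks$animal_id == id, ]
    kin <- kinematics(tt)
    keep <- kin$valid & tt$mode == "run" & !tt$dropped & is.na(tt$event_id)
    data.frame(animal_id = id, time_s = kin$time_s[keep],
               value = kin$speed_mms[keep])
  })
  ps <- binned_population_summary(do.call(rbind, rows), bin_min = 10)
  slope <- activity_decline_slope(ps, t_max_s = 3600)
  expect_lt(abs(slope - (-6.9e-5)) / 6.9e-5, 0.20)
})

test_that("speed/turn-rate correlation: exact cases and the null", {
  sp <- data.frame(animal_id = rep(1:2, each = 20), bin = rep(1:20, 2),
                   value = rep(sin(1:20), 2))
  tu <- sp                                    # identical series -> r = 1
  r <- speed_turnrate_correlation(sp, tu)
  expect_equal(r$population_r, 1)
  expect_equal(unname(r$individual_r), c(1, 1))
  # zero-variance animal -> missing coefficient
  sp2 <- sp; sp2$value[sp2$animal_id == 2] <- 1
  r2 <- speed_turnrate_correlation(sp2, tu)
  expect_true(is.na(r2$individual_r["2"]))
  # independent white noise, 100 bins: |r| is small
  set.seed(31)
  spn <- data.frame(animal_id = 1, bin = 1:100, value = rnorm(100))
  tun <- data.frame(animal_id = 1, bin = 1:100, value = rnorm(100))
  expect_lt(abs(speed_turnrate_correlation(spn, tun)$population_r), 0.2)
})

test_that("a shared activity latent with rho = 0.5 is recovered", {
  p <- sim_params(speed_decline_rate = 0, base_turn_rate = 3,
                  activity_sd_speed = 0.5, activity_sd_turn = 0.5,
                  activity_rho = 0.5, activity_tau_s = 300)
  sim <- simulate_experiment(6, 8 * 3600, p, seed = 1)
  sb <- list(); tb <- list()
  for (id in 1:6) {
    tt <- sim$tracks[sim$tracks$animal_id == id, ]
    lab <- classify_states(tt, exclude = tt$dropped | !is.na(tt$event_id))
    kin <- kinematics(tt)
    seg <- segment_behaviors(lab, kin$heading_deg, animal_id = id,
                             frames = tt$frame)
    ts <- turn_statistics(seg, window_min = 10, total_time_s = max(tt$time_s))
    keep <- kin$valid & lab == "run"   # run-frame crawl speed
    d <- data.frame(animal_id = id, bin = floor(kin$time_s[keep] / 600),
                    value = kin$speed_mms[keep])
    sb[[id]] <- stats::aggregate(value ~ animal_id + bin, d, mean)
    tb[[id]] <- data.frame(animal_id = id,
                           bin = floor(ts$series$t_mid_s / 600),
                           value = ts$series$turn_rate_per_min)
  }
  r <- speed_turnrate_correlation(do.call(rbind, sb), do.call(rbind, tb))
  # population estimate within the Fisher-z 95% CI of the configured 0.5
  # (Poisson counting noise in binned turn rates attenuates it slightly)
  expect_lt(abs(atanh(r$population_r) - atanh(0.5)),
            1.96 / sqrt(r$n_bins - 3))
  expect_gt(r$individual_mean, 0.2)
})
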