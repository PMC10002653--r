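test_that("bend angle: straight bodies score 0, an L-shape scores 90", {
  expect_equal(bend_angle(cbind(0:2, c(0, 0, 0))), 0)
  expect_equal(bend_angle(cbind(c(0, 1, 1), c(0, 0, 1))), 90)
  # right-angle bend with longer arms
  expect_equal(bend_angle(cbind(c(0, 1, 2, 2, 2), c(0, 0, 0, 1, 2))), 90)
})

test_that("bend angle is invariant under rigid rotation and translation", {
  set.seed(4)
  ml <- cbind(cumsum(runif(11, 0.5, 1)), cumsum(rnorm(11, 0, 0.4)))
  b0 <- bend_angle(ml)
  for (th in c(0.3, 1.2, 2.9)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    ml2 <- sweep(ml %*% R, 2, c(13.7, -4.2), `+`)
    expect_equal(bend_angle(ml2), b0, tolerance = 1e-8)
  }
})

test_that("midline of a straight rendered larva is collinear with heading", {
  for (hd in c(0, 35, -120)) {
    cr <- render_one_crop(bend_deg = 0, heading_deg = hd)
    ml <- extract_midline(cr)
    expect_true(ml$valid)
    ax <- atan2(ml$end1[2] - ml$end2[2], ml$end1[1] - ml$end2[1]) * 180 / pi
    d <- abs(larvawalk::wrap180(ax - hd))
    expect_lt(min(d, 180 - d), 5)     # axis is orientation-free
    expect_lt(bend_angle(ml$midline), 15)
  }
})

test_that("a 90-degree bent rendered larva recovers its bend within 15 deg", {
  cr <- render_one_crop(bend_deg = 90)
  ml <- extract_midline(cr)
  expect_true(ml$valid)
  expect_lt(abs(bend_angle(ml$midline) - 90), 15)
})

test_that("blank or too-small crops are flagged invalid", {
  expect_false(extract_midline(matrix(0, 64, 64))$valid)
  tiny <- matrix(0, 64, 64); tiny[30:31, 30:31] <- 255
  expect_false(extract_midline(tiny)$valid)
})

test_that("head/tail follows motion for steady crawling and survives pauses", {
  n <- 200
  x <- seq(0, 19.9, by = 0.1)           # crawling toward +x
  e1 <- cbind(x + 0.5, rep(0, n))       # e1 = leading (+x) endpoint
  e2 <- cbind(x - 0.5, rep(0, n))
  v <- cbind(rep(0.3, n), rep(0, n))
  ht <- assign_head_tail(e1, e2, v)
  expect_true(all(ht$orientation == 1L))
  expect_identical(ht$n_flips, 0L)
  expect_equal(ht$head, e1)
  # a pause (speed below v_min) retains the established orientation
  v2 <- v; v2[101:150, ] <- 0
  ht2 <- assign_head_tail(e1, e2, v2)
  expect_true(all(ht2$orientation == 1L))
  expect_identical(ht2$n_flips, 0L)
})

test_that("the flip penalty overrides a single corrupted frame", {
  n <- 100
  e1 <- cbind(seq(0.5, by = 0.1, length.out = n), 0)
  e2 <- cbind(seq(-0.5, by = 0.1, length.out = n), 0)
  v <- cbind(rep(0.3, n), rep(0, n))
  e1c <- e1; e2c <- e2
  e1c[50, ] <- e2[50, ]; e2c[50, ] <- e1[50, ]  # endpoints swapped once
  ht <- assign_head_tail(e1c, e2c, v)
  # the penalty outweighs one frame of contrary evidence, so the
  # orientation decision is unchanged through the corrupted frame
  expect_identical(ht$orientation[49:51], rep(1L, 3))
  expect_identical(ht$n_flips, 0L)
  expect_equal(ht$head[49, ], e1[49, ])
  expect_equal(ht$head[51, ], e1[51, ])
})

test_that("orientation at a stationary start is deferred then back-filled", {
  n <- 60
  e1 <- cbind(rep(0.5, n), 0); e2 <- cbind(rep(-0.5, n), 0)
  v <- cbind(c(rep(0, 20), rep(0.3, 40)), rep(0, n))
  e1[21:n, 1] <- e1[21:n, 1] + cumsum(rep(0.03, 40))
  e2[21:n, 1] <- e2[21:n, 1] + cumsum(rep(0.03, 40))
  ht <- assign_head_tail(e1, e2, v)
  expect_true(all(ht$orientation == 1L))   # including back-filled frames
})

test_that("penalized assignment out-flips naive assignment under noise", {
  set.seed(8)
  n <- 2000
  x <- seq(0, by = 0.05, length.out = n)
  e1 <- cbind(x + 0.5, rnorm(n, 0, 0.02))
  e2 <- cbind(x - 0.5, rnorm(n, 0, 0.02))
  bad <- sample(n, n * 0.05)            # 5% of frames: garbage endpoints
  e1[bad, ] <- e1[bad, ] + rnorm(length(bad) * 2, 0, 2)
  e2[bad, ] <- e2[bad, ] + rnorm(length(bad) * 2, 0, 2)
  v <- cbind(rep(0.3, n), rep(0, n))
  flips_pen <- assign_head_tail(e1, e2, v)$n_flips
  flips_naive <- assign_head_tail(e1, e2, v, flip_penalty = 0)$n_flips
  # heavy corruption can still overcome the penalty occasionally, but the
  # penalized assignment must flip strictly less often than the naive one
  expect_gt(flips_naive, flips_pen)
  expect_lt(flips_pen, length(bad) / 2)
})

test_that("orientation decisions are deterministic given the same series", {
  set.seed(12)
  n <- 300
  e1 <- cbind(cumsum(rnorm(n, 0.03, 0.02)), rnorm(n, 0, 0.1))
  e2 <- e1 - cbind(rep(1, n), 0)
  v <- cbind(rnorm(n, 0.2, 0.1), rnorm(n, 0, 0.05))
  a <- assign_head_tail(e1, e2, v)
  b <- assign_head_tail(e1, e2, v)
  expect_identical(a, b)
})

test_that("full posture pipeline on a rendered movie produces zero flips", {
  s <- simulate_larva(60, sim_params(base_turn_rate = 0.5), seed = 19,
                      ctrl_seed = 20,
                      controller = robot_controller(enabled = FALSE))
  st <- render_frames(s$track, arena_config())
  trk <- track_movie(st)
  pt <- posture_track(trk$tracks, extract_crops(trk$tracks, st), 0.1, 10)
  expect_identical(attr(pt, "n_flips"), 0L)
  run <- s$track$mode == "run" & pt$posture_valid
  err <- sqrt((pt$head_x_mm - s$track$head_x_mm)^2 +
              (pt$head_y_mm - s$track$head_y_mm)^2)[run]
  expect_lt(mean(err, na.rm = TRUE), 0.5)   # head on the right half, ~30 px body
})
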