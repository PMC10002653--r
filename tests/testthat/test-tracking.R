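test_that("blob detection: blank frames, area gating, injected clusters", {
  expect_identical(nrow(detect_blobs(matrix(0, 64, 64))), 0L)
  # two 5x5 clusters injected 50 px apart: centroid-of-mask oracle
  px <- expand.grid(x = 0:4, y = 0:4)
  f <- rbind(cbind(px$x + 100, px$y + 100, 255),
             cbind(px$x + 150, px$y + 100, 255))
  colnames(f) <- c("x_px", "y_px", "value")
  d <- detect_blobs(f, threshold = 128, min_area = 8, max_area = 100)
  expect_identical(nrow(d), 2L)
  d <- d[order(d$cx_px), ]
  expect_lt(abs(d$cx_px[1] - 102.5), 0.5)   # mask centroid = 100 + 2 + 0.5
  expect_lt(abs(d$cy_px[1] - 102.5), 0.5)
  expect_lt(abs(d$cx_px[2] - 152.5), 0.5)
  expect_identical(d$area, c(25L, 25L))
  # area gate: a 4-px speck is rejected at min_area = 8
  speck <- cbind(x_px = c(10, 11, 10, 11), y_px = c(10, 10, 11, 11),
                 value = 255)
  expect_identical(nrow(detect_blobs(speck, min_area = 8)), 0L)
  # dense-matrix input agrees with the sparse path
  m <- matrix(0, 200, 200)
  m[cbind(px$y + 101, px$x + 101)] <- 255
  dd <- detect_blobs(m)
  expect_equal(dd$cx_px, 102.5)
  expect_equal(dd$area, 25L)
})

test_that("one detection per frame yields one track covering all frames", {
  dets <- lapply(1:50, function(f)
    data.frame(blob_id = 1L, cx_px = 100 + f, cy_px = 200, area = 30L))
  tr <- link_identities(dets, pixel_scale_mm = 0.1)
  expect_identical(unique(tr$animal_id), 1L)
  expect_identical(nrow(tr), 50L)
  expect_true(all(tr$detected))
})

test_that("a sub-max_gap detection gap is bridged by interpolation", {
  dets <- lapply(1:20, function(f)
    data.frame(blob_id = 1L, cx_px = 100 + f, cy_px = 200, area = 30L))
  dets[8:10] <- list(data.frame(blob_id = integer(), cx_px = numeric(),
                                cy_px = numeric(), area = integer()))
  tr <- link_identities(dets, 0.1)
  tr <- interpolate_gaps(tr, max_gap = 5)
  expect_identical(sum(tr$interpolated), 3L)
  expect_true(all(!tr$track_break))
  expect_equal(tr$x_px, 100 + 1:20)   # linear motion: interpolation exact
})

test_that("interpolation is linear between flanks and honors max_gap/ends", {
  # detections (0,0) at t=0 and (2,0) at t=0.2 s; the t=0.1 s frame -> (1,0)
  tr <- data.frame(frame = 1:3, x_mm = c(0, NA, 2), y_mm = c(0, NA, 0),
                   detected = c(TRUE, FALSE, TRUE))
  out <- interpolate_gaps(tr, max_gap = 5)
  expect_equal(out$x_mm[2], 1)
  expect_equal(out$y_mm[2], 0)
  expect_true(out$interpolated[2])
  # no gaps -> unchanged
  full <- data.frame(frame = 1:4, x_mm = 1:4, y_mm = 0, detected = TRUE)
  expect_identical(interpolate_gaps(full, 5)[, names(full)], full)
  # over-long gaps and boundary gaps are flagged breaks, not filled
  long <- data.frame(frame = 1:10, x_mm = c(1, rep(NA, 8), 10), y_mm = 0,
                     detected = c(TRUE, rep(FALSE, 8), TRUE))
  out <- interpolate_gaps(long, max_gap = 3)
  expect_true(all(is.na(out$x_mm[2:9])))
  expect_true(all(out$track_break[2:9]))
  edge <- data.frame(frame = 1:5, x_mm = c(NA, NA, 3, 4, 5), y_mm = 0,
                     detected = c(FALSE, FALSE, TRUE, TRUE, TRUE))
  out <- interpolate_gaps(edge, max_gap = 3)
  expect_true(all(out$track_break[1:2]))
  expect_true(all(is.na(out$x_mm[1:2])))
})

test_that("identity is preserved for well-separated simulated animals", {
  p <- sim_params()
  s1 <- simulate_larva(60, p, seed = 5, ctrl_seed = 6, animal_id = 1L,
                       controller = robot_controller(enabled = FALSE),
                       start_xy = c(60, 60))
  s2 <- simulate_larva(60, p, seed = 7, ctrl_seed = 8, animal_id = 2L,
                       controller = robot_controller(enabled = FALSE),
                       start_xy = c(160, 160))
  tracks <- rbind(s1$track, s2$track)
  st <- render_frames(tracks, arena_config())
  trk <- track_movie(st)
  for (id in 1:2) {
    tt <- trk$tracks[trk$tracks$animal_id == id, ]
    gt <- if (id == 1) s1$track else s2$track
    err <- sqrt((tt$x_mm - gt$x_mm)^2 + (tt$y_mm - gt$y_mm)^2)
    expect_lt(max(err, na.rm = TRUE), 1)   # never jumps to the other animal
  }
  # conservation: non-interpolated assigned frames = total detections
  dets <- detect_stack(st)
  n_det <- sum(vapply(dets, function(d) if (is.null(d)) 0L else nrow(d),
                      integer(1)))
  expect_identical(sum(trk$tracks$detected), n_det)
})

test_that("crops are centred, zero-padded at borders, and conserve pixels", {
  s <- simulate_larva(10, sim_params(), seed = 15, ctrl_seed = 16,
                      controller = robot_controller(enabled = FALSE))
  st <- render_frames(s$track, arena_config())
  trk <- track_movie(st)
  crops <- extract_crops(trk$tracks, st)
  expect_identical(length(crops), sum(trk$tracks$detected))
  for (i in seq_along(st$pixels)) {
    cr <- crops[[as.character(i)]]
    expect_identical(dim(cr), c(64L, 64L))
    # isolated larva: crop pixel sum equals the frame's rendered pixel sum
    expect_equal(sum(cr), sum(st$pixels[[i]][, "value"]))
  }
  # a centroid near the arena border still yields a full-size padded crop
  near <- data.frame(frame = 1L, x_px = 5, y_px = 5, detected = TRUE)
  fake <- st
  fake$pixels[[1]] <- cbind(x_px = c(4, 5, 6), y_px = c(5, 5, 5), value = 255)
  cr <- extract_crops(near, fake)[[1]]
  expect_identical(dim(cr), c(64L, 64L))
  expect_equal(sum(cr > 0), 3)
})
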