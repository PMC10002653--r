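# Shared fixtures, all generated in code.

# Straight constant-velocity track: speed mm/s along heading_deg.
straight_track <- function(n = 600, speed = 0.3, heading_deg = 0,
                           start = c(60, 110), frame_rate = 10) {
  t <- (seq_len(n) - 1) / frame_rate
  data.frame(frame = seq_len(n), time_s = t, animal_id = 1L,
             x_mm = start[1] + speed * t * cos(heading_deg * pi / 180),
             y_mm = start[2] + speed * t * sin(heading_deg * pi / 180))
}

# Piecewise run/turn track built from exact heading ramps: runs of
# `run_s` seconds separated by turns rotating by `sizes_deg` (CCW
# positive) over `turn_s` seconds. Returns positions plus ground truth.
turny_track <- function(sizes_deg, run_s = 30, turn_s = 2, speed = 0.3,
                        frame_rate = 10, start = c(60, 110), heading0 = 0) {
  dt <- 1 / frame_rate
  hd <- heading0
  heads <- numeric(0); modes <- character(0)
  for (s in c(sizes_deg, NA)) {
    heads <- c(heads, rep(hd, run_s * frame_rate))
    modes <- c(modes, rep("run", run_s * frame_rate))
    if (is.na(s)) break
    nseg <- turn_s * frame_rate
    heads <- c(heads, hd + cumsum(rep(s / nseg, nseg)))
    modes <- c(modes, rep("turn", nseg))
    hd <- hd + s
  }
  n <- length(heads)
  x <- start[1] + cumsum(speed * dt * cos(heads * pi / 180))
  y <- start[2] + cumsum(speed * dt * sin(heads * pi / 180))
  data.frame(frame = seq_len(n), time_s = (seq_len(n) - 1) * dt,
             animal_id = 1L, x_mm = x, y_mm = y,
             heading_true = heads, mode_true = modes)
}

# Single rendered larva frame -> crop, for posture tests.
render_one_crop <- function(bend_deg, heading_deg = 20, bend_sign = 1) {
  ar <- arena_config()
  gt <- data.frame(frame = 1L, animal_id = 1L, x_mm = 110, y_mm = 110,
                   heading_deg = heading_deg, bend_deg = bend_deg,
                   bend_sign = bend_sign, dropped = FALSE)
  st <- render_frames(gt, ar)
  d <- detect_blobs(st, i = 1)
  tr <- data.frame(frame = 1L, x_px = d$cx_px, y_px = d$cy_px,
                   detected = TRUE)
  extract_crops(tr, st)[[1]]
}
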