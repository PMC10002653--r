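# Agent-based simulator of larva run-and-turn crawling, the thermal
# environment, and the transport robot. Each animal owns two RNG streams
# (behavior, controller) derived from the experiment seed, so adding
# animals never perturbs existing trajectories.

rng_set <- function(state) assign(".Random.seed", state, envir = globalenv())
rng_get <- function() get(".Random.seed", envir = globalenv())
rng_new <- function(seed) { set.seed(seed); rng_get() }

# Truncated |Gaussian| turn-size draw (degrees), by rejection.
draw_turn_size <- function(mean, sd, lo, hi) {
  for (k in 1:1000) {
    s <- abs(stats::rnorm(1, mean, sd))
    if (s >= lo && s <= hi) return(s)
  }
  stats::runif(1, lo, hi)
}

# Bernoulli retry ladder used for both pick-up and drop-off attempts.
# After `perturb_after` failures the per-attempt probability is nudged
# upward by `p_boost` per further failure (controller recalibration).
# Draws come from the current RNG stream.
attempt_with_retries <- function(p_first, max_attempts, perturb_after = 3L,
                                 p_boost = 0.05) {
  p <- p_first
  for (k in seq_len(max_attempts)) {
    if (stats::runif(1) < p) return(list(success = TRUE, attempts = k))
    if (k >= perturb_after) p <- min(p + p_boost, 0.999)
  }
  list(success = FALSE, attempts = as.integer(max_attempts))
}

# Head/tail positions from centroid, heading, bend and bend sign.
# The body is two equal chords of length L/2 meeting at the midpoint with
# interior angle 180 - bend; the head chord points along heading + s*bend/2.
# The midpoint is offset so the polyline centroid sits at (x, y).
body_endpoints <- function(x, y, heading_deg, bend_deg, bend_sign, L) {
  th <- deg2rad(heading_deg + bend_sign * bend_deg / 2)
  tt <- deg2rad(heading_deg + 180 - bend_sign * bend_deg / 2)
  ux_h <- cos(th); uy_h <- sin(th)
  ux_t <- cos(tt); uy_t <- sin(tt)
  mx <- x - (L / 8) * (ux_h + ux_t)
  my <- y - (L / 8) * (uy_h + uy_t)
  list(head_x = mx + (L / 2) * ux_h, head_y = my + (L / 2) * uy_h,
       tail_x = mx + (L / 2) * ux_t, tail_y = my + (L / 2) * uy_t)
}

# Midline polyline (head -> tail) for one frame, n points, centred so the
# sampled-point centroid equals (x, y). Used by the renderer.
larva_midline <- function(x, y, heading_deg, bend_deg, bend_sign, L, n = 21L) {
  th <- deg2rad(heading_deg + bend_sign * bend_deg / 2)
  tt <- deg2rad(heading_deg + 180 - bend_sign * bend_deg / 2)
  half <- n %/% 2L
  s_head <- seq(L / 2, 0, length.out = half + 1L)
  s_tail <- seq(0, L / 2, length.out = half + 1L)[-1]
  px <- c(s_head * cos(th), s_tail * cos(tt))
  py <- c(s_head * sin(th), s_tail * sin(tt))
  cbind(x + px - mean(px), y + py - mean(py))
}

# Exogenous Ornstein-Uhlenbeck path (stationary, unit variance), vectorized.
ou_path <- function(n, dt, tau) {
  if (n == 0L) return(numeric(0))
  a <- exp(-dt / tau)
  z <- stats::rnorm(n)
  x <- numeric(n)
  x[1] <- z[1]
  sig <- sqrt(1 - a^2)
  for (i in 2:n) x[i] <- a * x[i - 1] + sig * z[i]
  x
}

#' Simulate one larva
#'
#' Steps a single animal through `duration_s` seconds of run-and-turn
#' crawling at the arena frame rate, including wall handling, optional
#' klinokinesis under the thermal field, and optional transport-robot
#' interactions (edge-triggered pick-up/drop-off with dropped frames,
#' scheduled feeding pauses).
#'
#' @param duration_s simulated time in seconds.
#' @param params a [sim_params()].
#' @param arena an [arena_config()].
#' @param field a [thermal_field()] or `NULL` (uniform).
#' @param controller a [robot_controller()] or `NULL` (reflecting walls).
#' @param seed behavior-stream seed for this animal.
#' @param ctrl_seed controller-stream seed for this animal.
#' @param animal_id integer id stamped on all outputs.
#' @param start_xy,start_heading initial state; defaults to the arena centre
#'   area and a random heading drawn from the behavior stream.
#' @return list with `track` (per-frame data.frame), `turns` (turn-event
#'   table) and `events` (robot-event table).
#' @export
simulate_larva <- function(duration_s, params = sim_params(),
                           arena = arena_config(), field = NULL,
                           controller = robot_controller(),
                           seed = 1L, ctrl_seed = seed + 1L,
                           animal_id = 1L,
                           start_xy = NULL, start_heading = NULL) {
  fr <- arena$frame_rate_hz
  dt <- 1 / fr
  n <- as.integer(round(duration_s * fr))
  L <- arena$side_length_mm
  cx <- arena$center_mm[1]; cy <- arena$center_mm[2]
  if (is.null(controller)) controller <- robot_controller(enabled = FALSE)
  ctrl_on <- isTRUE(controller$enabled)
  taxis_on <- !is.null(field) && isTRUE(field$enabled) &&
    params$thermotaxis_gain > 0
  axis_ang <- if (!is.null(field)) atan2(field$axis[2], field$axis[1]) else 0

  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))

  beh <- rng_new(seed)
  ctrl <- rng_new(ctrl_seed)

  # --- behavior-stream pre-draws (positional by frame; unused entries are
  # simply skipped in non-run frames, which keeps streams deterministic) ---
  rng_set(beh)
  if (is.null(start_xy)) {
    half <- L / 4
    start_xy <- c(stats::runif(1, cx - half, cx + half),
                  stats::runif(1, cy - half, cy + half))
  }
  if (is.null(start_heading)) start_heading <- stats::runif(1, 0, 360)
  u_turn <- stats::runif(n)
  z_diff <- stats::rnorm(n)
  act_s <- rep(1, n); act_t <- rep(1, n)
  if (params$activity_sd_speed > 0 || params$activity_sd_turn > 0) {
    rho <- params$activity_rho
    a <- ou_path(n, dt, params$activity_tau_s)
    es <- ou_path(n, dt, params$activity_tau_s)
    et <- ou_path(n, dt, params$activity_tau_s)
    ls <- sqrt(rho) * a + sqrt(1 - rho) * es
    lt <- sqrt(rho) * a + sqrt(1 - rho) * et
    act_s <- exp(params$activity_sd_speed * ls - params$activity_sd_speed^2 / 2)
    act_t <- exp(params$activity_sd_turn * lt - params$activity_sd_turn^2 / 2)
  }
  beh <- rng_get()

  # --- state ---
  px <- start_xy[1]; py <- start_xy[2]; hd <- start_heading
  mode_cur <- 1L                      # 1 = run, 2 = turn
  turn_frames <- max(1L, as.integer(round(params$turn_duration_s * fr)))
  turn_k <- 0L; turn_step <- 0; turn_dir <- 0L; turn_size <- 0
  manip_left <- 0L; manip_dx <- 0; manip_dy <- 0; pending_hd <- NA_real_
  feed_left <- 0L
  cooldown_left <- 0L
  occ_frames <- max(1L, as.integer(round(controller$occlusion_s * fr)))
  cool_frames <- as.integer(round(controller$retrigger_cooldown_s * fr))
  feed_frames <- as.integer(round(controller$feed_duration_s * fr))
  next_feed <- if (ctrl_on && controller$feed_interval_s > 0)
    controller$feed_interval_s else Inf
  sig_step <- params$heading_diffusion * sqrt(dt)
  lam0 <- params$base_turn_rate
  margin <- arena$edge_margin_mm

  # --- outputs ---
  X <- numeric(n); Y <- numeric(n); H <- numeric(n); SP <- numeric(n)
  MODE <- integer(n); BEND <- numeric(n); BSIGN <- integer(n)
  DROP <- logical(n); EVID <- rep(NA_integer_, n)
  turns <- list(); events <- list(); ev_id <- 0L
  cur_turn_start <- NA_integer_; cur_evid <- NA_integer_

  log_event <- function(type, frame, from, to, attempts, success) {
    ev_id <<- ev_id + 1L
    events[[length(events) + 1L]] <<- data.frame(
      event_id = ev_id, animal_id = animal_id,
      time_s = (frame - 1L) / fr, frame = frame, type = type,
      from_x_mm = from[1], from_y_mm = from[2],
      to_x_mm = to[1], to_y_mm = to[2],
      attempts = attempts, success = success)
    ev_id
  }
  end_turn <- function(frame, complete) {
    if (is.na(cur_turn_start) || frame < cur_turn_start) {
      cur_turn_start <<- NA_integer_
      return(invisible(NULL))
    }
    turns[[length(turns) + 1L]] <<- data.frame(
      animal_id = animal_id, start_frame = cur_turn_start, end_frame = frame,
      direction = if (turn_dir > 0) "left" else "right",
      size_deg = turn_size, complete = complete)
    cur_turn_start <<- NA_integer_
  }

  for (i in seq_len(n)) {
    t_now <- (i - 1L) * dt

    if (manip_left > 0L) {              # being carried; camera occluded
      px <- px + manip_dx; py <- py + manip_dy
      DROP[i] <- TRUE; EVID[i] <- cur_evid
      manip_left <- manip_left - 1L
      if (manip_left == 0L) { hd <- pending_hd; cur_evid <- NA_integer_ }
      X[i] <- px; Y[i] <- py; H[i] <- hd; SP[i] <- 0
      MODE[i] <- 1L; BEND[i] <- 0; BSIGN[i] <- 1L
      next
    }

    if (feed_left > 0L) {               # paused at the juice drop
      feed_left <- feed_left - 1L
      X[i] <- px; Y[i] <- py; H[i] <- hd; SP[i] <- 0
      MODE[i] <- 1L; BEND[i] <- 0; BSIGN[i] <- 1L
      EVID[i] <- cur_evid
      if (feed_left == 0L) cur_evid <- NA_integer_
      next
    }

    if (t_now >= next_feed) {           # scheduled feeding
      if (mode_cur == 2L) { end_turn(i - 1L, FALSE); mode_cur <- 1L }
      cur_evid <- log_event("feed", i, c(px, py), c(px, py), 1L, TRUE)
      log_event("rinse", i, c(px, py), c(px, py), 1L, TRUE)
      next_feed <- next_feed + controller$feed_interval_s
      feed_left <- max(1L, feed_frames)
      X[i] <- px; Y[i] <- py; H[i] <- hd; SP[i] <- 0
      MODE[i] <- 1L; BEND[i] <- 0; BSIGN[i] <- 1L
      EVID[i] <- cur_evid
      feed_left <- feed_left - 1L
      if (feed_left == 0L) cur_evid <- NA_integer_
      next
    }

    if (cooldown_left > 0L) cooldown_left <- cooldown_left - 1L

    near_edge <- min(px, py, L - px, L - py) < margin
    if (ctrl_on && near_edge && cooldown_left == 0L) {
      if (mode_cur == 2L) { end_turn(i - 1L, FALSE); mode_cur <- 1L }
      beh <- rng_get()
      rng_set(ctrl)
      pick <- attempt_with_retries(controller$p_first_pickup,
                                   controller$max_attempts,
                                   controller$perturb_after,
                                   controller$p_boost)
      if (pick$success) {
        drop_att <- attempt_with_retries(controller$p_first_dropoff,
                                         controller$max_attempts,
                                         controller$perturb_after,
                                         controller$p_boost)
        tx <- cx + stats::rnorm(1, 0, controller$dropoff_scatter_mm)
        ty <- cy + stats::rnorm(1, 0, controller$dropoff_scatter_mm)
        pending_hd <- stats::runif(1, 0, 360)
      }
      ctrl <- rng_get(); rng_set(beh)
      from <- c(px, py)
      if (pick$success) {
        cur_evid <- log_event("pickup", i, from, from, pick$attempts, TRUE)
        log_event("dropoff", i, from, c(tx, ty), drop_att$attempts,
                  drop_att$success)
        manip_left <- occ_frames
        manip_dx <- (tx - px) / occ_frames
        manip_dy <- (ty - py) / occ_frames
        px <- px + manip_dx; py <- py + manip_dy
        DROP[i] <- TRUE; EVID[i] <- cur_evid
        manip_left <- manip_left - 1L
        if (manip_left == 0L) { hd <- pending_hd; cur_evid <- NA_integer_ }
        X[i] <- px; Y[i] <- py; H[i] <- hd; SP[i] <- 0
        MODE[i] <- 1L; BEND[i] <- 0; BSIGN[i] <- 1L
        next
      } else {
        log_event("pickup", i, from, from, pick$attempts, FALSE)
        # animal left in place; steer it inward and stand off for a while
        hd <- rad2deg(atan2(cy - py, cx - px))
        cooldown_left <- cool_frames
      }
    }

    speed_t <- max(params$base_speed +
                     params$speed_decline_rate * min(t_now, params$decline_duration_s),
                   params$min_speed) * act_s[i]

    if (mode_cur == 1L) {               # run
      hd <- hd + sig_step * z_diff[i]
      nx <- px + speed_t * dt * cos(deg2rad(hd))
      ny <- py + speed_t * dt * sin(deg2rad(hd))
      if (nx < 0 || nx > L) { hd <- 180 - hd; nx <- min(max(nx, 0), L) }
      if (ny < 0 || ny > L) { hd <- -hd; ny <- min(max(ny, 0), L) }
      px <- nx; py <- ny
      lam <- lam0 * act_t[i]
      if (taxis_on) {
        cpsi <- cos(deg2rad(hd) - axis_ang)
        lam <- lam * (1 + params$thermotaxis_gain * max(0, -cpsi))
      }
      p_turn <- 1 - exp(-lam * dt / 60)
      X[i] <- px; Y[i] <- py; H[i] <- hd; SP[i] <- speed_t
      MODE[i] <- 1L; BEND[i] <- 0; BSIGN[i] <- 1L
      if (u_turn[i] < p_turn) {
        turn_size <- draw_turn_size(params$turn_size_mean, params$turn_size_sd,
                                    params$turn_size_min, params$turn_size_max)
        turn_dir <- if (stats::runif(1) < params$handedness_bias) 1L else -1L
        turn_step <- turn_dir * turn_size / turn_frames
        turn_k <- 0L
        mode_cur <- 2L
        cur_turn_start <- i + 1L
      }
    } else {                            # turn
      turn_k <- turn_k + 1L
      hd <- hd + turn_step
      step_len <- params$turn_translation_frac * speed_t * dt
      px <- min(max(px + step_len * cos(deg2rad(hd)), 0), L)
      py <- min(max(py + step_len * sin(deg2rad(hd)), 0), L)
      X[i] <- px; Y[i] <- py; H[i] <- hd
      SP[i] <- params$turn_translation_frac * speed_t
      MODE[i] <- 2L
      BEND[i] <- params$head_cast_amplitude_deg * sin(pi * turn_k / turn_frames)
      BSIGN[i] <- turn_dir
      if (turn_k >= turn_frames) { end_turn(i, TRUE); mode_cur <- 1L }
    }
  }
  if (!is.na(cur_turn_start)) end_turn(n, FALSE)

  ep <- body_endpoints(X, Y, H, BEND, BSIGN, params$body_length_mm)
  track <- data.frame(
    frame = seq_len(n), time_s = (seq_len(n) - 1L) / fr,
    animal_id = animal_id,
    x_mm = X, y_mm = Y, heading_deg = wrap180(H), speed_mms = SP,
    mode = c("run", "turn")[MODE], bend_deg = BEND, bend_sign = BSIGN,
    head_x_mm = ep$head_x, head_y_mm = ep$head_y,
    tail_x_mm = ep$tail_x, tail_y_mm = ep$tail_y,
    dropped = DROP, event_id = EVID)
  list(
    track = track,
    turns = if (length(turns)) do.call(rbind, turns) else
      data.frame(animal_id = integer(), start_frame = integer(),
                 end_frame = integer(), direction = character(),
                 size_deg = numeric(), complete = logical()),
    events = if (length(events)) do.call(rbind, events) else
      data.frame(event_id = integer(), animal_id = integer(),
                 time_s = numeric(), frame = integer(), type = character(),
                 from_x_mm = numeric(), from_y_mm = numeric(),
                 to_x_mm = numeric(), to_y_mm = numeric(),
                 attempts = integer(), success = logical()))
}

#' Simulate a multi-animal experiment
#'
#' Runs [simulate_larva()] for `n_animals` independent animals (larvae do
#' not interact in the model; overlaps only matter to the renderer/tracker)
#' and collates ground truth: per-frame positions, head/tail, behavioral
#' state, bend, dropped-frame mask, turn events and robot events.
#'
#' @param n_animals number of larvae (the instrument runs 4-6).
#' @param duration_s experiment length in seconds.
#' @inheritParams simulate_larva
#' @param seed master seed; per-animal behavior/controller streams are
#'   derived from it.
#' @return an object of class `larva_experiment` with elements `tracks`,
#'   `turns`, `events`, plus the configuration used.
#' @export
simulate_experiment <- function(n_animals = 5, duration_s = 3600,
                                params = sim_params(),
                                arena = arena_config(), field = NULL,
                                controller = robot_controller(),
                                seed = 1L) {
  sims <- lapply(seq_len(n_animals), function(i) {
    simulate_larva(duration_s, params, arena, field, controller,
                   seed = derive_seed(seed, 2L * i),
                   ctrl_seed = derive_seed(seed, 2L * i + 1L),
                   animal_id = i)
  })
  ev <- do.call(rbind, lapply(sims, `[[`, "events"))
  if (nrow(ev)) ev$event_id <- seq_len(nrow(ev))
  structure(list(
    tracks = do.call(rbind, lapply(sims, `[[`, "track")),
    turns = do.call(rbind, lapply(sims, `[[`, "turns")),
    events = ev,
    n_animals = n_animals, duration_s = duration_s,
    params = params, arena = arena, field = field,
    controller = controller, seed = seed
  ), class = "larva_experiment")
}

#' @export
print.larva_experiment <- function(x, ...) {
  cat(sprintf("larva_experiment: %d animal(s), %.1f min at %g Hz, seed %d\n",
              x$n_animals, x$duration_s / 60, x$arena$frame_rate_hz, x$seed))
  cat(sprintf("  %d frames, %d turn events, %d robot events\n",
              nrow(x$tracks), nrow(x$turns), nrow(x$events)))
  invisible(x)
}
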