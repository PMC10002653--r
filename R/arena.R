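#' Arena configuration
#'
#' Describes the square crawling arena: a 22 x 22 cm agar surface imaged
#' from above at 10 Hz. Coordinates are in millimetres with the origin at
#' the lower-left corner, x rightward and y upward; pixel coordinates are
#' 0-based and converted through `pixel_scale`.
#'
#' @param side_length_mm arena side length in mm (default 220).
#' @param frame_rate_hz camera frame rate in Hz (default 10).
#' @param pixel_scale_mm mm per pixel (default 0.1, so a ~1 mm larva covers
#'   roughly 30 bright pixels when rendered).
#' @param edge_margin_mm width of the border band, in mm, inside which the
#'   transport robot triggers a pick-up (default 15).
#' @return an object of class `arena_config`.
#' @export
arena_config <- function(side_length_mm = 220, frame_rate_hz = 10,
                         pixel_scale_mm = 0.1, edge_margin_mm = 15) {
  stopifnot(side_length_mm > 0, frame_rate_hz > 0,
            edge_margin_mm > 0, edge_margin_mm < side_length_mm / 2,
            pixel_scale_mm > 0)
  structure(list(
    side_length_mm = side_length_mm,
    frame_rate_hz = frame_rate_hz,
    pixel_scale_mm = pixel_scale_mm,
    edge_margin_mm = edge_margin_mm,
    center_mm = c(side_length_mm / 2, side_length_mm / 2)
  ), class = "arena_config")
}

#' Linear thermal gradient across the arena
#'
#' A 1D linear thermal field: temperature is an affine function of position
#' along `axis`, anchored so the arena centre sits at `center_temp_c`. The
#' default steepness of 0.035 degC/mm with a 17 degC centre spans roughly
#' 13 degC to 21 degC across a 220 mm arena. The warm direction is +x by
#' convention.
#'
#' @param steepness_c_per_mm gradient steepness in degC/mm (default 0.035).
#' @param center_temp_c temperature at the arena centre in degC (default 17).
#' @param axis unit 2-vector pointing toward increasing temperature
#'   (default `c(1, 0)`).
#' @param enabled logical; `FALSE` gives a uniform field at `center_temp_c`.
#' @return an object of class `thermal_field`.
#' @export
thermal_field <- function(steepness_c_per_mm = 0.035, center_temp_c = 17,
                          axis = c(1, 0), enabled = TRUE) {
  stopifnot(length(axis) == 2, sum(axis^2) > 0)
  axis <- axis / sqrt(sum(axis^2))
  structure(list(
    steepness_c_per_mm = steepness_c_per_mm,
    center_temp_c = center_temp_c,
    axis = axis,
    enabled = isTRUE(enabled)
  ), class = "thermal_field")
}

#' Evaluate the thermal field at a position
#'
#' @param field a [thermal_field()].
#' @param position_mm numeric 2-vector (x, y) in mm, or an n x 2 matrix.
#' @param arena an [arena_config()]; positions outside the arena are an error.
#' @return temperature(s) in degC.
#' @examples
#' ar <- arena_config()
#' thermal_field_at(thermal_field(), ar$center_mm, ar)         # 17
#' thermal_field_at(thermal_field(), ar$center_mm + c(100, 0), ar) # 20.5
#' @export
thermal_field_at <- function(field, position_mm, arena = arena_config()) {
  stopifnot(inherits(field, "thermal_field"))
  p <- if (is.matrix(position_mm)) position_mm else matrix(position_mm, ncol = 2)
  if (any(p < 0) || any(p > arena$side_length_mm))
    stop("position outside arena bounds")
  if (!field$enabled) return(rep(field$center_temp_c, nrow(p)))
  d <- (p[, 1] - arena$center_mm[1]) * field$axis[1] +
       (p[, 2] - arena$center_mm[2]) * field$axis[2]
  field$center_temp_c + field$steepness_c_per_mm * d
}

#' Locomotion model parameters
#'
#' Generative parameters for the run-and-turn random walk. Runs advance the
#' animal along its heading with Gaussian heading diffusion; turns are
#' initiated as a Poisson process at rate `base_turn_rate` (events/min),
#' rotate the heading by a drawn turn size over `turn_duration_s` with
#' near-zero translation, and are accompanied by a head-cast body bend.
#' Under a thermal gradient, klinokinesis elevates the turn rate when the
#' animal crawls toward the cold side:
#' `lambda_eff = lambda * (1 + thermotaxis_gain * max(0, -cos(psi)))` with
#' `psi` the angle between heading and the warm axis.
#'
#' Crawl speed declines linearly at `speed_decline_rate` for the first
#' `decline_duration_s` seconds (the first hour by default), then stays at
#' the plateau; it is floored at `min_speed`.
#'
#' An optional shared latent "activity" process (Ornstein-Uhlenbeck with
#' timescale `activity_tau_s`) modulates speed and turn rate together with
#' log-normal multipliers whose log-correlation is `activity_rho`; this is
#' off by default (`activity_sd_* = 0`).
#'
#' @param base_speed mm/s at time 0 (default 0.55).
#' @param min_speed floor on run speed, mm/s (default 0.1).
#' @param speed_decline_rate mm/s^2 (default -6.9e-5, the first-hour decline).
#' @param decline_duration_s seconds over which the decline applies
#'   (default 3600).
#' @param base_turn_rate Poisson turn-initiation rate, events/min (default 2).
#' @param turn_size_mean,turn_size_sd Gaussian turn-size magnitude parameters
#'   in degrees, truncated to `[turn_size_min, turn_size_max]`
#'   (defaults 60, 30, 20, 180).
#' @param handedness_bias probability that a turn is to the left (CCW)
#'   (default 0.5).
#' @param heading_diffusion angular diffusion during runs, deg/sqrt(s)
#'   (default 2).
#' @param thermotaxis_gain dimensionless klinokinesis gain; 0 disables taxis
#'   (default 0; 1.0 is the calibrated value giving a mean navigation index
#'   near the 0.13 observed under a gradient).
#' @param turn_duration_s duration of a turn in seconds (default 2).
#' @param head_cast_amplitude_deg peak body bend during a turn, degrees
#'   (default 60; head-cast amplitude is largely independent of the
#'   resulting heading change).
#' @param turn_translation_frac fraction of run speed retained during a turn
#'   (default 0.1).
#' @param body_length_mm larva body length in mm (default 1.0).
#' @param activity_sd_speed,activity_sd_turn log-sd of the activity
#'   multipliers (defaults 0 = off).
#' @param activity_rho correlation of the speed and turn-rate log-multipliers
#'   (default 0).
#' @param activity_tau_s OU timescale of the latent activity, s (default 1800).
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(base_speed = 0.55, min_speed = 0.1,
                       speed_decline_rate = -6.9e-5, decline_duration_s = 3600,
                       base_turn_rate = 2,
                       turn_size_mean = 60, turn_size_sd = 30,
                       turn_size_min = 20, turn_size_max = 180,
                       handedness_bias = 0.5,
                       heading_diffusion = 2,
                       thermotaxis_gain = 0,
                       turn_duration_s = 2,
                       head_cast_amplitude_deg = 60,
                       turn_translation_frac = 0.1,
                       body_length_mm = 1.0,
                       activity_sd_speed = 0, activity_sd_turn = 0,
                       activity_rho = 0, activity_tau_s = 1800) {
  stopifnot(base_speed >= 0, min_speed > 0,
            handedness_bias >= 0, handedness_bias <= 1,
            thermotaxis_gain >= 0, turn_duration_s > 0,
            turn_size_min > 0, turn_size_max <= 180,
            activity_rho >= 0, activity_rho <= 1)
  structure(as.list(environment()), class = "sim_params")
}

#' Transport-robot controller parameters
#'
#' Stochastic model of the edge-triggered pick-up/drop-off feedback loop:
#' when an animal enters the edge margin the robot attempts a pick-up
#' (Bernoulli per attempt, first-try probability 0.90), relocates it to the
#' arena centre and attempts a drop-off (first-try probability 0.95).
#' Repeated failures nudge the per-attempt probability upward, modelling the
#' controller's self-recalibration. Frames during a manipulation are dropped
#' (arm occludes the camera). Feeding events are inserted on a fixed
#' schedule and pause the trajectory.
#'
#' @param enabled logical; `FALSE` replaces the robot by reflecting walls.
#' @param p_first_pickup,p_first_dropoff first-attempt success probabilities.
#' @param max_attempts attempts before an event is logged as failed.
#' @param perturb_after failures before the calibration nudge kicks in.
#' @param p_boost per-failure increment applied after `perturb_after`.
#' @param occlusion_s seconds of dropped frames per manipulation.
#' @param dropoff_scatter_mm sd of the drop-off position around the centre.
#' @param retrigger_cooldown_s refractory period after a failed pick-up.
#' @param feed_interval_s seconds between scheduled feedings (0 disables).
#' @param feed_duration_s seconds the animal pauses to feed.
#' @return an object of class `robot_controller`.
#' @export
robot_controller <- function(enabled = TRUE,
                             p_first_pickup = 0.90, p_first_dropoff = 0.95,
                             max_attempts = 10L, perturb_after = 3L,
                             p_boost = 0.05, occlusion_s = 10,
                             dropoff_scatter_mm = 2,
                             retrigger_cooldown_s = 30,
                             feed_interval_s = 0, feed_duration_s = 60) {
  stopifnot(p_first_pickup > 0, p_first_pickup <= 1,
            p_first_dropoff > 0, p_first_dropoff <= 1,
            max_attempts >= 1, occlusion_s >= 0)
  structure(as.list(environment()), class = "robot_controller")
}
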