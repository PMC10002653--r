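# Per-frame run/turn classification and segment extraction. A
# symmetric-window hysteresis rule on path heading rate and body bend
# stands in for the learned bidirectional state classifier: both cues are
# computed from centrally smoothed series, so labels are a pure function of
# a symmetric window around each frame and reversing the input in time
# reverses the labels exactly.

#' Classify frames as run or turn
#'
#' A frame is a turn candidate if its centrally smoothed absolute heading
#' rate is at least `heading_rate_on` deg/s or its body bend is at least
#' `bend_on` degrees. Candidate blocks are then expanded in both directions
#' (hysteresis) while the bend stays at or above `bend_off` or the heading
#' rate stays at or above `heading_rate_off`. All remaining frames are
#' runs. Frames flagged in `exclude` (dropped/interpolated/contact) are
#' labelled `"excluded"` and never absorb expansions.
#'
#' @param track single-animal data.frame with `x_mm, y_mm` (heading is
#'   derived from the path) and optionally `bend_deg`; or pass `heading_deg`
#'   explicitly via a column of that name plus `use_path_heading = FALSE`.
#' @param frame_rate_hz frames per second (default 10).
#' @param bend_on,bend_off bend hysteresis thresholds in degrees
#'   (defaults 30, 15).
#' @param heading_rate_on,heading_rate_off heading-rate hysteresis
#'   thresholds in deg/s (defaults 20, 10).
#' @param smooth_window centred boxcar width in frames (default 11, 1.1 s
#'   at 10 Hz); tracks shorter than this are an error.
#' @param use_bend set `FALSE` for heading-only classification.
#' @param use_path_heading derive heading from positions (default `TRUE`);
#'   otherwise a `heading_deg` column is required.
#' @param exclude optional logical vector of frames to mask out (dropped,
#'   interpolated, contact, or event frames such as feeding pauses).
#' @param exclude_dilate number of frames by which the exclusion mask is
#'   symmetrically dilated before use (default `smooth_window`): the
#'   smoothed cues of frames this close to excluded data are contaminated
#'   by it (robot relocations produce arbitrarily large apparent heading
#'   rates there, which would otherwise be scored as turns).
#' @return character vector of per-frame labels
#'   (`"run"`, `"turn"`, `"excluded"`).
#' @export
classify_states <- function(track, frame_rate_hz = 10,
                            bend_on = 30, bend_off = 15,
                            heading_rate_on = 20, heading_rate_off = 10,
                            smooth_window = 11L, use_bend = TRUE,
                            use_path_heading = TRUE, exclude = NULL,
                            exclude_dilate = smooth_window) {
  n <- nrow(track)
  if (n < smooth_window)
    stop("track shorter than smooth_window (", n, " < ", smooth_window, ")")
  dt <- 1 / frame_rate_hz
  if (use_path_heading) {
    sx <- boxcar(track$x_mm, smooth_window)
    sy <- boxcar(track$y_mm, smooth_window)
    heading <- rad2deg(atan2(central_diff(sy, dt), central_diff(sx, dt)))
  } else {
    heading <- track$heading_deg
  }
  hu <- unwrap_deg(heading)
  rate <- abs(central_diff(boxcar(hu, smooth_window), dt))
  bend <- if (use_bend && "bend_deg" %in% names(track)) {
    b <- track$bend_deg
    b[is.na(b)] <- 0
    boxcar(b, 3L)
  } else rep(0, n)

  if (!is.null(exclude) && exclude_dilate > 0 && any(exclude)) {
    ex <- exclude
    for (k in seq_len(exclude_dilate))
      ex <- ex | c(FALSE, ex[-n]) | c(ex[-1], FALSE)
    exclude <- ex
  }
  cand <- rate >= heading_rate_on | bend >= bend_on
  hold <- rate >= heading_rate_off | bend >= bend_off
  if (!is.null(exclude)) {
    cand[exclude] <- FALSE
    hold[exclude] <- FALSE
  }
  # bidirectional hysteresis expansion to a fixpoint
  turn <- cand
  repeat {
    grow <- hold & !turn &
      (c(FALSE, turn[-n]) | c(turn[-1], FALSE))
    if (!any(grow)) break
    turn[grow] <- TRUE
  }
  lab <- ifelse(turn, "turn", "run")
  if (!is.null(exclude)) lab[exclude] <- "excluded"
  lab
}

#' Convert frame labels to behavior segments
#'
#' Maximal constant-label intervals become segments. For each turn the
#' heading change is the wrapped difference between the circular mean
#' heading over the second after the segment and the second before it:
#' `turn_size` is its magnitude and the direction is left when the wrapped
#' difference is positive (counter-clockwise under y-up coordinates; an
#' exact 180-degree tie breaks left). Turns without a full one-second flank
#' of run frames inside the track keep their segment but carry missing
#' direction and size. `"excluded"` labels split the track; excluded
#' stretches are returned as segments of state `"excluded"`.
#'
#' @param labels per-frame labels from [classify_states()].
#' @param heading_deg per-frame heading in degrees (path heading; compute
#'   via [kinematics()] or pass the simulator's ground truth).
#' @param frame_rate_hz frames per second (default 10).
#' @param animal_id id stamped on the output (default 1).
#' @param frames optional frame numbers (defaults to `seq_along(labels)`).
#' @return data.frame `animal_id, state, start_frame, end_frame, start_s,
#'   end_s, direction, turn_size_deg`.
#' @export
segment_behaviors <- function(labels, heading_deg, frame_rate_hz = 10,
                              animal_id = 1L, frames = NULL) {
  n <- length(labels)
  stopifnot(length(heading_deg) == n)
  if (is.null(frames)) frames <- seq_len(n)
  flank <- as.integer(round(frame_rate_hz))   # 1 s
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(
    animal_id = animal_id, state = r$values,
    start_frame = frames[starts], end_frame = frames[ends],
    start_s = (frames[starts] - 1) / frame_rate_hz,
    end_s = frames[ends] / frame_rate_hz,
    direction = NA_character_, turn_size_deg = NA_real_)
  for (k in which(r$values == "turn")) {
    pre <- (starts[k] - flank):(starts[k] - 1L)
    post <- (ends[k] + 1L):(ends[k] + flank)
    if (min(pre) < 1L || max(post) > n) next
    if (any(labels[pre] != "run") || any(labels[post] != "run")) next
    d <- wrap180(circ_mean_deg(heading_deg[post]) -
                 circ_mean_deg(heading_deg[pre]))
    if (is.na(d) || d == 0) next
    out$direction[k] <- if (d > 0) "left" else "right"   # 180 wraps to +180
    out$turn_size_deg[k] <- abs(d)
  }
  out
}
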