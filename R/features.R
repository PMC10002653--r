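# Derived behavioral statistics: kinematics, turn statistics, navigation
# index, peri-event transients, trajectory stitching, population summaries
# and the speed/turn-rate correlation.

#' Per-frame kinematics of a track
#'
#' Positions are boxcar-smoothed (1.1 s by default) and centrally
#' differenced. Speed is the magnitude of the resulting velocity, heading
#' its direction, and curvature the absolute wrapped heading change per
#' unit path length; curvature is missing wherever speed falls below
#' `v_min`. A `valid` flag marks frames usable in summary statistics
#' (not dropped, interpolated or in contact).
#'
#' @param track single-animal data.frame with `x_mm, y_mm` and optional
#'   logical columns `dropped`, `interpolated`, `contact`.
#' @param frame_rate_hz frames per second (default 10).
#' @param smooth_window boxcar width in frames (default 11); tracks shorter
#'   than this are an error.
#' @param v_min speed floor in mm/s (default 0.05).
#' @return data.frame `frame, time_s, vx_mms, vy_mms, speed_mms,
#'   heading_deg, curvature_per_mm, valid`.
#' @export
kinematics <- function(track, frame_rate_hz = 10, smooth_window = 11L,
                       v_min = 0.05) {
  n <- nrow(track)
  if (n < smooth_window)
    stop("track shorter than smooth_window (", n, " < ", smooth_window, ")")
  dt <- 1 / frame_rate_hz
  sx <- boxcar(track$x_mm, smooth_window)
  sy <- boxcar(track$y_mm, smooth_window)
  vx <- central_diff(sx, dt)
  vy <- central_diff(sy, dt)
  speed <- sqrt(vx^2 + vy^2)
  heading <- rad2deg(atan2(vy, vx))
  dh <- abs(wrap180(c(NA, diff(heading))))
  ds <- speed * dt
  curv <- deg2rad(dh) / ds
  curv[speed < v_min] <- NA_real_
  valid <- rep(TRUE, n)
  for (col in c("dropped", "interpolated", "contact"))
    if (col %in% names(track)) valid <- valid & !isTRUE_vec(track[[col]])
  data.frame(
    frame = if ("frame" %in% names(track)) track$frame else seq_len(n),
    time_s = if ("time_s" %in% names(track)) track$time_s else (seq_len(n) - 1) * dt,
    vx_mms = vx, vy_mms = vy, speed_mms = speed, heading_deg = heading,
    curvature_per_mm = curv, valid = valid)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Turn-rate and turn-size series plus the handedness summary
#'
#' Turn rate is the number of turn initiations per tumbling time bin,
#' expressed in turns per minute of run (non-turn, non-excluded) time in
#' that bin. Handedness is `(N_left - N_right) / N_total` over all directed
#' turns; it is missing (not 0) when there are no directed turns.
#'
#' @param segments data.frame from [segment_behaviors()].
#' @param window_min bin width in minutes (default 10).
#' @param total_time_s optional track duration (defaults to max `end_s`).
#' @return list with `series` (data.frame `t_mid_s, turn_rate_per_min,
#'   mean_turn_size_deg, n_turns`) and `summary` (one-row data.frame
#'   `n_left, n_right, n_total, handedness, mean_size_deg`).
#' @export
turn_statistics <- function(segments, window_min = 10, total_time_s = NULL) {
  turns <- segments[segments$state == "turn", , drop = FALSE]
  if (is.null(total_time_s)) total_time_s <- max(segments$end_s, 0)
  win <- window_min * 60
  edges <- seq(0, total_time_s + win, by = win)
  nb <- length(edges) - 1L
  series <- data.frame(t_mid_s = (edges[-1] + edges[-length(edges)]) / 2,
                       turn_rate_per_min = NA_real_,
                       mean_turn_size_deg = NA_real_, n_turns = 0L)
  runs <- segments[segments$state == "run", , drop = FALSE]
  for (b in seq_len(nb)) {
    lo <- edges[b]; hi <- edges[b + 1]
    inb <- turns$start_s >= lo & turns$start_s < hi
    series$n_turns[b] <- sum(inb)
    run_s <- sum(pmax(0, pmin(runs$end_s, hi) - pmax(runs$start_s, lo)))
    if (run_s > 0)
      series$turn_rate_per_min[b] <- sum(inb) / (run_s / 60)
    sz <- turns$turn_size_deg[inb]
    if (any(!is.na(sz))) series$mean_turn_size_deg[b] <- mean(sz, na.rm = TRUE)
  }
  # keep every bin whose start lies inside the track (partial last bin kept)
  series <- series[edges[-length(edges)] < total_time_s, , drop = FALSE]
  nl <- sum(turns$direction == "left", na.rm = TRUE)
  nr <- sum(turns$direction == "right", na.rm = TRUE)
  nt <- nl + nr
  list(series = series,
       summary = data.frame(
         n_left = nl, n_right = nr, n_total = nt,
         handedness = if (nt > 0) (nl - nr) / nt else NA_real_,
         mean_size_deg = if (nrow(turns)) mean(turns$turn_size_deg, na.rm = TRUE)
                         else NA_real_))
}

#' Handedness statistic
#'
#' `(N_left - N_right) / N_total`: +1 means all left turns, -1 all right.
#'
#' @param n_left,n_right directed turn counts.
#' @return the handedness, or `NA` when there are no turns.
#' @export
handedness <- function(n_left, n_right) {
  nt <- n_left + n_right
  if (nt == 0) return(NA_real_)
  (n_left - n_right) / nt
}

#' Navigation index along the gradient axis
#'
#' `NI = <v_x> / <v>`: the time-average of the velocity component along the
#' warm axis divided by the time-average speed (ratio of means, matching
#' the defining formula; not a mean of per-frame ratios). Frames slower
#' than `v_min` or flagged invalid are excluded from both averages. +1 is
#' straight toward the warm side, -1 straight toward the cold side, 0
#' normal to the gradient.
#'
#' @param x a kinematics data.frame from [kinematics()] (columns `vx_mms,
#'   vy_mms, time_s`, optional `valid`), or a raw track with `x_mm, y_mm`
#'   (kinematics are computed first).
#' @param axis unit 2-vector of the warm direction (default `c(1, 0)`).
#' @param window_min optional window width in minutes for a per-window
#'   series (default 10; `NULL` skips the series).
#' @param v_min speed floor in mm/s (default 0.05).
#' @param runs_only if `TRUE` and a `state` column is present, restrict to
#'   run frames.
#' @param state optional per-frame state labels (used with `runs_only`).
#' @param frame_rate_hz used only when `x` is a raw track.
#' @return list with `ni` (overall), `mean_vx`, `mean_speed`, `n_frames`,
#'   and `windows` (data.frame `t_mid_s, ni, n_frames`).
#' @export
navigation_index <- function(x, axis = c(1, 0), window_min = 10,
                             v_min = 0.05, runs_only = FALSE, state = NULL,
                             frame_rate_hz = 10) {
  if (!all(c("vx_mms", "vy_mms") %in% names(x)))
    x <- kinematics(x, frame_rate_hz = frame_rate_hz, v_min = v_min)
  axis <- axis / sqrt(sum(axis^2))
  vx <- x$vx_mms * axis[1] + x$vy_mms * axis[2]
  speed <- sqrt(x$vx_mms^2 + x$vy_mms^2)
  keep <- speed >= v_min & !is.na(speed)
  if ("valid" %in% names(x)) keep <- keep & x$valid
  if (runs_only && !is.null(state)) keep <- keep & state == "run"
  ni_of <- function(sel) {
    if (!any(sel)) return(c(NA_real_, NA_real_, NA_real_))
    c(mean(vx[sel]) / mean(speed[sel]), mean(vx[sel]), mean(speed[sel]))
  }
  overall <- ni_of(keep)
  windows <- NULL
  if (!is.null(window_min)) {
    win <- window_min * 60
    bin <- floor(x$time_s / win)
    ub <- sort(unique(bin))
    windows <- data.frame(
      t_mid_s = (ub + 0.5) * win,
      ni = vapply(ub, function(b) ni_of(keep & bin == b)[1], numeric(1)),
      n_frames = vapply(ub, function(b) sum(keep & bin == b), numeric(1)))
  }
  list(ni = overall[1], mean_vx = overall[2], mean_speed = overall[3],
       n_frames = sum(keep), windows = windows)
}

#' Peri-event average and transient test
#'
#' Aligns a per-frame series on event times, averages across events over a
#' symmetric window, and t-tests each post-event minute against the pooled
#' pre-event baseline (two-sample Student's t-test, no multiple-testing
#' correction -- single-comparison usage, flagged here deliberately).
#' Events without a full window of data on both sides are skipped and
#' counted.
#'
#' @param series data.frame with `time_s` and `value` (e.g. speed), plus an
#'   optional logical `valid`.
#' @param event_times_s numeric vector of event times in seconds.
#' @param window_min half-window in minutes (default 5).
#' @param frame_rate_hz frames per second (default 10).
#' @param alpha significance level for the per-minute flags (default 0.05).
#' @return list with `aligned_t_s`, `mean`, `sd` (event-aligned average),
#'   `minute_tests` (data.frame `minute, mean_post, p, significant`),
#'   `pre_mean`, `n_events`, `n_skipped`, and `returns_to_baseline`
#'   (`TRUE` when the final post minute is not significant).
#' @export
peri_event_average <- function(series, event_times_s, window_min = 5,
                               frame_rate_hz = 10, alpha = 0.05) {
  half <- as.integer(round(window_min * 60 * frame_rate_hz))
  v <- series$value
  ok <- if ("valid" %in% names(series)) isTRUE_vec(series$valid) else
    rep(TRUE, length(v))
  n <- length(v)
  mats <- list(); skipped <- 0L
  for (et in event_times_s) {
    ei <- which.min(abs(series$time_s - et))
    if (ei - half < 1L || ei + half > n) { skipped <- skipped + 1L; next }
    w <- v[(ei - half):(ei + half)]
    w[!ok[(ei - half):(ei + half)]] <- NA
    mats[[length(mats) + 1L]] <- w
  }
  if (!length(mats)) {
    return(list(aligned_t_s = numeric(0), mean = numeric(0), sd = numeric(0),
                minute_tests = data.frame(minute = integer(), mean_post = numeric(),
                                          p = numeric(), significant = logical()),
                pre_mean = NA_real_, n_events = 0L, n_skipped = skipped,
                returns_to_baseline = NA))
  }
  M <- do.call(rbind, mats)
  aligned_t <- seq(-half, half) / frame_rate_hz
  pre_idx <- 1:half
  post_idx <- (half + 2):(2 * half + 1)
  pre_pool <- as.vector(M[, pre_idx]); pre_pool <- pre_pool[!is.na(pre_pool)]
  fpm <- 60L * frame_rate_hz
  n_min <- window_min
  tests <- data.frame(minute = seq_len(n_min), mean_post = NA_real_,
                      p = NA_real_, significant = NA)
  for (m in seq_len(n_min)) {
    cols <- post_idx[((m - 1L) * fpm + 1L):(m * fpm)]
    post <- as.vector(M[, cols]); post <- post[!is.na(post)]
    if (length(post) > 1L && stats::sd(post) > 0 && stats::sd(pre_pool) > 0) {
      tt <- stats::t.test(post, pre_pool)
      tests$mean_post[m] <- mean(post)
      tests$p[m] <- tt$p.value
      tests$significant[m] <- tt$p.value < alpha
    } else if (length(post) > 0L) {
      tests$mean_post[m] <- mean(post)
      eq <- isTRUE(all.equal(mean(post), mean(pre_pool)))
      tests$p[m] <- if (eq) 1 else NA_real_
      tests$significant[m] <- FALSE
    }
  }
  list(aligned_t_s = aligned_t,
       mean = colMeans(M, na.rm = TRUE),
       sd = apply(M, 2, stats::sd, na.rm = TRUE),
       minute_tests = tests,
       pre_mean = mean(pre_pool),
       n_events = nrow(M), n_skipped = skipped,
       returns_to_baseline = !isTRUE(tests$significant[n_min]))
}

#' Stitch a robot-transported trajectory into a continuous path
#'
#' Each sub-path after a drop-off is rigidly translated so that its first
#' point coincides with the last pre-pickup point, removing the transport
#' displacement. Path length is the sum of frame-to-frame displacements
#' over valid (non-dropped, non-interpolated) frames, excluding the
#' manipulation itself.
#'
#' @param track single-animal data.frame with `frame, x_mm, y_mm` and a
#'   logical `dropped` (or `interpolated`) column marking manipulation
#'   frames.
#' @param events optional event table (used only to flag events missing
#'   positions; stitching itself is driven by the dropped mask).
#' @return list with `path` (data.frame `frame, x_mm, y_mm` of the stitched
#'   continuous trajectory, manipulation frames removed), `length_m`
#'   (cumulative path length in metres) and `n_stitches`.
#' @export
stitch_trajectory <- function(track, events = NULL) {
  drop <- rep(FALSE, nrow(track))
  for (col in c("dropped", "interpolated"))
    if (col %in% names(track)) drop <- drop | isTRUE_vec(track[[col]])
  keep <- which(!drop & !is.na(track$x_mm))
  x <- track$x_mm[keep]; y <- track$y_mm[keep]; fr <- track$frame[keep]
  if (!length(keep))
    return(list(path = data.frame(frame = integer(), x_mm = numeric(),
                                  y_mm = numeric()),
                length_m = 0, n_stitches = 0L))
  if (length(keep) == 1L)
    return(list(path = data.frame(frame = fr, x_mm = x, y_mm = y),
                length_m = 0, n_stitches = 0L))
  # a gap in `keep` marks a manipulation: accumulate the rigid translation
  # that glues each post-drop-off sub-path onto the pre-pickup end point
  n_st <- sum(diff(keep) > 1L)
  shift_x <- 0; shift_y <- 0
  out_x <- numeric(length(keep)); out_y <- numeric(length(keep))
  out_x[1] <- x[1]; out_y[1] <- y[1]
  len <- 0
  for (i in 2:length(keep)) {
    if (keep[i] - keep[i - 1L] > 1L) {
      shift_x <- shift_x + (x[i] - x[i - 1L])
      shift_y <- shift_y + (y[i] - y[i - 1L])
    } else {
      len <- len + sqrt((x[i] - x[i - 1L])^2 + (y[i] - y[i - 1L])^2)
    }
    out_x[i] <- x[i] - shift_x
    out_y[i] <- y[i] - shift_y
  }
  list(path = data.frame(frame = fr, x_mm = out_x, y_mm = out_y),
       length_m = len / 1000, n_stitches = n_st)
}

#' Time-binned across-animal summary
#'
#' Bins each animal's series in time, takes the within-animal bin mean,
#' then reports the across-animal mean and standard deviation per bin (the
#' animal, not the frame, is the statistical unit). Bins with fewer than
#' two animals are missing.
#'
#' @param df data.frame with `animal_id, time_s, value`.
#' @param bin_min bin width in minutes (default 10).
#' @return data.frame `t_mid_s, mean, sd, n_animals`.
#' @export
binned_population_summary <- function(df, bin_min = 10) {
  win <- bin_min * 60
  df <- df[!is.na(df$value), , drop = FALSE]
  df$bin <- floor(df$time_s / win)
  per <- stats::aggregate(value ~ animal_id + bin, data = df, FUN = mean)
  agg_m <- stats::aggregate(value ~ bin, data = per, FUN = mean)
  agg_s <- stats::aggregate(value ~ bin, data = per, FUN = stats::sd)
  agg_n <- stats::aggregate(value ~ bin, data = per, FUN = length)
  out <- data.frame(t_mid_s = (agg_m$bin + 0.5) * win,
                    mean = agg_m$value, sd = agg_s$value,
                    n_animals = agg_n$value)
  out$mean[out$n_animals < 2] <- NA_real_
  out$sd[out$n_animals < 2] <- NA_real_
  out[order(out$t_mid_s), , drop = FALSE]
}

#' Slope of the activity decline
#'
#' Ordinary least-squares slope of a binned mean-speed series over a time
#' interval (the first hour by default), in mm/s^2.
#'
#' @param summary data.frame with `t_mid_s` and `mean`
#'   (from [binned_population_summary()]).
#' @param t_max_s upper end of the fitting window in seconds (default 3600).
#' @return the fitted slope in mm/s^2.
#' @export
activity_decline_slope <- function(summary, t_max_s = 3600) {
  sel <- summary$t_mid_s <= t_max_s & !is.na(summary$mean)
  if (sum(sel) < 2) return(NA_real_)
  unname(stats::coef(stats::lm(mean ~ t_mid_s, data = summary[sel, ]))[2])
}

#' Correlation between binned speed and turn rate
#'
#' Computes the linear correlation between matched time-binned speed and
#' turn-rate series: once on the across-animal mean series (the population
#' coefficient) and once per animal, reporting the per-animal mean and sd.
#' Animals with a zero-variance series get a missing coefficient.
#'
#' @param speed_bins data.frame `animal_id, bin, value` of per-animal
#'   binned mean speeds.
#' @param turn_bins data.frame `animal_id, bin, value` of per-animal binned
#'   turn rates, on the same bin grid.
#' @return list with `population_r`, `individual_r` (named vector),
#'   `individual_mean`, `individual_sd`, `n_bins`.
#' @export
speed_turnrate_correlation <- function(speed_bins, turn_bins) {
  m <- merge(speed_bins, turn_bins, by = c("animal_id", "bin"),
             suffixes = c("_speed", "_turn"))
  m <- m[stats::complete.cases(m[, c("value_speed", "value_turn")]), ]
  if (nrow(m) == 0) stop("no matched bins")
  pop_s <- stats::aggregate(value_speed ~ bin, data = m, FUN = mean)
  pop_t <- stats::aggregate(value_turn ~ bin, data = m, FUN = mean)
  pop <- merge(pop_s, pop_t, by = "bin")
  if (nrow(pop) < 10)
    warning("fewer than 10 matched bins for the population series")
  pop_r <- if (stats::sd(pop$value_speed) > 0 && stats::sd(pop$value_turn) > 0)
    stats::cor(pop$value_speed, pop$value_turn) else NA_real_
  ids <- unique(m$animal_id)
  ind <- vapply(ids, function(id) {
    s <- m[m$animal_id == id, ]
    if (nrow(s) < 3 || stats::sd(s$value_speed) == 0 ||
        stats::sd(s$value_turn) == 0) return(NA_real_)
    stats::cor(s$value_speed, s$value_turn)
  }, numeric(1))
  names(ind) <- ids
  list(population_r = pop_r, individual_r = ind,
       individual_mean = mean(ind, na.rm = TRUE),
       individual_sd = stats::sd(ind[!is.na(ind)]),
       n_bins = nrow(pop))
}
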