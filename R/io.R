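# File formats, configuration, and the end-to-end pipeline driver.
# Trajectory tables are CSV with a fixed column order; robot events are
# JSON Lines; configuration is a flat TOML file; reports are JSON.

trajectory_columns <- c("time_s", "frame", "animal_id", "x_mm", "y_mm",
                        "head_x_mm", "head_y_mm", "tail_x_mm", "tail_y_mm",
                        "bend_deg", "state", "interpolated", "contact",
                        "event_id")

#' Write a trajectory table
#'
#' CSV with the canonical column order (`time_s, frame, animal_id, x_mm,
#' y_mm, head_x_mm, head_y_mm, tail_x_mm, tail_y_mm, bend_deg, state,
#' interpolated, contact, event_id`). Numbers are serialized at full
#' precision (17 significant digits) so write-then-read is the identity on
#' values; missing values are empty fields.
#'
#' @param df data.frame containing at least `frame, animal_id, x_mm, y_mm`;
#'   missing canonical columns are filled with `NA`, extra columns are
#'   dropped with a warning.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_table <- function(df, path) {
  extra <- setdiff(names(df), trajectory_columns)
  if (length(extra))
    warning("dropping non-canonical column(s): ", paste(extra, collapse = ", "))
  for (cn in trajectory_columns) if (!cn %in% names(df)) df[[cn]] <- NA
  df <- df[, trajectory_columns]
  if (anyDuplicated(df[, c("frame", "animal_id")]))
    stop("duplicate (frame, animal_id) rows")
  fmt <- function(x) {
    if (is.numeric(x)) {
      out <- sprintf("%.17g", x)
      out[is.na(x)] <- ""
      out
    } else {
      out <- as.character(x)
      out[is.na(x)] <- ""
      out
    }
  }
  m <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1, dimnames = list(NULL, names(df)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(trajectory_columns, collapse = ","), con)
  if (nrow(df)) writeLines(apply(m, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a trajectory table
#'
#' @param path CSV file written by [write_trajectory_table()].
#' @return data.frame in canonical column order. Duplicate
#'   `(frame, animal_id)` keys are an error naming the first offending
#'   row; unknown columns produce a warning and are kept.
#' @export
read_trajectory_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA, na.strings = "")
  unknown <- setdiff(names(df), trajectory_columns)
  if (length(unknown))
    warning("unknown column(s): ", paste(unknown, collapse = ", "))
  missing_cols <- setdiff(c("frame", "animal_id"), names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  dup <- anyDuplicated(df[, c("frame", "animal_id")])
  if (dup)
    stop("duplicate (frame, animal_id) at data row ", dup,
         " (frame ", df$frame[dup], ", animal ", df$animal_id[dup], ")")
  # enforce canonical column types (all-NA columns otherwise read as logical)
  for (cn in c("time_s", "x_mm", "y_mm", "head_x_mm", "head_y_mm",
               "tail_x_mm", "tail_y_mm", "bend_deg"))
    if (cn %in% names(df)) df[[cn]] <- as.numeric(df[[cn]])
  for (cn in c("frame", "animal_id", "event_id"))
    if (cn %in% names(df)) df[[cn]] <- as.integer(df[[cn]])
  for (cn in c("interpolated", "contact"))
    if (cn %in% names(df) && !is.logical(df[[cn]]))
      df[[cn]] <- as.logical(df[[cn]])
  if ("state" %in% names(df)) df$state <- as.character(df$state)
  df
}

#' Write robot events as JSON Lines
#'
#' One JSON object per line with fields `time_s, frame, animal_id, type,
#' from_xy_mm, to_xy_mm, attempts, success`.
#'
#' @param events event data.frame from the simulator.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events_jsonl <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    obj <- list(time_s = e$time_s, frame = e$frame,
                animal_id = e$animal_id, type = e$type,
                from_xy_mm = c(e$from_x_mm, e$from_y_mm),
                to_xy_mm = c(e$to_x_mm, e$to_y_mm),
                attempts = e$attempts, success = e$success)
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, na = "null"),
               con)
  }
  invisible(path)
}

#' Read robot events from JSON Lines
#'
#' @param path file written by [write_events_jsonl()].
#' @return event data.frame.
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  rows <- lapply(lines, function(l) {
    o <- jsonlite::fromJSON(l)
    data.frame(time_s = o$time_s, frame = o$frame, animal_id = o$animal_id,
               type = o$type,
               from_x_mm = o$from_xy_mm[1], from_y_mm = o$from_xy_mm[2],
               to_x_mm = if (is.null(o$to_xy_mm[1])) NA_real_ else o$to_xy_mm[1],
               to_y_mm = if (is.null(o$to_xy_mm[2])) NA_real_ else o$to_xy_mm[2],
               attempts = o$attempts, success = o$success)
  })
  do.call(rbind, rows)
}

#' Write a flat TOML configuration file
#'
#' Serializes a flat named list (numbers, strings, logicals, numeric
#' vectors) as `key = value` TOML. Round-trips losslessly through
#' [read_config()].
#'
#' @param config flat named list.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt1 <- function(v) {
    if (is.character(v)) sprintf("\"%s\"", v)
    else if (is.logical(v)) ifelse(v, "true", "false")
    else sprintf("%.17g", v)
  }
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (length(v) > 1L)
      sprintf("%s = [%s]", k, paste(fmt1(v), collapse = ", "))
    else sprintf("%s = %s", k, fmt1(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a flat TOML configuration file
#'
#' @param path file of `key = value` lines (strings quoted, booleans
#'   true/false, arrays in brackets; comments with `#`).
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parse1 <- function(tok) {
    tok <- trimws(tok)
    if (grepl("^\".*\"$", tok)) return(sub("^\"(.*)\"$", "\\1", tok))
    if (tok == "true") return(TRUE)
    if (tok == "false") return(FALSE)
    as.numeric(tok)
  }
  out <- list()
  for (l in lines) {
    kv <- regmatches(l, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", l))[[1]]
    if (length(kv) != 3) stop("cannot parse config line: ", l)
    val <- trimws(kv[3])
    if (grepl("^\\[.*\\]$", val)) {
      toks <- strsplit(sub("^\\[(.*)\\]$", "\\1", val), ",")[[1]]
      out[[kv[2]]] <- vapply(toks, parse1, parse1(trimws(toks[1])),
                             USE.NAMES = FALSE)
    } else {
      out[[kv[2]]] <- parse1(val)
    }
  }
  out
}

#' Default pipeline configuration
#'
#' Flattened simulator + analysis configuration with all tunable
#' parameters; the values are the package defaults.
#'
#' @param seed global seed (default 1).
#' @param n_animals number of larvae (default 5).
#' @param duration_s experiment length in seconds (default 3600).
#' @param gradient_enabled simulate under the thermal gradient
#'   (default `FALSE`).
#' @param full_path render frames and re-track them instead of feeding
#'   ground-truth positions forward (default `FALSE`; much slower).
#' @return named list (a flat `run_config`).
#' @export
default_config <- function(seed = 1L, n_animals = 5L, duration_s = 3600,
                           gradient_enabled = FALSE, full_path = FALSE) {
  p <- sim_params()
  a <- arena_config()
  f <- thermal_field(enabled = gradient_enabled)
  list(
    seed = seed, n_animals = n_animals, duration_s = duration_s,
    full_path = full_path,
    side_length_mm = a$side_length_mm, frame_rate_hz = a$frame_rate_hz,
    pixel_scale_mm = a$pixel_scale_mm, edge_margin_mm = a$edge_margin_mm,
    gradient_enabled = gradient_enabled,
    gradient_steepness_c_per_mm = f$steepness_c_per_mm,
    gradient_center_temp_c = f$center_temp_c,
    base_speed = p$base_speed, min_speed = p$min_speed,
    speed_decline_rate = p$speed_decline_rate,
    decline_duration_s = p$decline_duration_s,
    base_turn_rate = p$base_turn_rate,
    turn_size_mean = p$turn_size_mean, turn_size_sd = p$turn_size_sd,
    handedness_bias = p$handedness_bias,
    heading_diffusion = p$heading_diffusion,
    thermotaxis_gain = if (gradient_enabled) 1.0 else 0,
    turn_duration_s = p$turn_duration_s,
    bend_on = 30, bend_off = 15, heading_rate_on = 20, heading_rate_off = 10,
    smooth_window = 11, v_min = 0.05, bin_min = 10, ni_window_min = 10
  )
}

config_objects <- function(config) {
  list(
    arena = arena_config(config$side_length_mm, config$frame_rate_hz,
                         config$pixel_scale_mm, config$edge_margin_mm),
    field = thermal_field(config$gradient_steepness_c_per_mm,
                          config$gradient_center_temp_c,
                          enabled = isTRUE(config$gradient_enabled)),
    params = sim_params(
      base_speed = config$base_speed, min_speed = config$min_speed,
      speed_decline_rate = config$speed_decline_rate,
      decline_duration_s = config$decline_duration_s,
      base_turn_rate = config$base_turn_rate,
      turn_size_mean = config$turn_size_mean,
      turn_size_sd = config$turn_size_sd,
      handedness_bias = config$handedness_bias,
      heading_diffusion = config$heading_diffusion,
      thermotaxis_gain = config$thermotaxis_gain,
      turn_duration_s = config$turn_duration_s)
  )
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' simulate -> (optionally render + track) -> posture -> behavior ->
#' features -> variability, writing every intermediate artifact into
#' `out_dir` (trajectory CSV, segment CSV, events JSONL, config TOML,
#' report JSON). By default the trajectory fast path feeds ground-truth
#' positions and postures forward; `full_path = TRUE` renders frames and
#' re-tracks them. Every output embeds the config hash and seed.
#'
#' @param config flat configuration list from [default_config()] (possibly
#'   modified) or [read_config()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing and just returns the report.
#' @return the experiment report (named list), invisibly when writing.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  obj <- config_objects(config)
  hash <- fnv1a_hash(paste(names(config), vapply(config, paste,
                                                 character(1), collapse = ","),
                           sep = "=", collapse = ";"))
  sim <- simulate_experiment(config$n_animals, config$duration_s,
                             obj$params, obj$arena,
                             field = obj$field,
                             controller = robot_controller(),
                             seed = config$seed)
  fr <- obj$arena$frame_rate_hz
  if (isTRUE(config$full_path)) {
    stack <- render_frames(sim, obj$arena)
    trk <- track_movie(stack)
    tracks <- trk$tracks
    tracks$time_s <- (tracks$frame - 1) / fr
    tracks$dropped <- !tracks$detected & tracks$interpolated
    ids <- sort(unique(tracks$animal_id))
    tracks_list <- lapply(ids, function(id) {
      tt <- tracks[tracks$animal_id == id, ]
      crops <- extract_crops(tt, stack)
      posture_track(tt, crops, obj$arena$pixel_scale_mm, fr)
    })
  } else {
    gt <- sim$tracks
    gt$interpolated <- FALSE
    gt$contact <- FALSE
    tracks_list <- split(gt, gt$animal_id)
  }

  seg_list <- list(); feat_rows <- list(); ni_per_animal <- numeric(0)
  speed_bins <- list(); turn_bins <- list()
  bin_s <- config$bin_min * 60
  for (tt in tracks_list) {
    id <- tt$animal_id[1]
    excl <- isTRUE_vec(tt$dropped)
    if ("interpolated" %in% names(tt)) excl <- excl | isTRUE_vec(tt$interpolated)
    lab <- classify_states(tt, fr, config$bend_on, config$bend_off,
                           config$heading_rate_on, config$heading_rate_off,
                           config$smooth_window, exclude = excl)
    kin <- kinematics(tt, fr, config$smooth_window, config$v_min)
    seg <- segment_behaviors(lab, kin$heading_deg, fr, animal_id = id,
                             frames = tt$frame)
    seg_list[[as.character(id)]] <- seg
    ni <- navigation_index(kin, window_min = config$ni_window_min,
                           v_min = config$v_min)
    ni_per_animal[as.character(id)] <- ni$ni
    feat_rows[[as.character(id)]] <- data.frame(
      animal_id = id, time_s = kin$time_s, value = kin$speed_mms)[kin$valid, ]
    ts <- turn_statistics(seg, config$bin_min,
                          total_time_s = max(tt$time_s) + 1 / fr)
    speed_bins[[as.character(id)]] <- data.frame(
      animal_id = id, bin = floor(kin$time_s[kin$valid] / bin_s),
      value = kin$speed_mms[kin$valid])
    turn_bins[[as.character(id)]] <- data.frame(
      animal_id = id, bin = floor(ts$series$t_mid_s / bin_s),
      value = ts$series$turn_rate_per_min)
    tt$state <- lab
  }
  segments <- do.call(rbind, seg_list)
  all_turn_stats <- turn_statistics(segments, config$bin_min,
                                    total_time_s = config$duration_s)
  speed_df <- do.call(rbind, feat_rows)
  pop_speed <- binned_population_summary(speed_df, config$bin_min)
  sb <- do.call(rbind, lapply(speed_bins, function(d)
    stats::aggregate(value ~ animal_id + bin, data = d, FUN = mean)))
  corr <- tryCatch(
    speed_turnrate_correlation(sb, do.call(rbind, turn_bins)),
    error = function(e) list(population_r = NA_real_,
                             individual_mean = NA_real_,
                             individual_sd = NA_real_))
  ni_vec <- ni_per_animal[!is.na(ni_per_animal)]
  bc <- if (length(ni_vec) >= 4 && stats::var(ni_vec) > 0)
    bimodality_coefficient(ni_vec)$bc else NA_real_

  report <- list(
    config_hash = hash, seed = config$seed,
    n_animals = config$n_animals, duration_s = config$duration_s,
    gradient = if (isTRUE(config$gradient_enabled)) "enabled" else "no gradient",
    n_turns = sum(segments$state == "turn"),
    n_robot_events = nrow(sim$events),
    handedness = all_turn_stats$summary$handedness,
    mean_speed_mms = mean(speed_df$value),
    decline_slope_mms2 = activity_decline_slope(pop_speed),
    navigation_index = if (isTRUE(config$gradient_enabled))
      list(per_animal = as.list(ni_per_animal),
           mean = mean(ni_vec), sd = stats::sd(ni_vec), bc = bc)
      else list(note = "no gradient", per_animal = as.list(ni_per_animal),
                mean = mean(ni_vec), sd = stats::sd(ni_vec), bc = bc),
    speed_turnrate_population_r = corr$population_r,
    speed_turnrate_individual = c(mean = corr$individual_mean,
                                  sd = corr$individual_sd)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- function(p) file.path(out_dir, p)
    gt_out <- do.call(rbind, tracks_list)
    gt_out$state <- unlist(lapply(tracks_list, function(tt) {
      excl <- isTRUE_vec(tt$dropped)
      classify_states(tt, fr, config$bend_on, config$bend_off,
                      config$heading_rate_on, config$heading_rate_off,
                      config$smooth_window, exclude = excl)
    }), use.names = FALSE)
    if (!"interpolated" %in% names(gt_out)) gt_out$interpolated <- FALSE
    if (!"contact" %in% names(gt_out)) gt_out$contact <- FALSE
    suppressWarnings(write_trajectory_table(gt_out, stamp("trajectories.csv")))
    utils::write.csv(segments, stamp("segments.csv"), row.names = FALSE)
    write_events_jsonl(sim$events, stamp("events.jsonl"))
    write_config(config, stamp("config.toml"))
    jsonlite::write_json(report, stamp("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    return(invisible(report))
  }
  report
}
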