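# Sparse-pixel renderer. A full-resolution 220 mm arena at 0.1 mm/px is a
# 2200 x 2200 frame of which ~30-200 pixels are lit; frames are therefore
# stored sparsely (one integer matrix of lit pixels per frame) and
# materialized to dense matrices only on demand.

#' Render a simulated experiment to a frame stack
#'
#' Produces 8-bit grayscale frames in which each larva appears as an
#' elongated cluster of roughly 30 uniformly bright pixels on a dark
#' background, oriented along its heading and bent at the midpoint by its
#' body bend. Frames during robot manipulations are emitted fully dark and
#' flagged in the dropped-frame mask. Overlapping animals render merged.
#'
#' @param x a `larva_experiment` from [simulate_experiment()], or a tracks
#'   data.frame with columns `frame, animal_id, x_mm, y_mm, heading_deg,
#'   bend_deg, bend_sign, dropped`.
#' @param arena an [arena_config()]; its `pixel_scale_mm` sets resolution.
#' @param intensity pixel value of the body (default 255).
#' @param half_width_px body half-width in pixels (default 1.2, which gives
#'   a ~30 px cluster for a 1 mm larva at 0.1 mm/px).
#' @param body_length_mm larva body length (default 1.0).
#' @param noise_sd sd of Gaussian noise added to lit pixels (default 0).
#' @param frames optional integer vector restricting which frames to render.
#' @return an object of class `frame_stack`: a list with `pixels` (list of
#'   3-column matrices `x_px, y_px, value`; 0-based, y-up), `width`,
#'   `height`, `pixel_scale_mm`, `frame_rate_hz`, `dropped` and `frames`.
#' @export
render_frames <- function(x, arena = arena_config(), intensity = 255,
                          half_width_px = 1.2, body_length_mm = 1.0,
                          noise_sd = 0, frames = NULL) {
  tracks <- if (inherits(x, "larva_experiment")) x$tracks else x
  if (inherits(x, "larva_experiment") && !is.null(x$params))
    body_length_mm <- x$params$body_length_mm
  scale <- arena$pixel_scale_mm
  wh <- as.integer(ceiling(arena$side_length_mm / scale))
  all_frames <- sort(unique(tracks$frame))
  if (!is.null(frames)) all_frames <- intersect(all_frames, frames)
  n <- length(all_frames)
  by_frame <- split(tracks, tracks$frame)
  r2 <- half_width_px^2
  off <- ceiling(half_width_px) + 1L
  dx_off <- rep(-off:off, times = 2L * off + 1L)
  dy_off <- rep(-off:off, each = 2L * off + 1L)

  pix_list <- vector("list", n)
  dropped <- logical(n)
  for (k in seq_len(n)) {
    fr <- by_frame[[as.character(all_frames[k])]]
    empty_px <- matrix(numeric(0), ncol = 3,
                       dimnames = list(NULL, c("x_px", "y_px", "value")))
    if (is.null(fr) || nrow(fr) == 0L) { pix_list[[k]] <- empty_px; next }
    # the arm occludes the whole camera view: any manipulated animal drops
    # the entire frame
    if (any(fr$dropped)) { pix_list[[k]] <- empty_px; dropped[k] <- TRUE; next }
    keys_all <- integer(0)
    for (j in seq_len(nrow(fr))) {
      bs <- if ("bend_sign" %in% names(fr)) fr$bend_sign[j] else 1
      bd <- if ("bend_deg" %in% names(fr)) fr$bend_deg[j] else 0
      ml <- larva_midline(fr$x_mm[j], fr$y_mm[j], fr$heading_deg[j],
                          bd, bs, body_length_mm, n = 25L)
      mlx <- ml[, 1] / scale; mly <- ml[, 2] / scale   # continuous px coords
      # candidate pixels: disks stamped around each midline sample
      cxp <- rep(floor(mlx), each = length(dx_off)) + dx_off
      cyp <- rep(floor(mly), each = length(dx_off)) + dy_off
      key <- cxp + cyp * wh
      keep <- !duplicated(key) & cxp >= 0 & cxp < wh & cyp >= 0 & cyp < wh
      cxp <- cxp[keep]; cyp <- cyp[keep]; key <- key[keep]
      # lit iff pixel centre within half_width of the midline polyline
      d2 <- rep(Inf, length(cxp))
      pcx <- cxp + 0.5; pcy <- cyp + 0.5
      for (m in seq_along(mlx)) {
        dd <- (pcx - mlx[m])^2 + (pcy - mly[m])^2
        d2 <- pmin(d2, dd)
      }
      keys_all <- c(keys_all, key[d2 <= r2])
    }
    keys_all <- unique(keys_all)
    v <- rep(as.numeric(intensity), length(keys_all))
    if (noise_sd > 0 && length(v)) {
      v <- pmin(pmax(round(v + stats::rnorm(length(v), 0, noise_sd)), 0), 255)
    }
    pix_list[[k]] <- cbind(x_px = keys_all %% wh, y_px = keys_all %/% wh,
                           value = v)
  }
  structure(list(pixels = pix_list, width = wh, height = wh,
                 pixel_scale_mm = scale,
                 frame_rate_hz = arena$frame_rate_hz,
                 dropped = dropped, frames = all_frames),
            class = "frame_stack")
}

#' Materialize one frame as a dense matrix
#'
#' @param stack a `frame_stack`.
#' @param i frame index into the stack (1-based position, not frame number).
#' @return a `height x width` numeric matrix; `[row, col]` = `[y + 1, x + 1]`
#'   with y-up pixel coordinates.
#' @export
frame_matrix <- function(stack, i) {
  m <- matrix(0, nrow = stack$height, ncol = stack$width)
  p <- stack$pixels[[i]]
  if (nrow(p)) m[cbind(p[, 2] + 1L, p[, 1] + 1L)] <- p[, 3]
  m
}

#' @export
print.frame_stack <- function(x, ...) {
  cat(sprintf("frame_stack: %d frame(s) of %d x %d px (%.3g mm/px), %d dropped\n",
              length(x$pixels), x$width, x$height, x$pixel_scale_mm,
              sum(x$dropped)))
  invisible(x)
}

#' Write a frame as a plain-text PGM image
#'
#' Portable graymap (P2) export for inspection with standard image tools.
#' The image is written in raster order (top row first), so y-up pixel
#' coordinates are flipped vertically.
#'
#' @param stack a `frame_stack`.
#' @param i frame index into the stack.
#' @param path output file path.
#' @export
write_pgm <- function(stack, i, path) {
  m <- frame_matrix(stack, i)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), "255"), con)
  for (r in nrow(m):1)
    writeLines(paste(as.integer(m[r, ]), collapse = " "), con)
  invisible(path)
}
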