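# Blob detection, identity-preserving linking, gap interpolation, and
# fixed-size crop extraction.

# Union-find over integers 1..n
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Detect larva-sized blobs in a frame
#'
#' Connected components (8-connectivity) of pixels above `threshold` with
#' area inside `[min_area, max_area]`. The centroid is the intensity-weighted
#' mean of pixel centres; the contour is the set of boundary pixels of the
#' component.
#'
#' @param frame either a dense numeric matrix (`[row, col]` with y-up rows,
#'   as from [frame_matrix()]), or a sparse 3-column matrix
#'   `x_px, y_px, value`, or a `frame_stack` together with `i`.
#' @param threshold intensity threshold (default 128).
#' @param min_area,max_area area gate in pixels (defaults 8 and 400; a lone
#'   larva covers ~30 px, merged pairs more).
#' @param i frame index when `frame` is a `frame_stack`.
#' @return a data.frame with one row per detection: `blob_id, cx_px, cy_px,
#'   area`, with attributes `pixels` and `contour` (lists of 2-column
#'   matrices of 0-based pixel coordinates). Empty frames give zero rows.
#' @export
detect_blobs <- function(frame, threshold = 128, min_area = 8,
                         max_area = 400, i = NULL) {
  if (inherits(frame, "frame_stack")) {
    stopifnot(!is.null(i))
    frame <- frame$pixels[[i]]
  }
  if (is.matrix(frame) && ncol(frame) != 3) {
    idx <- which(frame > threshold, arr.ind = TRUE)
    sp <- cbind(x_px = idx[, 2] - 1L, y_px = idx[, 1] - 1L,
                value = frame[idx])
  } else {
    sp <- frame
    if (nrow(sp)) sp <- sp[sp[, 3] > threshold, , drop = FALSE]
  }
  empty <- data.frame(blob_id = integer(), cx_px = numeric(),
                      cy_px = numeric(), area = integer())
  attr(empty, "pixels") <- list(); attr(empty, "contour") <- list()
  m <- nrow(sp)
  if (m == 0L) return(empty)

  xs <- as.integer(sp[, 1]); ys <- as.integer(sp[, 2]); vals <- sp[, 3]
  W <- max(xs) + 2L
  key <- xs + ys * W
  ord <- order(key)
  xs <- xs[ord]; ys <- ys[ord]; vals <- vals[ord]; key <- key[ord]
  parent <- uf_new(m)
  # union with 4 forward neighbors (covers all 8 by symmetry)
  for (d in list(c(1L, 0L), c(-1L, 1L), c(0L, 1L), c(1L, 1L))) {
    nk <- key + d[1] + d[2] * W
    j <- match(nk, key)
    hit <- which(!is.na(j))
    for (a in hit) {
      ra <- uf_find(parent, a); rb <- uf_find(parent, j[a])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_len(m), function(a) uf_find(parent, a), integer(1))
  comp <- match(root, unique(root))
  n_neigh <- integer(m)  # 8-neighbour counts, for boundary extraction
  for (d in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L),
                 c(1L, 1L), c(1L, -1L), c(-1L, 1L), c(-1L, -1L))) {
    n_neigh <- n_neigh + !is.na(match(key + d[1] + d[2] * W, key))
  }

  out <- list(); pix <- list(); cont <- list(); bid <- 0L
  for (cc in seq_len(max(comp))) {
    sel <- comp == cc
    area <- sum(sel)
    if (area < min_area || area > max_area) next
    bid <- bid + 1L
    w <- vals[sel] / sum(vals[sel])
    out[[bid]] <- data.frame(
      blob_id = bid,
      cx_px = sum((xs[sel] + 0.5) * w),
      cy_px = sum((ys[sel] + 0.5) * w),
      area = area)
    pix[[bid]] <- cbind(x_px = xs[sel], y_px = ys[sel])
    bsel <- sel & n_neigh < 8L
    cont[[bid]] <- cbind(x_px = xs[bsel], y_px = ys[bsel])
  }
  if (bid == 0L) return(empty)
  res <- do.call(rbind, out)
  attr(res, "pixels") <- pix
  attr(res, "contour") <- cont
  res
}

#' Detect blobs in every frame of a stack
#'
#' @param stack a `frame_stack`.
#' @inheritParams detect_blobs
#' @return list of per-frame detection data.frames (see [detect_blobs()]);
#'   `NULL` entries mark dropped frames.
#' @export
detect_stack <- function(stack, threshold = 128, min_area = 8,
                         max_area = 400) {
  lapply(seq_along(stack$pixels), function(i) {
    if (stack$dropped[i]) return(NULL)
    detect_blobs(stack$pixels[[i]], threshold, min_area, max_area)
  })
}

#' Link detections into identity-stable tracks
#'
#' Greedy mutual-nearest-neighbour assignment frame to frame within a
#' gating radius. The animal count is fixed at the first non-empty frame
#' (the experiment has a known number of larvae): new identities are never
#' created mid-sequence. A track that goes undetected persists awaiting
#' re-detection; after gated assignment, leftover detections are claimed by
#' the nearest lost track regardless of the gate, which re-acquires animals
#' relocated by the robot. A detection larger than `merge_factor` times the
#' running median per-animal area is treated as a merged pair: all gated
#' tracks are attached to it at their last-known offsets and the frames are
#' flagged `contact` (freeze-and-flag policy; the real system's behaviour
#' through larva-larva contact is not documented).
#'
#' @param detections list of per-frame detection tables from
#'   [detect_stack()] (`NULL` = dropped frame).
#' @param pixel_scale_mm mm per pixel, for the gate and output coordinates.
#' @param gating_radius_mm assignment gate in mm (default 3, about 6x the
#'   per-frame displacement at 0.5 mm/s and 10 Hz).
#' @param merge_factor area ratio above which a detection is a merged pair.
#' @param frames optional frame numbers (defaults to list positions).
#' @return a data.frame `frame, animal_id, x_px, y_px, x_mm, y_mm, area,
#'   detected, contact` where undetected frames carry `NA` coordinates.
#' @export
link_identities <- function(detections, pixel_scale_mm,
                            gating_radius_mm = 3, merge_factor = 1.6,
                            frames = NULL) {
  nf <- length(detections)
  if (is.null(frames)) frames <- seq_len(nf)
  gate_px <- gating_radius_mm / pixel_scale_mm
  first <- which(vapply(detections, function(d) !is.null(d) && nrow(d) > 0,
                        logical(1)))[1]
  if (is.na(first)) stop("no detections in any frame")
  n_tracks <- nrow(detections[[first]])
  last_x <- detections[[first]]$cx_px
  last_y <- detections[[first]]$cy_px
  areas <- detections[[first]]$area

  rows <- vector("list", nf)
  for (f in seq_len(nf)) {
    det <- detections[[f]]
    X <- rep(NA_real_, n_tracks); Y <- rep(NA_real_, n_tracks)
    A <- rep(NA_real_, n_tracks)
    DETECTED <- rep(FALSE, n_tracks); CONTACT <- rep(FALSE, n_tracks)
    if (!is.null(det) && nrow(det) > 0 && f >= first) {
      nd <- nrow(det)
      med_area <- stats::median(areas)
      big <- det$area > merge_factor * med_area
      D <- outer(last_x, det$cx_px, `-`)^2 + outer(last_y, det$cy_px, `-`)^2
      free_t <- rep(TRUE, n_tracks); free_d <- rep(TRUE, nd)
      # merged blobs first: attach every gated track, frozen at offsets
      for (j in which(big)) {
        tr <- which(free_t & D[, j] <= (2 * gate_px)^2)
        if (length(tr) >= 2L) {
          for (ti in tr) {
            X[ti] <- last_x[ti]; Y[ti] <- last_y[ti]
            A[ti] <- det$area[j] / length(tr)
            DETECTED[ti] <- TRUE; CONTACT[ti] <- TRUE
            free_t[ti] <- FALSE
          }
          free_d[j] <- FALSE
        }
      }
      # greedy minimum-distance gated assignment (ties -> lower animal_id)
      repeat {
        Dm <- D
        Dm[!free_t, ] <- Inf; Dm[, !free_d] <- Inf
        if (all(!is.finite(Dm))) break
        ij <- arrayInd(which.min(Dm), dim(Dm))
        if (Dm[ij] > gate_px^2) break
        ti <- ij[1]; dj <- ij[2]
        X[ti] <- det$cx_px[dj]; Y[ti] <- det$cy_px[dj]; A[ti] <- det$area[dj]
        DETECTED[ti] <- TRUE
        free_t[ti] <- FALSE; free_d[dj] <- FALSE
      }
      # re-acquisition: leftover detections claimed by nearest lost track
      while (any(free_d) && any(free_t)) {
        Dm <- D
        Dm[!free_t, ] <- Inf; Dm[, !free_d] <- Inf
        ij <- arrayInd(which.min(Dm), dim(Dm))
        ti <- ij[1]; dj <- ij[2]
        X[ti] <- det$cx_px[dj]; Y[ti] <- det$cy_px[dj]; A[ti] <- det$area[dj]
        DETECTED[ti] <- TRUE
        free_t[ti] <- FALSE; free_d[dj] <- FALSE
      }
      upd <- DETECTED & !CONTACT
      last_x[upd] <- X[upd]; last_y[upd] <- Y[upd]
      areas <- c(areas, A[upd & !is.na(A)])
      if (length(areas) > 500L) areas <- utils::tail(areas, 500L)
    }
    rows[[f]] <- data.frame(frame = frames[f],
                            animal_id = seq_len(n_tracks),
                            x_px = X, y_px = Y, area = A,
                            detected = DETECTED, contact = CONTACT)
  }
  out <- do.call(rbind, rows)
  out$x_mm <- out$x_px * pixel_scale_mm
  out$y_mm <- out$y_px * pixel_scale_mm
  out
}

#' Interpolate detection gaps in a track
#'
#' Fills runs of undetected frames bounded by detections on both sides by
#' linear interpolation of the centroid, flagging them `interpolated`.
#' Gaps longer than `max_gap` are left unfilled and flagged as track
#' breaks, as are gaps at the start or end of the track.
#'
#' @param track a single-animal slice of the [link_identities()] output
#'   (columns `frame, x_mm, y_mm, detected`), frames strictly increasing.
#' @param max_gap longest gap, in frames, that may be bridged
#'   (default 150, which spans a 10 s robot occlusion at 10 Hz).
#' @return the track with `x_mm, y_mm` filled where bridged and added
#'   logical columns `interpolated` and `track_break`.
#' @export
interpolate_gaps <- function(track, max_gap = 150) {
  stopifnot(!is.unsorted(track$frame, strictly = TRUE))
  n <- nrow(track)
  det <- track$detected & !is.na(track$x_mm)
  track$interpolated <- FALSE
  track$track_break <- FALSE
  if (all(det) || !any(det)) return(track)
  r <- rle(det)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    a <- starts[k]; b <- ends[k]
    if (a == 1L || b == n || r$lengths[k] > max_gap) {
      track$track_break[a:b] <- TRUE
      next
    }
    i0 <- a - 1L; i1 <- b + 1L
    w <- (track$frame[a:b] - track$frame[i0]) /
         (track$frame[i1] - track$frame[i0])
    track$x_mm[a:b] <- track$x_mm[i0] + w * (track$x_mm[i1] - track$x_mm[i0])
    track$y_mm[a:b] <- track$y_mm[i0] + w * (track$y_mm[i1] - track$y_mm[i0])
    if ("x_px" %in% names(track)) {
      track$x_px[a:b] <- track$x_px[i0] + w * (track$x_px[i1] - track$x_px[i0])
      track$y_px[a:b] <- track$y_px[i0] + w * (track$y_px[i1] - track$y_px[i0])
    }
    track$interpolated[a:b] <- TRUE
  }
  track
}

#' Extract fixed-size crops around a track
#'
#' Cuts a `size x size` pixel window centred on the tracked centroid from
#' each detected (non-interpolated) frame, zero-padded at arena borders.
#'
#' @param track single-animal track with `frame, x_px, y_px, detected`.
#' @param stack the `frame_stack` the track was made from.
#' @param size crop side length in pixels (default 64).
#' @return a named list (by frame number) of `size x size` matrices with
#'   attributes `origin` (0-based pixel coordinate of the crop's lower-left
#'   corner) on each crop.
#' @export
extract_crops <- function(track, stack, size = 64L) {
  size <- as.integer(size)
  pos <- match(track$frame, stack$frames)
  out <- list()
  for (r in seq_len(nrow(track))) {
    if (!isTRUE(track$detected[r]) || is.na(track$x_px[r])) next
    p <- stack$pixels[[pos[r]]]
    x0 <- as.integer(round(track$x_px[r])) - size %/% 2L
    y0 <- as.integer(round(track$y_px[r])) - size %/% 2L
    m <- matrix(0, size, size)
    if (nrow(p)) {
      sel <- p[, 1] >= x0 & p[, 1] < x0 + size &
             p[, 2] >= y0 & p[, 2] < y0 + size
      if (any(sel)) {
        m[cbind(p[sel, 2] - y0 + 1L, p[sel, 1] - x0 + 1L)] <- p[sel, 3]
      }
    }
    attr(m, "origin") <- c(x0, y0)
    out[[as.character(track$frame[r])]] <- m
  }
  out
}

#' Track a rendered movie end to end
#'
#' Convenience wrapper: detect blobs in every frame, link identities,
#' interpolate gaps per animal, and report QC counters.
#'
#' @param stack a `frame_stack`.
#' @param threshold,min_area,max_area passed to [detect_blobs()].
#' @param gating_radius_mm,merge_factor passed to [link_identities()].
#' @param max_gap passed to [interpolate_gaps()].
#' @return list with `tracks` (data.frame over all animals) and `qc`
#'   (detections-per-frame histogram, gap statistics, contact-frame count).
#' @export
track_movie <- function(stack, threshold = 128, min_area = 8, max_area = 400,
                        gating_radius_mm = 3, merge_factor = 1.6,
                        max_gap = 150) {
  dets <- detect_stack(stack, threshold, min_area, max_area)
  linked <- link_identities(dets, stack$pixel_scale_mm, gating_radius_mm,
                            merge_factor, frames = stack$frames)
  per_animal <- lapply(split(linked, linked$animal_id), interpolate_gaps,
                       max_gap = max_gap)
  tracks <- do.call(rbind, per_animal)
  rownames(tracks) <- NULL
  ndet <- vapply(dets, function(d) if (is.null(d)) NA_integer_ else nrow(d),
                 integer(1))
  qc <- list(
    n_frames = length(dets),
    n_dropped = sum(is.na(ndet)),
    detections_per_frame = table(ndet, useNA = "ifany"),
    n_interpolated = sum(tracks$interpolated),
    n_track_break = sum(tracks$track_break),
    n_contact = sum(tracks$contact)
  )
  list(tracks = tracks, qc = qc)
}
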