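# Classical posture estimation: morphological skeleton pruned to its
# longest path stands in for the learned posture network, and a
# momentum-plus-flip-penalty rule stands in for its temporal recurrence.

shift_mat <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  out <- matrix(0L, n, p)
  rs <- max(1, 1 + dr):min(n, n + dr)
  cs <- max(1, 1 + dc):min(p, p + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Zhang-Suen thinning of a logical matrix (TRUE = foreground).
thin_mask <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north (row+1 is "up" here; the
      # labelling is immaterial to the algorithm's symmetry)
      p2 <- shift_mat(m, -1, 0); p3 <- shift_mat(m, -1, 1)
      p4 <- shift_mat(m, 0, 1);  p5 <- shift_mat(m, 1, 1)
      p6 <- shift_mat(m, 1, 0);  p7 <- shift_mat(m, 1, -1)
      p8 <- shift_mat(m, 0, -1); p9 <- shift_mat(m, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & b >= 2 & b <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Longest geodesic path through a skeleton pixel set (two-sweep BFS),
# returned as an ordered 2-column matrix of 0-based pixel coordinates.
skeleton_longest_path <- function(xs, ys) {
  m <- length(xs)
  if (m == 1L) return(cbind(xs, ys))
  W <- max(xs) + 2L
  key <- xs + ys * W
  neigh <- function(i) {
    ks <- key[i] + c(1L, -1L, W, -W, W + 1L, W - 1L, -W + 1L, -W - 1L)
    j <- match(ks, key)
    j[!is.na(j)]
  }
  bfs <- function(src) {
    dist <- rep(NA_integer_, m); par <- rep(NA_integer_, m)
    dist[src] <- 0L
    q <- src
    while (length(q)) {
      i <- q[1]; q <- q[-1]
      for (j in neigh(i)) {
        if (is.na(dist[j])) {
          dist[j] <- dist[i] + 1L; par[j] <- i; q <- c(q, j)
        }
      }
    }
    list(dist = dist, par = par)
  }
  b1 <- bfs(1L)
  u <- which.max(b1$dist)
  b2 <- bfs(u)
  v <- which.max(b2$dist)
  path <- v
  while (!is.na(b2$par[path[1]])) path <- c(b2$par[path[1]], path)
  cbind(xs[path], ys[path])
}

# Extend both path termini outward along the local path direction while
# still inside the mask (recovers body tips eroded by thinning).
extend_path_tips <- function(path, mask, max_ext = 4, step = 0.5) {
  np <- nrow(path)
  if (np < 3L) return(path)
  in_mask <- function(p) {
    r <- floor(p[2]) + 1L; cc <- floor(p[1]) + 1L
    r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) && mask[r, cc]
  }
  ext_one <- function(end, dir) {
    dir <- dir / sqrt(sum(dir^2))
    best <- end
    for (s in seq(step, max_ext, by = step)) {
      p <- end + s * dir
      if (!in_mask(p)) break
      best <- p
    }
    best
  }
  k <- min(3L, np - 1L)
  p1 <- ext_one(path[1, ], path[1, ] - path[1 + k, ])
  p2 <- ext_one(path[np, ], path[np, ] - path[np - k, ])
  rbind(p1, path, p2)
}

# Resample a polyline to n points with the central point anchored at the
# maximum-deviation point from the end-to-end chord (the bend apex), each
# side at equal arc-length spacing.
resample_anchored <- function(path, n = 11L) {
  np <- nrow(path)
  if (np < 3L) return(resample_polyline(path, n))
  a <- path[1, ]; b <- path[np, ]
  ab <- b - a
  nab <- sqrt(sum(ab^2))
  if (nab == 0) return(resample_polyline(path, n))
  dev <- abs((path[, 1] - a[1]) * ab[2] - (path[, 2] - a[2]) * ab[1]) / nab
  apex <- which.max(dev)
  half <- (n + 1L) %/% 2L
  # near-straight bodies have no real apex; pixel jaggies would inject a
  # spurious bend, so fall back to plain arc-length resampling
  if (apex == 1L || apex == np || dev[apex] < 1.5)
    return(resample_polyline(path, n))
  h1 <- resample_polyline(path[1:apex, , drop = FALSE], half)
  h2 <- resample_polyline(path[apex:np, , drop = FALSE], half)
  rbind(h1, h2[-1, , drop = FALSE])
}

# Resample an ordered polyline to n points at equal arc-length spacing.
resample_polyline <- function(pts, n = 11L) {
  if (nrow(pts) == 1L) return(pts[rep(1, n), , drop = FALSE])
  seg <- sqrt(diff(pts[, 1])^2 + diff(pts[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts[rep(1, n), , drop = FALSE])
  tgt <- seq(0, total, length.out = n)
  cbind(stats::approx(s, pts[, 1], tgt, ties = "ordered")$y,
        stats::approx(s, pts[, 2], tgt, ties = "ordered")$y)
}

#' Extract the body midline from a crop
#'
#' Skeletonizes the thresholded crop (Zhang-Suen thinning), prunes the
#' skeleton to its longest geodesic path, and resamples it to a fixed
#' number of points. The path's termini are the two candidate endpoints;
#' which is head and which is tail is decided later by
#' [assign_head_tail()].
#'
#' @param crop numeric matrix (`[row, col]` = `[y + 1, x + 1]`, as from
#'   [extract_crops()]), or a logical mask.
#' @param threshold foreground threshold for numeric crops (default 128).
#' @param n_points number of midline points (default 11).
#' @param min_px components smaller than this are declared invalid
#'   (default 8).
#' @return list with `valid`; when valid also `midline` (n x 2 matrix of
#'   continuous pixel coordinates `x, y` in crop frame, 0-based pixel
#'   centres), `end1`, `end2` (the two termini).
#' @export
extract_midline <- function(crop, threshold = 128, n_points = 11L,
                            min_px = 8L) {
  mask <- if (is.logical(crop)) crop else crop > threshold
  if (sum(mask) < min_px) return(list(valid = FALSE))
  idx <- which(mask, arr.ind = TRUE)
  xs0 <- idx[, 2] - 1L; ys0 <- idx[, 1] - 1L
  # keep the largest connected component only
  d <- detect_blobs(cbind(x_px = xs0, y_px = ys0, value = 255),
                    threshold = 0, min_area = 1, max_area = Inf)
  if (nrow(d) == 0L) return(list(valid = FALSE))
  big <- which.max(d$area)
  px <- attr(d, "pixels")[[big]]
  if (nrow(px) < min_px) return(list(valid = FALSE))
  sub <- matrix(FALSE, nrow(mask), ncol(mask))
  sub[cbind(px[, 2] + 1L, px[, 1] + 1L)] <- TRUE
  sk <- thin_mask(sub)
  ski <- which(sk, arr.ind = TRUE)
  if (nrow(ski) == 0L) return(list(valid = FALSE))
  path <- skeleton_longest_path(ski[, 2] - 1L, ski[, 1] - 1L) + 0.5
  path <- extend_path_tips(path, sub)
  # anchor the central midline point at the bend apex (the path point
  # farthest from the end-to-end chord): thinning erodes the two arms
  # unevenly, so the arc-length midpoint can miss the apex
  ml <- resample_anchored(path, n_points)
  colnames(ml) <- c("x", "y")
  list(valid = TRUE, midline = ml,
       end1 = ml[1, ], end2 = ml[n_points, ])
}

#' Body bend angle of a midline
#'
#' The angle between the chord from the midline midpoint to the head end
#' and the chord from the midpoint to the tail end, reported as 180 degrees
#' minus the interior angle, so a straight body scores 0 and a body folded
#' back on itself approaches 180.
#'
#' @param midline n x 2 matrix of ordered midline points (n >= 3), any
#'   units; the measure is invariant to rigid motion and scale.
#' @return bend angle in degrees in `[0, 180]`; `NA` for degenerate input.
#' @examples
#' bend_angle(cbind(c(0, 1, 2), c(0, 0, 0)))  # 0
#' bend_angle(cbind(c(0, 1, 1), c(0, 0, 1)))  # 90
#' @export
bend_angle <- function(midline) {
  n <- nrow(midline)
  if (is.null(n) || n < 3L) return(NA_real_)
  mid <- midline[(n + 1L) %/% 2L, ]
  v1 <- midline[1L, ] - mid
  v2 <- midline[n, ] - mid
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) return(NA_real_)
  interior <- rad2deg(acos(pmin(pmax(sum(v1 * v2) / (n1 * n2), -1), 1)))
  180 - interior
}

#' Assign head and tail with momentum and a flip penalty
#'
#' Per frame, orientation is chosen to maximize the projection of the
#' head-minus-tail vector onto the (smoothed) centroid velocity, minus a
#' penalty whenever the orientation differs from the previous frame. When
#' speed is below `v_min` the motion term is zero and the previous
#' orientation is retained. Frames before the first informative frame are
#' back-filled with the first decided orientation. Decisions are
#' deterministic given the same series.
#'
#' @param end1,end2 n x 2 matrices: the two midline termini per frame
#'   (arbitrary per-frame labelling; `NA` rows mark invalid postures).
#' @param velocity n x 2 matrix of centroid velocity (same spatial units
#'   per second).
#' @param flip_penalty switch cost; `NULL` (default) sets it to 3x the
#'   median per-frame motion-evidence magnitude of the series.
#' @param v_min speed floor below which motion evidence is ignored
#'   (default 0.05, in the velocity's units).
#' @return list with `orientation` (+1 = `end1` is head, -1 = `end2`;
#'   `NA` where posture invalid), `head`, `tail` (n x 2 matrices),
#'   `n_flips`, and the `flip_penalty` used.
#' @export
assign_head_tail <- function(end1, end2, velocity, flip_penalty = NULL,
                             v_min = 0.05) {
  n <- nrow(end1)
  axis <- end1 - end2
  speed <- sqrt(rowSums(velocity^2))
  evid <- rowSums(axis * velocity)        # projection onto velocity
  evid[!is.finite(evid)] <- 0
  evid[speed < v_min] <- 0
  valid <- !is.na(axis[, 1])
  if (is.null(flip_penalty)) {
    mag <- abs(evid[valid & evid != 0])
    flip_penalty <- if (length(mag)) 3 * stats::median(mag) else 1
  }
  o <- rep(NA_integer_, n)
  prev <- NA_integer_
  for (i in seq_len(n)) {
    if (!valid[i]) next
    if (is.na(prev)) {
      if (evid[i] != 0) { o[i] <- if (evid[i] > 0) 1L else -1L; prev <- o[i] }
      # else deferred; back-filled below
    } else {
      # score(+1) = evid - pen*[prev != +1]; score(-1) = -evid - pen*[prev != -1]
      s_keep <- prev * evid[i]
      s_flip <- -prev * evid[i] - flip_penalty
      o[i] <- if (s_flip > s_keep) -prev else prev
      prev <- o[i]
    }
  }
  first <- which(!is.na(o))[1]
  if (!is.na(first) && first > 1L) {
    fill <- seq_len(first - 1L)
    o[fill[valid[fill]]] <- o[first]
  }
  head <- tail <- matrix(NA_real_, n, 2)
  pos <- which(!is.na(o) & o == 1L)
  neg <- which(!is.na(o) & o == -1L)
  head[pos, ] <- end1[pos, ]; tail[pos, ] <- end2[pos, ]
  head[neg, ] <- end2[neg, ]; tail[neg, ] <- end1[neg, ]
  oo <- o[!is.na(o)]
  list(orientation = o, head = head, tail = tail,
       n_flips = if (length(oo) > 1L) sum(diff(oo) != 0L) else 0L,
       flip_penalty = flip_penalty)
}

#' Posture-annotate a tracked animal
#'
#' Runs [extract_midline()] on every crop, converts midlines to arena
#' millimetres, assigns head/tail via centroid momentum, and appends the
#' posture columns to the track.
#'
#' @param track single-animal track (`frame, x_mm, y_mm, x_px, y_px,
#'   detected`).
#' @param crops named crop list from [extract_crops()].
#' @param pixel_scale_mm mm per pixel.
#' @param frame_rate_hz frames per second (for the velocity estimate).
#' @param smooth_window frames of boxcar smoothing for the velocity
#'   (default 11).
#' @param flip_penalty,v_min passed to [assign_head_tail()].
#' @return the track with columns `head_x_mm, head_y_mm, tail_x_mm,
#'   tail_y_mm, bend_deg, posture_valid` appended, plus attribute
#'   `n_flips`.
#' @export
posture_track <- function(track, crops, pixel_scale_mm, frame_rate_hz = 10,
                          smooth_window = 11L, flip_penalty = NULL,
                          v_min = 0.05) {
  n <- nrow(track)
  e1 <- e2 <- matrix(NA_real_, n, 2)
  bend <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    cr <- crops[[as.character(track$frame[i])]]
    if (is.null(cr)) next
    ml <- extract_midline(cr)
    if (!ml$valid) next
    org <- attr(cr, "origin")
    e1[i, ] <- (ml$end1 + org) * pixel_scale_mm
    e2[i, ] <- (ml$end2 + org) * pixel_scale_mm
    bend[i] <- bend_angle(ml$midline)
  }
  dtv <- 1 / frame_rate_hz
  vx <- central_diff(boxcar(track$x_mm, smooth_window), dtv)
  vy <- central_diff(boxcar(track$y_mm, smooth_window), dtv)
  ht <- assign_head_tail(e1, e2, cbind(vx, vy), flip_penalty, v_min)
  track$head_x_mm <- ht$head[, 1]; track$head_y_mm <- ht$head[, 2]
  track$tail_x_mm <- ht$tail[, 1]; track$tail_y_mm <- ht$tail[, 2]
  track$bend_deg <- bend
  track$posture_valid <- !is.na(ht$orientation)
  attr(track, "n_flips") <- ht$n_flips
  track
}
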