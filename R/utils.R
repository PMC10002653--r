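# Angle and small numeric helpers shared across the pipeline.
# Convention: headings in degrees, y-up, counter-clockwise positive, 0 = +x.

#' Wrap angles into (-180, 180]
#'
#' @param a numeric vector of angles in degrees.
#' @return angles wrapped to the half-open interval (-180, 180].
#' @examples
#' wrap180(c(190, -190, 180, -180, 540))
#' @export
wrap180 <- function(a) {
  r <- ((a + 180) %% 360) - 180
  r[r == -180] <- 180
  r
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Circular mean of angles in degrees
#'
#' @param a angles in degrees; `NA` values are dropped.
#' @return mean direction in degrees, in (-180, 180]; `NA` if no data.
#' @export
circ_mean_deg <- function(a) {
  a <- a[!is.na(a)]
  if (length(a) == 0L) return(NA_real_)
  wrap180(rad2deg(atan2(mean(sin(deg2rad(a))), mean(cos(deg2rad(a))))))
}

# Unwrap a heading series (degrees) so consecutive differences are in
# (-180, 180]; makes linear smoothing of headings meaningful.
unwrap_deg <- function(h) {
  if (length(h) < 2L) return(h)
  d <- wrap180(diff(h))
  h[1] + c(0, cumsum(d))
}

# Centered boxcar smoothing with edge replication. Symmetric, so a
# time-reversed input gives exactly the time-reversed output.
boxcar <- function(x, window) {
  window <- as.integer(window)
  if (window <= 1L) return(x)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  n <- length(x)
  xp <- c(rep(x[1], half), x, rep(x[n], half))
  cs <- c(0, cumsum(xp))
  (cs[(window + 1L):(n + window)] - cs[1:n]) / window
}

# Central difference with replicated ends (d[1] and d[n] use one-sided
# two-point stencils that are mirror images of each other).
central_diff <- function(x, dt = 1) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Deterministic 32-bit FNV-1a hash of a character scalar, for config
# provenance stamps. Returned as 8 hex digits.
fnv1a_hash <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  # 32-bit arithmetic via split multiply (doubles are exact below 2^53)
  h <- 2166136261
  for (b in bytes) {
    h <- floor(h) %% 2^32
    # XOR on 16-bit halves to stay in exact-double range
    lo <- bitwXor(as.integer(h %% 65536), b)
    hi <- as.integer(h %/% 65536)
    h <- hi * 65536 + lo
    # h * 16777619 mod 2^32, split into 16-bit limbs
    a0 <- h %% 65536; a1 <- h %/% 65536
    m <- 16777619
    p0 <- a0 * (m %% 65536)
    p1 <- (a0 * (m %/% 65536) + a1 * (m %% 65536)) %% 65536
    h <- (p0 + p1 * 65536) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Derive a child seed (< 2^31) from a master seed and a stream index.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483629)
}

# Save/restore .Random.seed around a block so library code does not
# perturb the caller's RNG stream.
with_preserved_rng <- function(expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
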