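# Internal numerical helpers. World coordinates are cm; world = (index-1) *
# voxelSize for R's 1-based arrays (0-based convention in the user docs).

# Wrap phase into [-pi, pi).
wrapPhase <- function(phi) {
  ((phi + pi) %% (2 * pi)) - pi
}

# Trilinear interpolation of a 3-D array at world points (n x 3 matrix, cm).
# Points outside the grid return NA.
trilinear <- function(arr, pts, voxelSize) {
  d <- dim(arr)
  g <- pts / voxelSize + 1 # continuous 1-based index
  out <- rep(NA_real_, nrow(pts))
  ok <- g[, 1] >= 1 & g[, 1] <= d[1] &
    g[, 2] >= 1 & g[, 2] <= d[2] &
    g[, 3] >= 1 & g[, 3] <= d[3]
  if (!any(ok)) return(out)
  g <- g[ok, , drop = FALSE]
  i0 <- pmin(floor(g[, 1]), d[1] - 1L); fx <- g[, 1] - i0
  j0 <- pmin(floor(g[, 2]), d[2] - 1L); fy <- g[, 2] - j0
  k0 <- pmin(floor(g[, 3]), d[3] - 1L); fz <- g[, 3] - k0
  n12 <- d[1] * d[2]
  base <- (i0 - 1) + (j0 - 1) * d[1] + (k0 - 1) * n12 + 1
  v000 <- arr[base]
  v100 <- arr[base + 1]
  v010 <- arr[base + d[1]]
  v110 <- arr[base + d[1] + 1]
  v001 <- arr[base + n12]
  v101 <- arr[base + n12 + 1]
  v011 <- arr[base + n12 + d[1]]
  v111 <- arr[base + n12 + d[1] + 1]
  out[ok] <-
    v000 * (1 - fx) * (1 - fy) * (1 - fz) +
    v100 * fx * (1 - fy) * (1 - fz) +
    v010 * (1 - fx) * fy * (1 - fz) +
    v110 * fx * fy * (1 - fz) +
    v001 * (1 - fx) * (1 - fy) * fz +
    v101 * fx * (1 - fy) * fz +
    v011 * (1 - fx) * fy * fz +
    v111 * fx * fy * fz
  out
}

# 3x3x3 box mean of a 3-D array (borders use available voxels).
boxSmooth3 <- function(arr) {
  d <- dim(arr)
  acc <- array(0, d)
  cnt <- array(0, d)
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    xs <- max(1, 1 + di):min(d[1], d[1] + di)
    ys <- max(1, 1 + dj):min(d[2], d[2] + dj)
    zs <- max(1, 1 + dk):min(d[3], d[3] + dk)
    xd <- xs - di; yd <- ys - dj; zd <- zs - dk
    acc[xd, yd, zd] <- acc[xd, yd, zd] + arr[xs, ys, zs]
    cnt[xd, yd, zd] <- cnt[xd, yd, zd] + 1
  }
  acc / cnt
}

# Euclidean norm over the 4th (component) axis of an (nx,ny,nz,3) array.
velocityNorm <- function(vel) {
  sqrt(vel[, , , 1]^2 + vel[, , , 2]^2 + vel[, , , 3]^2)
}

# Orthonormal in-plane basis for a unit normal, deterministic.
planeBasis <- function(normal) {
  a <- c(1, 0, 0)
  if (abs(normal[1]) > 0.9) a <- c(0, 1, 0)
  e1 <- c(
    normal[2] * a[3] - normal[3] * a[2],
    normal[3] * a[1] - normal[1] * a[3],
    normal[1] * a[2] - normal[2] * a[1]
  )
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(
    normal[2] * e1[3] - normal[3] * e1[2],
    normal[3] * e1[1] - normal[1] * e1[3],
    normal[1] * e1[2] - normal[2] * e1[1]
  )
  list(e1 = e1, e2 = e2 / sqrt(sum(e2^2)))
}

# Moving-average smoothing of a numeric vector with truncated windows.
movingAverage <- function(x, window = 5L) {
  half <- window %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Velocity-encoding samples per heartbeat
#'
#' Number of repetition intervals falling within one cardiac cycle for a
#' continuously sampled acquisition: \code{round((60000 / hrBpm) / trMs)}.
#' At TR = 7.8 ms and 60 beats/min this is 128.
#'
#' @param trMs repetition time, milliseconds.
#' @param hrBpm heart rate, beats per minute.
#' @return integer sample count per heartbeat.
#' @examples
#' samplesPerBeat(7.8, 60)
#' @export
samplesPerBeat <- function(trMs, hrBpm) {
  stopifnot(trMs > 0, hrBpm > 0)
  as.integer(round((60000 / hrBpm) / trMs))
}
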