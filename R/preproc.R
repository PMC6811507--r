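# Preprocessing of decoded velocity volumes: single-wrap velocity aliasing
# correction and static-tissue background/eddy-current phase-offset removal.

#' Correct velocity aliasing (phase wraps)
#'
#' Two complementary detectors, each correcting by whole wraps of
#' \eqn{2 Venc}:
#' \enumerate{
#'   \item Voxel rule: a voxel whose velocity component differs from the
#'     median of its 26-neighborhood by more than \code{threshold} (default
#'     Venc) is shifted by \eqn{\pm 2 Venc} toward the median — this catches
#'     isolated aliased voxels.
#'   \item Region rule: connected regions bounded by wrap discontinuities
#'     (6-neighbor velocity jumps exceeding Venc) are shifted by the whole
#'     number of wraps that minimizes the mean jump across their boundary —
#'     this recovers contiguous aliased jet cores, whose interior is smooth
#'     and invisible to the voxel rule.
#' }
#' Both stages leave alias-free data untouched (idempotent).
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param threshold voxel-rule detection threshold, cm/s (default Venc).
#' @param maxPasses cap on voxel-rule passes and region-rule iterations.
#' @return the corrected \linkS4class{VelocityVolume}; the total number of
#'   corrected voxel-components is stored in
#'   \code{metadata$unwrapCorrections}.
#' @export
unwrapVelocity <- function(vol, threshold = venc(vol), maxPasses = 6L) {
  stopifnot(venc(vol) > 0)
  vel <- vol@velocity
  d <- dim(vel)[1:3]
  twoV <- 2 * venc(vol)
  total <- 0L
  # stage 1: region rule for contiguous aliased cores
  for (c in 1:3) {
    for (iter in seq_len(maxPasses)) {
      comp <- vel[, , , c]
      lab <- array(.wrapRegions(as.numeric(comp), d, venc(vol)), d)
      nreg <- max(lab)
      if (nreg == 1L) break
      sizes <- tabulate(lab, nreg)
      main <- which.max(sizes)
      changed <- FALSE
      for (r in setdiff(order(sizes, decreasing = TRUE), main)) {
        jump <- regionBoundaryJump(comp, lab, r)
        if (is.na(jump)) next
        k <- round(jump / twoV)
        if (k == 0 || abs(jump - twoV * k) > venc(vol) / 2) next
        comp[lab == r] <- comp[lab == r] + twoV * k
        total <- total + sizes[r]
        changed <- TRUE
      }
      if (!changed) break
      vel[, , , c] <- comp
    }
  }
  # stage 2: neighborhood-median rule for isolated aliased voxels
  for (pass in seq_len(maxPasses)) {
    changed <- 0L
    for (c in 1:3) {
      comp <- vel[, , , c]
      med <- array(.nbhdMedian3d(as.numeric(comp), d), d)
      bad <- abs(comp - med) > threshold
      if (any(bad)) {
        comp[bad] <- comp[bad] + twoV * sign(med[bad] - comp[bad])
        vel[, , , c] <- comp
        changed <- changed + sum(bad)
      }
    }
    total <- total + changed
    if (changed == 0L) break
  }
  out <- vol
  out@velocity <- vel
  out@metadata$unwrapCorrections <- total
  out
}

# Mean velocity jump (outside minus inside) across the boundary of region r
# in a region-labeled component volume, over 6-neighbor pairs.
regionBoundaryJump <- function(comp, lab, r) {
  d <- dim(comp)
  total <- 0
  count <- 0
  for (ax in 1:3) {
    idxA <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
    idxB <- idxA
    idxA[[ax]] <- idxA[[ax]][-d[ax]]
    idxB[[ax]] <- idxB[[ax]][-1]
    a <- do.call(`[`, c(list(comp), idxA))
    b <- do.call(`[`, c(list(comp), idxB))
    la <- do.call(`[`, c(list(lab), idxA))
    lb <- do.call(`[`, c(list(lab), idxB))
    sel <- la == r & lb != r
    if (any(sel)) {
      total <- total + sum(b[sel] - a[sel])
      count <- count + sum(sel)
    }
    sel <- lb == r & la != r
    if (any(sel)) {
      total <- total + sum(a[sel] - b[sel])
      count <- count + sum(sel)
    }
  }
  if (count == 0) return(NA_real_)
  total / count
}

#' Detect static tissue
#'
#' Static-tissue voxels have signal magnitude at or above a configurable
#' percentile of the magnitude image and a (locally box-smoothed) velocity
#' norm below a configurable fraction of Venc; voxels of a supplied vessel
#' mask are excluded.
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param magPercentile magnitude percentile cut (default 0.05).
#' @param velFraction velocity cut as a fraction of Venc (default 0.05).
#' @param vesselMask optional logical array of segmented vessels to exclude.
#' @param smooth box-smooth the velocity norm over 3^3 voxels before
#'   thresholding (stabilizes the cut under noise; default TRUE).
#' @return logical array mask.
#' @export
detectStaticTissue <- function(vol, magPercentile = 0.05,
                               velFraction = 0.05, vesselMask = NULL,
                               smooth = TRUE) {
  mag <- vol@magnitude
  vn <- if (smooth) {
    # smooth each component before taking the norm: zero-mean noise then
    # averages out instead of rectifying into the norm
    sqrt(boxSmooth3(vol@velocity[, , , 1])^2 +
      boxSmooth3(vol@velocity[, , , 2])^2 +
      boxSmooth3(vol@velocity[, , , 3])^2)
  } else {
    velocityNorm(vol@velocity)
  }
  mask <- mag >= quantile(mag, magPercentile) &
    vn < velFraction * venc(vol)
  if (!is.null(vesselMask)) mask <- mask & !vesselMask
  if (!any(mask)) {
    stop(
      "static-tissue mask is empty; raise velFraction or lower ",
      "magPercentile"
    )
  }
  mask
}

backgroundTerms <- function(order) {
  if (order == 1) {
    c("1", "x", "y", "z")
  } else {
    c("1", "x", "y", "z", "x2", "y2", "z2", "xy", "xz", "yz")
  }
}

backgroundDesign <- function(x, y, z, order) {
  X <- cbind(1, x, y, z)
  if (order >= 2) X <- cbind(X, x^2, y^2, z^2, x * y, x * z, y * z)
  X
}

#' Fit and remove background phase offsets
#'
#' Per velocity axis, a low-order 3-D polynomial (default order 1: constant
#' plus linear terms, matching eddy-current phenomenology) is fitted by
#' least squares to the static-tissue velocities and subtracted everywhere.
#' Coefficients are reported in decoded-velocity units (cm/s; linear terms
#' cm/s per cm).
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param mask logical static-tissue mask (non-empty).
#' @param order polynomial order, 1 (default) or 2.
#' @param maxFitVoxels cap on fit voxels (an evenly spaced subset is used
#'   beyond it).
#' @return list with elements \code{volume} (corrected
#'   \linkS4class{VelocityVolume}) and \code{model}
#'   (\linkS4class{BackgroundModel}).
#' @export
correctBackgroundPhase <- function(vol, mask, order = 1L,
                                   maxFitVoxels = 50000L) {
  if (!any(mask)) stop("static-tissue mask is empty")
  order <- as.integer(order)
  stopifnot(order %in% c(1L, 2L))
  d <- dim(vol@magnitude)
  h <- vol@voxelSize
  idx <- which(mask)
  if (length(idx) > maxFitVoxels) {
    idx <- idx[seq(1L, length(idx), length.out = maxFitVoxels)]
  }
  k <- arrayInd(idx, d)
  x <- (k[, 1] - 1) * h
  y <- (k[, 2] - 1) * h
  z <- (k[, 3] - 1) * h
  X <- backgroundDesign(x, y, z, order)
  nterms <- ncol(X)

  # full-grid coordinates for subtraction
  gx <- (seq_len(d[1]) - 1) * h
  gy <- (seq_len(d[2]) - 1) * h
  gz <- (seq_len(d[3]) - 1) * h
  GX <- array(rep(gx, times = d[2] * d[3]), d)
  GY <- array(rep(rep(gy, each = d[1]), times = d[3]), d)
  GZ <- array(rep(gz, each = d[1] * d[2]), d)

  coefs <- matrix(NA_real_, nterms, 3)
  rms <- numeric(3)
  vel <- vol@velocity
  for (c in 1:3) {
    comp <- vel[, , , c]
    fit <- lm.fit(X, comp[idx])
    if (fit$rank < nterms || anyNA(fit$coefficients)) {
      stop(
        "background fit is rank-deficient (static mask is degenerate, ",
        "e.g. coplanar voxels)"
      )
    }
    b <- fit$coefficients
    coefs[, c] <- b
    rms[c] <- sqrt(mean(fit$residuals^2))
    trend <- b[1] + b[2] * GX + b[3] * GY + b[4] * GZ
    if (order >= 2) {
      trend <- trend + b[5] * GX^2 + b[6] * GY^2 + b[7] * GZ^2 +
        b[8] * GX * GY + b[9] * GX * GZ + b[10] * GY * GZ
    }
    vel[, , , c] <- comp - trend
  }
  out <- vol
  out@velocity <- vel
  out@metadata$backgroundCorrected <- TRUE
  model <- new("BackgroundModel",
    coefficients = coefs, terms = backgroundTerms(order),
    residualRMS = rms, nMask = length(idx), order = order
  )
  list(volume = out, model = model)
}

#' Standard preprocessing chain
#'
#' Aliasing correction followed by static-tissue detection and background
#' phase-offset removal.
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param bgOrder background polynomial order.
#' @param ... passed to \code{\link{detectStaticTissue}}.
#' @return list(volume, model, staticMask, unwrapCorrections).
#' @export
preprocessVolume <- function(vol, bgOrder = 1L, ...) {
  vol <- unwrapVelocity(vol)
  mask <- detectStaticTissue(vol, ...)
  bg <- correctBackgroundPhase(vol, mask, order = bgOrder)
  list(
    volume = bg$volume, model = bg$model, staticMask = mask,
    unwrapCorrections = vol@metadata$unwrapCorrections
  )
}
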