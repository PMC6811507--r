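# Synthetic 4D-flow phantom: Poiseuille tubes rendered into image space with
# partial-volume supersampling, phase-contrast encoding, complex Gaussian
# noise and smooth background phase offsets. Ground truth is analytic:
# flow = mean velocity x pi R^2 x 60, CSA = pi R^2.

#' Construct a VesselSpec
#'
#' @param label vessel label (ICA_L, ICA_R, MCA_L, MCA_R, BA or custom).
#' @param centerline n x 3 matrix of polyline control points, world cm.
#' @param radius lumen radius, cm.
#' @param meanVelocity cross-section mean velocity, cm/s; a scalar for
#'   steady flow or one value per cardiac phase.
#' @return a \linkS4class{VesselSpec}.
#' @examples
#' vesselSpec("BA", rbind(c(0.5, 0.5, 0.2), c(0.5, 0.5, 1.6)), 0.15, 30)
#' @export
vesselSpec <- function(label, centerline, radius, meanVelocity) {
  new("VesselSpec",
    label = as.character(label),
    centerline = as.matrix(centerline),
    radius = as.numeric(radius),
    meanVelocity = as.numeric(meanVelocity)
  )
}

#' Construct an AcquisitionSpec
#'
#' @param voxelSize isotropic voxel size, cm.
#' @param gridShape integer triple of grid dimensions.
#' @param venc velocity encoding, cm/s (default 80).
#' @param nCardiacPhases number of cardiac phases (default 1, steady).
#' @param snr magnitude signal-to-noise ratio (Inf = noise-free).
#' @param backgroundPhaseCoeffs 4 x 3 matrix of per-axis background phase
#'   polynomial coefficients (constant radians, then radians/cm along x, y,
#'   z); default all zero.
#' @param supersampling subsamples per voxel edge for partial-volume
#'   rendering (default 4).
#' @param tissueMagnitude static-tissue signal magnitude, vessel = 1
#'   (default 0.3).
#' @param pulsatility sinusoidal cardiac modulation amplitude (default 0).
#' @return an \linkS4class{AcquisitionSpec}.
#' @examples
#' acquisitionSpec(0.03, c(36, 36, 48))
#' @export
acquisitionSpec <- function(voxelSize, gridShape, venc = 80,
                            nCardiacPhases = 1L, snr = Inf,
                            backgroundPhaseCoeffs = matrix(0, 4, 3),
                            supersampling = 4L, tissueMagnitude = 0.3,
                            pulsatility = 0) {
  new("AcquisitionSpec",
    voxelSize = as.numeric(voxelSize),
    gridShape = as.integer(gridShape),
    venc = as.numeric(venc),
    nCardiacPhases = as.integer(nCardiacPhases),
    snr = as.numeric(snr),
    backgroundPhaseCoeffs = backgroundPhaseCoeffs,
    supersampling = as.integer(supersampling),
    tissueMagnitude = as.numeric(tissueMagnitude),
    pulsatility = as.numeric(pulsatility)
  )
}

#' Construct a StudySpec
#'
#' Defaults encode the young-adult hypercapnia protocol: conditions
#' normocapnia / 4\% CO2 / 6\% CO2 with ETCO2 40 / 47 / 49 mmHg, MAP
#' 94 / 93 / 96 mmHg, HR 53 / 56 / 58 bpm, SpO2 98\%; normocapnic global
#' flow 640 mL/min split 37.5\% per ICA and 25\% BA with each MCA carrying
#' 23.44\% of global flow; programmed global CVR slope 5 CVC-units/mmHg;
#' 4.35\% MCA CSA dilation at 6\% CO2 (0.069 to 0.072 cm2); brain volume
#' 1.20 l.
#'
#' @param conditions data.frame(condition, etco2, map, hr, spo2).
#' @param trueSlope programmed global CVR slope, CVC-units per mmHg.
#' @param globalFlowNormo normocapnic global flow, mL/min.
#' @param flowFractions named per-vessel fractions of global flow.
#' @param mcaDilationFraction relative MCA CSA increase at the top
#'   condition.
#' @param brainVolume GM + WM volume, liters.
#' @param subjects number of subjects.
#' @param seed base seed.
#' @return a \linkS4class{StudySpec}.
#' @examples
#' studySpec(trueSlope = 5)
#' @export
studySpec <- function(conditions = data.frame(
                        condition = c("normocapnia", "co2_4pct", "co2_6pct"),
                        etco2 = c(40, 47, 49),
                        map = c(94, 93, 96),
                        hr = c(53, 56, 58),
                        spo2 = c(98, 98, 98)
                      ),
                      trueSlope = 5, globalFlowNormo = 640,
                      flowFractions = c(
                        ICA_L = 0.375, ICA_R = 0.375, BA = 0.25,
                        MCA_L = 0.2344, MCA_R = 0.2344
                      ),
                      mcaDilationFraction = 0.072 / 0.069 - 1,
                      brainVolume = 1.20, subjects = 1L, seed = 1L) {
  new("StudySpec",
    conditions = conditions, trueSlope = as.numeric(trueSlope),
    globalFlowNormo = as.numeric(globalFlowNormo),
    flowFractions = flowFractions,
    mcaDilationFraction = as.numeric(mcaDilationFraction),
    brainVolume = as.numeric(brainVolume),
    subjects = as.integer(subjects), seed = as.integer(seed)
  )
}

# Closest point on a polyline: returns per-point squared distance and the
# direction of the nearest segment. pts is an n x 3 matrix.
polylineDistance <- function(pts, centerline) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  tang <- matrix(0, n, 3)
  for (s in seq_len(nrow(centerline) - 1)) {
    a <- centerline[s, ]
    d <- centerline[s + 1, ] - a
    L2 <- sum(d^2)
    t <- ((pts[, 1] - a[1]) * d[1] + (pts[, 2] - a[2]) * d[2] +
      (pts[, 3] - a[3]) * d[3]) / L2
    t <- pmin(pmax(t, 0), 1)
    dx <- pts[, 1] - (a[1] + t * d[1])
    dy <- pts[, 2] - (a[2] + t * d[2])
    dz <- pts[, 3] - (a[3] + t * d[3])
    d2 <- dx * dx + dy * dy + dz * dz
    upd <- d2 < best
    if (any(upd)) {
      best[upd] <- d2[upd]
      u <- d / sqrt(L2)
      tang[upd, 1] <- u[1]
      tang[upd, 2] <- u[2]
      tang[upd, 3] <- u[3]
    }
  }
  list(dist2 = best, tangent = tang)
}

# Render one vessel's unit-mean-velocity field over its bounding box with
# supersampled partial volume. Returns bbox index ranges, the inside
# fraction and the velocity components for mean velocity 1 (scale by vbar).
# Cached per geometry: fields are linear in the mean velocity.
.fieldCache <- new.env(parent = emptyenv())

vesselUnitField <- function(vessel, acq, cache = TRUE) {
  h <- acq@voxelSize
  dims <- acq@gridShape
  s <- acq@supersampling
  key <- paste(
    vessel@label, vessel@radius, h, paste(dims, collapse = ","), s,
    paste(signif(vessel@centerline, 10), collapse = ","),
    sep = "|"
  )
  if (cache && !is.null(.fieldCache[[key]])) return(.fieldCache[[key]])

  R <- vessel@radius
  cl <- vessel@centerline
  lo <- pmax(1L, floor((apply(cl, 2, min) - R - h) / h) + 1L)
  hi <- pmin(dims, ceiling((apply(cl, 2, max) + R + h) / h) + 1L)
  nb <- hi - lo + 1L
  centers <- list(
    (seq(lo[1], hi[1]) - 1) * h,
    (seq(lo[2], hi[2]) - 1) * h,
    (seq(lo[3], hi[3]) - 1) * h
  )
  nvox <- prod(nb)
  grid <- cbind(
    rep(centers[[1]], times = nb[2] * nb[3]),
    rep(rep(centers[[2]], each = nb[1]), times = nb[3]),
    rep(centers[[3]], each = nb[1] * nb[2])
  )
  frac <- numeric(nvox)
  vel <- matrix(0, nvox, 3)
  offs <- ((2 * seq_len(s) - 1) / (2 * s) - 0.5) * h
  for (oz in offs) for (oy in offs) for (ox in offs) {
    pts <- grid
    pts[, 1] <- pts[, 1] + ox
    pts[, 2] <- pts[, 2] + oy
    pts[, 3] <- pts[, 3] + oz
    pd <- polylineDistance(pts, cl)
    inside <- pd$dist2 < R * R
    if (any(inside)) {
      w <- 2 * (1 - pd$dist2[inside] / (R * R)) # Poiseuille, vbar = 1
      frac[inside] <- frac[inside] + 1
      vel[inside, ] <- vel[inside, ] + pd$tangent[inside, , drop = FALSE] * w
    }
  }
  ns <- s^3
  out <- list(
    lo = lo, hi = hi, nb = nb,
    frac = array(frac / ns, nb),
    vel = array(vel / ns, c(nb, 3L))
  )
  if (cache) .fieldCache[[key]] <- out
  out
}

#' Render Poiseuille vessels into a velocity volume
#'
#' Builds the noise-free ground-truth velocity field: every voxel inside a
#' tube carries the Poiseuille velocity \eqn{v(r) = 2\bar v (1-(r/R)^2)}
#' directed along the local centerline tangent; partial volume is handled by
#' supersampling each voxel and averaging. The magnitude image is 1 inside
#' vessels and \code{tissueMagnitude} outside, mixed by the inside fraction.
#'
#' @param vessels list of \linkS4class{VesselSpec}; vessels may share a
#'   junction point (bifurcation) but must not otherwise overlap. Vessels
#'   must fit inside the grid (with a radius margin).
#' @param acq an \linkS4class{AcquisitionSpec}.
#' @param phase cardiac phase index (used when a vessel's
#'   \code{meanVelocity} has one entry per phase).
#' @param cache cache per-geometry unit fields (they are linear in the mean
#'   velocity).
#' @return a \linkS4class{VelocityVolume} (the analytic field, before
#'   encoding).
#' @export
buildVelocityField <- function(vessels, acq, phase = 1L, cache = TRUE) {
  dims <- acq@gridShape
  h <- acq@voxelSize
  extent <- (dims - 1) * h
  for (v in vessels) {
    cl <- v@centerline
    if (any(t(cl) - v@radius < 0) || any(t(cl) + v@radius > extent)) {
      stop(
        "vessel ", v@label,
        " exits the grid (centerline within one radius of the boundary)"
      )
    }
  }
  # shared-endpoint bookkeeping for the overlap check
  sharesEndpoint <- function(a, b) {
    ea <- rbind(a@centerline[1, ], a@centerline[nrow(a@centerline), ])
    eb <- rbind(b@centerline[1, ], b@centerline[nrow(b@centerline), ])
    for (i in 1:2) for (j in 1:2) {
      if (sqrt(sum((ea[i, ] - eb[j, ])^2)) < 1e-9) return(ea[i, ])
    }
    NULL
  }
  vel <- array(0, c(dims, 3L))
  bestFrac <- array(0, dims)
  fields <- lapply(vessels, vesselUnitField, acq = acq, cache = cache)
  for (vi in seq_along(vessels)) {
    v <- vessels[[vi]]
    vbar <- if (length(v@meanVelocity) >= phase) {
      v@meanVelocity[phase]
    } else {
      v@meanVelocity[1]
    }
    f <- fields[[vi]]
    xs <- f$lo[1]:f$hi[1]
    ys <- f$lo[2]:f$hi[2]
    zs <- f$lo[3]:f$hi[3]
    sub <- bestFrac[xs, ys, zs]
    both <- f$frac > 0.5 & sub > 0.5
    if (any(both)) {
      # allowed only near a junction point shared with an earlier vessel
      jp <- NULL
      for (wj in seq_len(vi - 1)) {
        jp <- sharesEndpoint(v, vessels[[wj]])
        if (!is.null(jp)) break
      }
      if (is.null(jp)) {
        stop(
          "vessels overlap without sharing a junction point (",
          v@label, ")"
        )
      }
      w <- which(both, arr.ind = TRUE)
      wx <- (xs[w[, 1]] - 1) * h
      wy <- (ys[w[, 2]] - 1) * h
      wz <- (zs[w[, 3]] - 1) * h
      dj <- sqrt((wx - jp[1])^2 + (wy - jp[2])^2 + (wz - jp[3])^2)
      maxR <- 2 * max(v@radius, vapply(vessels, slot, numeric(1), "radius"))
      if (any(dj > maxR)) {
        stop(
          "vessels ", v@label,
          " overlap beyond the shared junction neighborhood"
        )
      }
    }
    take <- f$frac > sub
    if (any(take)) {
      sub[take] <- f$frac[take]
      bestFrac[xs, ys, zs] <- sub
      for (c in 1:3) {
        velSub <- vel[xs, ys, zs, c]
        velSub[take] <- vbar * f$vel[, , , c][take]
        vel[xs, ys, zs, c] <- velSub
      }
    }
  }
  mag <- acq@tissueMagnitude * (1 - bestFrac) + bestFrac
  new("VelocityVolume",
    velocity = vel, magnitude = mag,
    voxelSize = h, venc = acq@venc,
    metadata = list(insideFraction = bestFrac)
  )
}

#' Phase-contrast encoding
#'
#' Encodes each velocity component as a phase \eqn{\phi = \pi v / Venc},
#' wrapped into \code{[-pi, pi)}; velocities beyond Venc alias. Decoding is
#' \code{v = Venc * phi / pi}.
#'
#' @param vol a \linkS4class{VelocityVolume}.
#' @param vencValue velocity encoding, cm/s (defaults to the volume's).
#' @return an \linkS4class{EncodedVolume}.
#' @export
encodePhase <- function(vol, vencValue = venc(vol)) {
  stopifnot(vencValue > 0)
  phi <- wrapPhase(pi * vol@velocity / vencValue)
  d <- dim(vol@velocity)
  mag <- array(rep(vol@magnitude, 3L), d)
  new("EncodedVolume",
    phase = phi, magnitude = mag,
    voxelSize = vol@voxelSize, venc = vencValue
  )
}

#' Add complex Gaussian measurement noise
#'
#' Independent complex Gaussian noise (standard deviation \code{1/snr} per
#' real component, SNR defined on the unit vessel magnitude) is added to the
#' signal \eqn{S = m e^{i\phi}} of each velocity encoding; magnitude and
#' phase are recomputed from the noisy signal. Reproducible under a fixed
#' seed.
#'
#' @param enc an \linkS4class{EncodedVolume}.
#' @param snr signal-to-noise ratio; \code{Inf} returns the input unchanged.
#' @param seed integer seed.
#' @return an \linkS4class{EncodedVolume}.
#' @export
addNoise <- function(enc, snr, seed) {
  stopifnot(snr > 0)
  if (!is.finite(snr)) return(enc)
  sigma <- 1 / snr
  n <- length(enc@phase)
  withr::with_seed(as.integer(seed), {
    re <- enc@magnitude * cos(enc@phase) + rnorm(n, sd = sigma)
    im <- enc@magnitude * sin(enc@phase) + rnorm(n, sd = sigma)
  })
  new("EncodedVolume",
    phase = array(atan2(im, re), dim(enc@phase)),
    magnitude = array(sqrt(re^2 + im^2), dim(enc@phase)),
    voxelSize = enc@voxelSize, venc = enc@venc
  )
}

#' Add a spatially smooth background phase offset
#'
#' Adds \eqn{\phi_{bg}(x,y,z) = a_0 + a_1 x + a_2 y + a_3 z} (radians; x, y,
#' z world cm) to the encoded phase of each velocity axis, emulating
#' eddy-current/background offsets that the preprocessing stage removes.
#'
#' @param enc an \linkS4class{EncodedVolume}.
#' @param coeffs 4 x 3 matrix, one column per velocity axis.
#' @return an \linkS4class{EncodedVolume}.
#' @export
addBackgroundPhase <- function(enc, coeffs) {
  stopifnot(all(is.finite(coeffs)), all(dim(coeffs) == c(4, 3)))
  d <- dim(enc@phase)
  h <- enc@voxelSize
  x <- (seq_len(d[1]) - 1) * h
  y <- (seq_len(d[2]) - 1) * h
  z <- (seq_len(d[3]) - 1) * h
  X <- array(rep(x, times = d[2] * d[3]), d[1:3])
  Y <- array(rep(rep(y, each = d[1]), times = d[3]), d[1:3])
  Z <- array(rep(z, each = d[1] * d[2]), d[1:3])
  phi <- enc@phase
  for (c in 1:3) {
    bg <- coeffs[1, c] + coeffs[2, c] * X + coeffs[3, c] * Y + coeffs[4, c] * Z
    phi[, , , c] <- wrapPhase(phi[, , , c] + bg)
  }
  new("EncodedVolume",
    phase = phi, magnitude = enc@magnitude,
    voxelSize = enc@voxelSize, venc = enc@venc
  )
}

#' Decode an encoded volume to velocities
#'
#' @param enc an \linkS4class{EncodedVolume}.
#' @return a \linkS4class{VelocityVolume} with \code{v = Venc * phase / pi}
#'   and the magnitude averaged over the three encodings.
#' @export
decodeVelocity <- function(enc) {
  vel <- enc@venc * enc@phase / pi
  d <- dim(enc@phase)
  m <- array(enc@magnitude, c(prod(d[1:3]), 3))
  new("VelocityVolume",
    velocity = vel, magnitude = array(rowMeans(m), d[1:3]),
    voxelSize = enc@voxelSize, venc = enc@venc
  )
}

# Average a list of decoded volumes (cardiac phases) into one time-averaged
# volume.
timeAverageVolumes <- function(vols) {
  vel <- Reduce(`+`, lapply(vols, slot, "velocity")) / length(vols)
  mag <- Reduce(`+`, lapply(vols, slot, "magnitude")) / length(vols)
  new("VelocityVolume",
    velocity = vel, magnitude = mag,
    voxelSize = vols[[1]]@voxelSize, venc = vols[[1]]@venc
  )
}

# Full acquisition of one condition: per cardiac phase, scale the field,
# encode, add background phase and noise, decode; then time-average.
acquireVolume <- function(vessels, acq, seed) {
  np <- acq@nCardiacPhases
  base <- buildVelocityField(vessels, acq)
  scales <- if (np > 1) {
    1 + acq@pulsatility * sin(2 * pi * (seq_len(np) - 1) / np)
  } else {
    1
  }
  vols <- vector("list", np)
  for (p in seq_len(np)) {
    fld <- base
    if (scales[p] != 1) fld@velocity <- base@velocity * scales[p]
    enc <- encodePhase(fld, acq@venc)
    enc <- addBackgroundPhase(enc, acq@backgroundPhaseCoeffs)
    enc <- addNoise(enc, acq@snr, seed + p - 1L)
    vols[[p]] <- decodeVelocity(enc)
  }
  if (np == 1) vols[[1]] else timeAverageVolumes(vols)
}

# Default intracranial layout: five parallel tubes along z (two ICAs, two
# MCAs, BA) spaced so that measurement planes (side 4R) neither leave the
# grid nor cross a neighboring vessel. Calibers: MCA CSA 0.069 cm2
# (radius 0.1482 cm), ICA radius 0.20 cm, BA radius 0.16 cm.
studyVesselLayout <- function(acq, mcaRadiusScale = 1) {
  h <- acq@voxelSize
  extent <- (acq@gridShape - 1) * h
  cx <- extent[1] / 2
  cy <- extent[2] / 2
  a <- 1.08 / 2 # half side of the placement square, cm
  z0 <- 0.25
  z1 <- extent[3] - 0.25
  tube <- function(label, x, y, radius) {
    vesselSpec(label, rbind(c(x, y, z0), c(x, y, z1)), radius, 1)
  }
  rMCA <- sqrt(0.069 / pi) * mcaRadiusScale
  list(
    ICA_L = tube("ICA_L", cx - a, cy - a, 0.20),
    ICA_R = tube("ICA_R", cx + a, cy - a, 0.20),
    MCA_L = tube("MCA_L", cx - a, cy + a, rMCA),
    MCA_R = tube("MCA_R", cx + a, cy + a, rMCA),
    BA = tube("BA", cx, cy, 0.16)
  )
}

#' Default acquisition for the simulated hypercapnia study
#'
#' 60 x 60 x 48 grid at 0.036 cm isotropic (at least 8 voxels across the MCA
#' diameter), Venc 80 cm/s, SNR 20, small constant-plus-linear background
#' phase offsets.
#'
#' @param snr signal-to-noise ratio.
#' @param ... passed on to \code{\link{acquisitionSpec}}.
#' @return an \linkS4class{AcquisitionSpec}.
#' @export
studyAcquisition <- function(snr = 20, ...) {
  bg <- cbind(
    c(0.05, 0.010, -0.015, 0.008),
    c(-0.04, 0.012, 0.006, -0.010),
    c(0.03, -0.008, 0.014, 0.005)
  )
  acquisitionSpec(
    voxelSize = 0.036, gridShape = c(60L, 60L, 48L), venc = 80,
    snr = snr, backgroundPhaseCoeffs = bg, ...
  )
}

#' Simulate a hypercapnia CVR study with known truth
#'
#' For each condition, per-vessel flows are set so that the true global
#' conductance CVC = flow / MAP x 100 lies exactly on the programmed line
#' against ETCO2 (each vessel carrying a fixed fraction of global flow, so
#' per-vessel CVC lines are exact as well); the MCA radius is dilated by
#' \code{mcaDilationFraction} (in CSA) at the highest-ETCO2 condition. Each
#' condition is acquired through the phase-contrast model (encoding,
#' background phase, noise) and decoded.
#'
#' @param study a \linkS4class{StudySpec}.
#' @param acq an \linkS4class{AcquisitionSpec}
#'   (default \code{\link{studyAcquisition}()}).
#' @param seed noise seed (defaults to the study's seed). Truth is
#'   independent of the seed; only noise realizations change.
#' @return a \linkS4class{PhantomStudy} (for \code{subjects > 1}, a list of
#'   them, one per subject).
#' @export
simulateCVRStudy <- function(study, acq = studyAcquisition(),
                             seed = study@seed) {
  cond <- study@conditions
  nc <- nrow(cond)
  topCond <- which.max(cond$etco2)
  cvcNormo <- study@globalFlowNormo / cond$map[1] * 100
  intercept <- cvcNormo - study@trueSlope * cond$etco2[1]
  cvcGlobal <- intercept + study@trueSlope * cond$etco2
  flowGlobal <- cvcGlobal * cond$map / 100
  fr <- study@flowFractions

  makeSubject <- function(subjectSeed) {
    vols <- list()
    truthRows <- list()
    for (ci in seq_len(nc)) {
      scale <- if (ci == topCond) sqrt(1 + study@mcaDilationFraction) else 1
      vessels <- studyVesselLayout(acq, mcaRadiusScale = scale)
      for (lab in names(vessels)) {
        v <- vessels[[lab]]
        flow <- fr[[lab]] * flowGlobal[ci]
        area <- pi * v@radius^2
        vbar <- flow / (60 * area)
        if (vbar > acq@venc) {
          warning(
            "condition ", cond$condition[ci], ", vessel ", lab,
            ": mean velocity ", signif(vbar, 4),
            " cm/s exceeds Venc; aliasing will occur"
          )
        }
        v@meanVelocity <- vbar
        vessels[[lab]] <- v
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          vessel = lab, condition = cond$condition[ci],
          flow_ml_min = flow, csa_cm2 = area,
          mean_velocity_cm_s = vbar, radius_cm = v@radius
        )
      }
      vols[[cond$condition[ci]]] <-
        acquireVolume(vessels, acq, seed = subjectSeed + 97L * ci)
    }
    meas <- do.call(rbind, truthRows)
    gl <- data.frame(condition = cond$condition, flow_ml_min = flowGlobal)
    slopes <- rbind(
      data.frame(
        scope = "global", slope = study@trueSlope, intercept = intercept
      ),
      data.frame(
        scope = "global_bv_corrected",
        slope = study@trueSlope / study@brainVolume,
        intercept = intercept / study@brainVolume
      ),
      do.call(rbind, lapply(names(fr), function(lab) {
        data.frame(
          scope = lab, slope = fr[[lab]] * study@trueSlope,
          intercept = fr[[lab]] * intercept
        )
      }))
    )
    truth <- new("PhantomTruth",
      measurements = meas, globalFlow = gl, slopes = slopes
    )
    # seed points 15% along each tube from its low-z end
    layout0 <- studyVesselLayout(acq)
    seeds <- lapply(layout0, function(v) {
      p0 <- v@centerline[1, ]
      p1 <- v@centerline[nrow(v@centerline), ]
      p0 + 0.15 * (p1 - p0)
    })
    new("PhantomStudy",
      volumes = vols, conditions = cond, seeds = seeds, truth = truth,
      acquisition = acq, study = study
    )
  }

  if (study@subjects <= 1L) {
    makeSubject(as.integer(seed))
  } else {
    lapply(seq_len(study@subjects), function(s) {
      makeSubject(as.integer(seed) + 10007L * s)
    })
  }
}
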