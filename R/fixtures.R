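# Validation phantoms with closed-form truth: straight or oblique Poiseuille
# tubes and a Y-bifurcation. These are the workhorses of the package's
# verification suite; all return the decoded (artifact-bearing) volume
# together with the analytic ground truth.

#' Single-tube validation phantom
#'
#' One Poiseuille tube through a regular grid, optionally oblique, acquired
#' through the full phase-contrast model. Analytic truth: flow =
#' \eqn{\bar v \pi R^2 \times 60} mL/min, CSA = \eqn{\pi R^2} cm^2.
#'
#' @param radius lumen radius, cm.
#' @param meanVelocity cross-section mean velocity, cm/s.
#' @param voxelsPerDiameter grid resolution (default 10).
#' @param venc velocity encoding, cm/s (default 200: alias-free).
#' @param direction tube axis (need not be normalized; z component > 0).
#' @param length tube length, cm.
#' @param snr magnitude SNR (default Inf).
#' @param backgroundPhaseCoeffs optional 4 x 3 background phase matrix.
#' @param supersampling partial-volume supersampling factor.
#' @param seed noise seed.
#' @return list: \code{volume} (decoded \linkS4class{VelocityVolume}),
#'   \code{truthVolume} (analytic field), \code{acq}, \code{seeds} (seed
#'   point for labeling), \code{trueFlow}, \code{trueCsa}.
#' @export
tubePhantom <- function(radius, meanVelocity, voxelsPerDiameter = 10,
                        venc = 200, direction = c(0, 0, 1), length = 1.1,
                        snr = Inf, backgroundPhaseCoeffs = matrix(0, 4, 3),
                        supersampling = 4L, seed = 1L) {
  h <- 2 * radius / voxelsPerDiameter
  dirv <- direction / direction[3]
  span <- length * abs(dirv[1:2]) # in-plane extent of the axis
  n <- 2 * ceiling((0.56 + 2 * radius + span) / h / 2) + 1
  nz <- ceiling((length + 2 * radius + 0.3) / h)
  acq <- acquisitionSpec(
    voxelSize = h, gridShape = c(n[1], if (length(n) > 1) n[2] else n[1], nz),
    venc = venc, snr = snr,
    backgroundPhaseCoeffs = backgroundPhaseCoeffs,
    supersampling = supersampling
  )
  nxy <- acq@gridShape[1:2]
  ctr <- ((nxy - 1) / 2 + 0.5) * h - length * dirv[1:2] / 2
  z0 <- radius + 2 * h
  p0 <- c(ctr[1], ctr[2], z0)
  p1 <- p0 + length * dirv
  vessel <- vesselSpec("V", rbind(p0, p1), radius, meanVelocity)
  truthVolume <- buildVelocityField(list(vessel), acq)
  enc <- encodePhase(truthVolume, venc)
  enc <- addBackgroundPhase(enc, backgroundPhaseCoeffs)
  enc <- addNoise(enc, snr, seed)
  list(
    volume = decodeVelocity(enc), truthVolume = truthVolume, acq = acq,
    seeds = list(V = as.numeric(p0 + 0.2 * length * dirv)),
    trueFlow = meanVelocity * pi * radius^2 * 60,
    trueCsa = pi * radius^2
  )
}

#' Y-bifurcation validation phantom
#'
#' A parent tube splitting into two daughters at the programmed flow split;
#' truth records parent flow = sum of daughter flows (mass conservation by
#' construction).
#'
#' @param parentRadius,parentVelocity parent tube geometry/flow.
#' @param daughterRadii radii of the two daughters, cm.
#' @param flowSplit fraction of parent flow carried by the first daughter.
#' @param angle daughter half-angle from the parent axis, radians.
#' @param voxelSize grid spacing, cm.
#' @param venc velocity encoding (default 200).
#' @param snr magnitude SNR.
#' @param seed noise seed.
#' @return list: \code{volume}, \code{acq}, \code{seeds},
#'   \code{trueFlows} (named parent/dau1/dau2).
#' @export
bifurcationPhantom <- function(parentRadius = 0.20, parentVelocity = 30,
                               daughterRadii = c(0.16, 0.14),
                               flowSplit = 0.6, angle = pi / 4,
                               voxelSize = 0.033, venc = 200, snr = Inf,
                               seed = 1L) {
  Qp <- parentVelocity * pi * parentRadius^2 * 60
  Q1 <- flowSplit * Qp
  Q2 <- (1 - flowSplit) * Qp
  vb1 <- Q1 / (60 * pi * daughterRadii[1]^2)
  vb2 <- Q2 / (60 * pi * daughterRadii[2]^2)
  L <- 1.1
  h <- voxelSize
  J <- c(1.45, 0.45, 1.10)
  dirn <- function(a) c(sin(a), 0, cos(a))
  dims <- c(
    ceiling((J[1] + L * sin(angle) + 0.45) / h),
    ceiling(2 * J[2] / h),
    ceiling((J[3] + L * cos(angle) + 0.4) / h)
  )
  acq <- acquisitionSpec(h, dims, venc = venc, snr = snr)
  vessels <- list(
    vesselSpec("parent", rbind(c(J[1], J[2], 0.25), J), parentRadius,
      parentVelocity),
    vesselSpec("dau1", rbind(J, J + L * dirn(angle)), daughterRadii[1], vb1),
    vesselSpec("dau2", rbind(J, J + L * dirn(-angle)), daughterRadii[2], vb2)
  )
  vol <- buildVelocityField(vessels, acq)
  enc <- addNoise(encodePhase(vol, venc), snr, seed)
  list(
    volume = decodeVelocity(enc), acq = acq,
    seeds = list(
      parent = c(J[1], J[2], 0.45),
      dau1 = as.numeric(J + 0.35 * L * dirn(angle)),
      dau2 = as.numeric(J + 0.35 * L * dirn(-angle))
    ),
    trueFlows = c(parent = Qp, dau1 = Q1, dau2 = Q2)
  )
}
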