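# Phantom generator: analytic truth, phase encoding, noise and background
# phase artifacts.

test_that("rendered Poiseuille field carries the analytic flux", {
  b <- tubePhantom(radius = 0.15, meanVelocity = 30, voxelsPerDiameter = 10)
  expect_equal(b$trueFlow, 127.2345, tolerance = 1e-6)
  expect_equal(b$trueCsa, 0.0706858, tolerance = 1e-5)
  # Riemann sum over a mid-tube slice of the analytic field is flux-exact
  vz <- velocityData(b$truthVolume)[, , 20, 3]
  h <- voxelSize(b$truthVolume)
  expect_equal(sum(vz) * h^2 * 60, b$trueFlow, tolerance = 0.01)
  # peak velocity is 2 x mean (within partial-volume smoothing)
  expect_lt(max(vz), 2 * 30 + 1e-9)
  expect_gt(max(vz), 2 * 30 * 0.95)
})

test_that("zero mean velocity gives an all-zero field", {
  b <- tubePhantom(radius = 0.1, meanVelocity = 0, voxelsPerDiameter = 8)
  expect_true(all(velocityData(b$truthVolume) == 0))
})

test_that("vessels outside the grid or overlapping are rejected", {
  acq <- acquisitionSpec(0.03, c(20, 20, 30))
  out <- vesselSpec("A", rbind(c(0.3, 0.3, 0), c(0.3, 0.3, 0.8)), 0.1, 10)
  expect_error(buildVelocityField(list(out), acq), "exits the grid")
  a <- vesselSpec("A", rbind(c(0.27, 0.27, 0.15), c(0.27, 0.27, 0.7)), 0.1, 10)
  b <- vesselSpec("B", rbind(c(0.3, 0.3, 0.15), c(0.3, 0.3, 0.7)), 0.1, 10)
  expect_error(buildVelocityField(list(a, b), acq), "overlap")
})

test_that("vessels sharing a junction point are allowed", {
  acq <- acquisitionSpec(0.04, c(40, 20, 40))
  J <- c(0.75, 0.38, 0.75)
  par <- vesselSpec("P", rbind(c(0.75, 0.38, 0.2), J), 0.12, 20)
  d1 <- vesselSpec("D1", rbind(J, J + c(0.35, 0, 0.35)), 0.1, 18)
  expect_s4_class(buildVelocityField(list(par, d1), acq), "VelocityVolume")
})

test_that("phase encoding wraps exactly as the decode formula implies", {
  mk <- function(v) {
    new("VelocityVolume",
      velocity = array(v, c(1, 1, 1, 3)), magnitude = array(1, c(1, 1, 1)),
      voxelSize = 0.1, venc = 80
    )
  }
  dec <- function(v) velocityData(decodeVelocity(encodePhase(mk(v), 80)))[1]
  expect_equal(dec(0), 0)
  expect_equal(dec(79), 79) # below Venc: identity
  expect_equal(dec(100), -60) # 100 - 2*80
  expect_equal(dec(-100), 60)
  # phases always land in [-pi, pi)
  ph <- phaseData(encodePhase(mk(250), 80))
  expect_true(all(ph >= -pi & ph < pi))
})

test_that("noise is reproducible, absent at infinite SNR, and its decoded
          spread matches the propagation prediction", {
  vol <- new("VelocityVolume",
    velocity = array(0, c(22, 22, 22, 3)),
    magnitude = array(1, c(22, 22, 22)), voxelSize = 0.05, venc = 80
  )
  enc <- encodePhase(vol, 80)
  expect_identical(addNoise(enc, Inf, 1)@phase, enc@phase)
  n1 <- addNoise(enc, 20, seed = 7)
  n2 <- addNoise(enc, 20, seed = 7)
  expect_identical(n1@phase, n2@phase)
  n3 <- addNoise(enc, 20, seed = 8)
  expect_false(identical(n1@phase, n3@phase))
  # sigma_v = venc / (pi * snr * magnitude); > 10^4 static voxels
  v <- velocityData(decodeVelocity(n1))
  expect_equal(sd(v), 80 / (pi * 20), tolerance = 0.1)
})

test_that("background phase adds the predicted decoded velocity offset", {
  vol <- new("VelocityVolume",
    velocity = array(0, c(8, 8, 8, 3)), magnitude = array(1, c(8, 8, 8)),
    voxelSize = 0.05, venc = 80
  )
  enc <- encodePhase(vol, 80)
  expect_identical(addBackgroundPhase(enc, matrix(0, 4, 3))@phase, enc@phase)
  co <- matrix(0, 4, 3)
  co[1, 1] <- 0.1
  dec <- decodeVelocity(addBackgroundPhase(enc, co))
  shifted <- velocityData(dec)[, , , 1]
  expect_equal(mean(shifted), 80 * 0.1 / pi, tolerance = 1e-9) # 2.546 cm/s
  expect_lt(max(shifted) - min(shifted), 1e-9)
  # a linear ramp decodes to a plane with zero plane-fit residual
  co2 <- matrix(0, 4, 3)
  co2[2, 3] <- 0.05
  v <- decodeVelocity(addBackgroundPhase(enc, co2))
  mask <- array(TRUE, c(8, 8, 8))
  fit <- correctBackgroundPhase(v, mask)
  expect_lt(max(fit$model@residualRMS), 1e-10)
  expect_equal(fit$model@coefficients[2, 3], 0.05 * 80 / pi, tolerance = 1e-8)
})

test_that("study truth lies exactly on the programmed CVC line and
          conserves global flow", {
  st <- studySpec(trueSlope = 5, seed = 2L)
  ps <- simulateCVRStudy(st, acq = studyAcquisition(snr = Inf))
  tr <- studyTruth(ps)
  gf <- truthGlobalFlow(tr)
  cond <- studyConditions(ps)
  cvc <- computeCVC(gf$flow_ml_min, cond$map)
  fit <- fitCVR(data.frame(etco2 = cond$etco2, cvc = cvc))
  expect_equal(fit@slope, 5, tolerance = 1e-12)
  # conservation: global = ICA_L + ICA_R + BA, exactly, per condition
  m <- truthMeasurements(tr)
  for (cc in cond$condition) {
    sub <- m[m$condition == cc, ]
    expect_equal(
      globalFlow(sub[, c("vessel", "flow_ml_min")]),
      gf$flow_ml_min[gf$condition == cc]
    )
  }
  # MCA CSA dilates from 0.069 to 0.072 cm^2 at the top condition
  mca <- m[m$vessel == "MCA_L", ]
  expect_equal(mca$csa_cm2[mca$condition == "normocapnia"], 0.069,
    tolerance = 1e-6
  )
  expect_equal(mca$csa_cm2[mca$condition == "co2_6pct"], 0.072,
    tolerance = 1e-4
  )
})

test_that("independent seeds share the truth but differ in noise", {
  st <- studySpec(seed = 1L)
  a <- simulateCVRStudy(st, seed = 101L)
  b <- simulateCVRStudy(st, seed = 202L)
  expect_equal(truthMeasurements(a), truthMeasurements(b))
  expect_false(identical(
    velocityData(studyVolumes(a)$normocapnia),
    velocityData(studyVolumes(b)$normocapnia)
  ))
})

test_that("a flow demanding mean velocity beyond Venc warns about aliasing", {
  st <- studySpec(globalFlowNormo = 6000, seed = 1L)
  acq <- studyAcquisition(snr = Inf)
  expect_warning(simulateCVRStudy(st, acq), "exceeds Venc")
})

test_that("sinusoidal cardiac modulation time-averages to the steady field", {
  h <- 0.03
  acq1 <- acquisitionSpec(h, c(25, 25, 30), venc = 200)
  acq20 <- acquisitionSpec(h, c(25, 25, 30),
    venc = 200,
    nCardiacPhases = 20L, pulsatility = 0.3
  )
  cx <- 12.5 * h
  v <- vesselSpec("V", rbind(c(cx, cx, 0.15), c(cx, cx, 0.7)), 0.1, 25)
  steady <- cvrflow:::acquireVolume(list(v), acq1, seed = 1L)
  pulsed <- cvrflow:::acquireVolume(list(v), acq20, seed = 1L)
  expect_equal(velocityData(pulsed), velocityData(steady), tolerance = 1e-8)
})

test_that("doubling resolution reduces the decoded-field error", {
  err <- sapply(c(8, 16), function(npd) {
    b <- tubePhantom(radius = 0.12, meanVelocity = 30,
      voxelsPerDiameter = npd, length = 0.8)
    vol <- b$truthVolume
    h <- voxelSize(vol)
    d <- dim(magnitudeData(vol))
    # analytic velocity at voxel centers inside the half-radius core;
    # the tube axis sits half a voxel off the grid center
    x <- ((seq_len(d[1]) - 1) - ((d[1] - 1) / 2 + 0.5)) * h
    y <- ((seq_len(d[2]) - 1) - ((d[2] - 1) / 2 + 0.5)) * h
    r2 <- outer(x^2, y^2, "+")
    kmid <- round(d[3] / 2)
    va <- 2 * 30 * (1 - r2 / 0.12^2)
    core <- r2 < (0.5 * 0.12)^2
    vz <- velocityData(vol)[, , kmid, 3]
    sqrt(mean((vz[core] - va[core])^2)) / 30
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01) # < 1% of the mean velocity at 16 voxels/diameter
})
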