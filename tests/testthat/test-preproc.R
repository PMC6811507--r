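# Aliasing correction and background/eddy-current phase-offset removal.

test_that("unwrapping is idempotent and a no-op on alias-free data", {
  b <- tubePhantom(
    radius = 0.12, meanVelocity = 30, voxelsPerDiameter = 8,
    venc = 80, snr = 30, seed = 3
  )
  u1 <- unwrapVelocity(b$volume)
  expect_equal(u1@metadata$unwrapCorrections, 0)
  expect_identical(velocityData(u1), velocityData(b$volume))
  u2 <- unwrapVelocity(u1)
  expect_identical(velocityData(u2), velocityData(u1))
})

test_that("an isolated aliased voxel is corrected by one wrap", {
  vel <- array(0, c(9, 9, 9, 3))
  vel[, , , 3] <- 70 # uniform jet
  vel[5, 5, 5, 3] <- -60 # one wrapped voxel (true 100 at Venc 80)
  vol <- new("VelocityVolume",
    velocity = vel, magnitude = array(1, c(9, 9, 9)),
    voxelSize = 0.05, venc = 80
  )
  u <- unwrapVelocity(vol)
  expect_equal(velocityData(u)[5, 5, 5, 3], 100) # -60 + 2*80
  expect_gte(u@metadata$unwrapCorrections, 1)
})

test_that("a deeply aliased jet core is recovered to the analytic field", {
  b <- tubePhantom(
    radius = 0.15, meanVelocity = 90, voxelsPerDiameter = 10,
    venc = 80
  )
  dec <- b$volume
  expect_gt(max(abs(velocityData(dec) - velocityData(b$truthVolume))), 100)
  u <- unwrapVelocity(dec)
  expect_lt(max(abs(velocityData(u) - velocityData(b$truthVolume))), 1e-6)
})

test_that("static-tissue detection excludes vessels and flags tissue", {
  b <- tubePhantom(radius = 0.15, meanVelocity = 30, voxelsPerDiameter = 10)
  mask <- detectStaticTissue(b$volume)
  core <- velocityData(b$truthVolume)[, , , 3] > 10
  expect_true(!any(mask & core)) # no flowing-lumen voxel in the static mask
  # noise-free static region is fully covered outside the smoothing halo
  expect_gt(mean(mask), 0.8)
})

test_that("an all-vessel image yields no static tissue", {
  vel <- array(30, c(6, 6, 6, 3))
  vol <- new("VelocityVolume",
    velocity = vel, magnitude = array(1, c(6, 6, 6)),
    voxelSize = 0.05, venc = 80
  )
  expect_error(detectStaticTissue(vol), "static-tissue mask is empty")
})

test_that("background correction recovers injected offsets and cleans
          static tissue", {
  co <- cbind(
    c(0.10, 0.02, -0.03, 0.015),
    c(-0.08, 0.025, 0.012, -0.02),
    c(0.06, -0.015, 0.03, 0.01)
  )
  b <- tubePhantom(
    radius = 0.15, meanVelocity = 30, voxelsPerDiameter = 10,
    venc = 80, backgroundPhaseCoeffs = co
  )
  mask <- detectStaticTissue(b$volume)
  res <- correctBackgroundPhase(b$volume, mask)
  recovered <- res$model@coefficients
  truth <- co * 80 / pi
  expect_equal(unname(recovered), unname(truth), tolerance = 0.02)
  post <- velocityData(res$volume)
  expect_lt(mean(abs(post[, , , 1][mask])), 0.1)
  expect_lt(mean(abs(post[, , , 3][mask])), 0.1)
})

test_that("zero offsets fit to zero coefficients", {
  b <- tubePhantom(radius = 0.12, meanVelocity = 25, voxelsPerDiameter = 8)
  mask <- detectStaticTissue(b$volume)
  res <- correctBackgroundPhase(b$volume, mask)
  # partial-volume rim voxels carry tiny velocities into the static mask,
  # so "zero" here means well below any physiological offset
  expect_lt(max(abs(res$model@coefficients)), 0.1)
  expect_lt(
    max(abs(velocityData(res$volume) - velocityData(b$volume))), 0.3
  )
})

test_that("a degenerate (single-plane) static mask is rejected", {
  vel <- array(0, c(10, 10, 10, 3))
  vol <- new("VelocityVolume",
    velocity = vel, magnitude = array(1, c(10, 10, 10)),
    voxelSize = 0.05, venc = 80
  )
  mask <- array(FALSE, c(10, 10, 10))
  mask[, , 4] <- TRUE # coplanar: z term unidentifiable
  expect_error(correctBackgroundPhase(vol, mask), "rank-deficient")
  expect_error(correctBackgroundPhase(vol, array(FALSE, c(10, 10, 10))), "empty")
})

test_that("background correction preserves neighboring-voxel velocity
          differences up to the fitted trend", {
  co <- matrix(0, 4, 3)
  co[1, 3] <- 0.08
  b <- tubePhantom(
    radius = 0.12, meanVelocity = 25, voxelsPerDiameter = 8,
    venc = 80, backgroundPhaseCoeffs = co
  )
  mask <- detectStaticTissue(b$volume)
  res <- correctBackgroundPhase(b$volume, mask)
  pre <- velocityData(b$volume)[, , , 3]
  post <- velocityData(res$volume)[, , , 3]
  dPre <- diff(pre[, 5, 5])
  dPost <- diff(post[, 5, 5])
  expect_equal(dPost, dPre, tolerance = 1e-8) # constant offset: differences
})
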