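# PC-MRA, segmentation, centerline extraction, labeling and trimming.

test_that("PC-MRA intensity is the magnitude-velocity product", {
  set.seed(1)
  vel <- array(rnorm(5 * 5 * 5 * 3), c(5, 5, 5, 3))
  mag <- array(runif(125, 0.2, 1), c(5, 5, 5))
  vol <- new("VelocityVolume",
    velocity = vel, magnitude = mag, voxelSize = 0.05, venc = 80
  )
  ang <- computePCMRA(vol)
  vn <- sqrt(vel[, , , 1]^2 + vel[, , , 2]^2 + vel[, , , 3]^2)
  expect_equal(intensityData(ang), mag * vn)
  # static voxel maps to zero
  vel[2, 2, 2, ] <- 0
  vol@velocity <- vel
  expect_equal(intensityData(computePCMRA(vol))[2, 2, 2], 0)
})

test_that("vessel/background angiogram contrast is strong at SNR 20", {
  b <- tubePhantom(
    radius = 0.15, meanVelocity = 36, voxelsPerDiameter = 8,
    venc = 80, snr = 20, seed = 5
  )
  ang <- computePCMRA(b$volume)
  lumen <- velocityData(b$truthVolume)[, , , 3] > 1
  expect_gt(
    mean(intensityData(ang)[lumen]) / mean(intensityData(ang)[!lumen]),
    10
  )
})

test_that("segmentation is monotone in the threshold and recovers the
          lumen on noise-free data", {
  b <- tubePhantom(radius = 0.15, meanVelocity = 30, voxelsPerDiameter = 10)
  ang <- computePCMRA(b$volume)
  m1 <- segmentVessels(ang, method = "relmax", value = 0.02)
  m2 <- segmentVessels(ang, method = "relmax", value = 0.10)
  expect_true(all(m1[m2])) # higher threshold => subset mask
  truthLumen <- velocityData(b$truthVolume)[, , , 3] > 0
  dice <- 2 * sum(m1 & truthLumen) / (sum(m1) + sum(truthLumen))
  expect_gte(dice, 0.9)
})

test_that("degenerate angiograms are rejected", {
  zero <- new("Angiogram",
    intensity = array(0, c(6, 6, 6)), voxelSize = 0.05, provenance = "t"
  )
  expect_error(segmentVessels(zero), "all zero")
  b <- tubePhantom(radius = 0.12, meanVelocity = 20, voxelsPerDiameter = 8)
  ang <- computePCMRA(b$volume)
  expect_error(
    segmentVessels(ang, method = "fixed", value = 2 * max(intensityData(ang))),
    "empty"
  )
})

test_that("small connected components are removed", {
  b <- tubePhantom(radius = 0.15, meanVelocity = 30, voxelsPerDiameter = 10)
  ang <- computePCMRA(b$volume)
  I <- intensityData(ang)
  I[2, 2, 2] <- max(I) # isolated speck
  ang@intensity <- I
  mask <- segmentVessels(ang, method = "relmax", value = 0.02, minSize = 27L)
  expect_false(mask[2, 2, 2])
})

test_that("a straight tube yields a single junction-free path with axial
          tangents", {
  b <- tubePhantom(radius = 0.15, meanVelocity = 30, voxelsPerDiameter = 10)
  ang <- computePCMRA(b$volume)
  mask <- segmentVessels(ang, method = "relmax", value = 0.02)
  tree <- extractCenterlines(mask, voxelSize(ang))
  nd <- treeNodes(tree)
  expect_equal(sum(nd$flag == "junction"), 0)
  expect_equal(sum(nd$flag == "endpoint"), 2)
  tree <- labelAndTrim(tree, b$seeds, m = 6L)
  nd <- treeNodes(tree)
  sel <- nd$measurement
  expect_gt(sum(sel), 10)
  # tangents within 5 degrees of the tube axis
  expect_gt(min(abs(nd$tz[sel])), cos(5 * pi / 180))
})

test_that("a Y-bifurcation has exactly one junction", {
  bf <- bifurcationPhantom()
  ang <- computePCMRA(bf$volume)
  mask <- segmentVessels(ang, method = "relmax", value = 0.02)
  tree <- extractCenterlines(mask, voxelSize(ang))
  expect_equal(sum(treeNodes(tree)$flag == "junction"), 1)
})

test_that("masks without tubular structure are rejected", {
  expect_error(
    extractCenterlines(array(FALSE, c(8, 8, 8)), 0.03),
    "empty"
  )
  single <- array(FALSE, c(8, 8, 8))
  single[4, 4, 4] <- TRUE
  expect_error(extractCenterlines(single, 0.03), "tubular")
})

test_that("endpoint trimming follows the node-count arithmetic", {
  tree <- syntheticPathTree(n = 50)
  out <- labelAndTrim(tree, list(VES = c(4 * 0.03, 4 * 0.03, 0.1)), m = 3L)
  expect_equal(sum(treeNodes(out)$measurement), 44) # 50 - 2 x 3
  # ordering starts at the seed end
  nd <- treeNodes(out)
  expect_equal(nd$ord[1], 1L)
  # larger margins never increase the measurement count
  for (m in c(5L, 8L, 12L)) {
    bigger <- labelAndTrim(tree, list(VES = c(0.12, 0.12, 0.1)), m = m)
    expect_lte(
      sum(treeNodes(bigger)$measurement),
      sum(treeNodes(out)$measurement)
    )
  }
})

test_that("junction trimming keeps measurement nodes off the junction", {
  tree <- syntheticYTree(armLength = 12)
  h <- 0.03
  nd <- treeNodes(tree)
  seedFor <- function(id) c(nd$x[id], nd$y[id], nd$z[id])
  out <- labelAndTrim(
    tree,
    list(A = seedFor(3L), B = seedFor(20L), C = seedFor(32L)),
    k = 2L, m = 3L
  )
  ndo <- treeNodes(out)
  g <- igraph::graph_from_edgelist(treeEdges(out), directed = FALSE)
  jn <- which(ndo$flag == "junction")
  adjacent <- as.integer(igraph::neighbors(g, jn))
  expect_false(any(ndo$measurement[c(jn, adjacent)]))
  # three disjoint labeled sets
  expect_setequal(setdiff(unique(ndo$label), "unlabeled"), c("A", "B", "C"))
})

test_that("seed errors are informative", {
  tree <- syntheticPathTree(n = 30)
  expect_error(
    labelAndTrim(tree, list(BAD = c(5, 5, 5))),
    "BAD"
  )
  expect_error(
    labelAndTrim(tree, list(
      A = c(0.12, 0.12, 0.1),
      B = c(0.12, 0.12, 0.5)
    )),
    "same branch"
  )
})

test_that("the five-vessel study phantom yields five labeled disjoint
          measurement sets", {
  ps <- simulateCVRStudy(studySpec(seed = 4L), acq = studyAcquisition(snr = Inf))
  vol <- studyVolumes(ps)$normocapnia
  q <- quantifyVolume(vol, studySeeds(ps),
    params = list(thresholdMethod = "relmax"), preprocess = TRUE
  )
  nd <- treeNodes(q$tree)
  labs <- setdiff(unique(nd$label), "unlabeled")
  expect_setequal(labs, c("ICA_L", "ICA_R", "MCA_L", "MCA_R", "BA"))
  for (l in labs) expect_gt(sum(nd$label == l & nd$measurement), 5)
})
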