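# Conductance, CVR fitting, brain-volume correction, CSA change and
# condition summaries.

test_that("CVC follows flow / MAP x 100 and is homogeneous", {
  expect_equal(computeCVC(300, 100), 300)
  expect_equal(computeCVC(250, 125), 200)
  expect_equal(computeCVC(0, 90), 0)
  expect_error(computeCVC(300, 0), "positive")
  # scaling flow by c scales CVC by c; scaling MAP by c scales it by 1/c
  for (c in c(0.5, 2, 3.7)) {
    expect_equal(computeCVC(300 * c, 100), computeCVC(300, 100) * c)
    expect_equal(computeCVC(300, 100 * c), computeCVC(300, 100) / c)
  }
})

test_that("CVR fitting reproduces slopes for 2-point and collinear data", {
  f2 <- fitCVR(data.frame(etco2 = c(46, 48), cvc = c(200, 210)))
  expect_equal(f2@slope, 5)
  expect_equal(f2@nPoints, 2L)
  f3 <- fitCVR(data.frame(etco2 = c(40, 46, 48), cvc = c(170, 200, 210)))
  expect_equal(f3@slope, 5, tolerance = 1e-12)
  # hypercapnic-only mode drops the normocapnic point
  fh <- fitCVR(
    data.frame(
      etco2 = c(40, 46, 48), cvc = c(150, 200, 210),
      condition = c("normocapnia", "co2_4pct", "co2_6pct")
    ),
    mode = "hypercapnic_only"
  )
  expect_equal(fh@nPoints, 2L)
  expect_equal(fh@slope, 5)
  expect_false("normocapnia" %in% fh@conditionsUsed)
})

test_that("degenerate CVR inputs are rejected", {
  expect_error(fitCVR(data.frame(etco2 = 40, cvc = 100)), "2 points")
  expect_error(
    fitCVR(data.frame(etco2 = c(40, 40), cvc = c(100, 120))),
    "distinct"
  )
})

test_that("brain-volume correction divides by GM + WM", {
  expect_equal(correctGlobalFlow(640, 0.7, 0.5), 533.3333, tolerance = 1e-4)
  expect_equal(correctGlobalFlow(640, 0.66, 0.44), 581.8182, tolerance = 1e-4)
  expect_equal(correctGlobalFlow(0, 0.7, 0.5), 0)
  expect_error(correctGlobalFlow(640, -0.7, 0.5), "positive")
})

test_that("CSA change returns absolute and percent deltas", {
  ch <- csaChange(0.069, 0.072)
  expect_equal(ch$delta, 0.003)
  expect_equal(ch$percent, 4.3478, tolerance = 1e-4)
  ch0 <- csaChange(0.07, 0.07)
  expect_equal(ch0$delta, 0)
  expect_equal(ch0$percent, 0)
  expect_error(csaChange(0, 0.07), "positive")
})

test_that("condition summaries average channels within the scan window", {
  ts <- data.frame(
    time = 1:10,
    etco2 = rep(c(46, 48), 5),
    map = rep(95, 10),
    hr = 55:64,
    spo2 = rep(98, 10)
  )
  s <- summarizeCondition(ts, c(1, 10))
  expect_equal(s$etco2, 47)
  expect_equal(s$map, 95)
  expect_equal(s$hr, 59.5)
  expect_error(summarizeCondition(ts, c(20, 30)), "window")
})

test_that("fitting the truth-ledger CVC recovers the programmed slopes to
          machine precision", {
  st <- studySpec(trueSlope = 5, seed = 9L)
  ps <- simulateCVRStudy(st, acq = studyAcquisition(snr = Inf))
  tr <- studyTruth(ps)
  cond <- studyConditions(ps)
  res <- cvrTable(
    truthMeasurements(tr), cond,
    gm = 0.72, wm = 0.48
  )
  sl <- truthSlopes(tr)
  for (sc in sl$scope) {
    expect_equal(
      res$slope[res$scope == sc], sl$slope[sl$scope == sc],
      tolerance = 1e-10
    )
  }
  # both fit modes agree on collinear truth
  resH <- cvrTable(truthMeasurements(tr), cond, mode = "hypercapnic_only")
  expect_equal(
    resH$slope[resH$scope == "global"],
    res$slope[res$scope == "global"],
    tolerance = 1e-10
  )
})

test_that("samplesPerBeat reproduces the acquisition arithmetic", {
  expect_identical(samplesPerBeat(7.8, 60), 128L)
  expect_identical(samplesPerBeat(10, 60), 100L)
  expect_error(samplesPerBeat(-1, 60))
})
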