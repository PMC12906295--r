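test_that("isocenter composition reproduces the measured laser-relative shifts", {
  s <- composeIsocenterShifts(c(0, 0, 0), c(0.0, -0.4, -0.5))
  expect_equal(mrToRt(s), c(0.0, 0.4, 0.5))
  expect_equal(mrToRt(composeIsocenterShifts(c(0, 0, 0), c(0, 0, 0))),
               c(0, 0, 0))
  v <- c(0.3, -1.2, 0.7)
  expect_equal(mrToRt(composeIsocenterShifts(v, v)), c(0, 0, 0))
})

test_that("frame conversion follows the head-first-supine axis table", {
  expect_equal(convertFrame(c(1, 0, 0), "linac_iec", "mri_dicom"), c(1, 0, 0))
  expect_equal(convertFrame(c(0, 1, 0), "linac_iec", "mri_dicom"), c(0, 0, -1))
  expect_equal(convertFrame(c(0, 0, 1), "linac_iec", "mri_dicom"), c(0, 1, 0))
  expect_equal(convertFrame(c(1, 2, 3), "mri_dicom", "laser_dicom"), c(1, 2, 3))
  set.seed(1)
  for (i in 1:20) {
    v <- rnorm(3)
    for (pair in list(c("linac_iec", "mri_dicom"),
                      c("linac_iec", "laser_dicom"),
                      c("mri_dicom", "laser_dicom"))) {
      expect_equal(convertFrame(convertFrame(v, pair[1], pair[2]),
                                pair[2], pair[1]), v)
    }
  }
  expect_error(convertFrame(c(1, 0, 0), "linac_iec", "table"), "unknown frame")
})

test_that("composition commutes with frame conversion", {
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    composed <- mrToRt(composeIsocenterShifts(a, b))
    convertedFirst <- mrToRt(composeIsocenterShifts(
      convertFrame(a, "laser_dicom", "linac_iec"),
      convertFrame(b, "laser_dicom", "linac_iec"), frame = "linac_iec"))
    expect_equal(convertFrame(composed, "laser_dicom", "linac_iec"),
                 convertedFirst)
  }
})

test_that("couch attenuation forms and the factor deviation reproduce the printed table", {
  expect_equal(couchAttenuationMeas(1, 1), 0)
  expect_equal(couchAttenuationMeas(0.9, 1), 10)
  expect_equal(couchAttenuationCalc(110, 100), -10)
  expect_error(couchAttenuationMeas(1, 0), "positive")
  # factor form drives the table comparison: all seven deviations at 1 dp
  dev <- attenuationDeviation(table7Factors$measured, table7Factors$tps)
  expect_equal(dev, table7Factors$deviation)
  # factor of an unattenuated reading is 1
  expect_equal(attenuationFactor(2, 2), 1)
  expect_equal(attenuationFactor(1, 1.2), 1.2)
})

test_that("gating deviation reports the rounded magnitude with the signed value attached", {
  d <- gatingDeviation(-11.76, -11.77)
  expect_equal(as.numeric(d), 0.09)
  expect_equal(attr(d, "signed"), 100 * (-11.76 + 11.77) / (-11.76))
  expect_equal(as.numeric(gatingDeviation(5, 5)), 0)
  expect_equal(as.numeric(gatingDeviation(10, 9)), 10)
  expect_error(gatingDeviation(0, 1), "nonzero")
})

test_that("beam-off latency is recovered within the frame quantisation bound", {
  tr4 <- genMotionTrace(injectedLatencyS = 0.1, frameRateFPS = 4,
                        durationS = 40)
  expect_lt(abs(beamOffLatency(tr4, 3)$latencyS - 0.1), 0.25 / 2 + 1e-9)
  tr8 <- genMotionTrace(injectedLatencyS = 0.09, frameRateFPS = 8,
                        durationS = 40)
  expect_lt(abs(beamOffLatency(tr8, 3)$latencyS - 0.09), 0.125 / 2 + 1e-9)
  tr0 <- genMotionTrace(injectedLatencyS = 0, frameRateFPS = 4,
                        durationS = 40)
  expect_lt(abs(beamOffLatency(tr0, 3)$latencyS), 0.25)
  short <- genMotionTrace(durationS = 8)
  expect_error(beamOffLatency(MotionTrace(short@time[1:10],
                                          short@position[1:10],
                                          short@beamOn[1:10]), 3),
               "at least 3")
})

test_that("latency estimator is unbiased to half a frame over stochastic trials", {
  set.seed(9)
  errs <- vapply(1:200, function(s) {
    lat <- runif(1, 0.05, 0.3)
    bd <- runif(1, 1, 6)
    tr <- genMotionTrace(injectedLatencyS = lat, frameRateFPS = 4,
                         durationS = 20, gatingBoundaryMM = bd,
                         noiseSD = 0.05, seed = s)
    beamOffLatency(tr, bd)$latencyS - lat
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.25 / 2)
})

test_that("reference dose multiplies the TG-51-style factors and interpolates kQ", {
  expect_equal(referenceDose(1, 1, kQ = 1, kB = 1), 1)
  expect_equal(referenceDose(1, 1, kQ = 1), 0.9957)
  expect_equal(referenceDose(2, 0.05, kQ = 0.99, kB = 0.9957),
               2 * 0.05 * 0.99 * 0.9957)
  # linear interpolation between anchors at 63% and 66%, queried at 64%
  tab <- cbind(c(63, 66), c(0.996, 0.990))
  expect_equal(referenceDose(1, 1, kB = 1, pdd10xPct = 64, kQTable = tab),
               (2 / 3) * 0.996 + (1 / 3) * 0.990)
  expect_error(referenceDose(1, 1, kB = 1, pdd10xPct = 70, kQTable = tab),
               "outside")
})
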