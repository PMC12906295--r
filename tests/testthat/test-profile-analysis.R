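test_that("fwhm matches rectangle and generator closed forms and is scale-free", {
  x <- seq(-10, 10, by = 0.01)
  rect <- BeamProfile(x, as.numeric(abs(x) <= 5))
  expect_equal(fwhm(rect), 10, tolerance = 0.02 / 10)
  p <- genFieldProfile(nominalWidthCM = 9.96, fffPeakFraction = 0,
                       samplingStepMM = 0.5)
  expect_lt(abs(fwhm(p) - 9.96), 0.05)
  p2 <- BeamProfile(profilePositions(p), profileValues(p) * 12.5)
  expect_equal(fwhm(p2), fwhm(p))
  # multi-lobe input is rejected
  bad <- BeamProfile(x, as.numeric(abs(x) <= 2 | abs(x - 6) <= 1))
  expect_error(fwhm(bad), "times")
})

test_that("field size difference is measured minus TPS", {
  expect_equal(fieldSizeDifference(20.29, 20.16), 0.13)
  expect_equal(fieldSizeDifference(27.31, 27.21), 0.10)
  expect_equal(fieldSizeDifference(5, 5), 0)
  expect_error(fieldSizeDifference(-1, 5), ">")
})

test_that("penumbra matches ramp and logistic closed forms", {
  # linear ramp 0 -> 100 over 10 mm: the 20-80 span is 60% of the ramp
  x <- seq(-4, 4, by = 0.002)  # cm
  y <- pmin(pmax(x + 2, 0), 1) * pmin(pmax(2 - x, 0), 1)  # 10 mm ramps, plateau
  prof <- BeamProfile(x, y)
  pen <- penumbra(prof)
  expect_equal(pen$leftMM, 6, tolerance = 1e-3)
  expect_equal(pen$meanMM, (pen$leftMM + pen$rightMM) / 2)
  # logistic edge, scale s = 2 mm: 20-80 distance 2 s log(4)
  p <- genFieldProfile(nominalWidthCM = 9.96, edgeScaleMM = 2,
                       fffPeakFraction = 0, samplingStepMM = 0.2)
  expect_equal(penumbra(p)$meanMM, 2 * 2 * log(4), tolerance = 0.01)
  # normalization flag does not change the width (thresholds are relative)
  expect_equal(penumbra(p, normalize = FALSE)$meanMM, penumbra(p)$meanMM)
})

test_that("flatness and symmetry reproduce the printed off-axis comparisons", {
  # 9.96 cm field, gantry 0, cross-plane, OAP +/-2 and +/-4 cm
  fs <- flatnessSymmetry(oapCM = c(-2, 2, -4, 4),
                         measuredPct = c(97.49, 97.64, 91.48, 91.75),
                         tpsPct = c(97.82, 97.85, 92.32, 92.36))
  expect_equal(round(fs$flatnessDiffPct, 2), c(-0.33, -0.21, -0.84, -0.61))
  expect_equal(round(fs$symmetryPct[fs$oapCM == -2], 2), -0.15)
  expect_equal(round(fs$symmetryPct[fs$oapCM == -4], 2), -0.27)
  expect_true(all(fs$flatnessPass), all(fs$symmetryPass))
  # mirror-symmetric measurements give S = 0
  fs0 <- flatnessSymmetry(c(-3, 3), c(95, 95), c(94, 96))
  expect_equal(fs0$symmetryPct, c(0, 0))
  expect_error(flatnessSymmetry(c(-2, 3), c(1, 1), c(1, 1)), "pair")
})

test_that("output factors normalise to the reference and difference uses the TPS denominator", {
  tab <- fofTable(list(small = c(2, 2, 2), ref = c(2, 2, 2)), "ref")
  expect_equal(tab$fof, c(1, 1))
  # reference FOF is 1 for any reading scale
  tab2 <- fofTable(list(a = c(0.1, 0.2), ref = c(0.4, 0.6)), "ref")
  expect_equal(tab2$fof[tab2$fieldLabel == "ref"], 1)
  expect_equal(fofDifference(0.444, 0.504), -11.9)
  expect_equal(fofDifference(0.686, 0.702), -2.3)
  expect_equal(fofDifference(1, 1), 0)
  expect_error(fofTable(list(a = c(0, 1), ref = 1), "ref"), "positive")
})

test_that("gamma is zero for identical inputs and exactly one at the dose-criterion offset", {
  ref <- DoseImage(matrix(rep(seq(0.5, 1, length.out = 15), 15), 15, 15), 2)
  g <- gamma2d(ref, ref)
  expect_equal(max(g$gammaMap, na.rm = TRUE), 0)
  expect_equal(g$passRatePct, 100)
  refc <- DoseImage(matrix(1, 15, 15), 2)
  evc <- DoseImage(matrix(1.03, 15, 15), 2)
  g2 <- gamma2d(refc, evc, doseCritPct = 3, dtaMM = 3)
  expect_lt(max(abs(g2$gammaMap - 1), na.rm = TRUE), 1e-6)
  expect_equal(g2$passRatePct, 100)
})

test_that("gamma equals the exhaustive oracle on small grids", {
  set.seed(3)
  for (trial in 1:4) {
    rv <- matrix(0.7 + 0.3 * runif(25), 5, 5)
    ev <- rv * (1 + 0.02 * matrix(rnorm(25), 5, 5))
    ri <- DoseImage(rv, 2)
    ei <- DoseImage(ev, 2)
    g <- gamma2d(ri, ei)
    go <- oracleGamma(ri, ei)
    expect_lt(max(abs(g$gammaMap - go), na.rm = TRUE), 1e-6)
  }
})

test_that("gamma grows monotonically with a uniform dose offset", {
  ref <- DoseImage(matrix(1, 11, 11), 2)
  gmax <- vapply(c(0.01, 0.02, 0.04, 0.06), function(off) {
    max(gamma2d(ref, DoseImage(matrix(1 + off, 11, 11), 2))$gammaMap,
        na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(gmax) > 0))
  expect_error(gamma2d(ref, DoseImage(matrix(1, 5, 5), 2,
                                      origin = c(500, 500))), "disjoint")
})
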