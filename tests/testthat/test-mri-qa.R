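test_that("spectral homogeneity converts the linewidth to ppm of the central frequency", {
  # worst and best gantry-angle spectra at the displayed central frequency
  spWorst <- genSpectrum(centerFrequencyHz = 14713851, fwhmHz = 83.21,
                         samplingStepHz = 0.5, nominalF0 = 14713851)
  hW <- spectralHomogeneity(spWorst)
  expect_equal(round(hW$ppm, 1), 5.7)
  expect_false(hW$withinTolerance)
  spBest <- genSpectrum(centerFrequencyHz = 14713851, fwhmHz = 25.68,
                        samplingStepHz = 0.5, nominalF0 = 14713851)
  hB <- spectralHomogeneity(spBest)
  expect_equal(round(hB$ppm, 1), 1.7)
  expect_true(hB$withinTolerance)
  # fwhm numerically equal to cf * 1e-6 gives exactly 1 ppm
  sp1 <- genSpectrum(centerFrequencyHz = 2e7, fwhmHz = 20,
                     samplingStepHz = 0.5, nominalF0 = 2e7)
  expect_equal(spectralHomogeneity(sp1)$ppm, 1, tolerance = 0.02)
  # ppm invariant to magnitude scaling, proportional to fwhm at fixed cf
  spScaled <- SpectrumProfile(spWorst@frequency, spWorst@magnitude * 3,
                              nominalF0 = 14713851)
  expect_equal(spectralHomogeneity(spScaled)$ppm, hW$ppm)
  expect_equal(hW$ppm / hB$ppm, 83.21 / 25.68, tolerance = 0.01)
  # peak mode uses the interpolated peak frequency
  hPeak <- spectralHomogeneity(spWorst, cfMode = "peak")
  expect_lt(abs(hPeak$cfUsedHz - 14713851), 1)
})

test_that("central frequency check applies the closed permissible range", {
  expect_true(checkCentralFrequency(14701760))
  expect_true(checkCentralFrequency(14686760))   # lower boundary
  expect_true(checkCentralFrequency(14716760))   # upper boundary
  expect_false(checkCentralFrequency(14680000))
})

test_that("SNR follows the 0.66 NEMA form on known-moment images", {
  img <- genUniformPhantomImage(mean = 100, noiseSD = 1, sizePx = c(160, 160),
                                seed = 4)
  roi <- list(sizeMM = c(200, 200))
  expect_equal(snr(img, roi, roi), 66, tolerance = 0.05)
  img5 <- genUniformPhantomImage(mean = 100, noiseSD = 5, sizePx = c(160, 160),
                                 seed = 4)
  expect_equal(snr(img5, roi, roi), 13.2, tolerance = 0.05 * 13.2)
  # scale invariance: numerator and denominator scale together
  img2 <- GrayImage(imageValues(img) * 3, pixelSpacing(img))
  expect_equal(snr(img2, roi, roi), snr(img, roi, roi))
  expect_error(snr(genUniformPhantomImage(noiseSD = 0), roi, roi), "positive")
})

test_that("uniformity matches closed forms on constant and gradient images", {
  const <- genUniformPhantomImage(mean = 100, noiseSD = 0)
  roi <- list(sizeMM = c(100, 100))
  expect_equal(uniformity(const, roi), 100)
  # two-level image without prefiltering: max 3, min 1 -> 50%
  two <- GrayImage(matrix(c(1, 3), 20, 20), 1)
  expect_equal(uniformity(two, list(sizeMM = c(10, 10)), prefilterPx = 1), 50)
  # linear gradient spanning [90, 110]: 100 (1 - 20/200) = 90%
  grad <- GrayImage(matrix(rep(seq(90, 110, length.out = 101), each = 101),
                           101, 101), 1)
  expect_equal(uniformity(grad, list(sizeMM = c(100, 100))), 90,
               tolerance = 0.01)
  # scale invariance
  expect_equal(uniformity(GrayImage(imageValues(grad) * 2, 1),
                          list(sizeMM = c(100, 100))),
               uniformity(grad, list(sizeMM = c(100, 100))))
})

test_that("percent signal ghosting uses the four-ROI difference over twice the centre", {
  base <- matrix(0.001, 120, 120)
  base[41:80, 41:80] <- 100
  img <- GrayImage(base, 1)
  ctr <- list(centerMM = c(0, 0), sizeMM = c(20, 20))
  edges <- list(top = list(centerMM = c(0, -55), sizeMM = c(10, 6)),
                bottom = list(centerMM = c(0, 55), sizeMM = c(10, 6)),
                left = list(centerMM = c(-55, 0), sizeMM = c(6, 10)),
                right = list(centerMM = c(55, 0), sizeMM = c(6, 10)))
  expect_equal(percentSignalGhosting(img, ctr, edges), 0)
  # top = bottom = 2, left = right = 1, centre = 100 -> 0.01
  v <- base
  co <- pixelCoords(img)
  v[abs(co$y + 55) <= 3, abs(co$x) <= 5] <- 2
  v[abs(co$y - 55) <= 3, abs(co$x) <= 5] <- 2
  v[abs(co$y) <= 5, abs(co$x + 55) <= 3] <- 1
  v[abs(co$y) <= 5, abs(co$x - 55) <= 3] <- 1
  g <- percentSignalGhosting(GrayImage(v, 1), ctr, edges)
  expect_equal(g, (2 + 2 - 1 - 1) / (2 * 100), tolerance = 1e-6)
  # synthetic ghost stripe raising only top/bottom is detected at its ratio
  v2 <- base
  v2[abs(co$y + 55) <= 3, abs(co$x) <= 5] <- 0.501
  v2[abs(co$y - 55) <= 3, abs(co$x) <= 5] <- 0.501
  expect_equal(percentSignalGhosting(GrayImage(v2, 1), ctr, edges),
               2 * 0.5 / 200, tolerance = 1e-4)
})

test_that("ACR slice metrics follow their closed-form definitions", {
  expect_equal(sliceThickness(50, 50), 5)
  expect_equal(sliceThickness(60, 50), 0.2 * 3000 / 110)
  expect_error(sliceThickness(0, 50), "positive")
  expect_equal(slicePosition(0), 0)
  expect_equal(slicePosition(1.1), 0.55)
  expect_equal(percentIntegralUniformity(
    genUniformPhantomImage(mean = 50, noiseSD = 0),
    list(sizeMM = c(80, 80))), 100)
})

test_that("spatial integrity recovers identity, rigid-shift and radial distortions", {
  g0 <- genGridPhantomImage(markerSpacingMM = 20, extentMM = c(60, 60))
  halfpx <- pixelSpacing(g0) / 2
  r0 <- spatialIntegrity(g0)
  expect_lt(r0$meanMM, halfpx)
  # uniform 0.5 mm translation
  shift <- function(x, y) cbind(rep(0.5, length(x)), rep(0, length(x)))
  g1 <- genGridPhantomImage(markerSpacingMM = 20, extentMM = c(60, 60),
                            distortionField = shift)
  r1 <- spatialIntegrity(g1)
  expect_equal(r1$meanMM, 0.5, tolerance = halfpx)
  # radial distortion d(r) = a r^2 outward: per-bin means follow a r^2
  a <- 2e-4
  radial <- function(x, y) {
    r <- sqrt(x^2 + y^2)
    u <- cbind(x, y) / pmax(r, 1e-9)
    u * (a * r^2)
  }
  g2 <- genGridPhantomImage(markerSpacingMM = 20, extentMM = c(60, 60),
                            distortionField = radial)
  r2 <- spatialIntegrity(g2, dsvRadiiMM = c(30, 60, 90))
  nom <- groundTruth(g2)$nominal
  rr <- sqrt(rowSums(nom^2))
  bins <- findInterval(rr, c(30, 60, 90)) + 1
  pred <- tapply(a * rr^2, bins, mean)
  expect_lt(max(abs(r2$radiusBins$meanMM - pred)), halfpx)
})

test_that("spatial integrity errors when markers go undetected", {
  g <- genGridPhantomImage(markerSpacingMM = 20, extentMM = c(40, 40))
  nomFar <- rbind(groundTruth(g)$nominal, matrix(500, 10, 2))
  expect_error(spatialIntegrity(g, nominal = nomFar, windowMM = 8),
               "markers detected")
})
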