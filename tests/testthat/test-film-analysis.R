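test_that("film calibration applies monotone curves pixelwise and rejects bad input", {
  od <- DoseImage(matrix(0.5, 4, 4), 1, units = "od")
  expect_equal(imageValues(calibrateFilm(od, function(x) x)),
               imageValues(od))
  expect_equal(imageValues(calibrateFilm(od, function(x) 2 * x)),
               matrix(1, 4, 4))
  # rational curve round trip dose -> od -> dose
  fwd <- function(d) d / (d + 1.2)           # dose -> od, strictly monotone
  inv <- function(od) 1.2 * od / (1 - od)    # exact inverse
  dose <- matrix(seq(0.1, 3, length.out = 16), 4, 4)
  odImg <- DoseImage(fwd(dose), 1, units = "od")
  back <- calibrateFilm(odImg, inv)
  expect_lt(max(abs(imageValues(back) - dose)), 1e-9)
  # unit and domain guards
  expect_error(calibrateFilm(DoseImage(matrix(1, 2, 2), 1), function(x) x),
               "od")
  expect_error(calibrateFilm(od, function(x) x, domain = c(0, 0.4)),
               "outside the calibration domain")
})

test_that("concurrent starshot spokes give near-zero radius at the injected centre", {
  film <- genStarshotFilm(centerMM = c(2, -1.5), spokeOffsetsMM = 0, seed = 1)
  res <- analyzeStarshot(film, 5)
  halfpx <- pixelSpacing(film) / 2
  expect_lte(res$radiusMM, halfpx)
  expect_lt(max(abs(res$centerMM - c(2, -1.5))), halfpx)
  expect_equal(res$nSpokes, 5)
})

test_that("starshot recovers an analytic tangent-circle construction", {
  # alternating offset signs make the signed normals span the plane, so the
  # 0.6 mm circle about the centre is the minimum tangent circle
  film <- genStarshotFilm(spokeOffsetsMM = 0.6 * c(1, -1, 1, -1, 1), seed = 1)
  res <- analyzeStarshot(film, 5)
  halfpx <- pixelSpacing(film) / 2
  expect_lt(abs(res$radiusMM - 0.6), halfpx)
  expect_lt(max(abs(res$centerMM)), halfpx)
  # 3-line instance, radius 1.0 about (1, 0.5)
  film3 <- genStarshotFilm(centerMM = c(1, 0.5), spokeAnglesDeg = c(0, 60, 120),
                           spokeOffsetsMM = 1.0 * c(1, -1, 1), seed = 2)
  res3 <- analyzeStarshot(film3, 3)
  expect_lt(abs(res3$radiusMM - 1.0), halfpx)
  expect_lt(max(abs(res3$centerMM - c(1, 0.5))), halfpx)
})

test_that("starshot minimax solver matches the brute-force grid oracle", {
  set.seed(42)
  for (trial in 1:8) {
    n <- sample(3:7, 1)
    ang <- sort(runif(n, 0, 180))
    # keep orientations separated to stay a valid spoke set
    while (min(diff(c(ang, ang[1] + 180))) < 12) {
      ang <- sort(runif(n, 0, 180))
    }
    offs <- runif(n, -1.5, 1.5)
    th <- ang * pi / 180
    N <- cbind(-sin(th), cos(th))
    C <- offs
    sol <- mrlqa:::.chebyshevCenter(N, C)
    oracle <- oracleChebyshev(ang, offs, span = 3, step = 0.01)
    expect_lt(abs(sol$r - oracle$r), 0.01)
    # the solver's centre must be at least as good as the oracle's grid point
    expect_lte(sol$r, oracleMaxLineDist(oracle$p, ang, offs) + 1e-9)
  }
})

test_that("starshot radius is invariant under rotation of the spoke set", {
  base <- 0.6 * c(1, -1, 1, -1, 1)
  r0 <- analyzeStarshot(genStarshotFilm(spokeOffsetsMM = base, seed = 1),
                        5)$radiusMM
  for (rot in c(10, 37)) {
    film <- genStarshotFilm(spokeAnglesDeg = seq(0, 144, by = 36) + rot,
                            spokeOffsetsMM = base, seed = 1)
    expect_lt(abs(analyzeStarshot(film, 5)$radiusMM - r0), 0.1)
  }
})

test_that("starshot errors when fewer spokes are present than requested", {
  film <- genStarshotFilm(spokeAnglesDeg = c(0, 60, 120), seed = 1)
  expect_error(analyzeStarshot(film, 5), "expected 5")
})

test_that("picket fence recovers zero and injected shifts to sub-pixel accuracy", {
  nom <- c(-12, -8, -4, 0, 4, 8, 12)
  pf0 <- genPicketFenceFilm(nom, rep(0, 7))
  r0 <- analyzePicketFence(pf0, nom)
  halfpx <- pixelSpacing(pf0) / 2
  expect_lt(max(abs(r0$shiftsMM)), halfpx)
  expect_lt(r0$sdShiftMM, 0.05)

  set.seed(11)
  for (trial in 1:100) {
    shifts <- runif(7, -1, 1)
    pf <- genPicketFenceFilm(nom, shifts, imageSizePx = c(21, 551))
    r <- analyzePicketFence(pf, nom)
    expect_lt(max(abs(r$shiftsMM - shifts)), halfpx)
  }
})

test_that("picket fence errors when a strip is missing", {
  pf <- genPicketFenceFilm(c(-4, 4), c(0, 0))
  expect_error(analyzePicketFence(pf, c(-4, 0, 4)), "no strip detected")
})

test_that("leaf-shift statistics reproduce the printed per-gantry mean and SD", {
  expect_equal(leafShiftStats(c(0, 0, 0) + 0:2 * 0)[["sd"]], 0)
  printed <- list(g0 = c(0.03, 0.28), g90 = c(0.10, 0.28),
                  g180 = c(0.03, 0.28), g270 = c(0.01, 0.24))
  for (g in names(printed)) {
    st <- leafShiftStats(table4ShiftsMM[[g]])
    expect_equal(round(st[["mean"]], 2), printed[[g]][1])
    expect_equal(round(st[["sd"]], 2), printed[[g]][2])
  }
  expect_error(leafShiftStats(0.1), "at least 2")
})

test_that("leakage percentages follow the per-MU normalisation arithmetic", {
  mk <- function(val, n = 101, sp = 4) DoseImage(matrix(val, n, n), sp)
  r <- analyzeLeakage(mk(1), mk(1), leakMU = 10000, refMU = 100)
  expect_equal(r$avgLeakagePct, 1)
  expect_equal(r$maxLeakagePct, 1)
  # closed-MLC film at 8% of the reference CAX dose, same MU ratio
  r2 <- analyzeLeakage(mk(0.08), mk(1), 10000, 100)
  expect_equal(r2$avgLeakagePct, 0.08)
  # invariance under joint rescaling of the dose units
  r3 <- analyzeLeakage(mk(0.08 * 37), mk(37), 10000, 100)
  expect_equal(r3$avgLeakagePct, r2$avgLeakagePct)
  expect_equal(r3$maxLeakagePct, r2$maxLeakagePct)
  expect_error(analyzeLeakage(mk(1, n = 11), mk(1, n = 11), roiMM = c(300, 300)),
               "bounds")
})

test_that("sliding-window leakage maximum matches the exhaustive oracle", {
  set.seed(5)
  for (trial in 1:5) {
    m <- matrix(runif(2500), 50, 50)
    img <- DoseImage(m, 1)
    ref <- DoseImage(matrix(1, 50, 50), 1)
    r <- analyzeLeakage(img, ref, 1, 1, roiMM = c(40, 40),
                        maxWindowMM = c(10, 10))
    expect_equal(r$maxLeakagePct, 100 * oracleMaxWindowMean(m, 10, 10),
                 tolerance = 1e-10)
  }
})

test_that("film field size reports the FWHM of both central profiles", {
  mkField <- function(wx, wy, sp = 0.25, edge = 0.3) {
    xs <- (seq_len(121) - 61) * sp
    img <- outer(plogis((wy * 5 - abs(xs)) / edge),
                 plogis((wx * 5 - abs(xs)) / edge))
    DoseImage(img, sp)
  }
  fs <- mkField(0.83, 0.83) |> measureFieldSizeFilm()
  expect_lt(abs(fs$crossPlaneCM - 0.83), 0.025)
  expect_lt(abs(fs$inPlaneCM - 0.83), 0.025)
  # the mis-shaped smallest field: 0.34 cm x 0.80 cm
  fs2 <- mkField(0.34, 0.80) |> measureFieldSizeFilm()
  expect_lt(abs(fs2$crossPlaneCM - 0.34), 0.025)
  expect_lt(abs(fs2$inPlaneCM - 0.80), 0.025)
  # FWHM is invariant under intensity scaling
  img <- mkField(0.83, 0.83)
  scaled <- DoseImage(imageValues(img) * 7.3, pixelSpacing(img))
  expect_equal(measureFieldSizeFilm(scaled), fs)
  expect_error(measureFieldSizeFilm(DoseImage(matrix(0, 10, 10), 1)),
               "half max")
})
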