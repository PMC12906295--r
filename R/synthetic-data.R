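## Synthetic generators for every input the analyses need, with known ground
## truth, emulating the measurement set of a 0.35 T MR-Linac acceptance test.

#' Generate a synthetic starshot film
#'
#' Renders one high-dose strip per gantry angle, each a straight line through
#' (or offset from) the film centre, emulating a star pattern delivered with
#' narrow fields at successive gantry angles.  A strip at angle \eqn{\theta}
#' with signed perpendicular offset \eqn{d} is the set of points whose
#' distance to the line through `centerMM` with direction
#' \eqn{(\cos\theta, \sin\theta)}, shifted by \eqn{d} along the left normal
#' \eqn{(-\sin\theta, \cos\theta)}, is below half the strip width.  With
#' offsets of magnitude \eqn{r} and signs alternating so the signed normals
#' positively span the plane (e.g. `r * c(1, -1, 1, -1, 1)` for the default
#' angles), the centrelines are tangent to a circle of radius \eqn{r} about
#' `centerMM` and that circle is the minimum tangent circle the starshot
#' analysis must recover; all-zero offsets give concurrent lines and radius
#' zero.
#'
#' @param centerMM film-frame centre of the star, mm `(x, y)`.
#' @param spokeAnglesDeg spoke angles, degrees, distinct modulo 180.
#' @param spokeWidthMM strip full width, mm.
#' @param spokeOffsetsMM signed perpendicular offset per spoke, mm (recycled).
#' @param imageSizePx raster size `(rows, cols)`.
#' @param pixelSpacingMM mm per pixel.
#' @param noiseSD additive Gaussian noise SD in dose units.
#' @param seed integer seed; identical parameters and seed give identical output.
#' @param doseMax peak strip dose (arbitrary units).
#' @param edgeMM soft (Gaussian) strip edge scale, mm.
#' @return [DoseImage-class] with `groundTruth` listing the injected centre,
#'   angles and offsets.
#' @examples
#' film <- genStarshotFilm(spokeOffsetsMM = 0.6, seed = 1)
#' groundTruth(film)$spokeOffsetsMM
#' @export
genStarshotFilm <- function(centerMM = c(0, 0),
                            spokeAnglesDeg = seq(0, 144, by = 36),
                            spokeWidthMM = 10,
                            spokeOffsetsMM = 0,
                            imageSizePx = c(221, 221),
                            pixelSpacingMM = 0.5,
                            noiseSD = 0,
                            seed = 1,
                            doseMax = 1,
                            edgeMM = 0.4) {
  stopifnot(pixelSpacingMM > 0, spokeWidthMM > 0, noiseSD >= 0)
  ang <- spokeAnglesDeg %% 180
  if (anyDuplicated(round(ang, 6))) {
    stop("spoke angles must be distinct modulo 180 degrees", call. = FALSE)
  }
  offs <- rep_len(spokeOffsetsMM, length(spokeAnglesDeg))
  nr <- imageSizePx[1]; nc <- imageSizePx[2]
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixelSpacingMM
  ys <- (seq_len(nr) - (nr + 1) / 2) * pixelSpacingMM
  X <- matrix(xs, nr, nc, byrow = TRUE) - centerMM[1]
  Y <- matrix(ys, nr, nc) - centerMM[2]
  img <- matrix(0, nr, nc)
  for (k in seq_along(spokeAnglesDeg)) {
    th <- spokeAnglesDeg[k] * pi / 180
    # signed distance to the offset centreline, along the left normal
    dist <- -sin(th) * X + cos(th) * Y - offs[k]
    prof <- doseMax * plogis((spokeWidthMM / 2 - abs(dist)) / edgeMM)
    img <- pmax(img, prof)
  }
  if (noiseSD > 0) {
    img <- .withSeed(seed, img + matrix(rnorm(nr * nc, 0, noiseSD), nr, nc))
    img <- pmax(img, 0)
  }
  DoseImage(img, pixelSpacingMM,
            groundTruth = list(centerMM = centerMM,
                               spokeAnglesDeg = spokeAnglesDeg,
                               spokeOffsetsMM = offs,
                               spokeWidthMM = spokeWidthMM))
}

#' Generate a synthetic picket-fence film
#'
#' One in-plane strip per nominal cross-plane position, each displaced by its
#' injected shift, emulating a 1 cm x 24 cm MLC strip pattern delivered at
#' several carriage positions.
#'
#' @param nominalPositionsCM nominal strip centres along the cross-plane
#'   axis, cm.
#' @param injectedShiftsMM signed displacement per strip, mm (same length).
#' @param stripWidthMM strip full width, mm.
#' @param imageSizePx raster size `(rows, cols)`.
#' @param pixelSpacingMM mm per pixel.
#' @param noiseSD additive Gaussian noise SD.
#' @param seed integer seed.
#' @param edgeMM Gaussian-softened strip edge scale, mm.
#' @return [DoseImage-class]; `groundTruth` records nominals and shifts.
#' @export
genPicketFenceFilm <- function(nominalPositionsCM = c(-12, -8, -4, 0, 4, 8, 12),
                               injectedShiftsMM = rep(0, length(nominalPositionsCM)),
                               stripWidthMM = 10,
                               imageSizePx = c(101, 551),
                               pixelSpacingMM = 0.5,
                               noiseSD = 0,
                               seed = 1,
                               edgeMM = 0.6) {
  if (length(nominalPositionsCM) != length(injectedShiftsMM)) {
    stop("nominal positions and injected shifts must have equal length",
         call. = FALSE)
  }
  centres <- nominalPositionsCM * 10 + injectedShiftsMM
  if (length(centres) > 1) {
    gaps <- diff(sort(centres))
    if (any(gaps <= stripWidthMM)) {
      stop("strips overlap: centre gaps must exceed the strip width",
           call. = FALSE)
    }
  }
  nr <- imageSizePx[1]; nc <- imageSizePx[2]
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixelSpacingMM
  row <- rep(0, nc)
  for (c0 in centres) {
    row <- row + plogis((stripWidthMM / 2 - abs(xs - c0)) / edgeMM)
  }
  img <- matrix(row, nr, nc, byrow = TRUE)
  if (noiseSD > 0) {
    img <- .withSeed(seed, img + matrix(rnorm(nr * nc, 0, noiseSD), nr, nc))
    img <- pmax(img, 0)
  }
  DoseImage(img, pixelSpacingMM,
            groundTruth = list(nominalPositionsCM = nominalPositionsCM,
                               injectedShiftsMM = injectedShiftsMM,
                               stripWidthMM = stripWidthMM))
}

#' Generate a synthetic FFF field profile
#'
#' A symmetric plateau with logistic sigmoid edges centred at half the
#' nominal width, optionally topped by a shallow quadratic dome emulating an
#' unflattened (FFF) beam.  The edge position is corrected analytically so
#' that the noiseless FWHM equals `nominalWidthCM` even with a nonzero dome:
#' the half-maximum level of a domed profile is \eqn{(1+a)/2} of the plateau,
#' so each edge is pushed out by \eqn{s \log((1+a)/(1-a))}.
#'
#' A pure logistic edge of scale \eqn{s} has 20--80 penumbra \eqn{2 s \log 4}.
#'
#' @param nominalWidthCM nominal field width, cm.
#' @param edgeScaleMM logistic edge scale \eqn{s}, mm.
#' @param fffPeakFraction dome height as a fraction of the plateau, in
#'   `[0, 1)`; 0 gives a flat top.
#' @param samplingStepMM sample spacing, mm; must resolve the edges
#'   (`samplingStepMM <= edgeScaleMM`).
#' @param noiseSD additive Gaussian noise SD (value units; plateau is 1).
#' @param extentCM half-extent of the sampled axis, cm; default covers the
#'   field plus margin.
#' @param axis profile axis label.
#' @param seed integer seed (used only when `noiseSD > 0`).
#' @return [BeamProfile-class] in cm; `groundTruth` records the parameters.
#' @export
genFieldProfile <- function(nominalWidthCM = 9.96,
                            edgeScaleMM = 2,
                            fffPeakFraction = 0.05,
                            samplingStepMM = 0.5,
                            noiseSD = 0,
                            extentCM = nominalWidthCM / 2 + 3,
                            axis = "cross_plane",
                            seed = 1) {
  stopifnot(nominalWidthCM > 0, edgeScaleMM > 0,
            fffPeakFraction >= 0, fffPeakFraction < 1)
  if (samplingStepMM > edgeScaleMM) {
    stop("sampling step must not exceed the edge scale", call. = FALSE)
  }
  xmm <- seq(-extentCM * 10, extentCM * 10, by = samplingStepMM)
  wmm <- nominalWidthCM * 10
  s <- edgeScaleMM
  a <- fffPeakFraction
  half <- wmm / 2 + s * log((1 + a) / (1 - a))
  base <- plogis((xmm + half) / s) * plogis((half - xmm) / s)
  dome <- 1 + a * pmax(0, 1 - (2 * xmm / wmm)^2)
  v <- base * dome
  if (noiseSD > 0) v <- pmax(0, .withSeed(seed, v + rnorm(length(v), 0, noiseSD)))
  BeamProfile(xmm / 10, v, axis = axis,
              groundTruth = list(nominalWidthCM = nominalWidthCM,
                                 edgeScaleMM = edgeScaleMM,
                                 fffPeakFraction = fffPeakFraction,
                                 samplingStepMM = samplingStepMM))
}

#' Generate a synthetic resonance spectrum
#'
#' Magnitude peak of declared line shape and FWHM around a central frequency,
#' emulating the Larmor-peak frequency profile used for B0 homogeneity.
#'
#' @param centerFrequencyHz peak centre, Hz.
#' @param fwhmHz full width at half maximum of the noiseless peak, Hz.
#' @param lineShape `"gaussian"` or `"lorentzian"`.
#' @param samplingStepHz sample spacing, Hz; must satisfy
#'   `samplingStepHz <= fwhmHz / 10`.
#' @param spanFWHM sampled span on each side of the centre, in FWHM units.
#' @param noiseSD additive Gaussian noise SD (peak magnitude is 1).
#' @param nominalF0 nominal central frequency stored on the spectrum, Hz.
#' @param seed integer seed.
#' @return [SpectrumProfile-class]; `groundTruth` records the parameters.
#' @export
genSpectrum <- function(centerFrequencyHz = 14701760,
                        fwhmHz = 50,
                        lineShape = c("gaussian", "lorentzian"),
                        samplingStepHz = fwhmHz / 20,
                        spanFWHM = 6,
                        noiseSD = 0,
                        nominalF0 = centerFrequencyHz,
                        seed = 1) {
  lineShape <- match.arg(lineShape)
  stopifnot(centerFrequencyHz > 0, fwhmHz > 0, noiseSD >= 0)
  if (samplingStepHz > fwhmHz / 10) {
    stop("sampling step must be at most FWHM/10", call. = FALSE)
  }
  f <- seq(centerFrequencyHz - spanFWHM * fwhmHz,
           centerFrequencyHz + spanFWHM * fwhmHz, by = samplingStepHz)
  d <- f - centerFrequencyHz
  mag <- switch(lineShape,
    gaussian = exp(-4 * log(2) * (d / fwhmHz)^2),
    lorentzian = 1 / (1 + (2 * d / fwhmHz)^2)
  )
  if (noiseSD > 0) mag <- pmax(0, .withSeed(seed, mag + rnorm(length(mag), 0, noiseSD)))
  SpectrumProfile(f, mag, nominalF0 = nominalF0,
                  groundTruth = list(centerFrequencyHz = centerFrequencyHz,
                                     fwhmHz = fwhmHz, lineShape = lineShape,
                                     samplingStepHz = samplingStepHz))
}

#' Generate a uniform-sphere phantom image
#'
#' Constant signal plus additive Gaussian noise, emulating the central slice
#' of a 24 cm uniform spherical phantom for SNR/uniformity checks.
#'
#' @param mean mean signal.
#' @param noiseSD noise standard deviation.
#' @param sizePx raster size `(rows, cols)`.
#' @param pixelSpacingMM mm per pixel.
#' @param seed integer seed.
#' @return [GrayImage-class]; `groundTruth` records `mean` and `noiseSD`.
#' @export
genUniformPhantomImage <- function(mean = 100, noiseSD = 1,
                                   sizePx = c(128, 128),
                                   pixelSpacingMM = 1.5, seed = 1) {
  stopifnot(noiseSD >= 0)
  v <- matrix(mean, sizePx[1], sizePx[2])
  if (noiseSD > 0) {
    v <- .withSeed(seed, v + matrix(rnorm(prod(sizePx), 0, noiseSD),
                                    sizePx[1], sizePx[2]))
  }
  GrayImage(v, pixelSpacingMM,
            groundTruth = list(mean = mean, noiseSD = noiseSD))
}

#' Generate a grid-phantom image with a controllable distortion field
#'
#' Gaussian marker blobs on a regular grid, each displaced by a supplied
#' distortion field, emulating a spatial-integrity phantom slice.
#'
#' @param markerSpacingMM nominal marker spacing, mm; must exceed
#'   `4 * pixelSpacingMM`.
#' @param extentMM half-extent of the marker grid `(x, y)`, mm.
#' @param distortionField `function(x, y)` returning a 2-column matrix of
#'   displacements (mm) for vectors of nominal positions; `NULL` = identity.
#' @param pixelSpacingMM mm per pixel.
#' @param markerSigmaMM Gaussian blob sigma, mm.
#' @return [GrayImage-class]; `groundTruth` records nominal and displaced
#'   marker positions.
#' @export
genGridPhantomImage <- function(markerSpacingMM = 20,
                                extentMM = c(60, 60),
                                distortionField = NULL,
                                pixelSpacingMM = 1,
                                markerSigmaMM = 2) {
  if (markerSpacingMM <= 4 * pixelSpacingMM) {
    stop("marker spacing must exceed 4 pixels", call. = FALSE)
  }
  gx <- seq(-extentMM[1], extentMM[1], by = markerSpacingMM)
  gy <- seq(-extentMM[2], extentMM[2], by = markerSpacingMM)
  nom <- as.matrix(expand.grid(x = gx, y = gy))
  disp <- if (is.null(distortionField)) {
    matrix(0, nrow(nom), 2)
  } else {
    d <- distortionField(nom[, 1], nom[, 2])
    stopifnot(is.matrix(d), nrow(d) == nrow(nom), ncol(d) == 2)
    d
  }
  act <- nom + disp
  halfspan <- apply(abs(act), 2, max) + 4 * markerSigmaMM
  nc <- 2 * ceiling(halfspan[1] / pixelSpacingMM) + 1
  nr <- 2 * ceiling(halfspan[2] / pixelSpacingMM) + 1
  xs <- (seq_len(nc) - (nc + 1) / 2) * pixelSpacingMM
  ys <- (seq_len(nr) - (nr + 1) / 2) * pixelSpacingMM
  img <- matrix(0, nr, nc)
  for (k in seq_len(nrow(act))) {
    img <- img + outer(exp(-(ys - act[k, 2])^2 / (2 * markerSigmaMM^2)),
                       exp(-(xs - act[k, 1])^2 / (2 * markerSigmaMM^2)))
  }
  GrayImage(img, pixelSpacingMM,
            groundTruth = list(nominal = nom, actual = act,
                               markerSpacingMM = markerSpacingMM,
                               markerSigmaMM = markerSigmaMM))
}

#' Generate a sinusoidal motion trace with gated beam state
#'
#' Sinusoidal longitudinal target motion sampled at the cine frame rate, with
#' the beam gated on while the target sits below the gating boundary.  The
#' recorded beam state switches `injectedLatencyS` seconds after each true
#' boundary crossing, then is sampled at the frames — the latency the paired
#' analysis must recover.
#'
#' @param amplitudeMM motion amplitude, mm.
#' @param periodS motion period, s.
#' @param frameRateFPS cine frame rate, frames/s.
#' @param gatingBoundaryMM gating boundary, mm; beam on while
#'   `position <= boundary`.
#' @param injectedLatencyS beam-state reaction delay, s.
#' @param durationS trace duration, s; must be at least two periods.
#' @param noiseSD positional noise SD, mm.
#' @param seed integer seed.
#' @return [MotionTrace-class]; `groundTruth` records the injected latency
#'   and the exact boundary-crossing times.
#' @export
genMotionTrace <- function(amplitudeMM = 12, periodS = 4, frameRateFPS = 4,
                           gatingBoundaryMM = 3, injectedLatencyS = 0.1,
                           durationS = 40, noiseSD = 0, seed = 1) {
  stopifnot(amplitudeMM > 0, periodS > 0, frameRateFPS > 0,
            injectedLatencyS >= 0)
  if (durationS < 2 * periodS) {
    stop("duration must cover at least two motion periods", call. = FALSE)
  }
  t <- seq(0, durationS, by = 1 / frameRateFPS)
  pos <- amplitudeMM * sin(2 * pi * t / periodS)
  # exact upward crossings of the boundary (target exits the gate)
  phi <- asin(pmin(1, pmax(-1, gatingBoundaryMM / amplitudeMM)))
  k <- 0:ceiling(durationS / periodS)
  exitT <- periodS * (phi / (2 * pi) + k)
  exitT <- exitT[exitT >= 0 & exitT <= durationS]
  entryT <- periodS * ((pi - phi) / (2 * pi) + k)
  entryT <- entryT[entryT >= 0 & entryT <= durationS]
  # beam state with delayed reaction, evaluated at frame times
  stateAt <- function(tt) {
    td <- tt - injectedLatencyS
    amplitudeMM * sin(2 * pi * td / periodS) <= gatingBoundaryMM
  }
  beam <- stateAt(t)
  if (noiseSD > 0) pos <- .withSeed(seed, pos + rnorm(length(pos), 0, noiseSD))
  MotionTrace(t, pos, beam,
              groundTruth = list(amplitudeMM = amplitudeMM, periodS = periodS,
                                 frameRateFPS = frameRateFPS,
                                 gatingBoundaryMM = gatingBoundaryMM,
                                 injectedLatencyS = injectedLatencyS,
                                 exitTimesS = exitT, entryTimesS = entryT))
}
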