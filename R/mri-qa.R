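## MR-side analyses: B0 homogeneity from spectra, NEMA SNR/uniformity,
## ACR-style image-quality metrics, and grid-phantom spatial integrity.

#' B0 homogeneity from a resonance spectrum
#'
#' The spectral linewidth (FWHM, Hz) of the Larmor peak is found from
#' linearly interpolated half-maximum crossings and converted to parts per
#' million of the central frequency:
#' \deqn{ppm = FWHM(Hz) / f_0 \times 10^6.}  The central frequency is either
#' the spectrum's nominal value (`cfMode = "nominal"`, default) or the
#' interpolated peak location (`"peak"`).
#'
#' @param spectrum a [SpectrumProfile-class].
#' @param cfMode `"nominal"` or `"peak"`.
#' @param tolerancePPM homogeneity tolerance (default 5 ppm over a 24 cm
#'   spherical volume).
#' @param smoothBins odd moving-average window (bins) applied to the
#'   magnitude before the half-maximum search; `1` (default) disables
#'   smoothing.  Useful for noisy spectra where noise near the half level
#'   would otherwise produce spurious crossings.
#' @return list of class `"HomogeneityResult"`: `fwhmHz`, `ppm`, `cfUsedHz`,
#'   `withinTolerance`.
#' @examples
#' sp <- genSpectrum(centerFrequencyHz = 14713851, fwhmHz = 83.21,
#'                   nominalF0 = 14713851)
#' spectralHomogeneity(sp)$ppm  # ~5.66
#' @export
spectralHomogeneity <- function(spectrum, cfMode = c("nominal", "peak"),
                                tolerancePPM = 5, smoothBins = 1) {
  cfMode <- match.arg(cfMode)
  stopifnot(is(spectrum, "SpectrumProfile"))
  f <- spectrum@frequency
  m <- .maybeSmooth(spectrum@magnitude, smoothBins)
  base <- min(m)
  if (max(m) <= 2 * max(base, .Machine$double.eps)) {
    stop("peak magnitude must exceed twice the baseline", call. = FALSE)
  }
  cr <- .levelWidth(f, m, max(m) / 2, "spectrum")
  fw <- cr[2] - cr[1]
  cf <- if (cfMode == "nominal") spectrum@nominalF0 else .parabolicPeak(f, m)
  res <- list(fwhmHz = fw, ppm = fw / cf * 1e6, cfUsedHz = cf,
              withinTolerance = (fw / cf * 1e6) <= tolerancePPM)
  class(res) <- "HomogeneityResult"
  res
}

#' @export
print.HomogeneityResult <- function(x, ...) {
  cat(sprintf("B0 homogeneity: FWHM %.2f Hz at f0 %.6g Hz -> %.1f ppm (%s)\n",
              x$fwhmHz, x$cfUsedHz, x$ppm,
              if (x$withinTolerance) "within tolerance" else "out of tolerance"))
  invisible(x)
}

#' Check the central frequency against its permissible range
#'
#' @param f0Hz measured central frequency, Hz.
#' @param nominalHz nominal central frequency (default 14,701,760 Hz).
#' @param tolHz permitted deviation (default 15,000 Hz, i.e. 0.015 MHz).
#' @return `TRUE` iff `f0Hz` lies within the closed permissible range.
#' @examples
#' checkCentralFrequency(14701760)
#' @export
checkCentralFrequency <- function(f0Hz, nominalHz = 14701760, tolHz = 15000) {
  f0Hz >= nominalHz - tolHz & f0Hz <= nominalHz + tolHz
}

## Rectangular ROI selector: roi = list(centerMM = c(x, y), sizeMM = c(w, h)).
.roiValues <- function(image, roi) {
  co <- pixelCoords(image)
  ctr <- roi$centerMM %||% c(0, 0)
  sz <- roi$sizeMM
  if (is.null(sz)) stop("ROI needs a sizeMM", call. = FALSE)
  selx <- abs(co$x - ctr[1]) <= sz[1] / 2
  sely <- abs(co$y - ctr[2]) <= sz[2] / 2
  if (!any(selx) || !any(sely)) stop("ROI outside image", call. = FALSE)
  imageValues(image)[sely, selx, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' ROI summary statistics
#'
#' @param image a [RasterImage-class].
#' @param roi list with `centerMM` (default image centre) and `sizeMM`, mm.
#' @return list: `mean`, `sd`, `min`, `max`, `n`, and the ROI geometry.
#' @export
roiStats <- function(image, roi) {
  v <- .roiValues(image, roi)
  list(mean = mean(v), sd = sd(as.vector(v)), min = min(v), max = max(v),
       n = length(v), roi = roi)
}

#' NEMA signal-to-noise ratio
#'
#' \deqn{SNR = 0.66 \times \bar{S}_{signal} / \sigma_{noise}} with the signal
#' mean over a central phantom ROI and the noise SD from a background ROI
#' (single-image method).
#'
#' @param image a [GrayImage-class].
#' @param signalROI,noiseROI ROI lists (`centerMM`, `sizeMM`, mm).
#' @return SNR (dimensionless).
#' @examples
#' img <- genUniformPhantomImage(mean = 100, noiseSD = 1, seed = 1)
#' roi <- list(sizeMM = c(120, 120))
#' snr(img, roi, roi)  # ~66
#' @export
snr <- function(image, signalROI, noiseROI) {
  s <- mean(.roiValues(image, signalROI))
  n <- sd(as.vector(.roiValues(image, noiseROI)))
  if (!is.finite(n) || n <= 0) stop("noise SD must be positive", call. = FALSE)
  0.66 * s / n
}

#' NEMA percent uniformity
#'
#' \deqn{U\% = 100 (1 - (S_{max} - S_{min}) / (S_{max} + S_{min}))} computed
#' on the ROI after a mean pre-filter (default 3 x 3 pixels) that suppresses
#' single-pixel noise, per NEMA practice.
#'
#' @param image a [GrayImage-class].
#' @param roi ROI list (`centerMM`, `sizeMM`, mm).
#' @param prefilterPx odd box-filter side in pixels; 1 disables filtering.
#' @return uniformity, percent.
#' @examples
#' img <- genUniformPhantomImage(noiseSD = 0)
#' uniformity(img, list(sizeMM = c(100, 100)))  # 100
#' @export
uniformity <- function(image, roi, prefilterPx = 3) {
  v <- .roiValues(image, roi)
  stopifnot(prefilterPx >= 1, prefilterPx %% 2 == 1)
  if (prefilterPx > 1 && all(dim(v) >= prefilterPx)) {
    v <- .windowMeans(v, prefilterPx, prefilterPx)
  }
  hi <- max(v); lo <- min(v)
  if (hi + lo == 0) stop("max + min is zero", call. = FALSE)
  100 * (1 - (hi - lo) / (hi + lo))
}

#' ACR percent signal ghosting
#'
#' Standard four-ROI formula:
#' \deqn{PSG = |(T + B) - (L + R)| / (2 \bar{S}_{centre})} using the mean of
#' the top, bottom, left and right background ROIs and the centre phantom
#' ROI.
#'
#' @param image a [GrayImage-class].
#' @param centerROI phantom-centre ROI list.
#' @param edgeROIs named list of the four background ROIs: `top`, `bottom`,
#'   `left`, `right`.
#' @return ghosting fraction (not percent).
#' @export
percentSignalGhosting <- function(image, centerROI, edgeROIs) {
  stopifnot(all(c("top", "bottom", "left", "right") %in% names(edgeROIs)))
  ctr <- mean(.roiValues(image, centerROI))
  if (ctr <= 0) stop("centre ROI mean must be positive", call. = FALSE)
  m <- vapply(edgeROIs[c("top", "bottom", "left", "right")],
              function(r) mean(.roiValues(image, r)), numeric(1))
  abs((m[["top"]] + m[["bottom"]]) - (m[["left"]] + m[["right"]])) / (2 * ctr)
}

#' ACR percent integral uniformity
#'
#' \deqn{PIU = 100 (1 - (high - low) / (high + low))} on the pre-filtered
#' ROI's extreme window means (same measurement core as [uniformity()]).
#'
#' @inheritParams uniformity
#' @return PIU, percent.
#' @export
percentIntegralUniformity <- function(image, roi, prefilterPx = 3) {
  uniformity(image, roi, prefilterPx)
}

#' ACR slice thickness from ramp lengths
#'
#' \deqn{thickness = 0.2 \cdot (top \cdot bottom) / (top + bottom)} from the
#' measured signal-ramp lengths in the ACR phantom insert.
#'
#' @param topLenMM,bottomLenMM ramp lengths, mm (positive).
#' @return slice thickness, mm.
#' @examples
#' sliceThickness(60, 50)  # 5.4545...
#' @export
sliceThickness <- function(topLenMM, bottomLenMM) {
  if (any(topLenMM <= 0) || any(bottomLenMM <= 0)) {
    stop("ramp lengths must be positive", call. = FALSE)
  }
  0.2 * (topLenMM * bottomLenMM) / (topLenMM + bottomLenMM)
}

#' ACR slice position from bar-length difference
#'
#' @param barDiffMM signed difference between the two bar lengths, mm.
#' @return slice-position error, mm (half the bar difference).
#' @export
slicePosition <- function(barDiffMM) {
  barDiffMM / 2
}

#' Grid-phantom spatial integrity
#'
#' Detects each marker by the local intensity centre of mass in a window
#' around its nominal position and reports the deviation
#' \eqn{|detected - nominal|} per marker, overall, and grouped by distance
#' from the isocenter.
#'
#' @param image a [GrayImage-class] grid-phantom image.
#' @param nominal 2-column matrix of nominal marker positions, mm; defaults
#'   to the generator ground truth carried by `image`.
#' @param dsvRadiiMM increasing radii (mm) bounding the radial bins.
#' @param windowMM half-width of the detection window, mm; default 0.4 x the
#'   nominal marker spacing.
#' @param minDetectedFrac minimum fraction of markers that must be detected.
#' @return list of class `"DistortionResult"`: `deviationsMM`, `meanMM`,
#'   `maxMM`, `radiusBins` (data.frame), `detected` (matrix).
#' @export
spatialIntegrity <- function(image, nominal = NULL,
                             dsvRadiiMM = c(50, 100, 175),
                             windowMM = NULL, minDetectedFrac = 0.9) {
  stopifnot(is(image, "RasterImage"))
  gt <- groundTruth(image)
  if (is.null(nominal)) {
    if (is.null(gt$nominal)) stop("no nominal marker grid supplied", call. = FALSE)
    nominal <- gt$nominal
  }
  nominal <- as.matrix(nominal)
  if (is.null(windowMM)) {
    sp <- if (!is.null(gt$markerSpacingMM)) gt$markerSpacingMM else {
      min(dist(nominal))
    }
    windowMM <- 0.4 * sp
  }
  v <- imageValues(image)
  co <- pixelCoords(image)
  bg <- quantile(v, 0.2)
  det <- matrix(NA_real_, nrow(nominal), 2)
  for (k in seq_len(nrow(nominal))) {
    selx <- which(abs(co$x - nominal[k, 1]) <= windowMM)
    sely <- which(abs(co$y - nominal[k, 2]) <= windowMM)
    if (!length(selx) || !length(sely)) next
    sub <- v[sely, selx, drop = FALSE]
    w <- pmax(sub - bg, 0)
    if (sum(w) <= 0 || max(sub) < bg + 0.1 * (max(v) - bg)) next
    det[k, 1] <- sum(outer(rep(1, length(sely)), co$x[selx]) * w) / sum(w)
    det[k, 2] <- sum(outer(co$y[sely], rep(1, length(selx))) * w) / sum(w)
  }
  ok <- !is.na(det[, 1])
  if (mean(ok) < minDetectedFrac) {
    missing <- which(!ok)
    stop(sprintf("only %.0f%% of markers detected; missing indices: %s",
                 100 * mean(ok), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  dev <- sqrt(rowSums((det[ok, , drop = FALSE] -
                       nominal[ok, , drop = FALSE])^2))
  r <- sqrt(rowSums(nominal[ok, , drop = FALSE]^2))
  bin <- findInterval(r, dsvRadiiMM, rightmost.closed = FALSE) + 1
  labs <- c(paste0("<=", dsvRadiiMM, "mm"), paste0(">", max(dsvRadiiMM), "mm"))
  bins <- data.frame(bin = labs[sort(unique(bin))],
                     n = as.vector(table(bin)),
                     meanMM = as.vector(tapply(dev, bin, mean)),
                     maxMM = as.vector(tapply(dev, bin, max)))
  res <- list(deviationsMM = dev, meanMM = mean(dev), maxMM = max(dev),
              radiusBins = bins, detected = det)
  class(res) <- "DistortionResult"
  res
}

#' @export
print.DistortionResult <- function(x, ...) {
  cat(sprintf("Spatial integrity: %d markers, mean %.3f mm, max %.3f mm\n",
              length(x$deviationsMM), x$meanMM, x$maxMM))
  invisible(x)
}
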