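## 1-D/2-D dose-distribution analytics: FWHM field size, penumbra,
## flatness/symmetry, field output factors, and the 2-D gamma index.

#' Full width at half maximum of a beam profile
#'
#' Half-maximum crossings are located by linear interpolation; the profile
#' must cross its half-maximum exactly twice (single dominant lobe).
#'
#' @param profile a [BeamProfile-class].
#' @param smoothWindow optional odd moving-average window length (samples);
#'   `NULL` (default) applies no smoothing.
#' @return field width, cm.
#' @examples
#' p <- genFieldProfile(nominalWidthCM = 9.96, fffPeakFraction = 0)
#' fwhm(p)
#' @export
fwhm <- function(profile, smoothWindow = NULL) {
  stopifnot(is(profile, "BeamProfile"))
  x <- profilePositions(profile)
  y <- .maybeSmooth(profileValues(profile), smoothWindow)
  if (max(y) <= 0) stop("profile maximum must be positive", call. = FALSE)
  cr <- .levelWidth(x, y, max(y) / 2, "beam profile")
  cr[2] - cr[1]
}

.maybeSmooth <- function(y, window) {
  if (is.null(window)) return(y)
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(y)
  as.numeric(stats::filter(y, rep(1 / window, window), sides = 2)) |>
    (\(s) ifelse(is.na(s), y, s))()
}

#' Measured-minus-TPS field size difference
#'
#' @param measuredCM,tpsCM positive field sizes, cm.
#' @return `measuredCM - tpsCM`, cm.
#' @export
fieldSizeDifference <- function(measuredCM, tpsCM) {
  stopifnot(all(measuredCM > 0), all(tpsCM > 0))
  measuredCM - tpsCM
}

#' 20--80% penumbra of a beam profile
#'
#' For each field edge, the lateral distance between the linearly
#' interpolated 20% and 80% crossings of the profile maximum.  With
#' `normalize = TRUE` the profile is first rescaled to 100 at its maximum
#' (the convention used for larger fields); thresholds are relative to the
#' maximum either way, so the widths are identical — the flag records the
#' reporting convention.
#'
#' @param profile a [BeamProfile-class].
#' @param normalize logical; rescale to 100 at the maximum first.
#' @param smoothWindow optional odd moving-average window (samples).
#' @return list of class `"PenumbraResult"`: `leftMM`, `rightMM`, `meanMM`,
#'   `normalized`.
#' @examples
#' p <- genFieldProfile(edgeScaleMM = 2, fffPeakFraction = 0)
#' penumbra(p)$meanMM  # ~ 2 * 2 * log(4)
#' @export
penumbra <- function(profile, normalize = TRUE, smoothWindow = NULL) {
  stopifnot(is(profile, "BeamProfile"))
  x <- profilePositions(profile) * 10   # cm -> mm
  y <- .maybeSmooth(profileValues(profile), smoothWindow)
  if (max(y) <= 0) stop("profile maximum must be positive", call. = FALSE)
  if (normalize) y <- 100 * y / max(y)
  top <- max(y)
  cr20 <- .levelWidth(x, y, 0.2 * top, "profile at 20%")
  cr80 <- .levelWidth(x, y, 0.8 * top, "profile at 80%")
  left <- cr80[1] - cr20[1]
  right <- cr20[2] - cr80[2]
  if (left <= 0 || right <= 0) {
    stop("20/80 crossings are not ordered; edge not resolved", call. = FALSE)
  }
  res <- list(leftMM = left, rightMM = right, meanMM = (left + right) / 2,
              normalized = normalize)
  class(res) <- "PenumbraResult"
  res
}

#' @export
print.PenumbraResult <- function(x, ...) {
  cat(sprintf("Penumbra 20-80%%: left %.2f mm, right %.2f mm, mean %.2f mm%s\n",
              x$leftMM, x$rightMM, x$meanMM,
              if (x$normalized) " (normalized)" else ""))
  invisible(x)
}

#' Pointwise flatness and per-pair symmetry of off-axis ratios
#'
#' For measured (M) and TPS off-axis ratios supplied at symmetric off-axis
#' points, computes per point the flatness difference \eqn{F = M - TPS} and
#' per \eqn{\pm}OAP pair the symmetry \eqn{S = M(-OAP) - M(+OAP)}, with
#' verdicts against a \eqn{\pm 2\%} tolerance on both.
#'
#' @param oapCM signed off-axis positions, cm; every `+p` needs a `-p`.
#' @param measuredPct measured off-axis ratios, percent of CAX.
#' @param tpsPct TPS-calculated ratios, percent of CAX.
#' @param tolerancePct tolerance applied to `|F|` and `|S|` (default 2).
#' @return data.frame with one row per point: `oapCM`, `tpsPct`,
#'   `measuredPct`, `flatnessDiffPct`, `symmetryPct` (reported on each pair's
#'   rows), `flatnessPass`, `symmetryPass`.
#' @examples
#' flatnessSymmetry(c(-2, 2), c(97.49, 97.64), c(97.82, 97.85))
#' @export
flatnessSymmetry <- function(oapCM, measuredPct, tpsPct, tolerancePct = 2) {
  stopifnot(length(oapCM) == length(measuredPct),
            length(oapCM) == length(tpsPct))
  key <- round(abs(oapCM), 8)
  for (k in unique(key)) {
    sel <- key == k
    if (sum(oapCM[sel] > 0) != 1 || sum(oapCM[sel] < 0) != 1) {
      stop(sprintf("off-axis point %.4g cm is not a +/- pair", k),
           call. = FALSE)
    }
  }
  f <- measuredPct - tpsPct
  s <- numeric(length(oapCM))
  for (k in unique(key)) {
    sel <- key == k
    sk <- measuredPct[sel & oapCM < 0] - measuredPct[sel & oapCM > 0]
    s[sel] <- sk
  }
  data.frame(oapCM = oapCM, tpsPct = tpsPct, measuredPct = measuredPct,
             flatnessDiffPct = f, symmetryPct = s,
             flatnessPass = abs(f) <= tolerancePct,
             symmetryPass = abs(s) <= tolerancePct)
}

#' Field output factor table from replicate detector readings
#'
#' Each field's replicates are averaged; the FOF is the field's mean reading
#' divided by the reference field's mean reading, so the reference FOF is 1
#' for any reading scale.
#'
#' @param readingsByField named list of numeric replicate vectors (all > 0).
#' @param referenceLabel name of the reference field in `readingsByField`.
#' @param tpsFOF optional named numeric of TPS-calculated FOFs; when present,
#'   `diffPct = 100 (measured - tps) / tps` is reported to 1 decimal.
#' @return data.frame: `fieldLabel`, `meanReading`, `fof`, and when supplied
#'   `tpsFOF`, `diffPct`.
#' @examples
#' fofTable(list(a = c(0.44, 0.45), ref = c(1.0, 1.0)), "ref")
#' @export
fofTable <- function(readingsByField, referenceLabel, tpsFOF = NULL) {
  stopifnot(is.list(readingsByField), referenceLabel %in% names(readingsByField))
  if (any(unlist(readingsByField) <= 0)) {
    stop("all readings must be positive", call. = FALSE)
  }
  means <- vapply(readingsByField, mean, 0)
  refMean <- means[[referenceLabel]]
  if (refMean <= 0) stop("reference mean reading must be positive", call. = FALSE)
  out <- data.frame(fieldLabel = names(means), meanReading = unname(means),
                    fof = unname(means) / refMean)
  if (!is.null(tpsFOF)) {
    out$tpsFOF <- unname(tpsFOF[out$fieldLabel])
    out$diffPct <- fofDifference(out$fof, out$tpsFOF)
  }
  out
}

#' Percent difference between measured and TPS output factors
#'
#' @param measuredFOF,tpsFOF output factors (tps > 0).
#' @return `100 * (measured - tps) / tps` rounded to 1 decimal.
#' @examples
#' fofDifference(0.444, 0.504)  # -11.9
#' @export
fofDifference <- function(measuredFOF, tpsFOF) {
  stopifnot(all(tpsFOF > 0))
  round(100 * (measuredFOF - tpsFOF) / tpsFOF, 1)
}

#' 2-D gamma index between dose distributions
#'
#' For each reference point, \deqn{\gamma = \min_e \sqrt{(\Delta d /
#' \Delta d_{crit})^2 + (\Delta r / DTA)^2}} over evaluation points within a
#' search radius of `3 * dtaMM`, with the evaluation image bilinearly
#' resampled to a grid no coarser than `0.1 * dtaMM`.  Global normalisation
#' takes \eqn{\Delta d_{crit}} as `doseCritPct` percent of the reference
#' maximum; local normalisation uses the local reference dose.  Reference
#' points below `lowDoseCutPct` of the reference maximum are excluded from
#' the pass rate.
#'
#' @param ref,eval [DoseImage-class] distributions with overlapping extents,
#'   dose units.
#' @param doseCritPct dose-difference criterion, percent (default 3).
#' @param dtaMM distance-to-agreement criterion, mm (default 3).
#' @param normalization `"global"` (default) or `"local"`.
#' @param lowDoseCutPct threshold below which reference points are not
#'   evaluated (default 10).
#' @return list of class `"GammaResult"`: `gammaMap` (matrix, `NA` where not
#'   evaluated), `passRatePct`, `doseCritPct`, `dtaMM`, `normalization`.
#' @export
gamma2d <- function(ref, eval, doseCritPct = 3, dtaMM = 3,
                    normalization = c("global", "local"),
                    lowDoseCutPct = 10) {
  normalization <- match.arg(normalization)
  stopifnot(is(ref, "DoseImage"), is(eval, "DoseImage"),
            doseCritPct > 0, dtaMM > 0)
  rco <- pixelCoords(ref)
  eco <- pixelCoords(eval)
  if (max(rco$x) < min(eco$x) || min(rco$x) > max(eco$x) ||
      max(rco$y) < min(eco$y) || min(rco$y) > max(eco$y)) {
    stop("reference and evaluation extents are disjoint", call. = FALSE)
  }
  rv <- imageValues(ref)
  refMax <- max(rv)
  if (refMax <= 0) stop("reference maximum must be positive", call. = FALSE)
  # fine resampling grid covering the evaluation extent; the step divides the
  # evaluation spacing so original sample positions are grid nodes
  nsub <- max(1L, ceiling(pixelSpacing(eval) / (0.1 * dtaMM)))
  step <- pixelSpacing(eval) / nsub
  fx <- seq(min(eco$x), max(eco$x), by = step)
  fy <- seq(min(eco$y), max(eco$y), by = step)
  ev <- imageValues(eval)
  fine <- matrix(.bilinear(ev, eco$x, eco$y,
                           rep(fx, each = length(fy)),
                           rep(fy, times = length(fx))),
                 nrow = length(fy), ncol = length(fx))
  radius <- 3 * dtaMM
  gmap <- matrix(NA_real_, nrow(rv), ncol(rv))
  cut <- lowDoseCutPct / 100 * refMax
  for (i in seq_len(nrow(rv))) {
    yy <- rco$y[i]
    jy <- which(abs(fy - yy) <= radius)
    if (!length(jy)) next
    dy2 <- (fy[jy] - yy)^2
    for (j in seq_len(ncol(rv))) {
      d0 <- rv[i, j]
      if (d0 < cut) next
      xx <- rco$x[j]
      jx <- which(abs(fx - xx) <= radius)
      if (!length(jx)) next
      crit <- if (normalization == "global") {
        doseCritPct / 100 * refMax
      } else {
        doseCritPct / 100 * d0
      }
      sub <- fine[jy, jx, drop = FALSE]
      dx2 <- (fx[jx] - xx)^2
      r2 <- outer(dy2, dx2, `+`)
      g2 <- ((sub - d0) / crit)^2 + r2 / dtaMM^2
      gmap[i, j] <- sqrt(min(g2, na.rm = TRUE))
    }
  }
  evaluated <- !is.na(gmap)
  if (!any(evaluated)) stop("no reference points above the low-dose cut",
                            call. = FALSE)
  res <- list(gammaMap = gmap,
              passRatePct = 100 * mean(gmap[evaluated] <= 1 + 1e-6),
              doseCritPct = doseCritPct, dtaMM = dtaMM,
              normalization = normalization)
  class(res) <- "GammaResult"
  res
}

#' @export
print.GammaResult <- function(x, ...) {
  cat(sprintf("Gamma %g%%/%g mm (%s): pass rate %.1f%%\n",
              x$doseCritPct, x$dtaMM, x$normalization, x$passRatePct))
  invisible(x)
}
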