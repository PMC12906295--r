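## Film-image analyses: calibration, starshot isocentricity, picket fence,
## MLC leakage, and small-field size measurement.

#' Apply a calibration curve to an optical-density film image
#'
#' Pixelwise application of a strictly monotone OD-to-dose mapping; geometry
#' is preserved and the result carries dose units.
#'
#' @param image a [DoseImage-class] in `"od"` units.
#' @param curve a strictly monotone `function(od) -> dose`, or a two-column
#'   matrix/data.frame of `(od, dose)` anchors interpolated linearly.
#' @param domain optional length-2 OD domain of validity; image values
#'   outside it are rejected with a range report.  Defaults to the anchor
#'   range when `curve` is tabular.
#' @return A [DoseImage-class] in `"dose"` units.
#' @examples
#' od <- DoseImage(matrix(0.5, 4, 4), 1, units = "od")
#' calibrateFilm(od, function(x) 2 * x)
#' @export
calibrateFilm <- function(image, curve, domain = NULL) {
  stopifnot(is(image, "DoseImage"))
  if (imageUnits(image) != "od") {
    stop("calibrateFilm expects an image in 'od' units", call. = FALSE)
  }
  if (!is.function(curve)) {
    tab <- as.matrix(curve)
    stopifnot(ncol(tab) == 2, nrow(tab) >= 2)
    tab <- tab[order(tab[, 1]), , drop = FALSE]
    if (is.null(domain)) domain <- range(tab[, 1])
    fn <- function(x) approx(tab[, 1], tab[, 2], xout = x)$y
  } else {
    fn <- curve
  }
  v <- imageValues(image)
  if (!is.null(domain)) {
    bad <- v < domain[1] | v > domain[2]
    if (any(bad)) {
      stop(sprintf(
        "%d pixel(s) outside the calibration domain [%.4g, %.4g]; image OD range [%.4g, %.4g]",
        sum(bad), domain[1], domain[2], min(v), max(v)), call. = FALSE)
    }
  }
  # monotonicity check on a dense probe of the image's OD range
  probe <- seq(min(v), max(v), length.out = 64)
  pv <- fn(probe)
  if (any(!is.finite(pv)) || (length(unique(probe)) > 1 && any(diff(pv) < 0) && any(diff(pv) > 0))) {
    stop("calibration curve must be strictly monotone over the image's OD range",
         call. = FALSE)
  }
  out <- matrix(fn(as.vector(v)), nrow(v), ncol(v))
  DoseImage(out, pixelSpacing(image), originMM(image), units = "dose",
            groundTruth = groundTruth(image))
}

## ---- starshot ----

## Signed distance from points P (n x 2) to the line with unit left-normal n0
## and offset c0 (line = {p : n0 . p = c0}).
.lineDist <- function(P, n0, c0) abs(P %*% n0 - c0)

## Extract spoke centrelines: sample the image on concentric circles about
## the intensity-weighted centre, find angular peaks, pair opposite peaks
## into rays, and fit each spoke by orthogonal regression (principal axis)
## through its circle-crossing centroids.
.extractSpokes <- function(image, nSpokes) {
  v <- imageValues(image)
  co <- pixelCoords(image)
  # intensity-weighted centre as the centre seed
  w <- v - min(v)
  cx <- sum(outer(rep(1, nrow(v)), co$x) * w) / sum(w)
  cy <- sum(outer(co$y, rep(1, ncol(v))) * w) / sum(w)
  rmax <- min(max(co$x) - cx, cx - min(co$x),
              max(co$y) - cy, cy - min(co$y))
  radii <- rmax * c(0.45, 0.6, 0.75, 0.9)
  nang <- 1440
  th <- seq(0, 2 * pi, length.out = nang + 1)[-(nang + 1)]
  pts <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    px <- cx + r * cos(th)
    py <- cy + r * sin(th)
    prof <- .bilinear(v, co$x, co$y, px, py, fill = 0)
    thr <- (max(prof) + median(prof)) / 2
    above <- prof > thr
    if (!any(above)) next
    # group contiguous runs (circular) and take the weighted angular centroid
    runs <- rle(above)
    idx <- cumsum(runs$lengths)
    starts <- c(1, head(idx, -1) + 1)
    segs <- which(runs$values)
    centres <- list()
    for (s in segs) {
      ii <- starts[s]:idx[s]
      weight <- prof[ii] - thr
      ang <- atan2(sum(weight * sin(th[ii])), sum(weight * cos(th[ii])))
      centres[[length(centres) + 1]] <- ang
    }
    # merge wrap-around first/last runs
    if (length(segs) >= 2 && above[1] && above[nang]) {
      centres[[1]] <- atan2(sin(centres[[1]]) + sin(centres[[length(centres)]]),
                            cos(centres[[1]]) + cos(centres[[length(centres)]]))
      centres[[length(centres)]] <- NULL
    }
    angv <- unlist(centres)
    pts[[i]] <- cbind(cx + r * cos(angv), cy + r * sin(angv), ang = angv)
  }
  allpts <- do.call(rbind, pts)
  if (is.null(allpts) || nrow(allpts) < 2 * 2) {
    stop("too few spoke crossings detected", call. = FALSE)
  }
  # cluster crossing points by spoke orientation (angle modulo 180 deg)
  orient <- (allpts[, 3] * 180 / pi) %% 180
  ordu <- sort(unique(round(orient, 4)))
  # k-medoid-free clustering: sort orientations, split at the largest gaps
  o <- sort(orient)
  gaps <- diff(c(o, o[1] + 180))
  nclust <- nSpokes
  # distinct orientations must be separated by a clear angular gap; the
  # within-spoke angular jitter is far below 5 degrees, so fewer than
  # nSpokes well-separated gaps means fewer spokes are present
  nFound <- sum(gaps >= 5)
  if (nFound < nclust) {
    stop(sprintf("detected %d spoke orientation(s), expected %d",
                 nFound, nSpokes), call. = FALSE)
  }
  cutpts <- order(gaps, decreasing = TRUE)[seq_len(nclust)]
  bounds <- sort(o[cutpts] + gaps[cutpts] / 2)
  assign <- findInterval(orient, bounds)
  assign[assign == 0] <- nclust   # wrap-around cluster
  lines <- vector("list", nclust)
  for (k in seq_len(nclust)) {
    P <- allpts[assign == k, 1:2, drop = FALSE]
    if (nrow(P) < 2) next
    mu <- colMeans(P)
    e <- eigen(cov(P))
    d <- e$vectors[, 1]                 # principal direction = spoke direction
    n0 <- c(-d[2], d[1])                # left normal
    lines[[k]] <- list(n = n0, c = sum(n0 * mu),
                       angle = (atan2(d[2], d[1]) * 180 / pi) %% 180)
  }
  lines <- Filter(Negate(is.null), lines)
  if (length(lines) < nSpokes) {
    stop(sprintf("detected %d spoke(s), expected %d (angles: %s)",
                 length(lines), nSpokes,
                 paste(round(vapply(lines, `[[`, 0, "angle"), 1),
                       collapse = ", ")), call. = FALSE)
  }
  lines
}

## Chebyshev centre of a set of lines: the point minimising the maximum
## perpendicular distance.  Candidates from all sign-resolved triples of the
## piecewise-linear residuals, polished by Nelder-Mead; ties broken towards
## the least-squares centre.
.chebyshevCenter <- function(N, C) {
  m <- nrow(N)
  maxd <- function(p) max(abs(N %*% p - C))
  # least-squares centre (normal equations of sum of squared line distances)
  A <- t(N) %*% N
  b <- t(N) %*% C
  pls <- tryCatch(as.vector(solve(A, b)), error = function(e) c(0, 0))
  best <- list(p = pls, r = maxd(pls))
  if (m >= 3) {
    combs <- combn(m, 3)
    signs <- as.matrix(expand.grid(s1 = c(-1, 1), s2 = c(-1, 1), s3 = c(-1, 1)))
    for (j in seq_len(ncol(combs))) {
      ii <- combs[, j]
      for (srow in seq_len(nrow(signs))) {
        s <- signs[srow, ]
        # solve n_i . p - c_i = s_i * r  for (p, r)
        M <- cbind(N[ii, , drop = FALSE], -s)
        sol <- tryCatch(solve(M, C[ii]), error = function(e) NULL)
        if (is.null(sol) || sol[3] < 0) next
        p <- sol[1:2]
        r <- maxd(p)
        if (r < best$r - 1e-12 ||
            (abs(r - best$r) <= 1e-12 &&
             sum((p - pls)^2) < sum((best$p - pls)^2))) {
          best <- list(p = p, r = r)
        }
      }
    }
  }
  # Nelder-Mead polish of the piecewise-linear max (convex)
  opt <- optim(best$p, maxd, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  if (opt$value < best$r - 1e-12) best <- list(p = opt$par, r = opt$value)
  best
}

#' Analyze a starshot film
#'
#' Reduces each spoke to a straight centreline (angular peaks on concentric
#' sampling circles about the intensity-weighted centre, joined by orthogonal
#' regression) and finds the centre of the minimum circle tangent to all
#' centrelines: the Chebyshev centre minimising the maximum perpendicular
#' point-to-line distance.  The minimised maximum is the isocenter radius.
#'
#' @param image a [DoseImage-class] containing the star pattern.
#' @param nSpokes expected number of spokes (>= 3).
#' @return A list of class `"StarshotResult"` with `centerMM` (2-vector),
#'   `radiusMM`, `spokeLines` (data.frame of `angleDeg`,
#'   `perpendicularOffsetMM` relative to the found centre) and `nSpokes`.
#' @examples
#' film <- genStarshotFilm(spokeOffsetsMM = 0, seed = 1)
#' analyzeStarshot(film, 5)$radiusMM
#' @export
analyzeStarshot <- function(image, nSpokes) {
  stopifnot(is(image, "RasterImage"), nSpokes >= 3)
  lines <- .extractSpokes(image, nSpokes)
  N <- t(vapply(lines, `[[`, numeric(2), "n"))
  C <- vapply(lines, `[[`, 0, "c")
  sol <- .chebyshevCenter(N, C)
  offs <- as.vector(N %*% sol$p - C)
  res <- list(centerMM = sol$p, radiusMM = sol$r,
              spokeLines = data.frame(
                angleDeg = vapply(lines, `[[`, 0, "angle"),
                perpendicularOffsetMM = -offs),
              nSpokes = length(lines))
  class(res) <- "StarshotResult"
  res
}

#' @export
print.StarshotResult <- function(x, ...) {
  cat(sprintf("Starshot: %d spokes, centre (%.3f, %.3f) mm, radius %.3f mm\n",
              x$nSpokes, x$centerMM[1], x$centerMM[2], x$radiusMM))
  invisible(x)
}

## ---- picket fence ----

#' Analyze a picket-fence film
#'
#' Projects the film onto the cross-plane axis, locates each strip near its
#' nominal position by a 3-point parabolic-interpolated peak, and reports
#' detected-minus-nominal shifts with their mean and sample (n-1) SD.
#'
#' @param image a [DoseImage-class] of in-plane strips.
#' @param nominalPositionsCM nominal strip centres, cm.
#' @param windowMM half-width of the search window around each nominal, mm.
#' @return A list of class `"PicketFenceResult"` with `detectedPositionsCM`,
#'   `shiftsMM`, `meanShiftMM`, `sdShiftMM`.
#' @export
analyzePicketFence <- function(image, nominalPositionsCM, windowMM = 15) {
  stopifnot(is(image, "RasterImage"))
  v <- imageValues(image)
  co <- pixelCoords(image)
  prof <- colMeans(v)
  bg <- quantile(prof, 0.1)
  detected <- vapply(nominalPositionsCM, function(nom) {
    sel <- which(abs(co$x - nom * 10) <= windowMM)
    if (length(sel) < 3 || max(prof[sel]) < bg + 0.25 * (max(prof) - bg)) {
      stop(sprintf("no strip detected near nominal %.3g cm", nom),
           call. = FALSE)
    }
    .parabolicPeak(co$x[sel], prof[sel]) / 10
  }, numeric(1))
  shifts <- (detected - nominalPositionsCM) * 10
  st <- leafShiftStats(shifts)
  res <- list(detectedPositionsCM = detected, shiftsMM = shifts,
              meanShiftMM = st[["mean"]], sdShiftMM = st[["sd"]])
  class(res) <- "PicketFenceResult"
  res
}

#' @export
print.PicketFenceResult <- function(x, ...) {
  cat(sprintf("Picket fence: %d strips, shift %.2f +/- %.2f mm\n",
              length(x$shiftsMM), x$meanShiftMM, x$sdShiftMM))
  invisible(x)
}

#' Mean and sample SD of leaf-position shifts
#'
#' @param shiftsMM numeric vector of detected-minus-nominal shifts, mm
#'   (length >= 2).
#' @return named numeric vector `c(mean = ..., sd = ...)`; the SD uses the
#'   n-1 denominator.
#' @examples
#' leafShiftStats(c(0.3, 0.0, -0.5, 0.0, 0.3, -0.1, 0.2))
#' @export
leafShiftStats <- function(shiftsMM) {
  if (length(shiftsMM) < 2) stop("need at least 2 shifts", call. = FALSE)
  c(mean = mean(shiftsMM), sd = sd(shiftsMM))
}

## ---- MLC leakage ----

#' MLC transmission and inter-leaf leakage from closed-field film
#'
#' Average leakage is the mean dose in a large ROI (default 300 x 300 mm)
#' centred on the image; maximum leakage is the largest mean over sliding
#' windows (default 10 x 10 mm) stepped at pixel resolution, partial windows
#' excluded.  Both are normalised per MU to the reference field's
#' central-axis dose:
#' \deqn{\%Avg = \frac{AverageDose / MU_{leak}}{ReferenceDose / MU_{ref}} \times 100}
#' and identically for the maximum.
#'
#' @param leak closed-MLC film, [DoseImage-class] in dose units.
#' @param ref open reference-field film, dose units; its central-axis dose is
#'   the mean over a small central ROI.
#' @param leakMU,refMU monitor units delivered for each film.
#' @param roiMM average-leakage ROI size `(x, y)`, mm.
#' @param maxWindowMM sliding-window size `(x, y)`, mm.
#' @param refCaxMM size of the central ROI defining the reference CAX dose, mm.
#' @return A list of class `"LeakageResult"`: `avgLeakagePct`,
#'   `maxLeakagePct`, `leakageMU`, `referenceMU`, `maxRoiCenterMM`.
#' @export
analyzeLeakage <- function(leak, ref, leakMU = 10000, refMU = 100,
                           roiMM = c(300, 300), maxWindowMM = c(10, 10),
                           refCaxMM = 10) {
  stopifnot(is(leak, "DoseImage"), is(ref, "DoseImage"),
            leakMU > 0, refMU > 0)
  if (imageUnits(leak) != "dose" || imageUnits(ref) != "dose") {
    stop("both images must be in dose units", call. = FALSE)
  }
  v <- imageValues(leak)
  sp <- pixelSpacing(leak)
  co <- pixelCoords(leak)
  selx <- abs(co$x) <= roiMM[1] / 2
  sely <- abs(co$y) <= roiMM[2] / 2
  if (roiMM[1] / 2 > max(co$x) + sp / 2 || roiMM[2] / 2 > max(co$y) + sp / 2) {
    stop("ROI exceeds image bounds", call. = FALSE)
  }
  avgDose <- mean(v[sely, selx])
  wpx <- max(1, round(maxWindowMM[1] / sp))
  hpx <- max(1, round(maxWindowMM[2] / sp))
  wm <- .windowMeans(v, hpx, wpx)
  imax <- which(wm == max(wm), arr.ind = TRUE)[1, ]
  maxDose <- max(wm)
  # window-centre coordinates (window top-left at [imax])
  cyi <- imax[1] + (hpx - 1) / 2
  cxi <- imax[2] + (wpx - 1) / 2
  ctr <- c((cxi - (ncol(v) + 1) / 2) * sp + originMM(leak)[1],
           (cyi - (nrow(v) + 1) / 2) * sp + originMM(leak)[2])
  # reference CAX dose
  rv <- imageValues(ref)
  rco <- pixelCoords(ref)
  refDose <- mean(rv[abs(rco$y) <= refCaxMM / 2, abs(rco$x) <= refCaxMM / 2])
  if (refDose <= 0) stop("reference CAX dose must be positive", call. = FALSE)
  res <- list(
    avgLeakagePct = 100 * (avgDose / leakMU) / (refDose / refMU),
    maxLeakagePct = 100 * (maxDose / leakMU) / (refDose / refMU),
    leakageMU = leakMU, referenceMU = refMU, maxRoiCenterMM = ctr)
  class(res) <- "LeakageResult"
  res
}

#' @export
print.LeakageResult <- function(x, ...) {
  cat(sprintf("MLC leakage: avg %.3g%%, max %.3g%% (window at %.1f, %.1f mm)\n",
              x$avgLeakagePct, x$maxLeakagePct,
              x$maxRoiCenterMM[1], x$maxRoiCenterMM[2]))
  invisible(x)
}

## ---- film field size ----

#' Measure field size from a film image
#'
#' FWHM of the central cross-plane and in-plane dose profiles taken through
#' the field centroid, with linearly interpolated half-maximum crossings.
#'
#' @param image a [DoseImage-class] containing a single connected field.
#' @return list with `crossPlaneCM` and `inPlaneCM`.
#' @export
measureFieldSizeFilm <- function(image) {
  stopifnot(is(image, "RasterImage"))
  v <- imageValues(image)
  co <- pixelCoords(image)
  w <- pmax(v - min(v), 0)
  if (max(w) <= 0) stop("no region above half maximum", call. = FALSE)
  cx <- sum(outer(rep(1, nrow(v)), co$x) * w) / sum(w)
  cy <- sum(outer(co$y, rep(1, ncol(v))) * w) / sum(w)
  irow <- which.min(abs(co$y - cy))
  icol <- which.min(abs(co$x - cx))
  fsOne <- function(x, y) {
    half <- max(y) / 2
    if (max(y) <= 0 || all(y <= half)) {
      stop("no region above half maximum", call. = FALSE)
    }
    cr <- .levelWidth(x, y, half, "field profile")
    (cr[2] - cr[1]) / 10
  }
  list(crossPlaneCM = fsOne(co$x, v[irow, ]),
       inPlaneCM = fsOne(co$y, v[, icol]))
}
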