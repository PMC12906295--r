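#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Planar raster with physical pixel geometry
#'
#' Virtual parent for all 2-D rasters handled by the package.  The matrix is
#' indexed `[row, col]` with rows running along the in-plane (y, longitudinal)
#' axis and columns along the cross-plane (x, lateral) axis.  Physical
#' coordinates are in millimetres with the origin at the raster centre, so a
#' pixel's centre is at `origin + (index - centre_index) * spacing`.
#'
#' @slot values numeric matrix of pixel values (finite, non-negative for dose).
#' @slot pixelSpacing positive scalar, mm per pixel (isotropic).
#' @slot origin length-2 numeric, mm offset of the raster centre, `(x, y)`.
#' @slot groundTruth optional list recording the parameters a synthetic
#'   generator injected (`NULL` for measured data).
#'
#' @name RasterImage-class
#' @aliases RasterImage
#' @exportClass RasterImage
setClass("RasterImage",
  representation("VIRTUAL",
    values = "matrix",
    pixelSpacing = "numeric",
    origin = "numeric",
    groundTruth = "listOrNULL"
  ),
  prototype(pixelSpacing = 1, origin = c(0, 0), groundTruth = NULL)
)

.validRaster <- function(object) {
  msg <- character()
  if (!is.numeric(object@values)) {
    msg <- c(msg, "'values' must be a numeric matrix")
  }
  if (any(!is.finite(object@values))) {
    msg <- c(msg, "'values' must be finite")
  }
  if (length(object@pixelSpacing) != 1 || !is.finite(object@pixelSpacing) ||
      object@pixelSpacing <= 0) {
    msg <- c(msg, "'pixelSpacing' must be a positive scalar (mm)")
  }
  if (length(object@origin) != 2 || any(!is.finite(object@origin))) {
    msg <- c(msg, "'origin' must be a finite 2-vector (mm)")
  }
  if (length(msg)) msg else TRUE
}
setValidity("RasterImage", .validRaster)

#' Film dose image
#'
#' A [RasterImage-class] carrying film-type data in one of three unit systems:
#' absorbed dose (arbitrary but consistent dose units), net optical density
#' (`"od"`), or raw scanner counts (`"raw"`).
#'
#' @slot units one of `"dose"`, `"od"`, `"raw"`.
#' @seealso [DoseImage()], [calibrateFilm()], [analyzeStarshot()]
#' @name DoseImage-class
#' @aliases DoseImage-class
#' @exportClass DoseImage
setClass("DoseImage",
  contains = "RasterImage",
  representation(units = "character"),
  prototype(units = "dose")
)

setValidity("DoseImage", function(object) {
  msg <- character()
  if (!(length(object@units) == 1 && object@units %in% c("dose", "od", "raw"))) {
    msg <- c(msg, "'units' must be one of \"dose\", \"od\", \"raw\"")
  }
  if (object@units != "raw" && any(object@values < 0)) {
    msg <- c(msg, "dose/od values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Grayscale MR phantom image
#'
#' A [RasterImage-class] holding MR magnitude data (uniform-sphere phantom,
#' grid phantom, ACR-style phantom).  Values are arbitrary signal units.
#'
#' @name GrayImage-class
#' @aliases GrayImage-class
#' @exportClass GrayImage
setClass("GrayImage", contains = "RasterImage")

#' Construct a DoseImage
#'
#' @param values numeric matrix (rows = in-plane y, cols = cross-plane x).
#' @param pixelSpacing mm per pixel.
#' @param origin mm offset `(x, y)` of the raster centre; default `c(0, 0)`.
#' @param units `"dose"` (default), `"od"` or `"raw"`.
#' @param groundTruth optional list of injected generator parameters.
#' @return A [DoseImage-class] object.
#' @examples
#' img <- DoseImage(matrix(1, 5, 5), pixelSpacing = 0.5)
#' pixelSpacing(img)
#' @export
DoseImage <- function(values, pixelSpacing, origin = c(0, 0), units = "dose",
                      groundTruth = NULL) {
  new("DoseImage", values = values, pixelSpacing = pixelSpacing,
      origin = origin, units = units, groundTruth = groundTruth)
}

#' Construct a GrayImage
#'
#' @inheritParams DoseImage
#' @return A [GrayImage-class] object.
#' @export
GrayImage <- function(values, pixelSpacing, origin = c(0, 0),
                      groundTruth = NULL) {
  new("GrayImage", values = values, pixelSpacing = pixelSpacing,
      origin = origin, groundTruth = groundTruth)
}

#' One-dimensional beam profile
#'
#' Ordered (position, value) samples along one scan axis, the carrier for
#' FWHM, penumbra and flatness/symmetry analyses.
#'
#' @slot positions strictly increasing numeric vector, cm.
#' @slot values non-negative numeric vector, same length.
#' @slot axis `"cross_plane"` or `"in_plane"`.
#' @slot groundTruth optional generator parameter list.
#' @name BeamProfile-class
#' @exportClass BeamProfile
setClass("BeamProfile",
  representation(positions = "numeric", values = "numeric",
                 axis = "character", groundTruth = "listOrNULL"),
  prototype(axis = "cross_plane", groundTruth = NULL)
)

setValidity("BeamProfile", function(object) {
  msg <- character()
  if (length(object@positions) != length(object@values)) {
    msg <- c(msg, "'positions' and 'values' must have equal length")
  }
  if (length(object@positions) < 8) {
    msg <- c(msg, "a profile needs at least 8 samples")
  }
  if (any(diff(object@positions) <= 0)) {
    msg <- c(msg, "'positions' must be strictly increasing")
  }
  if (any(!is.finite(object@values)) || any(object@values < 0)) {
    msg <- c(msg, "'values' must be finite and non-negative")
  }
  if (!(object@axis %in% c("cross_plane", "in_plane"))) {
    msg <- c(msg, "'axis' must be \"cross_plane\" or \"in_plane\"")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BeamProfile
#'
#' @param positions strictly increasing sample positions, cm.
#' @param values non-negative profile values.
#' @param axis `"cross_plane"` (default) or `"in_plane"`.
#' @param groundTruth optional generator parameter list.
#' @return A [BeamProfile-class] object.
#' @export
BeamProfile <- function(positions, values, axis = "cross_plane",
                        groundTruth = NULL) {
  new("BeamProfile", positions = as.numeric(positions),
      values = as.numeric(values), axis = axis, groundTruth = groundTruth)
}

#' Resonance-frequency spectrum
#'
#' Magnitude spectrum around the proton Larmor peak, the carrier for B0
#' homogeneity analysis.  `nominalF0` holds the machine's nominal central
#' frequency, the default reference for the ppm conversion.
#'
#' @slot frequency increasing numeric vector, Hz.
#' @slot magnitude non-negative numeric vector.
#' @slot nominalF0 positive scalar, Hz (default 14,701,760 Hz at 0.35 T).
#' @slot groundTruth optional generator parameter list.
#' @name SpectrumProfile-class
#' @exportClass SpectrumProfile
setClass("SpectrumProfile",
  representation(frequency = "numeric", magnitude = "numeric",
                 nominalF0 = "numeric", groundTruth = "listOrNULL"),
  prototype(nominalF0 = 14701760, groundTruth = NULL)
)

setValidity("SpectrumProfile", function(object) {
  msg <- character()
  if (length(object@frequency) != length(object@magnitude)) {
    msg <- c(msg, "'frequency' and 'magnitude' must have equal length")
  }
  if (any(diff(object@frequency) <= 0)) {
    msg <- c(msg, "'frequency' must be strictly increasing")
  }
  if (any(object@magnitude < 0)) {
    msg <- c(msg, "'magnitude' must be non-negative")
  }
  if (length(object@nominalF0) != 1 || object@nominalF0 <= 0) {
    msg <- c(msg, "'nominalF0' must be a positive scalar (Hz)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumProfile
#'
#' @param frequency increasing frequencies, Hz.
#' @param magnitude non-negative magnitudes.
#' @param nominalF0 nominal central frequency, Hz.
#' @param groundTruth optional generator parameter list.
#' @return A [SpectrumProfile-class] object.
#' @export
SpectrumProfile <- function(frequency, magnitude, nominalF0 = 14701760,
                            groundTruth = NULL) {
  new("SpectrumProfile", frequency = as.numeric(frequency),
      magnitude = as.numeric(magnitude), nominalF0 = nominalF0,
      groundTruth = groundTruth)
}

#' Target-motion trace with beam state
#'
#' Frame-sampled target position together with the machine's beam-on/off
#' state, the carrier for gating-latency analysis.
#'
#' @slot time strictly increasing numeric vector, s.
#' @slot position numeric vector, mm (longitudinal target position).
#' @slot beamOn logical vector, beam state per frame.
#' @slot groundTruth optional generator parameter list.
#' @name MotionTrace-class
#' @exportClass MotionTrace
setClass("MotionTrace",
  representation(time = "numeric", position = "numeric", beamOn = "logical",
                 groundTruth = "listOrNULL"),
  prototype(groundTruth = NULL)
)

setValidity("MotionTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (length(object@position) != n || length(object@beamOn) != n) {
    msg <- c(msg, "time/position/beamOn must have equal length")
  }
  if (any(diff(object@time) <= 0)) {
    msg <- c(msg, "'time' must be strictly increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MotionTrace
#'
#' @param time strictly increasing frame times, s.
#' @param position target positions, mm.
#' @param beamOn logical beam state per frame.
#' @param groundTruth optional generator parameter list.
#' @return A [MotionTrace-class] object.
#' @export
MotionTrace <- function(time, position, beamOn, groundTruth = NULL) {
  new("MotionTrace", time = as.numeric(time), position = as.numeric(position),
      beamOn = as.logical(beamOn), groundTruth = groundTruth)
}

#' Isocenter shift set
#'
#' The three pairwise shifts between the laser (L), radiation (RT) and MRI
#' (MR) isocenters, in a declared frame.  By construction
#' `mrToRt = mrToLaser + laserToRt` componentwise with
#' `laserToRt = -rtToLaser`.
#'
#' @slot mrToLaser,rtToLaser,mrToRt length-3 numeric shifts, mm.
#' @slot frame `"laser_dicom"` or `"linac_iec"`.
#' @name IsocenterShiftSet-class
#' @exportClass IsocenterShiftSet
setClass("IsocenterShiftSet",
  representation(mrToLaser = "numeric", rtToLaser = "numeric",
                 mrToRt = "numeric", frame = "character"),
  prototype(frame = "laser_dicom")
)

setValidity("IsocenterShiftSet", function(object) {
  msg <- character()
  if (length(object@mrToLaser) != 3 || length(object@rtToLaser) != 3 ||
      length(object@mrToRt) != 3) {
    msg <- c(msg, "shift vectors must have length 3")
  }
  if (!(object@frame %in% c("laser_dicom", "linac_iec"))) {
    msg <- c(msg, "'frame' must be \"laser_dicom\" or \"linac_iec\"")
  }
  if (length(msg) == 0 &&
      max(abs(object@mrToRt - (object@mrToLaser - object@rtToLaser))) > 1e-9) {
    msg <- c(msg, "mrToRt must equal mrToLaser - rtToLaser componentwise")
  }
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' Raster and profile accessors
#'
#' @param x an mrlqa data object.
#' @return `imageValues`: the value matrix; `pixelSpacing`: mm per pixel;
#'   `originMM`: the 2-vector origin; `groundTruth`: the generator ground
#'   truth list (or `NULL`); `imageUnits`: the unit label of a
#'   [DoseImage-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setMethod("imageValues", "RasterImage", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))
#' @rdname accessors
#' @export
setMethod("pixelSpacing", "RasterImage", function(x) x@pixelSpacing)

#' @rdname accessors
#' @export
setGeneric("originMM", function(x) standardGeneric("originMM"))
#' @rdname accessors
#' @export
setMethod("originMM", "RasterImage", function(x) x@origin)

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "RasterImage", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "BeamProfile", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SpectrumProfile", function(x) x@groundTruth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "MotionTrace", function(x) x@groundTruth)

#' @rdname accessors
#' @export
setGeneric("imageUnits", function(x) standardGeneric("imageUnits"))
#' @rdname accessors
#' @export
setMethod("imageUnits", "DoseImage", function(x) x@units)

#' @rdname accessors
#' @export
setGeneric("profilePositions", function(x) standardGeneric("profilePositions"))
#' @rdname accessors
#' @export
setMethod("profilePositions", "BeamProfile", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))
#' @rdname accessors
#' @export
setMethod("profileValues", "BeamProfile", function(x) x@values)

#' Physical pixel-centre coordinates of a raster
#'
#' @param x a [RasterImage-class].
#' @return list with components `x` (column centres, mm, cross-plane) and
#'   `y` (row centres, mm, in-plane).
#' @export
pixelCoords <- function(x) {
  stopifnot(is(x, "RasterImage"))
  v <- x@values
  sp <- x@pixelSpacing
  list(
    x = (seq_len(ncol(v)) - (ncol(v) + 1) / 2) * sp + x@origin[1],
    y = (seq_len(nrow(v)) - (nrow(v) + 1) / 2) * sp + x@origin[2]
  )
}

## ---- show methods ----

setMethod("show", "DoseImage", function(object) {
  cat(sprintf("DoseImage: %d x %d px, %.4g mm/px, units=%s\n",
              nrow(object@values), ncol(object@values),
              object@pixelSpacing, object@units))
  cat(sprintf("  value range [%.4g, %.4g]%s\n",
              min(object@values), max(object@values),
              if (is.null(object@groundTruth)) "" else ", with ground truth"))
})

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %d x %d px, %.4g mm/px\n",
              nrow(object@values), ncol(object@values), object@pixelSpacing))
})

setMethod("show", "BeamProfile", function(object) {
  cat(sprintf("BeamProfile (%s): %d samples over [%.3g, %.3g] cm\n",
              object@axis, length(object@positions),
              min(object@positions), max(object@positions)))
})

setMethod("show", "SpectrumProfile", function(object) {
  cat(sprintf("SpectrumProfile: %d samples, %.6g-%.6g Hz, nominal f0 %.6g Hz\n",
              length(object@frequency), min(object@frequency),
              max(object@frequency), object@nominalF0))
})

setMethod("show", "MotionTrace", function(object) {
  cat(sprintf("MotionTrace: %d frames over %.3g s, beam on %.1f%%\n",
              length(object@time), diff(range(object@time)),
              100 * mean(object@beamOn)))
})

setMethod("show", "IsocenterShiftSet", function(object) {
  cat(sprintf("IsocenterShiftSet (%s frame), mm:\n", object@frame))
  m <- rbind(`MR-L` = object@mrToLaser, `RT-L` = object@rtToLaser,
             `MR-RT` = object@mrToRt)
  colnames(m) <- c("x", "y", "z")
  print(round(m, 3))
})
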