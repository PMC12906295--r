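## File interchange: 16-bit grayscale TIFF with a JSON sidecar for rasters,
## plain CSV for profiles, spectra and motion traces.

#' Write a raster as 16-bit TIFF with a JSON sidecar
#'
#' Values are scaled to the 16-bit range; the sidecar (`<path>.json`)
#' records the scale, pixel spacing, origin, units and any generator ground
#' truth so [readRasterTIFF()] restores the object losslessly up to 16-bit
#' quantisation.
#'
#' @param image a [DoseImage-class] or [GrayImage-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeRasterTIFF <- function(image, path) {
  stopifnot(is(image, "RasterImage"))
  v <- imageValues(image)
  vmax <- max(v, 1e-12)
  tiff::writeTIFF(v / vmax, path, bits.per.sample = 16)
  side <- list(pixel_spacing_mm = pixelSpacing(image),
               origin_mm = originMM(image),
               value_scale = vmax,
               class = class(image)[1],
               units = if (is(image, "DoseImage")) imageUnits(image) else NULL,
               ground_truth = groundTruth(image))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a raster written by [writeRasterTIFF()]
#'
#' @param path TIFF path (sidecar expected at `<path>.json`).
#' @return the restored [DoseImage-class] or [GrayImage-class].
#' @export
readRasterTIFF <- function(path) {
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- v * side$value_scale
  gt <- side$ground_truth
  if (!is.null(gt)) gt <- as.list(gt)
  if (identical(side$class, "DoseImage")) {
    DoseImage(vals, side$pixel_spacing_mm, unlist(side$origin_mm),
              units = side$units, groundTruth = gt)
  } else {
    GrayImage(vals, side$pixel_spacing_mm, unlist(side$origin_mm),
              groundTruth = gt)
  }
}

#' Profile, spectrum and trace CSV interchange
#'
#' Profiles are `position_cm,value`; spectra are `frequency_hz,magnitude`;
#' traces are `time_s,position_mm,beam_on` (0/1).
#'
#' @param x the object to write.
#' @param path CSV path.
#' @return `path` (writers, invisibly) or the restored object (readers).
#' @name csv-io
NULL

#' @rdname csv-io
#' @export
writeProfileCSV <- function(x, path) {
  stopifnot(is(x, "BeamProfile"))
  write.csv(data.frame(position_cm = profilePositions(x),
                       value = profileValues(x)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @param axis axis label for the restored profile.
#' @export
readProfileCSV <- function(path, axis = "cross_plane") {
  d <- read.csv(path)
  BeamProfile(d$position_cm, d$value, axis = axis)
}

#' @rdname csv-io
#' @export
writeSpectrumCSV <- function(x, path) {
  stopifnot(is(x, "SpectrumProfile"))
  write.csv(data.frame(frequency_hz = x@frequency, magnitude = x@magnitude),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @param nominalF0 nominal central frequency for the restored spectrum, Hz.
#' @export
readSpectrumCSV <- function(path, nominalF0 = 14701760) {
  d <- read.csv(path)
  SpectrumProfile(d$frequency_hz, d$magnitude, nominalF0 = nominalF0)
}

#' @rdname csv-io
#' @export
writeTraceCSV <- function(x, path) {
  stopifnot(is(x, "MotionTrace"))
  write.csv(data.frame(time_s = x@time, position_mm = x@position,
                       beam_on = as.integer(x@beamOn)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname csv-io
#' @export
readTraceCSV <- function(path) {
  d <- read.csv(path)
  MotionTrace(d$time_s, d$position_mm, d$beam_on > 0)
}
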