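## Scalar-detector analyses: isocenter-shift composition and frame
## conversion, couch attenuation, gating dose deviation and beam-off latency,
## and the reference-dose equation.

#' Compose the MRI-to-radiation isocenter shift
#'
#' Given the MRI-to-laser and radiation-to-laser shifts measured in a common
#' frame, the MRI-to-radiation shift follows componentwise from
#' \deqn{(X,Y,Z)_{MR,RT} = (X,Y,Z)_{MR,L} + (X,Y,Z)_{L,RT}} with the
#' laser-to-RT terms the negated RT-to-laser measurements.
#'
#' @param mrToLaser MRI-to-laser shift, mm (length 3).
#' @param rtToLaser radiation-to-laser shift, mm (length 3).
#' @param frame frame both vectors are expressed in: `"laser_dicom"`
#'   (default) or `"linac_iec"`.
#' @return An [IsocenterShiftSet-class] with all three shift vectors.
#' @examples
#' composeIsocenterShifts(c(0, 0, 0), c(0.0, -0.4, -0.5))
#' @export
composeIsocenterShifts <- function(mrToLaser, rtToLaser,
                                   frame = c("laser_dicom", "linac_iec")) {
  frame <- match.arg(frame)
  stopifnot(length(mrToLaser) == 3, length(rtToLaser) == 3)
  new("IsocenterShiftSet",
      mrToLaser = as.numeric(mrToLaser),
      rtToLaser = as.numeric(rtToLaser),
      mrToRt = as.numeric(mrToLaser) - as.numeric(rtToLaser),
      frame = frame)
}

#' Shift-set accessors
#'
#' @param x an [IsocenterShiftSet-class].
#' @return the requested 3-vector (mm) or frame label.
#' @name shift-accessors
NULL

#' @rdname shift-accessors
#' @export
setGeneric("mrToRt", function(x) standardGeneric("mrToRt"))
#' @rdname shift-accessors
#' @export
setMethod("mrToRt", "IsocenterShiftSet", function(x) x@mrToRt)
#' @rdname shift-accessors
#' @export
setGeneric("mrToLaser", function(x) standardGeneric("mrToLaser"))
#' @rdname shift-accessors
#' @export
setMethod("mrToLaser", "IsocenterShiftSet", function(x) x@mrToLaser)
#' @rdname shift-accessors
#' @export
setGeneric("rtToLaser", function(x) standardGeneric("rtToLaser"))
#' @rdname shift-accessors
#' @export
setMethod("rtToLaser", "IsocenterShiftSet", function(x) x@rtToLaser)
#' @rdname shift-accessors
#' @export
setGeneric("shiftFrame", function(x) standardGeneric("shiftFrame"))
#' @rdname shift-accessors
#' @export
setMethod("shiftFrame", "IsocenterShiftSet", function(x) x@frame)

#' Convert a vector between machine coordinate frames
#'
#' For a head-first supine patient the Linac follows IEC 61217 and the MRI
#' and laser systems follow the DICOM patient convention.  The anatomical
#' directions map as: Left = \eqn{+X} in all frames; Superior =
#' \eqn{+Y_{RT} = -Z_{MRI} = -Z_L}; Anterior = \eqn{+Z_{RT} = +Y_{MRI} =
#' +Y_L}.  Hence RT \eqn{(x,y,z) \to} MRI \eqn{(x, z, -y)} and MRI
#' \eqn{(x,y,z) \to} RT \eqn{(x, -z, y)}; the laser frame shares the MRI
#' axis convention.
#'
#' @param v numeric length-3 vector.
#' @param from,to frame names: `"linac_iec"`, `"mri_dicom"`, `"laser_dicom"`.
#' @return the converted length-3 vector.
#' @examples
#' convertFrame(c(0, 1, 0), "linac_iec", "mri_dicom")  # (0, 0, -1)
#' @export
convertFrame <- function(v, from, to) {
  frames <- c("linac_iec", "mri_dicom", "laser_dicom")
  if (!(from %in% frames) || !(to %in% frames)) {
    stop("unknown frame; supported: ", paste(frames, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(length(v) == 3)
  v <- as.numeric(v)
  dicom <- function(f) f %in% c("mri_dicom", "laser_dicom")
  if (from == to || (dicom(from) && dicom(to))) return(v)
  if (from == "linac_iec") c(v[1], v[3], -v[2]) else c(v[1], -v[3], v[2])
}

#' Couch attenuation, literal percentage forms
#'
#' The reading-based form is \eqn{100 (1 - R_\theta / R_0)} with \eqn{R_0}
#' the mean reading at the unattenuated 90/270 gantry angles; the TPS form is
#' \eqn{100 (1 - MU / Reference)} with the monitor units required to deliver
#' a fixed dose.  Positive values mean more attenuation than the reference.
#'
#' @param rTheta measured reading at the gantry angle.
#' @param r0 mean reference reading (> 0).
#' @return attenuation, percent.
#' @export
couchAttenuationMeas <- function(rTheta, r0) {
  if (any(r0 <= 0)) stop("reference reading must be positive", call. = FALSE)
  100 * (1 - rTheta / r0)
}

#' @rdname couchAttenuationMeas
#' @param mu monitor units required at the gantry angle.
#' @param referenceMU mean monitor units at 90/270 (> 0).
#' @export
couchAttenuationCalc <- function(mu, referenceMU) {
  if (any(referenceMU <= 0)) stop("reference MU must be positive", call. = FALSE)
  100 * (1 - mu / referenceMU)
}

#' Relative attenuation factor
#'
#' Reference-normalised attenuation factor (about 1 at the unattenuated
#' angles, larger where the couch attenuates): reading ratio \eqn{R_0 /
#' R_\theta} for measurements, or MU ratio \eqn{MU / Reference} for the TPS.
#'
#' @param rTheta reading (or MU) at the gantry angle.
#' @param r0 reference reading (or reference MU), > 0.
#' @param type `"reading"` (factor = r0 / rTheta) or `"mu"`
#'   (factor = rTheta / r0, with `rTheta` the MU).
#' @return attenuation factor.
#' @export
attenuationFactor <- function(rTheta, r0, type = c("reading", "mu")) {
  type <- match.arg(type)
  if (any(r0 <= 0) || any(rTheta <= 0)) {
    stop("readings must be positive", call. = FALSE)
  }
  if (type == "reading") r0 / rTheta else rTheta / r0
}

#' Percent deviation between measured and TPS attenuation factors
#'
#' @param measuredFactor,tpsFactor attenuation factors (tps > 0).
#' @param digits rounding for the report (default 1 decimal).
#' @return `100 * (measured - tps) / tps`, rounded.
#' @examples
#' attenuationDeviation(1.144, 1.155)  # -1.0
#' @export
attenuationDeviation <- function(measuredFactor, tpsFactor, digits = 1) {
  if (any(tpsFactor <= 0)) stop("TPS factor must be positive", call. = FALSE)
  round(100 * (measuredFactor - tpsFactor) / tpsFactor, digits)
}

#' Gated vs non-gated dose deviation
#'
#' \deqn{Deviation\% = 100 (D_{ng} - D_g) / D_{ng}} with \eqn{D_{ng}} the
#' non-gated and \eqn{D_g} the gated electrometer charge.  The reported value
#' is the magnitude rounded to 2 decimals; the signed value is attached as
#' attribute `"signed"`.
#'
#' @param dNg non-gated charge, nC (nonzero).
#' @param dG gated charge, nC.
#' @return deviation magnitude, percent.
#' @examples
#' gatingDeviation(-11.76, -11.77)  # 0.09
#' @export
gatingDeviation <- function(dNg, dG) {
  if (dNg == 0) stop("non-gated charge must be nonzero", call. = FALSE)
  signed <- 100 * (dNg - dG) / dNg
  structure(round(abs(signed), 2), signed = signed)
}

#' Beam-off gating latency from a motion trace
#'
#' For each event where the target exits the gate (position crosses the
#' gating boundary upward, located by linear interpolation between frames),
#' the latency is the observed beam-off time minus the crossing time; the
#' beam-off time is the midpoint of the last beam-on and first beam-off
#' frames.  The estimate is the mean over events, resolved to the frame
#' period.
#'
#' @param trace a [MotionTrace-class] with beam states.
#' @param boundaryMM gating boundary, mm.
#' @return list: `latencyS` (mean), `perEventS`, `nEvents`.
#' @export
beamOffLatency <- function(trace, boundaryMM) {
  stopifnot(is(trace, "MotionTrace"))
  t <- trace@time; p <- trace@position; b <- trace@beamOn
  # upward crossings of the boundary
  cross <- numeric(0)
  for (i in seq_len(length(t) - 1)) {
    if (p[i] <= boundaryMM && p[i + 1] > boundaryMM) {
      frac <- (boundaryMM - p[i]) / (p[i + 1] - p[i])
      cross <- c(cross, t[i] + frac * (t[i + 1] - t[i]))
    }
  }
  # beam-off transitions, midpoint convention
  offIdx <- which(b[-length(b)] & !b[-1])
  offT <- (t[offIdx] + t[offIdx + 1]) / 2
  if (length(cross) < 3) {
    stop("need at least 3 boundary-exit events", call. = FALSE)
  }
  lat <- vapply(cross, function(tc) {
    nxt <- offT[offT >= tc - (t[2] - t[1])]
    if (!length(nxt)) return(NA_real_)
    min(nxt) - tc
  }, numeric(1))
  lat <- lat[!is.na(lat)]
  if (!length(lat)) stop("no beam-off events follow the exits", call. = FALSE)
  list(latencyS = mean(lat), perEventS = lat, nEvents = length(lat))
}

#' Reference dose per monitor unit
#'
#' TG-51-style reference dose from a corrected electrometer reading:
#' \deqn{D = M_{corr} \cdot N_{D,w} \cdot k_Q \cdot k_B} per MU, with
#' \eqn{k_B} the magnetic-field correction (default 0.9957 for a
#' Farmer-type chamber perpendicular to a 0.35 T field) and \eqn{k_Q} either
#' supplied directly or linearly interpolated at `pdd10xPct` from a
#' user-provided `(pdd10x, kQ)` anchor table.
#'
#' @param correctedReading fully corrected reading per MU.
#' @param ndw absorbed-dose-to-water calibration coefficient.
#' @param kQ beam-quality conversion factor; omit to interpolate.
#' @param kB magnetic-field correction factor (default 0.9957).
#' @param pdd10xPct beam-quality specifier %dd(10)x, required when
#'   interpolating.
#' @param kQTable two-column matrix/data.frame of `(pdd10xPct, kQ)` anchors.
#' @return dose per MU (units follow `ndw`).
#' @examples
#' referenceDose(1, 1, kQ = 1, kB = 0.9957)
#' @export
referenceDose <- function(correctedReading, ndw, kQ = NULL, kB = 0.9957,
                          pdd10xPct = NULL, kQTable = NULL) {
  stopifnot(ndw > 0, kB > 0.9, kB < 1.1)
  if (is.null(kQ)) {
    if (is.null(pdd10xPct) || is.null(kQTable)) {
      stop("supply kQ, or pdd10xPct with a kQTable", call. = FALSE)
    }
    tab <- as.matrix(kQTable)
    tab <- tab[order(tab[, 1]), , drop = FALSE]
    if (pdd10xPct < tab[1, 1] || pdd10xPct > tab[nrow(tab), 1]) {
      stop(sprintf("%%dd(10)x = %.4g outside the kQ table range [%.4g, %.4g]",
                   pdd10xPct, tab[1, 1], tab[nrow(tab), 1]), call. = FALSE)
    }
    kQ <- approx(tab[, 1], tab[, 2], xout = pdd10xPct)$y
  }
  stopifnot(kQ > 0.9, kQ < 1.1)
  correctedReading * ndw * kQ * kB
}
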