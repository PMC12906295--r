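## Tolerance registry, pass/fail evaluation and acceptance reporting.

#' Default acceptance-tolerance registry
#'
#' One row per metric: the comparator, threshold(s), units, group and a
#' source note.  Comparators: `abs_le` (|value| <= threshold, inclusive),
#' `le` / `ge` (inclusive bounds), `lt` / `gt` (strict, for tolerances
#' printed as "<"), `within_range` (closed interval), `none` (informational,
#' verdict `"n/a"`).  Couch attenuation carries two entries — the method
#' tolerance (+/-3%) and the stricter results tolerance (+/-1%) — and the
#' stricter one is the default comparator for reports.
#'
#' @return data.frame registry.
#' @export
defaultToleranceRegistry <- function() {
  reg <- rbind(
    data.frame(metricId = "starshot_radius", comparator = "abs_le",
               lower = NA, threshold = 1, units = "mm",
               group = "mechanical", note = "isocentricity, minimum tangent circle"),
    data.frame(metricId = "isocenter_coincidence", comparator = "abs_le",
               lower = NA, threshold = 1, units = "mm",
               group = "mechanical", note = "laser/RT/MRI isocenter coincidence, per axis"),
    data.frame(metricId = "field_size_diff", comparator = "abs_le",
               lower = NA, threshold = 0.2, units = "cm",
               group = "mechanical", note = "FWHM field size vs TPS"),
    data.frame(metricId = "mlc_leakage_avg", comparator = "lt",
               lower = NA, threshold = 0.375, units = "%",
               group = "mechanical", note = "average MLC transmission"),
    data.frame(metricId = "mlc_leakage_max", comparator = "lt",
               lower = NA, threshold = 1, units = "%",
               group = "mechanical", note = "maximum MLC transmission over 1x1 cm"),
    data.frame(metricId = "mlc_position", comparator = "abs_le",
               lower = NA, threshold = 2, units = "mm",
               group = "mechanical", note = "picket-fence leaf position"),
    data.frame(metricId = "flatness", comparator = "abs_le",
               lower = NA, threshold = 2, units = "%",
               group = "dosimetric", note = "pointwise M-TPS off-axis ratio"),
    data.frame(metricId = "symmetry", comparator = "abs_le",
               lower = NA, threshold = 2, units = "%",
               group = "dosimetric", note = "M(-OAP)-M(+OAP)"),
    data.frame(metricId = "penumbra_diff", comparator = "abs_le",
               lower = NA, threshold = 1, units = "mm",
               group = "dosimetric", note = "20-80 penumbra vs TPS"),
    data.frame(metricId = "couch_attenuation_method", comparator = "abs_le",
               lower = NA, threshold = 3, units = "%",
               group = "dosimetric", note = "method tolerance"),
    data.frame(metricId = "couch_attenuation", comparator = "abs_le",
               lower = NA, threshold = 1, units = "%",
               group = "dosimetric", note = "results tolerance (stricter default)"),
    data.frame(metricId = "fof_diff", comparator = "none",
               lower = NA, threshold = NA, units = "%",
               group = "dosimetric", note = "no manufacturer tolerance"),
    data.frame(metricId = "gamma_pass_rate", comparator = "ge",
               lower = NA, threshold = 95, units = "%",
               group = "dosimetric", note = "3%/3mm global"),
    data.frame(metricId = "b0_homogeneity", comparator = "le",
               lower = NA, threshold = 5, units = "ppm",
               group = "mri", note = "24 cm DSV peak-to-peak"),
    data.frame(metricId = "central_frequency", comparator = "within_range",
               lower = 14686760, threshold = 14716760, units = "Hz",
               group = "mri", note = "nominal 14.70176 MHz +/- 0.015 MHz"),
    data.frame(metricId = "spatial_integrity_20cm", comparator = "lt",
               lower = NA, threshold = 1, units = "mm",
               group = "mri", note = "20 cm DSV"),
    data.frame(metricId = "spatial_integrity_35cm", comparator = "lt",
               lower = NA, threshold = 2, units = "mm",
               group = "mri", note = "20-35 cm DSV"),
    data.frame(metricId = "snr_body", comparator = "ge",
               lower = NA, threshold = 12, units = "",
               group = "mri", note = "body coil"),
    data.frame(metricId = "uniformity_body", comparator = "ge",
               lower = NA, threshold = 60, units = "%",
               group = "mri", note = "body coil"),
    data.frame(metricId = "acr_psg", comparator = "lt",
               lower = NA, threshold = 0.025, units = "",
               group = "mri", note = "percent signal ghosting"),
    data.frame(metricId = "acr_piu", comparator = "gt",
               lower = NA, threshold = 87.5, units = "%",
               group = "mri", note = "percent integral uniformity"),
    data.frame(metricId = "acr_slice_thickness", comparator = "within_range",
               lower = 4.3, threshold = 5.7, units = "mm",
               group = "mri", note = "5.0 +/- 0.7 mm"),
    data.frame(metricId = "acr_slice_position", comparator = "abs_le",
               lower = NA, threshold = 5, units = "mm",
               group = "mri", note = "slice position accuracy")
  )
  rownames(reg) <- NULL
  reg
}

#' Load a tolerance registry, optionally overridden from YAML
#'
#' @param path YAML file whose top-level keys are metric ids; each entry may
#'   override `comparator`, `threshold`, `lower`, `units`, `note`.  `NULL`
#'   returns the default registry.
#' @return data.frame registry.
#' @export
loadToleranceRegistry <- function(path = NULL) {
  reg <- defaultToleranceRegistry()
  if (is.null(path)) return(reg)
  ov <- yaml::read_yaml(path)
  for (id in names(ov)) {
    i <- match(id, reg$metricId)
    if (is.na(i)) {
      row <- reg[1, ]
      row$metricId <- id
      row[c("comparator", "lower", "threshold", "units", "group", "note")] <-
        list("none", NA, NA, "", "custom", "")
      reg <- rbind(reg, row)
      i <- nrow(reg)
    }
    for (fld in intersect(names(ov[[id]]),
                          c("comparator", "threshold", "lower", "units",
                            "group", "note"))) {
      reg[i, fld] <- ov[[id]][[fld]]
    }
  }
  reg
}

#' Evaluate a value against a tolerance
#'
#' Pure comparator application; boundary values pass for the inclusive
#' comparators (`le`, `ge`, `abs_le`, `within_range`) and fail for the
#' strict ones (`lt`, `gt`).  Comparator `none` yields `"n/a"`.
#'
#' @param value numeric metric value.
#' @param tol one-row registry entry (from [defaultToleranceRegistry()]) or
#'   a list with `comparator`, `threshold` and optionally `lower`.
#' @return `"pass"`, `"fail"` or `"n/a"`.
#' @examples
#' reg <- defaultToleranceRegistry()
#' evaluateTolerance(0.6, reg[reg$metricId == "starshot_radius", ])
#' @export
evaluateTolerance <- function(value, tol) {
  cmp <- tol$comparator
  thr <- tol$threshold
  if (cmp == "none") return("n/a")
  ok <- switch(cmp,
    abs_le = abs(value) <= thr,
    le = value <= thr,
    ge = value >= thr,
    lt = value < thr,
    gt = value > thr,
    within_range = value >= tol$lower & value <= thr,
    stop("unknown comparator: ", cmp, call. = FALSE)
  )
  if (isTRUE(ok)) "pass" else "fail"
}

#' Assemble an acceptance report
#'
#' @param results data.frame with columns `metricId` and `value` (one row
#'   per measurement; duplicate ids are rejected), plus optional
#'   `provenance`.
#' @param registry tolerance registry (default [defaultToleranceRegistry()]).
#' @param metadata named list of machine/session metadata.
#' @return list of class `"AcceptanceReport"`: `metadata`, `results`
#'   (with tolerance columns and verdicts, ordered
#'   mechanical/dosimetric/mri), `summary` counts per group.
#' @export
buildReport <- function(results, registry = defaultToleranceRegistry(),
                        metadata = list()) {
  if (NROW(results) == 0) stop("no results to report", call. = FALSE)
  if (anyDuplicated(results$metricId)) {
    stop("duplicate metric ids: ",
         paste(unique(results$metricId[duplicated(results$metricId)]),
               collapse = ", "), call. = FALSE)
  }
  i <- match(results$metricId, registry$metricId)
  if (anyNA(i)) {
    stop("unknown metric ids: ",
         paste(results$metricId[is.na(i)], collapse = ", "), call. = FALSE)
  }
  tab <- cbind(results,
               registry[i, c("comparator", "lower", "threshold", "units",
                             "group", "note")])
  tab$verdict <- vapply(seq_len(nrow(tab)), function(r) {
    evaluateTolerance(tab$value[r], tab[r, ])
  }, character(1))
  grp <- factor(tab$group, levels = c("mechanical", "dosimetric", "mri"))
  tab <- tab[order(grp, tab$metricId), ]
  rownames(tab) <- NULL
  sm <- as.data.frame(table(group = grp[order(grp)],
                            verdict = factor(tab$verdict,
                                             c("pass", "fail", "n/a"))))
  res <- list(metadata = metadata, results = tab, summary = sm)
  class(res) <- "AcceptanceReport"
  res
}

#' Render an acceptance report
#'
#' @param report an `"AcceptanceReport"` from [buildReport()].
#' @param format `"json"` (lossless round-trip) or `"markdown"`.
#' @param path optional file to write; the rendered text is returned
#'   invisibly either way.
#' @return character scalar of the rendered document.
#' @export
renderReport <- function(report, format = c("json", "markdown"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(report, "AcceptanceReport"))
  txt <- if (format == "json") {
    jsonlite::toJSON(list(metadata = report$metadata,
                          results = report$results,
                          summary = report$summary),
                     dataframe = "rows", auto_unbox = TRUE, digits = NA,
                     pretty = TRUE, na = "null")
  } else {
    r <- report$results
    lines <- c("# Acceptance report", "",
               sprintf("- %s: %s", names(report$metadata),
                       unlist(lapply(report$metadata, as.character))),
               "",
               "| metric | value | tolerance | units | verdict | source |",
               "|---|---|---|---|---|---|",
               sprintf("| %s | %.4g | %s | %s | %s | %s |",
                       r$metricId, r$value,
                       ifelse(r$comparator == "none", "-",
                         ifelse(r$comparator == "within_range",
                                sprintf("[%.4g, %.4g]", r$lower, r$threshold),
                                sprintf("%s %.4g", r$comparator, r$threshold))),
                       r$units, r$verdict, r$note))
    paste(lines, collapse = "\n")
  }
  if (!is.null(path)) writeLines(as.character(txt), path)
  invisible(as.character(txt))
}

#' Parse a JSON acceptance report back into report form
#'
#' @param txt JSON text or file path produced by [renderReport()].
#' @return list with `metadata`, `results`, `summary`.
#' @export
parseReport <- function(txt) {
  jsonlite::fromJSON(txt)
}

#' @export
print.AcceptanceReport <- function(x, ...) {
  cat(sprintf("AcceptanceReport: %d metrics (%s)\n", nrow(x$results),
              paste(sprintf("%s %d",
                            levels(factor(x$results$verdict)),
                            as.vector(table(x$results$verdict))),
                    collapse = ", ")))
  invisible(x)
}
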