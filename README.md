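# mrlqa

Acceptance-test analysis for a 0.35 T MR-Linac.

Commissioning a hybrid MRI + linear accelerator means demonstrating, with
quantitative tolerances, that (1) the machine's mechanical geometry is
sound, (2) its dosimetry matches the treatment planning system (TPS), and
(3) the integrated MRI images accurately — all in one connected coordinate
world where the MRI isocenter must coincide with the radiation isocenter.
`mrlqa` implements the analysis side of that programme for a low-field
(0.35 T) MR-Linac with a double-focused MLC and an FFF 6 MV beam, aimed at
clinical medical physicists and QA software developers.

## What it computes

**Mechanical**

* Starshot isocentricity: spoke lines extracted by concentric-circle
  sampling and orthogonal regression; the metric is the radius of the
  *minimum tangent circle* (Chebyshev center of the line set), solved
  exactly by sign-resolved triple enumeration and validated against a
  brute-force oracle.
* Picket-fence MLC leaf positions with sub-pixel (parabolic) peak
  interpolation; per-gantry mean ± sample SD.
* MLC transmission/leakage with per-MU normalisation, including the
  sliding 10 × 10 mm window maximum via an integral image.
* Field size as profile FWHM, on films and scanned profiles.

**Dosimetric**

* 20–80 % penumbra, pointwise flatness (measured − TPS) and mirror
  symmetry M(−x) − M(+x), with ±2 % windows.
* Field output factors and percent differences (TPS denominator).
* 2-D gamma, 3 %/3 mm global with 10 % cutoff, node-aligned resampling,
  validated against an exhaustive oracle.
* Couch attenuation-factor deviations, gated-vs-non-gated dose deviation
  100 (Dng − Dg)/Dng, and beam-off latency from cine traces (half-frame
  accuracy).
* Reference dosimetry D = M · N<sub>D,w</sub> · k<sub>Q</sub> ·
  k<sub>B</sub> with k<sub>Q</sub> interpolation and a magnetic-field
  correction factor.

**MRI**

* B0 homogeneity: resonance-peak FWHM converted to ppm of the central
  frequency (5 ppm tolerance), plus a permissible-range check on the
  frequency itself.
* NEMA single-image SNR (0.66 · mean / background SD), uniformity, ACR
  percent signal ghosting, percent integral uniformity, slice thickness
  and position.
* Grid-phantom spatial integrity with per-radial-bin deviations.

**Reporting** — a tolerance registry with explicit inclusive/strict
comparators, YAML site overrides, grouped pass/fail reports rendered to
JSON (lossless round trip) or markdown.

Every analysis is paired with a synthetic generator (`genStarshotFilm()`,
`genPicketFenceFilm()`, `genFieldProfile()`, `genSpectrum()`,
`genGridPhantomImage()`, `genMotionTrace()`, …) that embeds its ground
truth, so the whole pipeline runs and is verifiable without hardware. See
the vignette `vignettes/mrlinac-acceptance-methods.Rmd` for models,
conventions and numerical choices.

## Worked example

```r
library(mrlqa)

# A starshot with spokes offset 0.6 mm in alternating directions: the
# minimum tangent circle has radius 0.6 mm about the film centre.
film <- genStarshotFilm(spokeOffsetsMM = 0.6 * c(1, -1, 1, -1, 1), seed = 1)
star <- analyzeStarshot(film, nSpokes = 5)
star
#> Starshot: 5 spokes, centre (0.000, 0.005) mm, radius 0.605 mm

# Laser-relative isocenter shifts compose to the MRI-to-RT displacement.
shift <- composeIsocenterShifts(mrToLaser = c(0, 0, 0),
                                rtToLaser = c(0.0, -0.4, -0.5))
mrToRt(shift)
#> [1] 0.0 0.4 0.5

# B0 homogeneity from a resonance spectrum: 83.21 Hz FWHM at 14,713,851 Hz.
sp <- genSpectrum(centerFrequencyHz = 14713851, fwhmHz = 83.21,
                  nominalF0 = 14713851)
spectralHomogeneity(sp)
#> B0 homogeneity: FWHM 83.21 Hz at f0 1.47139e+07 Hz -> 5.7 ppm (out of tolerance)

# Assemble a toleranced report.
res <- data.frame(
  metricId = c("starshot_radius", "b0_homogeneity", "couch_attenuation"),
  value = c(star$radiusMM, spectralHomogeneity(sp)$ppm, -1.0))
cat(renderReport(buildReport(res), "markdown"))
#> | metric | value | tolerance | units | verdict | source |
#> |---|---|---|---|---|---|
#> | starshot_radius | 0.6052 | abs_le 1 | mm | pass | isocentricity, minimum tangent circle |
#> | couch_attenuation | -1 | abs_le 1 | % | pass | results tolerance (stricter default) |
#> | b0_homogeneity | 5.655 | le 5 | ppm | fail | 24 cm DSV peak-to-peak |
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/mrlqa` (subcommands `b0`, `starshot`, `picket`, `report`).

## License

MIT (see `LICENSE`).
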