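---
title: "Methods: acceptance-test analyses for a low-field MR-Linac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acceptance-test analyses for a low-field MR-Linac}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlqa)
```

This vignette documents the models, conventions and numerical choices behind
each analysis in `mrlqa`. The package targets commissioning and acceptance
testing of a 0.35 T MR-Linac: a double-focused MLC defining the field (no
jaws), a flattening-filter-free (FFF) 6 MV beam, and an integrated MRI whose
isocenter must coincide with the radiation isocenter. Every analysis can be
exercised against the synthetic generators, which embed known ground truth
for verification.

## Coordinate frames and isocenter coincidence

Three frames are used, all in millimetres and related by axis permutations
for a head-first supine setup:

* `linac_iec` — IEC 61217 machine frame: x cross-plane, y in-plane
  (toward gantry), z up.
* `mri_dicom` — DICOM patient frame: x left, y posterior, z superior.
* `laser_dicom` — the laser-bridge frame, aligned with `mri_dicom`.

`convertFrame()` maps vectors between frames; the conversions are exact
permutations with sign flips, so round trips are lossless.

Because neither the MRI nor the radiation isocenter can be observed
directly against the other, each is measured against the laser origin and
the two measurements are composed by vector subtraction:

\[
\Delta_{MR \to RT} \;=\; \Delta_{MR \to laser} \;-\; \Delta_{RT \to laser}.
\]

`composeIsocenterShifts()` stores all three vectors in an
`IsocenterShiftSet` whose validity check enforces the identity, so an
inconsistent object cannot be constructed. With a zero MRI-to-laser shift
and a radiation-to-laser shift of (0.0, −0.4, −0.5) mm, the composed
MRI-to-radiation shift is:

```{r}
mrToRt(composeIsocenterShifts(c(0, 0, 0), c(0.0, -0.4, -0.5)))
```

## Starshot analysis: the minimum tangent circle

A starshot film exposes narrow strips at several gantry angles; each strip
is a chord whose supporting line should pass through the radiation
isocenter. The isocentricity metric is the radius of the smallest circle
tangent to (i.e. touching) every spoke line — equivalently the Chebyshev
center of the line set: the point minimising the maximum perpendicular
distance to the lines.

`analyzeStarshot()` proceeds in three steps:

1. **Spoke sampling.** Intensity is sampled on four concentric circles at
   0.45, 0.6, 0.75 and 0.9 of the largest inscribed radius, at 1440
   angular positions each. Runs above a threshold midway between the
   maximum and the median are grouped (with wrap-around merging) and the
   intensity-weighted angular centroid of each run gives one
   circle-crossing point.
2. **Line fitting.** Crossings are clustered by orientation (angle modulo
   180°) by cutting the sorted orientations at the largest circular gaps.
   Distinct spokes must be separated by at least 5° — far above the
   sub-degree jitter of crossings belonging to one spoke — so a film with
   fewer spokes than requested raises an error rather than silently
   splitting a cluster. Each cluster is fit by orthogonal regression
   (principal axis through the crossing centroids), which treats both
   coordinates symmetrically, unlike ordinary least squares.
3. **Minimax center.** The maximum line distance is a piecewise-linear
   convex function, so its minimiser is determined by at most three active
   lines with resolved residual signs. The solver enumerates all
   sign-resolved triples (each a 3×3 linear solve), polishes the best
   candidate with Nelder–Mead, and breaks ties toward the least-squares
   center. The test suite validates this solver against a brute-force
   0.01 mm grid oracle.

A geometric subtlety governs the synthetic ground truth: displacing each
spoke line by a distance $r$ along its left normal does *not* in general
make the $r$-circle about the original center minimal. It does when the
displaced lines' signed normals positively span the plane, which is
achieved by alternating the offset signs (e.g. `0.6 * c(1, -1, 1, -1, 1)`
for five spokes 36° apart). `genStarshotFilm()` documents this, and the
tangent-circle recovery tests rely on it.

## Picket fence: MLC leaf position

`genPicketFenceFilm()` renders strips with logistic (soft) edges at
nominal centres plus injected shifts. `analyzePicketFence()` averages the
film along the leaf-travel direction, searches ±15 mm around each nominal
position, and locates each strip peak with a three-point parabolic
interpolation, giving sub-pixel resolution (the tests demand half-pixel
accuracy over 100 randomized trials at 0.5 mm pixels). Summary statistics
use the sample (n−1) standard deviation via `leafShiftStats()`.

## MLC transmission and leakage

Closed-leaf transmission films are compared against a reference open
field delivered with far fewer monitor units (MU). Readings are
normalised per MU before taking the ratio:

\[
L_{avg} = 100 \cdot \frac{\bar D_{leak}/MU_{leak}}{D_{ref}/MU_{ref}},
\qquad
L_{max} = 100 \cdot \frac{\max_W \bar D_W / MU_{leak}}{D_{ref}/MU_{ref}},
\]

where the maximum runs over all fully-contained 10 × 10 mm windows. The
sliding-window mean is computed with an integral image (summed-area
table), which is exact and linear-time; the tests check it against an
exhaustive double-loop oracle.

## Profiles: FWHM, penumbra, flatness/symmetry

`genFieldProfile()` models an FFF field as logistic edges times a central
quadratic dome. Logistic edges have two convenient closed forms used
throughout the tests: the 20–80 % penumbra of a logistic of scale $s$ mm
is $2 s \ln 4$, and the half-maximum sits at the edge location. Because
the dome multiplies the edge profile, the generator applies an analytic
edge correction — the half-width is widened by
$s \log\!\big((1+a)/(1-a)\big)$ where $a$ is the relative dome amplitude
at the edge — so the noiseless FWHM equals the nominal width exactly
rather than shrinking with dome height.

`fwhm()` finds half-maximum crossings by linear interpolation and insists
on exactly two crossings (multi-lobe inputs error out). `penumbra()`
reports the 20–80 % distance per edge; since both thresholds are relative
to the profile maximum, renormalisation cannot change the result, and the
`normalize` flag is a reporting convention only.

Flatness is compared pointwise as measured-minus-calculated percent dose
at matched off-axis positions; symmetry is the difference between
mirror-position measured doses, $M(-x) - M(+x)$, both with a ±2 %
acceptance window. These conventions — differences of percent-of-maximum
doses rather than ratios — reproduce typical commissioning worksheets and
are exercised against worked values in the tests.

## 2-D gamma (3 %/3 mm, global)

`gamma2d()` implements the standard gamma index with global normalisation
(dose criterion as a percentage of the reference maximum) and a 10 % low-dose
cutoff. The evaluation grid is bilinearly resampled at a step chosen as an
exact divisor of the evaluation pixel spacing,
`step = spacing / ceiling(spacing / (0.1 * dta))`, so the fine grid contains
the original nodes. Without this alignment, identical inputs would score a
spurious nonzero gamma. Pass is declared at $\gamma \le 1 + 10^{-6}$ so the
analytic boundary case — a uniform dose offset exactly equal to the dose
criterion, which must give $\gamma \equiv 1$ — passes deterministically.
The implementation is validated against an exhaustive oracle with no search
radius on small grids; the production path caps the search at three DTA
radii, beyond which $\gamma$ would exceed any passing value from distance
alone.

## Couch attenuation

Transmission through the couch is characterised by the ratio of an open
reading to a couch-attenuated reading at each gantry angle (an
*attenuation factor* ≥ 1 when the couch attenuates). Measured and
TPS-calculated factors are compared as a percent deviation with the TPS
value in the denominator, rounded to one decimal:

\[
d = 100\,\frac{F_{meas} - F_{tps}}{F_{tps}}.
\]

The percentage attenuation forms $100 (1 - r/r_0)$ are also provided
(`couchAttenuationMeas()`, `couchAttenuationCalc()`), but the factor-based
deviation is the comparison convention used in reports because it is the
one under which measured-vs-calculated tables are internally consistent at
the printed precision. A ±3 % window applies to the method itself and a
stricter ±1 % window to the site results; the registry carries both.

## Gating and beam-off latency

Gated-vs-non-gated dose deviation uses the non-gated reading as the
reference, $100 (D_{ng} - D_g)/D_{ng}$, reported as a two-decimal
magnitude with the signed value preserved as an attribute.

Beam-off latency is estimated from a cine trace of target position and
beam state. The boundary-crossing time is found by linear interpolation of
the position samples; the beam-off time is the midpoint between the last
beam-on and first beam-off frames, which is unbiased under uniform phase.
The estimate is therefore accurate to half a frame period — ±0.125 s at
4 frames/s — and the tests verify both single-trace recovery within that
bound and near-zero mean error over 100 randomized-phase trials.

## B0 homogeneity and central frequency

Magnet homogeneity is reported as the full width at half maximum of the
proton resonance peak, converted to parts per million of the central
frequency: $ppm = FWHM_{Hz}/f_0 \times 10^6$, with a 5 ppm tolerance over
a 24 cm spherical volume. By default the nominal central frequency
(14,701,760 Hz at 0.345 T) is used as the denominator rather than the
fitted peak location: the denominator is then a fixed instrument constant,
and the two choices differ only at the $10^{-3}$ ppm level for any
realistic shim. The measured frequency itself is checked separately
against the permissible range 14,701,760 ± 15,000 Hz
(`checkCentralFrequency()`). An optional odd moving-average
(`smoothBins`) stabilises the half-maximum search for noisy spectra.

## SNR, uniformity and image-quality metrics

Single-image SNR follows the NEMA estimate $0.66\,\bar S/\sigma_{bg}$,
with 0.66 correcting the Rayleigh-distributed background noise of a
magnitude image. Uniformity is $100\,(1 - (S_{max}-S_{min})/(S_{max}+S_{min}))$
after a 3 × 3 mean prefilter (computed with the same integral-image
helper as the leakage window, so no image-processing dependency is
needed); percent integral uniformity is the identical formula on an
ACR-style ROI. Percent signal ghosting is
$|(T+B)-(L+R)|/(2 S_{center})$ over four edge ROIs. Slice thickness uses
the ramp-phantom form $0.2\,(t\cdot b)/(t+b)$ and slice position half the
bar-length difference.

## Spatial integrity

`genGridPhantomImage()` renders Gaussian markers on a grid and can warp
them with an arbitrary distortion field; nominal and actual positions are
stored as ground truth. `spatialIntegrity()` detects each marker by
background-subtracted center of mass in a window around its nominal
position (background as the 20 % intensity quantile), errors if fewer
than 90 % of markers are found, and reports mean/max deviation overall
and per radial bin so concentric-volume tolerances (e.g. 1 mm within a
20 cm sphere, 2 mm to 35 cm) can be applied via the registry.

## Synthetic generators: realism and limits

The generators are designed for *verifiability*, not photorealism: each
embeds its ground truth in the returned object, uses explicit seeds
(restoring the caller's RNG state), and keeps noise additive Gaussian.
They omit film-scanner artefacts (lateral response, Newton rings), MLC
tongue-and-groove structure, spectrum baseline roll and B0 drift, and MRI
bias fields. Problem sizes (e.g. 551-pixel-wide picket films at 0.5 mm,
1440 angular samples for spoke extraction, 0.01 mm oracle grids) are the
package's own choices balancing sub-pixel accuracy targets against a
test-suite runtime of minutes on one CPU.

## Tolerances and reporting

`defaultToleranceRegistry()` encodes the acceptance tolerances with
explicit comparators: inclusive `le`/`ge`/`abs_le`/`within_range` and
strict `lt`/`gt` for tolerances stated as strict inequalities; metrics
without a manufacturer tolerance (field output factors) are carried as
informational (`none` → verdict `n/a`). `buildReport()` joins measured
values to the registry, orders results mechanical → dosimetric → MRI, and
`renderReport()` emits JSON (lossless round trip via `parseReport()`) or
markdown. Site-specific overrides load from YAML.
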