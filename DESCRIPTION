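Package: mrlqa
Title: Acceptance-Test Analysis for a 0.35 T MR-Linac
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mechanical, dosimetric and MRI acceptance-test analyses for a
    low-field (0.35 T) MR-Linac: starshot isocentricity via the minimum
    tangent circle, picket-fence MLC position accuracy, MLC transmission and
    inter-leaf leakage, FWHM field size, 20-80 penumbra, pointwise flatness
    and symmetry, field output factors, 2-D gamma comparison, couch
    attenuation, gating dose deviation and beam-off latency, B0 homogeneity
    as spectral FWHM in ppm, NEMA SNR and uniformity, ACR-style image-quality
    metrics, and grid-phantom spatial integrity.  A synthetic-data generator
    with known ground truth stands in for the machine so every analysis is
    exercisable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
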