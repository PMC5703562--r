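Package: slidescope
Title: Virtual Slide Scanning, Field Triage and Telecytology Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A virtual automated tablet-microscope for oral brush-biopsy
    telecytology. Generates ground-truth synthetic H&E-stained liquid-cytology
    slides (dispersed and clumped squamous cells, normal and atypical
    morphology, a non-flat focal surface), renders field-of-view images
    through a simple defocus-blur optics model, and implements the
    acquisition stack of an automated slide scanner: a variance-of-Laplacian
    focus metric, coarse-to-fine Z-search autofocus with warm starts, and a
    125-field raster-scan controller. Acquired fields are triaged for
    diagnostic adequacy (cell density, blur, clumping) with the 30%/50%
    density rules and 60-100 field selection band used in telepathology
    screening practice. A concordance module computes Cohen's kappa with
    observed and chance agreement, and screening sensitivity/specificity
    against histology or cytology gold standards, and ships a 32-patient
    oral-lesion diagnosis table as a packaged fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
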