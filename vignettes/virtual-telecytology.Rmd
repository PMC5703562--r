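---
title: "A virtual automated tablet-microscope for brush-biopsy telecytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A virtual automated tablet-microscope for brush-biopsy telecytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Why a virtual instrument

Point-of-care oral cancer screening programmes in South Asia pair a
minimally invasive brush biopsy with an automated, tablet-based slide
scanner: the device autofocuses, raster-scans the smear, captures on
the order of 125 fields of view, a technician triages the images for
diagnostic adequacy, and remote pathologists call each case positive
(carcinoma or dysplasia) or negative. The hardware side of such a
system — stage motors, optics, Bluetooth — is not reproducible in
software, but every algorithmic decision it makes is. `slidescope`
re-implements that acquisition stack against a *synthetic* slide whose
ground truth is known exactly, which turns the scanner's behaviour
(does autofocus find the focal surface? does the density estimate track
true coverage? does triage enforce the adequacy rules?) into testable
propositions. The companion concordance module reproduces the
evaluation statistics of a 32-patient pilot of such a system from its
packaged per-patient diagnosis table.

## The synthetic slide

`generate_slide()` emulates a liquid-based cytology preparation of an
oral brush biopsy.

**Cell placement.** Dispersed cells follow a homogeneous Poisson
(Boolean) process over the central placement region of the slide
(default: the central 70% of each dimension — smears are deliberately
spread near the slide centre). For a Boolean model, expected areal
coverage is `1 - exp(-lambda * E[A])`, so the generator inverts the
requested `target_coverage` into the intensity
`lambda = -log(1 - target_coverage) / E[A]`, with `E[A]` the mean
cytoplasm ellipse area. The expected coverage of any interior field
therefore *equals* the target without calibration constants; the test
suite checks the realised grid average to ±0.05. Clumps are
Matérn-style clusters (default 4 parents, 80 µm radius, 20 daughter
cells) superimposed on the dispersed population; they add under one
percentage point of coverage at the defaults.

**Morphology.** Each cell is a rotated ellipse (semi-major axis
18–30 µm, aspect 0.6–0.95 — squamous epithelial scale) containing a
concentric similar nucleus ellipse scaled by `sqrt(nc_area_ratio)`, so
the nuclear/cell *area* ratio is exact by construction. The nucleus
centre may be offset by at most `0.8 * (1 - sqrt(nc)) * b`, a bound that
provably keeps the nucleus inside the cytoplasm for any offset
direction. Atypical cells — the features pathologists actually call
positive on — are encoded as a high nucleus-to-cytoplasm ratio
(0.45–0.70 vs 0.06–0.20 for normal cells) and hyperchromatic nuclei
(chromatin intensity 0.60–0.95 vs 0.15–0.45), rendered darker. The
default atypical fraction is 0.25: these are smears from patients with
clinically suspicious lesions, not population screening, so a
substantial atypical population is the realistic default. Other atypia
features (polynucleation, mitotic figures, nucleoli, membrane
irregularity) are deliberately not modelled — nothing downstream
consumes them.

**Focal surface.** Best focus varies across a real slide by more than
the instrument's micrometre-scale depth of field. The generator models
`z*(x, y) = a0 + a1 x + a2 y + a3 x^2 + a4 y^2` with default
coefficients giving a few-µm tilt plus mild curvature across the
scanned area — enough that a scanner which never refocused would drift
out of focus within a row.

## The optics model

Fields are rendered through `optics_model()`: a 20X/0.4NA objective
(the magnification/FOV compromise chosen for this application),
three-colour H&E-like palette, and a defocus model in which the
Gaussian PSF sigma is

    sigma(dz) = max(0, k * (|dz| - DOF/2)),   DOF = lambda / NA^2 ≈ 3.44 µm

i.e. perfectly sharp across the depth of field, then linearly growing
blur — the standard incoherent-imaging approximation. `k` defaults to
0.2 µm of sigma per µm of defocus (of the order of the geometric blur
cone `NA·dz` for this NA). Blur is applied per channel in the frequency
domain with periodic boundaries (field borders are background, so
wrap-around is immaterial). Additive Gaussian sensor noise (default
2/255 per channel) is seeded deterministically from the slide seed and
the stage position, then the image is clipped and quantised to 8-bit.
The physical pixel pitch of the real tablet-plus-objective system is
not published; 0.5 µm/pixel at the sample plane (512 px ≈ 256 µm field)
was chosen once as a plausible value and is configurable.

Ground-truth masks always come from the *unblurred* geometry, so
`true_coverage()` is exact regardless of focus.

## Autofocus

The focus metric is the population variance of the discrete
4-neighbour Laplacian of the Rec.601 luminance over every interior
pixel, on [0, 1]-scaled intensities — zero for any uniform image and
invariant to adding a constant. The search is two-stage: a coarse pass
(±30 µm in 6 µm steps, centred on the previous field's best focus) and
a fine pass (±5 µm in 1 µm steps around the coarse optimum).

Three numerical choices deserve explanation:

* **Plateau tie-break.** Because the PSF model is *exactly* sharp
  across the depth of field, the metric is flat-topped over ~3.4 µm
  around true focus; a raw argmax inside that plateau would be decided
  by sensor noise. `best_z` is therefore the evaluated candidate
  closest to the centre of the plateau (all candidates within 5% of the
  maximum metric) — the usual flat-peak treatment in autofocus
  practice, and what makes sub-fine-step recovery of the focal surface
  possible at all.
* **Contrast floor.** Sensor noise alone gives the metric an expected
  value of about `20 * noise_sigma^2` (the Laplacian kernel's
  coefficient sum of squares), ≈ 1.2e-3 at default noise. The flat
  floor (2e-3) sits just above it, so blank fields report `flat`
  and keep the warm-start height rather than chasing noise — sparse
  hyperkeratotic (leukoplakia-like) smears are exactly where real
  autofocus struggles.
* **Focus window.** During the z-search the metric is evaluated on a
  central 128-px crop; the final capture is full-frame. This is a pure
  speed measure (it keeps a default 125-field scan under two minutes on
  one CPU) and matches how real autofocus uses a focus ROI.

`execute_scan()` walks a serpentine 5 × 25 grid (125 fields) with
autofocus at every field (`refocus_every` is configurable; whether the
real device refocused at every field is not documented).

## Triage

Adequacy rules follow the deployed acquisition protocol: discard
fields under ~30% cell density or blurry or clumped; prefer fields
over 50% density; assemble 60–100 adequate images; below 60, flag the
slide (`sparse_mode`) for manual capture.

* **Density** is the foreground fraction, where foreground means RGB
  distance from the background colour above 0.15 — far below the
  cytoplasm (~0.45) and nucleus (~1.2) distances, far above sensor
  noise. An Otsu fallback on the distance map exists for foreign
  palettes but is *not* the default: on three-mode H&E distance
  distributions Otsu tends to split cytoplasm from nuclei instead of
  stain from background.
* **Blur** is relative, because "perceived blurry" has no published
  cutoff: a field is flagged when its focus score is below 25% of the
  median score of the scan's dense (≥30%) fields. Content-poor fields
  can be flagged by this rule; they are discarded as sparse anyway.
* **Clumping** is a two-condition heuristic standing in for a human
  judgement: the largest 4-connected foreground component must exceed
  20% of the field *and* be nuclear-rich (nuclear-pixel fraction above
  1.5× the scan median) — piled-up cells present more nuclear material
  per unit area than a monolayer.

Survivors are ranked (≥50% density first, then by density, ties by
scan order) and the top 100 selected. All thresholds are `triage_policy()`
arguments; none is buried in code.

## Concordance statistics

`cohen_kappa()` computes chance-corrected two-rater agreement

    kappa = (Pr(a) - Pr(e)) / (1 - Pr(e))

with observed agreement `Pr(a) = (a + d)/n` and chance agreement
`Pr(e)` the sum of the products of marginal proportions, using integer
numerators over the exact denominators `n` and `n²`; degenerate
marginals (`Pr(e) = 1`) are an explicit error. Sensitivity
`tp/(tp+fn)` and specificity `tn/(tn+fp)` return `NA`, never 0, on a
zero denominator. Reported percentages round half *away from zero*
(46.67 → 47, 90.48 → 90), matching the convention of the published
tables this package reproduces; kappa reports to 3 decimals, agreement
proportions to 2-decimal percentages.

The packaged fixture (`oral_cytology_calls.csv`, checksum-verified) is
the 32-patient table of a pilot study: histology and cytology calls
plus two pathologists' independent readings of the scanner images.
Two quirks of the source table are handled deliberately: the one
non-squamous (lymphoma) case is encoded histology-negative because
squamous carcinoma was the screening target, and the fixture follows
the per-patient table's columns and sexes where the source's summary
tables disagree with it. Post-discordance consensus calls were never
published per patient, so consensus is reported only as the list of
discordant records, never imputed.

## What the simulator does and does not establish

The generator reproduces the features the *algorithms* are sensitive
to: coverage statistics, sparse-vs-dense contrast, clump geometry,
defocus blur, sensor noise, a drifting focal surface. It does not
emulate staining variability, debris, folded or overlapping cytoplasm
texture, chromatin patterns, uneven illumination, or a camera ISP.
Green acquisition/triage tests therefore establish that the
*implementation* honours its contracts on a world where ground truth
is knowable — not that the thresholds would be optimal on clinical
images. The concordance module, by contrast, reproduces the published
statistics exactly, because its input is the published table itself.

Scaling note: unit tests run the same code paths on small optics
(64–128 px fields, 1 µm/px) and small slides to keep the suite fast;
the acceptance checks run one full-size default scan (125 fields at
512 px) against its two-minute budget.

## Reproducibility

Every stochastic step derives from one integer seed: slide generation
uses it directly, and each rendered field's noise is seeded from
`(slide seed, x, y, z)`, so any field re-rendered at the same position
is byte-identical regardless of call order. A `run_config()` persists
every resolved parameter to the run manifest; a pipeline re-run from
the same config reproduces images, focus trajectory and triage report
exactly.
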