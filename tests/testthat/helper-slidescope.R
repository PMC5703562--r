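# Shared fixtures: everything is generated in code at test time.

# Small optics for fast rendering in unit tests (1 um/px, 96x96 px).
small_optics <- function(h = 96, w = h, pixel_pitch = 1,
                         noise_sigma = 2 / 255, ...) {
  optics_model(field_shape = c(h, w), pixel_pitch = pixel_pitch,
               noise_sigma = noise_sigma, ...)
}

# Small dense-ish slide, flat-ish focal surface unless overridden.
test_slide <- function(seed = 7, target_coverage = 0.5,
                       extent = c(2000, 1000), n_clumps = 0,
                       focal_coef = c(0, 0, 0, 0, 0), ...) {
  generate_slide(slide_params(extent = extent,
                              target_coverage = target_coverage,
                              n_clumps = n_clumps,
                              focal_coef = focal_coef, ...),
                 seed = seed)
}

# Replace a slide's cells with a single hand-built cell; keeps the
# object's determinism machinery (seed etc.) intact.
one_cell_slide <- function(x, y, cyto_a = 30, cyto_b = 24, theta = 0,
                           nc = 0.49, chromatin = 0.8,
                           off = c(0, 0), seed = 11,
                           extent = c(400, 400),
                           label = "atypical") {
  sl <- generate_slide(slide_params(extent = extent, target_coverage = 0,
                                    n_clumps = 0,
                                    focal_coef = c(0, 0, 0, 0, 0)),
                       seed = seed)
  s <- sqrt(nc)
  sl$cells <- data.frame(x = x, y = y, cyto_a = cyto_a, cyto_b = cyto_b,
                         theta = theta, nuc_a = s * cyto_a,
                         nuc_b = s * cyto_b,
                         off_x = off[1], off_y = off[2],
                         nc_area_ratio = nc, chromatin = chromatin,
                         label = label, stringsAsFactors = FALSE)
  sl
}

# Synthetic per-field assessment rows for triage-policy tests.
fake_assessments <- function(density, blur = FALSE, clump = FALSE,
                             focus = 0.05) {
  n <- length(density)
  data.frame(field_id = seq_len(n), density = density,
             focus_score = rep_len(focus, n),
             blur_flag = rep_len(blur, n),
             clump_flag = rep_len(clump, n))
}
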