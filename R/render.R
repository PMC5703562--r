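# Field rasterisation and optical rendering.
#
# Rasterisation (geometry -> masks) is separated from the optics
# (masks -> blurred, noisy 8-bit RGB) so that autofocus can re-render
# one field at many z positions without re-rasterising.

# Pixel-centre coordinates of a field centred at (x, y).
# Row 1 is the top of the image (largest y), column 1 the left.
field_grid <- function(optics, x, y) {
  h <- optics$field_shape[1]
  w <- optics$field_shape[2]
  p <- optics$pixel_pitch
  list(xs = x + (seq_len(w) - (w + 1) / 2) * p,
       ys = y + ((h + 1) / 2 - seq_len(h)) * p)
}

check_in_extent <- function(slide, x, y) {
  if (x < 0 || x > slide$extent[1] || y < 0 || y > slide$extent[2]) {
    stopf("stage position (%g, %g) outside slide extent %g x %g um",
          x, y, slide$extent[1], slide$extent[2])
  }
}

# Rasterise the ground-truth geometry of one field: logical cytoplasm
# and nucleus masks plus the per-pixel chromatin intensity. Cells are
# painted in table order (later cells overwrite earlier where they
# overlap), with each cell's nucleus over its cytoplasm.
rasterize_field <- function(slide, optics, x, y) {
  check_in_extent(slide, x, y)
  g <- field_grid(optics, x, y)
  h <- optics$field_shape[1]
  w <- optics$field_shape[2]
  cyto <- matrix(FALSE, h, w)
  nuc <- matrix(FALSE, h, w)
  chrom <- matrix(0, h, w)

  cells <- slide$cells
  if (nrow(cells) > 0) {
    fov <- field_of_view(optics)
    rmax <- cells$cyto_a
    keep <- which(abs(cells$x - x) <= fov[1] / 2 + rmax &
                  abs(cells$y - y) <= fov[2] / 2 + rmax)
    for (i in keep) {
      ce <- cells[i, ]
      jr <- which(abs(g$xs - ce$x) <= ce$cyto_a)
      ir <- which(abs(g$ys - ce$y) <= ce$cyto_a)
      if (length(jr) == 0 || length(ir) == 0) next
      dx <- g$xs[jr] - ce$x
      dy <- g$ys[ir] - ce$y
      ct <- cos(ce$theta); st <- sin(ce$theta)
      # rotated frame: u along the major axis, v along the minor axis
      u <- outer(dy * st, dx * ct, "+")
      v <- outer(dy * ct, -dx * st, "+")
      inside_c <- (u / ce$cyto_a)^2 + (v / ce$cyto_b)^2 <= 1
      # nucleus offset is stored in the cell's rotated frame
      un <- u - ce$off_x
      vn <- v - ce$off_y
      inside_n <- (un / ce$nuc_a)^2 + (vn / ce$nuc_b)^2 <= 1
      sub_c <- cyto[ir, jr, drop = FALSE]
      sub_n <- nuc[ir, jr, drop = FALSE]
      sub_ch <- chrom[ir, jr, drop = FALSE]
      sub_c[inside_c] <- TRUE
      sub_n[inside_c] <- FALSE     # painter's order: this cell wins
      sub_ch[inside_c] <- 0
      sub_n[inside_n] <- TRUE
      sub_ch[inside_n] <- ce$chromatin
      cyto[ir, jr] <- sub_c
      nuc[ir, jr] <- sub_n
      chrom[ir, jr] <- sub_ch
    }
  }
  list(cyto_mask = cyto, nucleus_mask = nuc, chromatin = chrom,
       coverage = mean(cyto), true_z = focal_z(slide, x, y),
       x = x, y = y)
}

# Turn a rasterised field into an 8-bit RGB image at stage height z:
# palette colours, defocus blur, additive Gaussian noise, clipping.
apply_optics <- function(raster, optics, z, seed) {
  pal <- optics$palette
  h <- nrow(raster$cyto_mask)
  w <- ncol(raster$cyto_mask)
  cyto_only <- raster$cyto_mask & !raster$nucleus_mask
  # hyperchromatic nuclei render darker
  nuc_scale <- 1 - 0.5 * raster$chromatin
  channels <- lapply(1:3, function(k) {
    ch <- matrix(pal$background[k], h, w)
    ch[cyto_only] <- pal$cytoplasm[k]
    ch[raster$nucleus_mask] <- pal$nucleus[k] * nuc_scale[raster$nucleus_mask]
    ch
  })
  sigma_px <- psf_sigma(optics, z - raster$true_z) / optics$pixel_pitch
  if (sigma_px > 0) {
    channels <- lapply(channels, gaussian_blur, sigma_px = sigma_px)
  }
  if (optics$noise_sigma > 0) {
    noise <- with_fixed_seed(seed,
      stats::rnorm(h * w * 3, sd = optics$noise_sigma))
    dim(noise) <- c(h, w, 3)
    channels <- lapply(1:3, function(k) channels[[k]] + noise[, , k])
  }
  px <- array(0L, dim = c(h, w, 3))
  for (k in 1:3) {
    px[, , k] <- as.integer(round(pmin(1, pmax(0, channels[[k]])) * 255))
  }
  px
}

#' Render one field-of-view image of a virtual slide
#'
#' Produces the 8-bit RGB image the tablet camera would record with the
#' stage at `(x, y)` and the focus drive at height `z`. Defocus
#' `|z - z*(x, y)|` beyond half the depth of field blurs the image with
#' a Gaussian PSF; ground-truth masks are computed from the unblurred
#' geometry. Rendering is deterministic: the noise field is seeded from
#' the slide seed and the stage position.
#'
#' @param slide a [generate_slide()] result.
#' @param optics an [optics_model()].
#' @param x,y stage position, micrometres (must lie within the slide).
#' @param z focus height, micrometres.
#' @param capture_mode `"automated"` or `"manual"`.
#' @param with_ground_truth keep the ground-truth masks on the image?
#' @return an object of class `field_image`: `pixels` (HxWx3 integer,
#'   0-255), `stage_position`, `capture_mode`, `focus_metric_value`
#'   (filled by the scanner), and `ground_truth` (`cell_mask`,
#'   `nucleus_mask`, `coverage`, `true_z`) when requested.
#' @export
render_field <- function(slide, optics, x, y, z = 0,
                         capture_mode = c("manual", "automated"),
                         with_ground_truth = TRUE) {
  capture_mode <- match.arg(capture_mode)
  raster <- rasterize_field(slide, optics, x, y)
  field_from_raster(raster, slide, optics, z, capture_mode,
                    with_ground_truth)
}

# Shared by render_field() and the scanner's cached-raster path.
field_from_raster <- function(raster, slide, optics, z, capture_mode,
                              with_ground_truth = TRUE) {
  px <- apply_optics(raster, optics, z,
                     seed = mix_seed(slide$seed, raster$x, raster$y, z))
  gt <- NULL
  if (with_ground_truth) {
    gt <- list(cell_mask = raster$cyto_mask,
               nucleus_mask = raster$nucleus_mask,
               coverage = raster$coverage,
               true_z = raster$true_z)
  }
  structure(
    list(pixels = px,
         stage_position = c(x = raster$x, y = raster$y, z = z),
         capture_mode = capture_mode,
         focus_metric_value = NULL,
         ground_truth = gt),
    class = "field_image"
  )
}

#' @export
print.field_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<field_image> %dx%d px, %s capture at (%.0f, %.0f, %.2f) um%s\n",
              d[1], d[2], x$capture_mode,
              x$stage_position[1], x$stage_position[2], x$stage_position[3],
              if (!is.null(x$ground_truth))
                sprintf(", true coverage %.3f", x$ground_truth$coverage)
              else ""))
  invisible(x)
}

#' Ground-truth cellular coverage of a field
#'
#' Fraction of the field of view covered by cellular material, computed
#' from the unblurred geometry masks (the "true" side of the density
#' estimate the triage module makes from pixels).
#'
#' @inheritParams render_field
#' @return fraction in `[0, 1]`.
#' @export
true_coverage <- function(slide, optics, x, y) {
  rasterize_field(slide, optics, x, y)$coverage
}

#' Write a field image (and optional ground truth) to disk
#'
#' The RGB image is written as a lossless 8-bit PNG. When ground truth
#' is present and `with_ground_truth = TRUE`, binary cell/nucleus mask
#' PNGs and a JSON sidecar (`x`, `y`, `z`, `true_z`, `coverage`) are
#' written next to it.
#'
#' @param image a [render_field()] result.
#' @param path output PNG path.
#' @param with_ground_truth also write masks and the JSON sidecar?
#' @return `path`, invisibly.
#' @export
write_field_png <- function(image, path, with_ground_truth = FALSE) {
  png::writePNG(image$pixels / 255, target = path)
  if (with_ground_truth && !is.null(image$ground_truth)) {
    base <- sub("\\.png$", "", path)
    gt <- image$ground_truth
    png::writePNG(gt$cell_mask * 1, target = paste0(base, "_cells.png"))
    png::writePNG(gt$nucleus_mask * 1, target = paste0(base, "_nuclei.png"))
    side <- list(x = unname(image$stage_position[1]),
                 y = unname(image$stage_position[2]),
                 z = unname(image$stage_position[3]),
                 true_z = gt$true_z,
                 coverage = gt$coverage)
    jsonlite::write_json(side, paste0(base, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read an RGB field image from a PNG file
#'
#' For standalone triage of externally acquired fields; the result has
#' no ground truth attached.
#'
#' @param path PNG path.
#' @param capture_mode capture mode to record.
#' @return a `field_image`.
#' @export
read_field_png <- function(path, capture_mode = "manual") {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2) {
    arr <- array(rep(arr, 3), dim = c(dim(arr), 3))
  }
  if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
  px <- array(as.integer(round(arr * 255)), dim = dim(arr))
  structure(
    list(pixels = px,
         stage_position = c(x = NA_real_, y = NA_real_, z = NA_real_),
         capture_mode = capture_mode,
         focus_metric_value = NULL,
         ground_truth = NULL),
    class = "field_image"
  )
}
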