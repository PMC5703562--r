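# Acquisition stack: focus metric, coarse-to-fine autofocus, raster scan.

#' Variance-of-Laplacian focus metric
#'
#' The scanner judges focus by image contrast: the image is converted to
#' luminance (Rec.601 weights 0.299, 0.587, 0.114) on a 0-1 scale, the
#' discrete 4-neighbour Laplacian (3x3 kernel: centre -4, N/S/E/W +1) is
#' computed over every interior pixel where the kernel fits, and the
#' population variance of the Laplacian values is returned. Adding a
#' constant to all pixels leaves the metric unchanged; a uniform image
#' scores exactly zero.
#'
#' @param image a `field_image`, an HxWx3 RGB array (0-255 or 0-1), or a
#'   numeric matrix already in luminance.
#' @return non-negative scalar.
#' @export
#' @examples
#' focus_metric(matrix(0.5, 32, 32))   # uniform -> 0
focus_metric <- function(image) {
  lum <- as_luminance(image)
  h <- nrow(lum)
  w <- ncol(lum)
  if (h < 3 || w < 3) stopf("image too small for a 3x3 Laplacian")
  lap <- -4 * lum[2:(h - 1), 2:(w - 1)] +
    lum[1:(h - 2), 2:(w - 1)] + lum[3:h, 2:(w - 1)] +
    lum[2:(h - 1), 1:(w - 2)] + lum[2:(h - 1), 3:w]
  mean((lap - mean(lap))^2)
}

# Accepts field_image / RGB array / matrix; returns luminance in [0, 1].
as_luminance <- function(image) {
  if (inherits(image, "field_image")) image <- image$pixels
  if (is.matrix(image)) {
    lum <- image
  } else if (length(dim(image)) == 3) {
    lum <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    stopf("expected a matrix or HxWx3 array")
  }
  if (length(lum) == 0) stopf("degenerate image with zero pixels")
  # integer pixel buffers are 8-bit; float inputs are taken as already
  # on the [0, 1] scale unless clearly 0-255 (the cutoff at 2 keeps the
  # metric invariant under adding constants to a [0, 1] image)
  if (is.integer(image) || max(lum) > 2) lum <- lum / 255
  lum
}

#' Z-search configuration for autofocus
#'
#' Two-stage search: a coarse pass over `warm_start + seq(-coarse_range,
#' coarse_range, coarse_step)`, then a fine pass at `fine_step` spacing
#' within `fine_range` of the coarse optimum. The instrument this
#' emulates reports only that several z positions were tried and the
#' highest-contrast image kept; the ranges and steps here are defaults
#' of this implementation.
#'
#' @param coarse_range,coarse_step coarse pass half-range and step, um.
#' @param fine_range,fine_step fine pass half-range and step, um.
#' @param contrast_floor absolute metric floor below which a field is
#'   declared content-free (`flat`). The default sits just above the
#'   Laplacian variance that sensor noise alone produces
#'   (`20 * noise_sigma^2`, about 1.2e-3 at the default noise), so a
#'   blank noisy field cannot masquerade as content.
#' @param flat_span_fraction a field is `flat` when the metric's
#'   max-min span is below this fraction of its max.
#' @param plateau_tol candidates within `plateau_tol` of the maximum
#'   metric (relative) count as the focus plateau; `best_z` is the
#'   plateau candidate closest to the plateau centre. With a defocus
#'   model that is exactly sharp across the depth of field, the metric
#'   is flat-topped and a raw argmax would be decided by noise.
#' @param focus_window edge length (pixels) of the central crop used to
#'   evaluate the metric during the search; the final capture is always
#'   full-frame. `NULL` uses the full field.
#' @return a `z_search` config list.
#' @export
z_search <- function(coarse_range = 30, coarse_step = 6,
                     fine_range = 5, fine_step = 1,
                     contrast_floor = 2e-03,
                     flat_span_fraction = 0.05,
                     plateau_tol = 0.05,
                     focus_window = 128L) {
  if (coarse_step < fine_step || fine_step <= 0) {
    stopf("need coarse_step >= fine_step > 0")
  }
  as.list(environment())
}

# Optics used during the z-search (possibly a central crop).
focus_optics <- function(optics, zs) {
  fw <- zs$focus_window
  if (is.null(fw)) return(optics)
  shape <- pmin(optics$field_shape, as.integer(fw))
  if (all(shape == optics$field_shape)) return(optics)
  o <- optics
  o$field_shape <- shape
  o
}

#' Autofocus at one stage position
#'
#' Renders the field at each candidate z, scores it with
#' [focus_metric()], and returns the best focus height. Content-free
#' fields (metric span below the contrast floor or nearly constant
#' across z) are reported as `flat` and keep the warm-start height, the
#' behaviour a scanner needs on sparse smears where autofocus has
#' nothing to grip.
#'
#' @inheritParams render_field
#' @param zs a [z_search()] configuration.
#' @param warm_start centre of the coarse grid, um (the previous field's
#'   best focus during a scan).
#' @return an object of class `focus_result`: `evaluated` (data frame of
#'   z and metric in evaluation order), `best_z`, `status` (`"ok"` or
#'   `"flat"`).
#' @export
autofocus <- function(slide, optics, x, y, zs = z_search(),
                      warm_start = 0) {
  fo <- focus_optics(optics, zs)
  raster <- rasterize_field(slide, fo, x, y)
  eval_z <- function(z) {
    px <- apply_optics(raster, fo, z, seed = mix_seed(slide$seed, x, y, z))
    focus_metric(px)
  }
  coarse_z <- warm_start +
    seq(-zs$coarse_range, zs$coarse_range, by = zs$coarse_step)
  if (length(coarse_z) == 0) stopf("empty coarse z grid")
  coarse_m <- vapply(coarse_z, eval_z, numeric(1))
  z0 <- coarse_z[which.max(coarse_m)]
  fine_z <- z0 + seq(-zs$fine_range, zs$fine_range, by = zs$fine_step)
  fine_z <- setdiff(fine_z, coarse_z)
  fine_m <- vapply(fine_z, eval_z, numeric(1))
  evaluated <- data.frame(z = c(coarse_z, fine_z),
                          metric = c(coarse_m, fine_m))

  maxm <- max(evaluated$metric)
  minm <- min(evaluated$metric)
  flat <- maxm < zs$contrast_floor ||
    (nrow(evaluated) > 1 && (maxm - minm) < zs$flat_span_fraction * maxm)
  if (flat) {
    best_z <- warm_start
    status <- "flat"
  } else {
    plateau <- evaluated$z[evaluated$metric >= (1 - zs$plateau_tol) * maxm]
    centre <- mean(plateau)
    best_z <- plateau[order(abs(plateau - centre), plateau)][1]
    status <- "ok"
  }
  structure(list(evaluated = evaluated, best_z = best_z, status = status),
            class = "focus_result")
}

#' @export
print.focus_result <- function(x, ...) {
  cat(sprintf("<focus_result> best_z %.2f um (%s), %d evaluations\n",
              x$best_z, x$status, nrow(x$evaluated)))
  invisible(x)
}

#' Raster-scan plan
#'
#' The default plan mirrors the deployed instrument: 125 fields
#' (a 5 x 25 grid over the centre of the smear) captured along a
#' serpentine raster with autofocus at every field.
#'
#' @param rows,cols grid dimensions; `rows * cols` fields.
#' @param spacing centre-to-centre field spacing, um; `NULL` uses the
#'   physical field-of-view size (contiguous tiling).
#' @param center grid centre `c(x, y)` um; `NULL` centres on the slide.
#' @param serpentine reverse alternate rows to minimise stage travel?
#' @param positions optional explicit data frame of `x`, `y` positions,
#'   overriding the grid.
#' @param zs a [z_search()] configuration.
#' @param refocus_every run autofocus every this many fields (1 =
#'   every field); intermediate fields reuse the last best focus.
#' @return an object of class `scan_plan`.
#' @export
scan_plan <- function(rows = 5, cols = 25, spacing = NULL, center = NULL,
                      serpentine = TRUE, positions = NULL,
                      zs = z_search(), refocus_every = 1) {
  if (is.null(positions)) {
    if (rows < 1 || cols < 1) stopf("grid must have positive dimensions")
    n_fields <- as.integer(rows * cols)
  } else {
    if (!all(c("x", "y") %in% names(positions))) {
      stopf("explicit positions need x and y columns")
    }
    n_fields <- nrow(positions)
  }
  if (refocus_every < 1) stopf("refocus_every must be >= 1")
  structure(
    list(rows = rows, cols = cols, spacing = spacing, center = center,
         serpentine = serpentine, positions = positions,
         n_fields = n_fields, zs = zs,
         refocus_every = as.integer(refocus_every)),
    class = "scan_plan"
  )
}

# Resolve a plan into an ordered data frame of field positions.
plan_positions <- function(plan, slide, optics) {
  if (!is.null(plan$positions)) {
    pos <- plan$positions
    pos$row <- pos$row %||% rep(1L, nrow(pos))
    pos$col <- pos$col %||% seq_len(nrow(pos))
    return(pos[, c("row", "col", "x", "y")])
  }
  sp <- plan$spacing %||% field_of_view(optics)
  if (length(sp) == 1) sp <- c(sp, sp)
  ctr <- plan$center %||% (slide$extent / 2)
  xs <- ctr[1] + (seq_len(plan$cols) - (plan$cols + 1) / 2) * sp[1]
  ys <- ctr[2] + ((plan$rows + 1) / 2 - seq_len(plan$rows)) * sp[2]
  pos <- do.call(rbind, lapply(seq_len(plan$rows), function(r) {
    cols <- seq_len(plan$cols)
    if (plan$serpentine && r %% 2 == 0) cols <- rev(cols)
    data.frame(row = r, col = cols, x = xs[cols], y = ys[r])
  }))
  pos
}

#' Execute an automated raster scan
#'
#' Walks the plan's fields in raster (optionally serpentine) order,
#' autofocusing at each field with the previous field's best focus as
#' warm start, and captures one full-frame image per field at its best
#' z. Fully reproducible: a fixed slide seed gives identical images and
#' an identical best-z sequence.
#'
#' @inheritParams render_field
#' @param plan a [scan_plan()].
#' @return an object of class `scan_result`: `fields` (list of
#'   `field_image`, `capture_mode = "automated"`, each carrying its
#'   full-frame focus metric) and `log` (data frame: field_id, row, col,
#'   x, y, best_z, metric, status, n_evaluated).
#' @export
execute_scan <- function(slide, optics, plan = scan_plan()) {
  pos <- plan_positions(plan, slide, optics)
  for (i in seq_len(nrow(pos))) check_in_extent(slide, pos$x[i], pos$y[i])

  fields <- vector("list", nrow(pos))
  log <- data.frame(field_id = seq_len(nrow(pos)),
                    row = pos$row, col = pos$col, x = pos$x, y = pos$y,
                    best_z = NA_real_, metric = NA_real_,
                    status = NA_character_, n_evaluated = 0L)
  warm <- 0
  for (i in seq_len(nrow(pos))) {
    if ((i - 1L) %% plan$refocus_every == 0L) {
      af <- autofocus(slide, optics, pos$x[i], pos$y[i],
                      zs = plan$zs, warm_start = warm)
      z <- af$best_z
      log$status[i] <- af$status
      log$n_evaluated[i] <- nrow(af$evaluated)
    } else {
      z <- warm
      log$status[i] <- "reused"
    }
    img <- render_field(slide, optics, pos$x[i], pos$y[i], z,
                        capture_mode = "automated")
    img$focus_metric_value <- focus_metric(img)
    fields[[i]] <- img
    log$best_z[i] <- z
    log$metric[i] <- img$focus_metric_value
    warm <- z
  }
  structure(list(fields = fields, log = log, plan = plan),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d fields, best_z in [%.2f, %.2f] um, %d flat\n",
              nrow(x$log), min(x$log$best_z), max(x$log$best_z),
              sum(x$log$status == "flat")))
  invisible(x)
}

#' Manual field capture
#'
#' Emulates the fallback used on sparse smears: the technician pans to
#' chosen positions and captures one autofocused image at each.
#'
#' @inheritParams execute_scan
#' @param positions data frame with `x`, `y` columns (um).
#' @param zs a [z_search()] configuration.
#' @return list of `field_image` with `capture_mode = "manual"`.
#' @export
manual_capture <- function(slide, optics, positions, zs = z_search()) {
  if (nrow(positions) == 0) return(list())
  warm <- 0
  out <- vector("list", nrow(positions))
  for (i in seq_len(nrow(positions))) {
    af <- autofocus(slide, optics, positions$x[i], positions$y[i],
                    zs = zs, warm_start = warm)
    img <- render_field(slide, optics, positions$x[i], positions$y[i],
                        af$best_z, capture_mode = "manual")
    img$focus_metric_value <- focus_metric(img)
    out[[i]] <- img
    warm <- af$best_z
  }
  out
}

#' Densest candidate fields by ground truth
#'
#' Ranks candidate stage positions by true cellular coverage; used to
#' emulate the technician seeking out the denser regions of a sparse
#' smear for manual capture.
#'
#' @inheritParams render_field
#' @param candidates data frame of `x`, `y` positions.
#' @param k number of positions to return.
#' @return the `k` densest rows of `candidates`, densest first.
#' @export
densest_fields <- function(slide, optics, candidates, k) {
  cov <- vapply(seq_len(nrow(candidates)), function(i) {
    true_coverage(slide, optics, candidates$x[i], candidates$y[i])
  }, numeric(1))
  ord <- order(-cov, seq_along(cov))
  candidates[ord[seq_len(min(k, nrow(candidates)))], , drop = FALSE]
}
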