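#' Parameters for synthetic slide generation
#'
#' The generator emulates a liquid-based cytology preparation of an oral
#' brush biopsy: dissociated nucleated squamous cells spread over the
#' central region of the slide, a minority population of atypical cells
#' (enlarged, hyperchromatic nuclei with a high nucleus-to-cytoplasm
#' ratio), occasional dense clumps, and a gently tilted/curved focal
#' surface so that refocusing is required across a scan.
#'
#' Dispersed cells are placed by a homogeneous Poisson (Boolean) process
#' whose intensity is inverted from the target areal coverage,
#' `lambda = -log(1 - target_coverage) / E[cell area]`, so the expected
#' realised coverage of any interior field equals `target_coverage`.
#' Clumps are Matern-style clusters: a handful of parent points each
#' surrounded by a disc of daughter cells.
#'
#' @param extent slide width and height in micrometres.
#' @param target_coverage intended areal fraction of cellular material in
#'   the placement region, in `[0, 1]`.
#' @param fraction_atypical expected fraction of cells with atypical
#'   morphology.
#' @param placement_fraction fraction of each slide dimension forming the
#'   central placement region (smears are constrained to the slide centre
#'   to keep scanned fields dense).
#' @param cyto_major range (min, max) of the cytoplasm semi-major axis, um.
#' @param cyto_aspect range of the semi-minor/semi-major aspect ratio.
#' @param nc_normal,nc_atypical ranges of the nucleus/cell area ratio for
#'   normal and atypical cells.
#' @param chromatin_normal,chromatin_atypical ranges of nuclear stain
#'   darkness (0-1); atypical cells are hyperchromatic.
#' @param atypia_nc_threshold,hyperchromasia_threshold minimum N:C ratio
#'   and chromatin intensity an atypical cell must satisfy.
#' @param n_clumps number of clump clusters (0 disables clumping).
#' @param clump_radius cluster disc radius, um.
#' @param clump_cells cells per cluster.
#' @param focal_coef coefficients `c(a0, a1, a2, a3, a4)` of the focal
#'   surface `z*(x, y) = a0 + a1 x + a2 y + a3 x^2 + a4 y^2` (um; x, y in um
#'   from the lower-left slide origin).
#' @return a list of validated generation parameters.
#' @export
slide_params <- function(extent = c(10000, 5000),
                         target_coverage = 0.5,
                         fraction_atypical = 0.25,
                         placement_fraction = 0.7,
                         cyto_major = c(18, 30),
                         cyto_aspect = c(0.6, 0.95),
                         nc_normal = c(0.06, 0.20),
                         nc_atypical = c(0.45, 0.70),
                         chromatin_normal = c(0.15, 0.45),
                         chromatin_atypical = c(0.60, 0.95),
                         atypia_nc_threshold = 0.40,
                         hyperchromasia_threshold = 0.60,
                         n_clumps = 4,
                         clump_radius = 80,
                         clump_cells = 20,
                         focal_coef = c(a0 = 0, a1 = 0.002, a2 = -0.0015,
                                        a3 = 1e-07, a4 = -8e-08)) {
  if (any(extent <= 0)) stopf("slide extent must be positive")
  if (target_coverage < 0 || target_coverage > 1) {
    stopf("target_coverage must be in [0, 1]")
  }
  if (fraction_atypical < 0 || fraction_atypical > 1) {
    stopf("fraction_atypical must be in [0, 1]")
  }
  if (any(cyto_major <= 0) || any(cyto_aspect <= 0) || any(cyto_aspect > 1)) {
    stopf("cell size parameters must be positive (aspect in (0, 1])")
  }
  if (placement_fraction <= 0 || placement_fraction > 1) {
    stopf("placement_fraction must be in (0, 1]")
  }
  if (length(focal_coef) != 5) stopf("focal_coef must have 5 coefficients")
  as.list(environment())
}

# Mean cell (cytoplasm ellipse) area under the size distribution, um^2.
mean_cell_area <- function(params) {
  a <- mean(params$cyto_major)
  b <- a * mean(params$cyto_aspect)
  pi * a * b
}

# Sample n cells uniformly over [x0,x1]x[y0,y1]; morphology per label.
sample_cells <- function(n, params, x0, x1, y0, y1) {
  if (n == 0) {
    return(data.frame(x = numeric(0), y = numeric(0),
                      cyto_a = numeric(0), cyto_b = numeric(0),
                      theta = numeric(0),
                      nuc_a = numeric(0), nuc_b = numeric(0),
                      off_x = numeric(0), off_y = numeric(0),
                      nc_area_ratio = numeric(0),
                      chromatin = numeric(0),
                      label = character(0),
                      stringsAsFactors = FALSE))
  }
  x <- stats::runif(n, x0, x1)
  y <- stats::runif(n, y0, y1)
  a <- stats::runif(n, params$cyto_major[1], params$cyto_major[2])
  b <- a * stats::runif(n, params$cyto_aspect[1], params$cyto_aspect[2])
  theta <- stats::runif(n, 0, pi)
  atyp <- stats::runif(n) < params$fraction_atypical
  nc <- ifelse(atyp,
               stats::runif(n, params$nc_atypical[1], params$nc_atypical[2]),
               stats::runif(n, params$nc_normal[1], params$nc_normal[2]))
  chrom <- ifelse(atyp,
                  stats::runif(n, params$chromatin_atypical[1],
                               params$chromatin_atypical[2]),
                  stats::runif(n, params$chromatin_normal[1],
                               params$chromatin_normal[2]))
  # Nucleus: similar concentric ellipse scaled by sqrt(nc), so the area
  # ratio is exact; offset bounded by (1 - s) * b which guarantees the
  # nucleus stays inside the cytoplasm for any offset direction.
  s <- sqrt(nc)
  off_mag <- stats::runif(n, 0, 0.8) * (1 - s) * b
  off_dir <- stats::runif(n, 0, 2 * pi)
  data.frame(x = x, y = y, cyto_a = a, cyto_b = b, theta = theta,
             nuc_a = s * a, nuc_b = s * b,
             off_x = off_mag * cos(off_dir), off_y = off_mag * sin(off_dir),
             nc_area_ratio = nc, chromatin = chrom,
             label = ifelse(atyp, "atypical", "normal"),
             stringsAsFactors = FALSE)
}

#' Generate a ground-truth synthetic slide
#'
#' Deterministic under a fixed `(params, seed)` pair: the same inputs
#' always produce an identical cell table and hence identical rendered
#' pixels.
#'
#' @param params generation parameters from [slide_params()].
#' @param seed integer RNG seed (mandatory).
#' @return an object of class `virtual_slide` with components `extent`,
#'   `cells` (one row per cell), `clumps`, `target_coverage`,
#'   `focal_coef`, `seed` and `params`.
#' @export
#' @examples
#' sl <- generate_slide(slide_params(extent = c(2000, 2000),
#'                                   target_coverage = 0.3), seed = 7)
#' sl
generate_slide <- function(params = slide_params(), seed) {
  if (missing(seed)) stopf("a seed is mandatory for slide generation")
  ext <- params$extent
  pf <- params$placement_fraction
  x0 <- ext[1] * (1 - pf) / 2; x1 <- ext[1] - x0
  y0 <- ext[2] * (1 - pf) / 2; y1 <- ext[2] - y0
  region_area <- (x1 - x0) * (y1 - y0)

  cells <- with_fixed_seed(mix_seed(seed, 1), {
    if (params$target_coverage == 0) {
      n_disp <- 0L
      n_cl <- 0L
    } else {
      lambda <- -log(1 - min(params$target_coverage, 0.999)) /
        mean_cell_area(params)
      n_disp <- stats::rpois(1, lambda * region_area)
      n_cl <- params$n_clumps
    }
    dispersed <- sample_cells(n_disp, params, x0, x1, y0, y1)
    clumps <- data.frame(x = numeric(0), y = numeric(0),
                         radius = numeric(0), n = integer(0))
    clumped <- dispersed[0, ]
    if (n_cl > 0) {
      margin <- params$clump_radius
      cx <- stats::runif(n_cl, x0 + margin, x1 - margin)
      cy <- stats::runif(n_cl, y0 + margin, y1 - margin)
      clumps <- data.frame(x = cx, y = cy,
                           radius = rep(params$clump_radius, n_cl),
                           n = rep(as.integer(params$clump_cells), n_cl))
      parts <- lapply(seq_len(n_cl), function(i) {
        cc <- sample_cells(clumps$n[i], params,
                           cx[i] - margin, cx[i] + margin,
                           cy[i] - margin, cy[i] + margin)
        # keep daughters within the cluster disc
        r <- sqrt(stats::runif(clumps$n[i])) * params$clump_radius
        ang <- stats::runif(clumps$n[i], 0, 2 * pi)
        cc$x <- cx[i] + r * cos(ang)
        cc$y <- cy[i] + r * sin(ang)
        cc
      })
      clumped <- do.call(rbind, parts)
    }
    list(cells = rbind(dispersed, clumped), clumps = clumps)
  })

  slide <- structure(
    list(extent = ext,
         cells = cells$cells,
         clumps = cells$clumps,
         target_coverage = params$target_coverage,
         focal_coef = unname(params$focal_coef),
         seed = as.integer(seed),
         params = params),
    class = "virtual_slide"
  )
  validate_slide(slide)
  slide
}

# Enforce the cell-level invariants: nucleus contained in cytoplasm,
# exact N:C area ratio, atypical thresholds, centers within extent.
validate_slide <- function(slide) {
  cells <- slide$cells
  if (nrow(cells) == 0) return(invisible(slide))
  if (any(cells$x < 0 | cells$x > slide$extent[1] |
          cells$y < 0 | cells$y > slide$extent[2])) {
    stopf("cell centers outside slide extent")
  }
  ratio <- (cells$nuc_a * cells$nuc_b) / (cells$cyto_a * cells$cyto_b)
  if (any(abs(ratio - cells$nc_area_ratio) > 1e-6)) {
    stopf("nucleus/cell area ratio inconsistent with axes")
  }
  off <- sqrt(cells$off_x^2 + cells$off_y^2)
  s <- sqrt(cells$nc_area_ratio)
  if (any(off > (1 - s) * cells$cyto_b + 1e-9)) {
    stopf("nucleus not contained in cytoplasm")
  }
  p <- slide$params
  aty <- cells$label == "atypical"
  if (any(cells$nc_area_ratio[aty] < p$atypia_nc_threshold) ||
      any(cells$chromatin[aty] < p$hyperchromasia_threshold)) {
    stopf("atypical cell below atypia thresholds")
  }
  invisible(slide)
}

#' True best-focus height of the focal surface
#'
#' Evaluates `z*(x, y) = a0 + a1 x + a2 y + a3 x^2 + a4 y^2` in
#' micrometres. Real smears are never perfectly flat relative to a
#' micrometre-scale depth of field, which is what forces per-field
#' refocusing during a scan.
#'
#' @param slide a [generate_slide()] result.
#' @param x,y stage position in micrometres (vectorised).
#' @return z in micrometres.
#' @export
focal_z <- function(slide, x, y) {
  a <- slide$focal_coef
  a[1] + a[2] * x + a[3] * y + a[4] * x^2 + a[5] * y^2
}

#' @export
print.virtual_slide <- function(x, ...) {
  cat(sprintf("<virtual_slide> %g x %g um, %d cells (%d atypical), target coverage %.2f, seed %d\n",
              x$extent[1], x$extent[2], nrow(x$cells),
              sum(x$cells$label == "atypical"), x$target_coverage, x$seed))
  invisible(x)
}
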