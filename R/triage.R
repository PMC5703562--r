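# Field adequacy triage: density, blur, clumping, and the selection
# policy (discard <30% density, prefer >50%, keep 60-100 fields).

#' Segmentation configuration for density and clump scoring
#'
#' Foreground = pixels whose Euclidean RGB distance (0-1 scale) from the
#' background colour exceeds `distance_threshold`. The background colour
#' defaults to the rendering palette's; for external images an automatic
#' Otsu threshold on the distance map can be used instead.
#'
#' @param background RGB triple in `[0, 1]`; `NULL` uses [he_palette()].
#' @param distance_threshold foreground distance cutoff.
#' @param auto_threshold use Otsu's method on the distance map instead
#'   of the fixed cutoff?
#' @param clump_area_fraction a field is clump-flagged when its largest
#'   connected foreground component exceeds this fraction of the field...
#' @param nuclear_multiple ...and that component's nuclear-pixel fraction
#'   exceeds this multiple of the reference nuclear fraction.
#' @param nuclear_reference slide-level median nuclear fraction; `NA`
#'   falls back to `nuclear_default`.
#' @param nuclear_default fallback reference nuclear fraction.
#' @return a `seg_config` list.
#' @export
seg_config <- function(background = NULL,
                       distance_threshold = 0.15,
                       auto_threshold = FALSE,
                       clump_area_fraction = 0.20,
                       nuclear_multiple = 1.5,
                       nuclear_reference = NA_real_,
                       nuclear_default = 0.08) {
  background <- background %||% he_palette()$background
  as.list(environment())
}

# Per-pixel distance from the background colour, 0-1 scale.
background_distance <- function(px, background) {
  if (length(dim(px)) != 3 || dim(px)[3] != 3) stopf("expected an RGB image")
  if (max(px) > 1) px <- px / 255
  sqrt((px[, , 1] - background[1])^2 +
       (px[, , 2] - background[2])^2 +
       (px[, , 3] - background[3])^2)
}

# Otsu's threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1] + 1e-9)
  h <- tabulate(pmin(256L, 1L + as.integer((v - rng[1]) / diff(rng) * 256)),
                nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / 256 * diff(rng)
}

foreground_mask <- function(image, seg) {
  px <- if (inherits(image, "field_image")) image$pixels else image
  d <- background_distance(px, seg$background)
  thr <- if (seg$auto_threshold) otsu_threshold(as.vector(d)) else
    seg$distance_threshold
  d > thr
}

#' Estimate cellular density of a field from its pixels
#'
#' The adequacy rule the technician applied was the proportion of the
#' field of view covered by cellular material; this estimates it as the
#' foreground pixel fraction under the stain-space segmentation of
#' [seg_config()].
#'
#' @param image a `field_image` or HxWx3 RGB array.
#' @param seg a [seg_config()].
#' @return fraction in `[0, 1]`.
#' @export
estimate_cell_density <- function(image, seg = seg_config()) {
  mean(foreground_mask(image, seg))
}

#' Flag a field as blurry relative to its scan
#'
#' "Perceived to be blurry" is a human judgement with no printed cutoff,
#' so the rule is relative: a field is flagged when its focus score
#' falls below a fraction `f` of the median focus score of the scan's
#' adequately dense fields.
#'
#' @param image a `field_image` (its recorded `focus_metric_value` is
#'   used when present, otherwise the metric is computed).
#' @param reference a [focus_reference()] or a single number (the median
#'   focus score of dense fields). `NA`/`NULL` means no reference was
#'   available: the flag is `FALSE` with a warning.
#' @param f fraction of the reference below which a field is blurry.
#' @return logical flag.
#' @export
assess_blur <- function(image, reference, f = 0.25) {
  ref <- if (is.list(reference)) reference$median_focus else reference
  if (is.null(ref) || is.na(ref)) {
    warning("no dense fields to reference; blur assessment skipped",
            call. = FALSE)
    return(FALSE)
  }
  score <- image$focus_metric_value %||% focus_metric(image)
  score < f * ref
}

#' Slide-level focus reference for blur assessment
#'
#' Median focus score over fields with density at or above the sparse
#' threshold, computed from one scan's assessments.
#'
#' @param focus_scores numeric vector of per-field focus scores.
#' @param densities matching vector of density estimates.
#' @param sparse_threshold density below which fields are excluded.
#' @return list with `median_focus` (`NA` when no dense fields exist)
#'   and `n_dense`.
#' @export
focus_reference <- function(focus_scores, densities,
                            sparse_threshold = 0.30) {
  dense <- densities >= sparse_threshold
  list(median_focus = if (any(dense)) stats::median(focus_scores[dense])
       else NA_real_,
       n_dense = sum(dense))
}

# Label 4-connected components of a logical mask by row-run union-find.
# Returns list(labels = integer matrix, sizes = named component sizes).
label_components <- function(mask) {
  h <- nrow(mask)
  runs <- vector("list", h)  # per row: data.frame(start, end, id)
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nid <- 0L
  prev <- NULL
  for (r in seq_len(h)) {
    rr <- rle(mask[r, ])
    ends <- cumsum(rr$lengths)
    starts <- ends - rr$lengths + 1L
    sel <- which(rr$values)
    cur <- if (length(sel)) {
      data.frame(start = starts[sel], end = ends[sel], id = NA_integer_)
    } else NULL
    if (!is.null(cur)) {
      for (k in seq_len(nrow(cur))) {
        id <- NA_integer_
        if (!is.null(prev)) {
          ov <- which(prev$start <= cur$end[k] & cur$start[k] <= prev$end)
          for (j in ov) {
            pid <- find(prev$id[j])
            if (is.na(id)) {
              id <- pid
            } else if (pid != id) {
              parent[pid] <- find(id)
            }
          }
        }
        if (is.na(id)) {
          nid <- nid + 1L
          parent[nid] <- nid
          id <- nid
        }
        cur$id[k] <- id
      }
    }
    runs[r] <- list(cur)  # plain [[<- would drop NULL entries
    prev <- cur
  }
  labels <- matrix(0L, h, ncol(mask))
  sizes <- integer(0)
  for (r in seq_len(h)) {
    cur <- runs[[r]]
    if (is.null(cur)) next
    for (k in seq_len(nrow(cur))) {
      root <- find(cur$id[k])
      labels[r, cur$start[k]:cur$end[k]] <- root
      len <- cur$end[k] - cur$start[k] + 1L
      sizes[as.character(root)] <-
        (if (is.na(sizes[as.character(root)])) 0L
         else sizes[as.character(root)]) + len
    }
  }
  list(labels = labels, sizes = sizes)
}

#' Detect cell clumping in a field
#'
#' Overlapping/clumped cells were discarded by the technician; this
#' proxies that judgement with two conditions that must both hold: the
#' largest connected foreground component exceeds
#' `clump_area_fraction` of the field, and that component's
#' nuclear-pixel fraction exceeds `nuclear_multiple` times the
#' reference nuclear fraction (piled-up cells present more nuclear
#' material per unit area than a monolayer).
#'
#' @inheritParams estimate_cell_density
#' @return logical flag (with a warning and `FALSE` if segmentation
#'   fails).
#' @export
detect_clumps <- function(image, seg = seg_config()) {
  res <- tryCatch({
    fg <- foreground_mask(image, seg)
    if (!any(fg)) return(FALSE)
    comp <- label_components(fg)
    big <- names(comp$sizes)[which.max(comp$sizes)]
    frac <- max(comp$sizes) / length(fg)
    if (frac <= seg$clump_area_fraction) return(FALSE)
    px <- if (inherits(image, "field_image")) image$pixels else image
    if (max(px) > 1) px <- px / 255
    pal <- he_palette()
    in_big <- comp$labels == as.integer(big)
    dn <- background_distance(px, pal$nucleus)
    dc <- background_distance(px, pal$cytoplasm)
    nuclear <- in_big & (dn < dc)
    nuc_frac <- sum(nuclear) / sum(in_big)
    ref <- if (is.na(seg$nuclear_reference)) seg$nuclear_default
           else seg$nuclear_reference
    nuc_frac > seg$nuclear_multiple * ref
  }, error = function(e) {
    warning("clump segmentation failed: ", conditionMessage(e),
            call. = FALSE)
    FALSE
  })
  res
}

#' Triage policy
#'
#' The deployed acquisition protocol: fields under ~30% cell density or
#' blurry or clumped are inadequate; fields over 50% density are
#' preferred; 60-100 adequate images form the diagnostic set, and a
#' slide that cannot supply 60 is handled by manual capture.
#'
#' @param sparse_threshold density below which a field is discarded.
#' @param prefer_threshold density above which fields rank first.
#' @param min_fields,max_fields the selection band.
#' @param blur_fraction `f` of [assess_blur()].
#' @return a `triage_policy` list.
#' @export
triage_policy <- function(sparse_threshold = 0.30,
                          prefer_threshold = 0.50,
                          min_fields = 60L, max_fields = 100L,
                          blur_fraction = 0.25) {
  as.list(environment())
}

#' Assess every field of a scan
#'
#' Computes per-field density, focus score, blur and clump flags for a
#' `scan_result` (or any list of `field_image`), using the scan itself
#' as the blur/nuclear reference.
#'
#' @param scan a `scan_result` or list of `field_image`.
#' @param seg a [seg_config()].
#' @param policy a [triage_policy()].
#' @return data frame: `field_id`, `density`, `focus_score`,
#'   `blur_flag`, `clump_flag`.
#' @export
assess_fields <- function(scan, seg = seg_config(),
                          policy = triage_policy()) {
  fields <- if (inherits(scan, "scan_result")) scan$fields else scan
  if (length(fields) == 0) stopf("no fields to assess")
  density <- vapply(fields, estimate_cell_density, numeric(1), seg = seg)
  score <- vapply(fields, function(f) {
    f$focus_metric_value %||% focus_metric(f)
  }, numeric(1))
  ref <- focus_reference(score, density, policy$sparse_threshold)
  blur <- if (is.na(ref$median_focus)) {
    warning("no dense fields to reference; blur assessment skipped",
            call. = FALSE)
    rep(FALSE, length(fields))
  } else {
    score < policy$blur_fraction * ref$median_focus
  }
  # nuclear reference: median nuclear fraction over the scan's fields
  nuc_fracs <- vapply(fields, field_nuclear_fraction, numeric(1))
  seg$nuclear_reference <- stats::median(nuc_fracs[density >=
                                                     policy$sparse_threshold])
  if (is.na(seg$nuclear_reference)) seg$nuclear_reference <- NA_real_
  clump <- vapply(fields, detect_clumps, logical(1), seg = seg)
  data.frame(field_id = seq_along(fields), density = density,
             focus_score = score, blur_flag = blur, clump_flag = clump)
}

# Nuclear-pixel fraction of a field's foreground (palette-based).
field_nuclear_fraction <- function(image, seg = seg_config()) {
  fg <- foreground_mask(image, seg)
  if (!any(fg)) return(0)
  px <- if (inherits(image, "field_image")) image$pixels else image
  if (max(px) > 1) px <- px / 255
  pal <- he_palette()
  dn <- background_distance(px, pal$nucleus)
  dc <- background_distance(px, pal$cytoplasm)
  sum(fg & dn < dc) / sum(fg)
}

#' Triage assessed fields into the diagnostic set
#'
#' Applies the selection policy: discard sparse (density below the
#' sparse threshold), blurry and clumped fields; rank survivors with
#' high-density (>= prefer threshold) fields above the rest, then by
#' density, ties broken by field id (scan order); select up to
#' `max_fields`; raise `sparse_mode` when fewer than `min_fields`
#' survive (manual capture advised).
#'
#' @param assessments data frame from [assess_fields()].
#' @param policy a [triage_policy()].
#' @return an object of class `triage_report`: `assessments` (with a
#'   `verdict` column), `selected_ids` (ordered), `sparse_mode`,
#'   `counts`.
#' @export
triage_fields <- function(assessments, policy = triage_policy()) {
  if (nrow(assessments) == 0) stopf("empty assessment list")
  a <- assessments
  verdict <- rep("reserve", nrow(a))
  verdict[a$clump_flag] <- "discarded_clump"
  verdict[a$blur_flag] <- "discarded_blur"
  verdict[a$density < policy$sparse_threshold] <- "discarded_sparse"
  surv <- which(verdict == "reserve")
  ord <- surv[order(-(a$density[surv] >= policy$prefer_threshold),
                    -a$density[surv], a$field_id[surv])]
  sel <- ord[seq_len(min(length(ord), policy$max_fields))]
  verdict[sel] <- "selected"
  a$verdict <- verdict
  structure(
    list(assessments = a,
         selected_ids = a$field_id[sel],
         sparse_mode = length(surv) < policy$min_fields,
         counts = table(factor(verdict,
                               levels = c("selected", "reserve",
                                          "discarded_sparse",
                                          "discarded_blur",
                                          "discarded_clump"))),
         policy = policy),
    class = "triage_report"
  )
}

#' @export
print.triage_report <- function(x, ...) {
  cat(sprintf("<triage_report> %d fields: %d selected, sparse_mode=%s\n",
              nrow(x$assessments), length(x$selected_ids), x$sparse_mode))
  print(x$counts)
  invisible(x)
}
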