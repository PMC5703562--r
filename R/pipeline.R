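# End-to-end pipeline: generate a virtual slide, scan it, triage the
# fields, persist a reproducible run manifest.

#' Assemble a reproducible run configuration
#'
#' Everything a run needs — seed, slide generation parameters, optics,
#' scan plan, segmentation and triage policy — in one serialisable
#' list. A run is reproducible from its persisted configuration alone.
#'
#' @param seed integer master seed (mandatory).
#' @param slide [slide_params()] list.
#' @param optics [optics_model()].
#' @param plan [scan_plan()].
#' @param seg [seg_config()].
#' @param policy [triage_policy()].
#' @param out_dir output directory (`NULL` = keep everything in memory).
#' @param write_images write per-field PNGs under `out_dir/fields`?
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed,
                       slide = slide_params(),
                       optics = optics_model(),
                       plan = scan_plan(),
                       seg = seg_config(),
                       policy = triage_policy(),
                       out_dir = NULL,
                       write_images = !is.null(out_dir)) {
  if (missing(seed)) stopf("a seed is mandatory in a run configuration")
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Only keys present in the file override the defaults of
#' [run_config()]; the seed key is mandatory. Nested sections `slide`,
#' `optics`, `plan` (with optional `plan$zs`), `seg` and `policy` take
#' the same fields as their constructors.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw$seed)) stopf("config %s lacks a seed", path)
  build <- function(ctor, args) do.call(ctor, args %||% list())
  plan_args <- raw$plan %||% list()
  if (!is.null(plan_args$zs)) plan_args$zs <- build(z_search, plan_args$zs)
  run_config(
    seed = raw$seed,
    slide = build(slide_params, raw$slide),
    optics = build(optics_model, raw$optics),
    plan = build(scan_plan, plan_args),
    seg = build(seg_config, raw$seg),
    policy = build(triage_policy, raw$policy),
    out_dir = raw$out_dir,
    write_images = raw$write_images %||% !is.null(raw$out_dir)
  )
}

#' Run the full acquisition pipeline
#'
#' Generates the virtual slide, executes the automated raster scan with
#' per-field autofocus, assesses and triages every field, and (when an
#' output directory is configured) writes the field PNGs, a
#' `scan_log.csv`, an `assessments.csv`, a `triage_report.json` and a
#' `manifest.json` recording the fully resolved configuration, seed and
#' package version — no hidden parameters.
#'
#' @param config a [run_config()].
#' @return an object of class `pipeline_report`: `slide`, `scan`,
#'   `assessments`, `triage`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stopf("config must be a run_config")
  slide <- generate_slide(config$slide, seed = config$seed)
  scan <- execute_scan(slide, config$optics, config$plan)
  assessments <- assess_fields(scan, seg = config$seg,
                               policy = config$policy)
  triage <- triage_fields(assessments, policy = config$policy)

  manifest <- list(
    package = "slidescope",
    version = as.character(utils::packageVersion("slidescope")),
    seed = config$seed,
    n_fields_acquired = length(scan$fields),
    n_fields_selected = length(triage$selected_ids),
    sparse_mode = triage$sparse_mode,
    slide = config$slide[setdiff(names(config$slide), "focal_coef")],
    focal_coef = as.list(config$slide$focal_coef),
    optics = config$optics[setdiff(names(config$optics), "palette")],
    plan = config$plan[c("rows", "cols", "serpentine", "n_fields",
                         "refocus_every")],
    z_search = config$plan$zs,
    seg = config$seg,
    policy = config$policy
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scan$log,
                     file.path(config$out_dir, "scan_log.csv"),
                     row.names = FALSE)
    utils::write.csv(triage$assessments,
                     file.path(config$out_dir, "assessments.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(selected_ids = triage$selected_ids,
           sparse_mode = triage$sparse_mode,
           counts = as.list(triage$counts)),
      file.path(config$out_dir, "triage_report.json"),
      auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    if (isTRUE(config$write_images)) {
      fdir <- file.path(config$out_dir, "fields")
      dir.create(fdir, showWarnings = FALSE)
      for (i in seq_along(scan$fields)) {
        write_field_png(scan$fields[[i]],
                        file.path(fdir, sprintf("field_%d_%d.png",
                                                scan$log$row[i],
                                                scan$log$col[i])))
      }
    }
  }
  if (triage$sparse_mode) {
    warning("sparse slide: fewer than the minimum adequate fields; ",
            "manual capture advised", call. = FALSE)
  }
  structure(list(slide = slide, scan = scan, assessments = assessments,
                 triage = triage, manifest = manifest),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> seed %d: %d fields acquired, %d selected, sparse_mode=%s\n",
              x$manifest$seed, x$manifest$n_fields_acquired,
              x$manifest$n_fields_selected, x$manifest$sparse_mode))
  invisible(x)
}
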