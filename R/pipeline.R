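#' Pipeline configuration
#'
#' A flat, namespaced key set covering every stage of the pipeline. Unknown
#' keys are rejected. Segmentation defaults follow the published parameter
#' values where stated: `s_min = 3` px, `s_max = 12` px (`4 * s_min`),
#' `max_iter = 30`, slice step 1.04 mm; a configuration with
#' `s_max != 4 * s_min` is accepted with a logged notice of the deviation.
#'
#' @param ... key-value overrides of the defaults (see
#'   `names(default_config())`).
#' @return named list of configuration values.
#' @export
default_config <- function(...) {
  cfg <- list(
    input_path = NULL,          # stack file (NIfTI or TIFF)
    input_format = "auto",
    spacing_mm = NULL,          # TIFF spacing override
    centerline_path = NULL,     # JSON [x,y,z] node list
    scale_factor = 1,           # isotropic rescale factor (1 = skip)
    diffusion_iterations = 10,
    diffusion_kappa = 10,
    diffusion_step = 1 / 7,
    step_mm = 1.04,             # distance between cross-section centers
    pixel_size_mm = 0.35,       # cross-section pixel size
    section_size_px = 97,       # cross-section image side
    seed_uv = NULL,             # snake seed (pixels); default image center
    start_index = 1,
    direction = "forward",
    init_radius_px = 6,
    alpha = -1, beta = 0.2, gamma = 2, delta = 1,
    s_min = 3, s_max = 12, max_iter = 30, window = 3,
    normalize = TRUE,
    dev_mode = "vertices",
    overrides_path = NULL,      # contour JSON replacing computed slices
    mask_path = NULL,           # forbidden-region TIFF (same grid as xsecs)
    caps = TRUE,                # close mesh ends
    out_dir = "."
  )
  ov <- list(...)
  .merge_config(cfg, ov)
}

.merge_config <- function(cfg, ov) {
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(ov)] <- ov
  }
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file of config keys (see [default_config()]).
#' @return named list of configuration values, defaults filled in.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  .merge_config(default_config(), yaml::read_yaml(path))
}

#' Run the segmentation pipeline
#'
#' Executes preprocess (stack I/O, optional isotropic rescale, anisotropic
#' diffusion), cross-section resampling along the centerline, greedy-snake
#' segmentation with slice propagation, and geometric reconstruction,
#' writing artifacts into `out_dir`: the preprocessed stack
#' (`preprocessed.nii.gz`), the cross sections (`cross_sections.tif` +
#' frames sidecar), the contours (`contours.json`), the area function
#' (`area_function.csv`), world polygons (`world_polygons.json`), the
#' surface mesh (`mesh.ply`), a per-slice `run.log`, and a `manifest.json`
#' recording the full configuration, its hash, package/R versions, and each
#' slice's convergence iterations. All stages are deterministic, so a rerun
#' with the same config reproduces every artifact byte for byte. Partial
#' artifacts are preserved if a later stage fails.
#'
#' @param config a config list (see [default_config()]) or the path to a
#'   YAML config file.
#' @param through last stage to execute: `"preprocess"`, `"resample"`,
#'   `"segment"` or `"reconstruct"` (the default, i.e. the full run).
#' @return invisibly, a list with the computed objects (`stack`, `xsecs`,
#'   `contours`, `area_function`, `mesh`, ...) present up to `through`.
#' @export
run_pipeline <- function(config, through = c("reconstruct", "preprocess",
                                             "resample", "segment")) {
  through <- match.arg(through)
  if (is.character(config)) config <- read_config(config)
  config <- .merge_config(default_config(), config)
  if (!isTRUE(all.equal(config$s_max, 4 * config$s_min)))
    message(sprintf(
      "note: s_max (%g) deviates from the reference setting 4*s_min (%g)",
      config$s_max, 4 * config$s_min))
  if (is.null(config$input_path) || is.null(config$centerline_path))
    stop("config must set input_path and centerline_path", call. = FALSE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  res <- list(config = config)

  # --- preprocess -------------------------------------------------------
  stack <- read_stack(config$input_path, config$input_format,
                      spacing_mm = config$spacing_mm)
  if (config$scale_factor != 1)
    stack <- make_isotropic(stack, config$scale_factor)
  if (config$diffusion_iterations > 0)
    stack <- anisotropic_diffusion(stack, config$diffusion_iterations,
                                   config$diffusion_kappa,
                                   config$diffusion_step)
  res$stack <- stack
  write_stack(stack, out("preprocessed.nii.gz"))
  if (through == "preprocess") return(invisible(.finish(res, config, out)))

  # --- resample ---------------------------------------------------------
  spline <- fit_spline(read_centerline_json(config$centerline_path))
  xsecs <- resample_cross_sections(stack, spline, config$step_mm,
                                   config$section_size_px,
                                   config$pixel_size_mm)
  res$spline <- spline
  res$xsecs <- xsecs
  write_cross_sections(xsecs, out("cross_sections.tif"))
  if (through == "resample") return(invisible(.finish(res, config, out)))

  # --- segment ----------------------------------------------------------
  params <- snake_params(alpha = config$alpha, beta = config$beta,
                         gamma = config$gamma, delta = config$delta,
                         s_min = config$s_min, s_max = config$s_max,
                         max_iter = config$max_iter,
                         window = config$window,
                         normalize = config$normalize,
                         dev_mode = config$dev_mode)
  seed <- config$seed_uv
  if (is.null(seed)) seed <- rep((config$section_size_px - 1) / 2, 2L)
  overrides <- if (!is.null(config$overrides_path))
    read_contours(config$overrides_path) else NULL
  mask <- NULL
  if (!is.null(config$mask_path)) {
    ms <- read_stack(config$mask_path, spacing_mm = c(1, 1, 1))
    mask <- lapply(seq_len(dim(ms$voxels)[3]),
                   function(k) ms$voxels[, , k] > 0.5)
    if (length(mask) == 1L) mask <- mask[[1]]
  }
  cset <- segment_stack(xsecs, seed, params,
                        start_index = config$start_index,
                        overrides = overrides, mask = mask,
                        direction = config$direction,
                        init_radius_px = config$init_radius_px)
  res$contours <- cset
  write_contours(cset, out("contours.json"))
  log_lines <- sprintf("slice %d: %s", seq_along(cset$contours),
                       ifelse(cset$failed, "FAILED",
                              sprintf("%d iterations, %s", cset$iterations,
                                      ifelse(cset$converged, "converged",
                                             "iteration cap reached"))))
  writeLines(log_lines, out("run.log"))
  if (through == "segment") return(invisible(.finish(res, config, out)))

  # --- reconstruct ------------------------------------------------------
  af <- area_function(cset)
  res$area_function <- af
  write_area_function(af, out("area_function.csv"))
  polys <- back_transform(cset, xsecs$frames,
                          size_px = config$section_size_px)
  res$world_polygons <- polys
  write_world_polygons(polys, out("world_polygons.json"))
  mesh <- loft_mesh(polys, caps = config$caps)
  res$mesh <- mesh
  write_mesh(mesh, out("mesh.ply"))
  invisible(.finish(res, config, out))
}

# write the manifest; returns res
.finish <- function(res, config, out) {
  cfg_path <- out("config_used.yaml")
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], cfg_path)
  manifest <- list(
    config = config[!vapply(config, is.null, TRUE)],
    config_md5 = unname(tools::md5sum(cfg_path)),
    package_version = as.character(utils::packageVersion("vtseg")),
    r_version = R.version.string)
  if (!is.null(res$contours)) {
    manifest$slices <- list(iterations = res$contours$iterations,
                            converged = res$contours$converged,
                            failed = res$contours$failed)
  }
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  res
}

#' Write a phantom stack plus ground truth to disk
#'
#' Convenience wrapper used by the `phantom` CLI subcommand: generates the
#' phantom and writes the stack, the analytic area function as CSV, and the
#' centerline landmark nodes as JSON (ready for `centerline_path`).
#'
#' @param spec a [phantom_spec()] or path to a YAML file of its fields.
#' @param seed noise seed.
#' @param out_stack output stack path (`.nii.gz` or `.tif`).
#' @param out_truth output CSV path for the analytic area function.
#' @param out_centerline optional JSON path for the landmark nodes.
#' @return invisibly, the [generate_phantom()] result.
#' @export
write_phantom <- function(spec, seed = 0L, out_stack = "phantom.nii.gz",
                          out_truth = "phantom_truth.csv",
                          out_centerline = NULL) {
  if (is.character(spec))
    spec <- do.call(phantom_spec, yaml::read_yaml(spec))
  ph <- generate_phantom(spec, seed = seed)
  write_stack(ph$stack, out_stack)
  write_area_function(ph$truth, out_truth)
  if (!is.null(out_centerline))
    jsonlite::write_json(lapply(seq_len(nrow(ph$nodes)), function(i)
                           unname(as.list(ph$nodes[i, ]))),
                         out_centerline, auto_unbox = TRUE, digits = NA)
  invisible(ph)
}
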