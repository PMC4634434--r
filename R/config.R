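#' Default run configuration
#'
#' The full configuration schema with its documented defaults. A run
#' configuration has four blocks:
#'
#' * `geometry`: `n_pixels`, `span_deg`, `start_deg` - the pixel/angle map.
#' * `stack`: `prism_index`, `bulk_index`, `wavelength_nm`,
#'   `cr_thickness_nm`, `gold_thickness_nm`, and optional complex parts
#'   `gold_index_re/_im`, `cr_index_re/_im`.
#' * `fit`: `model` (sa | asym | poly), `order` (polynomial order),
#'   `criterion_mode` (auto | angle | pixel), `criterion_value`, `seed`.
#' * `noise`: `dark_offset`, `dark_sd`, `shot_sd`, `n_rows`,
#'   `signal_level`.
#' * `io`: `out_dir`.
#'
#' @return nested named list.
#' @export
default_config <- function() {
  gold <- gold_index_770(); cr <- chromium_index_770()
  list(
    geometry = list(n_pixels = 1280L, span_deg = 7.296, start_deg = 60.5),
    stack = list(prism_index = 1.5125, bulk_index = 1.333,
                 wavelength_nm = 770, cr_thickness_nm = 2,
                 gold_thickness_nm = 50,
                 gold_index_re = Re(gold), gold_index_im = Im(gold),
                 cr_index_re = Re(cr), cr_index_im = Im(cr)),
    fit = list(model = "sa", order = 24L, criterion_mode = "auto",
               criterion_value = NA, seed = 1L),
    noise = list(dark_offset = 400, dark_sd = 8, shot_sd = 0.01,
                 n_rows = 128L, signal_level = 30000),
    io = list(out_dir = "sprfit-out"))
}

#' Read and validate a run configuration
#'
#' YAML key-value file; unknown keys anywhere in the tree are rejected,
#' and every omitted key falls back to [default_config()]. An empty file
#' yields the fully-defaulted (valid) configuration.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated nested list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop_input("no such config file: ", path)
    yaml::read_yaml(path) %||% list()
  }
  validate_config(user)
}

#' Validate a configuration list against the schema
#'
#' @param user nested list of overrides (possibly empty).
#' @return merged, validated configuration of class `run_config`.
#' @export
validate_config <- function(user = list()) {
  defs <- default_config()
  if (!is.list(user)) stop_input("config must be a key-value mapping")
  bad_blocks <- setdiff(names(user), names(defs))
  if (length(bad_blocks))
    stop_input("unknown config block(s): ", paste(bad_blocks, collapse = ", "))
  cfg <- defs
  for (blk in names(user)) {
    if (!is.list(user[[blk]]))
      stop_input("config block '", blk, "' must be a mapping")
    bad <- setdiff(names(user[[blk]]), names(defs[[blk]]))
    if (length(bad))
      stop_input("unknown key(s) in '", blk, "': ",
                 paste(bad, collapse = ", "))
    cfg[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  g <- cfg$geometry
  if (g$n_pixels < 2) stop_input("geometry.n_pixels must be >= 2")
  cfg$geometry_obj <- detector_geometry(g$n_pixels, g$span_deg, g$start_deg)
  s <- cfg$stack
  cfg$stack_obj <- kretschmann_stack(
    bulk_index = s$bulk_index,
    gold_thickness_nm = s$gold_thickness_nm,
    cr_thickness_nm = s$cr_thickness_nm,
    gold_index = complex(real = s$gold_index_re, imaginary = s$gold_index_im),
    cr_index = complex(real = s$cr_index_re, imaginary = s$cr_index_im),
    prism_index = s$prism_index,
    wavelength_nm = s$wavelength_nm)
  if (!cfg$fit$model %in% c("sa", "asym", "poly"))
    stop_input("fit.model must be one of sa, asym, poly")
  if (!cfg$fit$criterion_mode %in% c("auto", "angle", "pixel"))
    stop_input("fit.criterion_mode must be auto, angle or pixel")
  class(cfg) <- "run_config"
  cfg
}

config_split <- function(cfg, fit) {
  switch(cfg$fit$criterion_mode,
         auto = default_region_split(fit),
         angle = region_split(as.numeric(cfg$fit$criterion_value)),
         pixel = region_split_at_pixel(cfg$geometry_obj,
                                       as.integer(cfg$fit$criterion_value)))
}

#' Run the simulate - extract - fit - angles pipeline
#'
#' Executes the configured stage chain with seeded determinism: simulates
#' the detector image triplet, normalises and extracts the SPR curve, fits
#' the configured model, extracts the angles (sigmoid-asymmetric model
#' only), and writes `curve.csv` plus `report.json` to the output
#' directory. Identical configuration and seed give byte-identical numeric
#' output.
#'
#' @param config a `run_config` from [read_run_config()] /
#'   [validate_config()].
#' @return invisibly, a list with elements `curve`, `fit`, `angles`
#'   (possibly `NULL`), and `paths`.
#' @export
run_pipeline <- function(config = read_run_config()) {
  stopifnot(inherits(config, "run_config"))
  nz <- config$noise
  ns <- noise_spec(nz$dark_offset, nz$dark_sd, nz$shot_sd,
                   seed = config$fit$seed)
  raw <- synthesize_image_set(config$stack_obj, config$geometry_obj,
                              n_rows = nz$n_rows, noise = ns,
                              signal_level = nz$signal_level)
  ratio <- normalize_images(raw)
  curve <- extract_curve(ratio, geometry = config$geometry_obj)

  fit <- switch(config$fit$model,
                sa = fit_curve(curve, "sigmoid_asymmetric"),
                asym = fit_curve(curve, "asymmetric"),
                poly = fit_polynomial(curve, config$fit$order))
  split <- tryCatch(config_split(config, fit), error = function(e) NULL)
  stats <- if (!is.null(split))
    tryCatch(region_quality(curve, fit, split), error = function(e) NULL)
  angles <- if (config$fit$model == "sa" && !is.null(split))
    tryCatch(angle_estimates(fit, split), error = function(e) NULL)

  out <- config$io$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- c(curve = file.path(out, "curve.csv"),
             report = file.path(out, "report.json"))
  write_spr_curve(curve, paths[["curve"]])
  write_fit_report(fit, angles, paths[["report"]], region_stats = stats)
  invisible(list(curve = curve, fit = fit, angles = angles,
                 region_stats = stats, paths = paths))
}
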