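## YAML configuration. Keys carry their units as suffixes (_mm, _um, _cm,
## _m, _us) to keep the centimetre/metre bookkeeping of camera arrangements
## explicit. Unknown keys are rejected rather than ignored.

configDefaults <- function() {
  list(
    camera = list(
      focal_length_mm = 10.0, pixel_pitch_um = 5.5,
      sensor_width_px = 2336, sensor_height_px = 1752,
      principal_point = NULL,
      pitch_alpha_deg = 20, roll_theta_deg = 0, yaw_beta_deg = 0,
      height_h_cm = 220),
    scene = list(
      row_spacing_m = 0.75, row_width_m = 0.15, n_rows = 4,
      weed_density = 0.04, weed_seed = 1,
      cardboard_distance_m = NULL, panel_distance_m = NULL,
      soil_color = c(120, 95, 70), crop_color = c(60, 140, 55),
      weed_color = c(70, 150, 60), cardboard_color = c(240, 120, 30),
      color_jitter_sd = 20),
    sensor = list(
      full_scale_exposure_us = 35000, saturation_level = 255,
      noise_sd = 2, seed = 1),
    exposure = list(
      a = 0.90, b = 0.98, p = 0.20, max_level = 255, max_iter = 10,
      initial_exposure_us = 20000),
    vignetting = list(k_r = 0.3, k_g = 0.0, k_b = 0.0),
    segmentation = list(
      n_samples = 2000, seed = 1,
      hue_min = 15, hue_max = 40, sat_min = 0.5, val_min = 0.5),
    evaluation = list(crop_top_third = TRUE)
  )
}

mergeBlock <- function(defaults, given, blockName) {
  if (is.null(given)) return(defaults)
  unknown <- setdiff(names(given), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown configuration key%s in `%s`: %s",
                 if (length(unknown) > 1) "s" else "", blockName,
                 paste0(blockName, ".", unknown, collapse = ", ")),
         call. = FALSE)
  defaults[names(given)] <- given
  defaults
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML configuration with blocks `camera`, `scene`, `sensor`,
#' `exposure`, `vignetting`, `segmentation` and `evaluation`; every omitted
#' key takes its documented default (the reference sensor: 10 mm focal
#' length, 5.5 um pixels, 2336 x 1752; exposure band a = 0.90, b = 0.98,
#' p = 0.20; K_r = 0.3; 0.75 m row spacing). Unknown keys and invalid
#' values raise errors naming the offending field.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated named list of configuration blocks, with constructed
#'   parameter objects under `objects` (`camera`, `scene`, `sensor`,
#'   `exposure_state`, `gains`).
#' @export
loadConfig <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()   # empty file parses to NULL
  defs <- configDefaults()
  unknown <- setdiff(names(raw), names(defs))
  if (length(unknown))
    stop("unknown configuration block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- lapply(names(defs), function(b) mergeBlock(defs[[b]], raw[[b]], b))
  names(cfg) <- names(defs)

  buildOr <- function(field, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("invalid configuration near `%s`: %s", field,
                   conditionMessage(e)), call. = FALSE))
  }
  cam <- cfg$camera
  intr <- buildOr("camera", cameraIntrinsics(
    cam$focal_length_mm, cam$pixel_pitch_um, cam$sensor_width_px,
    cam$sensor_height_px, cam$principal_point))
  extr <- buildOr("camera", cameraExtrinsics(
    cam$pitch_alpha_deg, cam$height_h_cm, cam$roll_theta_deg,
    cam$yaw_beta_deg))
  sc <- cfg$scene
  scene <- buildOr("scene", sceneSpec(
    row_spacing_m = sc$row_spacing_m, row_width_m = sc$row_width_m,
    n_rows = sc$n_rows, weed_density = sc$weed_density,
    weed_seed = sc$weed_seed,
    cardboard = if (!is.null(sc$cardboard_distance_m))
      groundROI(sc$cardboard_distance_m),
    panel = if (!is.null(sc$panel_distance_m))
      groundROI(sc$panel_distance_m, width_m = 1.2, depth_m = 0.6),
    soil_color = sc$soil_color, crop_color = sc$crop_color,
    weed_color = sc$weed_color, cardboard_color = sc$cardboard_color,
    color_jitter_sd = sc$color_jitter_sd))
  gains <- buildOr("vignetting", vignettingGains(
    cfg$vignetting$k_r, cfg$vignetting$k_g, cfg$vignetting$k_b))
  sensor <- buildOr("sensor", sensorSpec(
    cfg$sensor$full_scale_exposure_us, cfg$sensor$saturation_level,
    gains, cfg$sensor$noise_sd, cfg$sensor$seed))
  ex <- cfg$exposure
  state <- buildOr("exposure", exposureState(
    ex$initial_exposure_us, lower_frac = ex$a, upper_frac = ex$b,
    adjust_frac = ex$p, max_level = ex$max_level))
  cfg$objects <- list(camera = cameraModel(extr, intr), scene = scene,
                      sensor = sensor, exposure_state = state, gains = gains)
  cfg
}
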