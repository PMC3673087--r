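## Core S4 classes. Pixel convention throughout the package: continuous image
## coordinates (u, v) with origin at the top-left corner, u rightward and v
## downward, half-open sensor bounds [0, W) x [0, H); pixel (i, j) covers
## [i, i+1) x [j, j+1) so its centre sits at (i + 0.5, j + 0.5). Images are
## stored as integer arrays of dimension H x W x 3 with levels in [0, M].

#' Camera intrinsic parameters
#'
#' Sensor and lens constants of the camera-based sensor: focal length, pixel
#' pitch, sensor resolution and principal point. Defaults describe a
#' 2336 x 1752 CCD with 5.5 um square pixels behind a 10 mm lens, the
#' configuration the package's arrangement study assumes.
#'
#' @slot focalLengthMm focal length in millimetres (> 0).
#' @slot pixelPitchUm pixel pitch in micrometres (> 0); square pixels.
#' @slot sensorWidthPx,sensorHeightPx sensor resolution in pixels.
#' @slot principalPoint numeric length-2, principal point (c_x, c_y) in
#'   continuous pixel coordinates; defaults to the sensor centre.
#' @export
setClass("CameraIntrinsics",
  representation(
    focalLengthMm  = "numeric",
    pixelPitchUm   = "numeric",
    sensorWidthPx  = "numeric",
    sensorHeightPx = "numeric",
    principalPoint = "numeric"
  )
)

setValidity("CameraIntrinsics", function(object) {
  msg <- character()
  if (length(object@focalLengthMm) != 1 || object@focalLengthMm <= 0)
    msg <- c(msg, "focalLengthMm must be a single positive number")
  if (length(object@pixelPitchUm) != 1 || object@pixelPitchUm <= 0)
    msg <- c(msg, "pixelPitchUm must be a single positive number")
  if (object@sensorWidthPx < 1 || object@sensorHeightPx < 1)
    msg <- c(msg, "sensor dimensions must be >= 1 pixel")
  if (length(object@principalPoint) != 2)
    msg <- c(msg, "principalPoint must have two elements")
  else if (object@principalPoint[1] < 0 || object@principalPoint[1] > object@sensorWidthPx ||
           object@principalPoint[2] < 0 || object@principalPoint[2] > object@sensorHeightPx)
    msg <- c(msg, "principalPoint must lie inside the sensor bounds")
  if (length(msg)) msg else TRUE
})

#' @param focal_length_mm,pixel_pitch_um,sensor_width_px,sensor_height_px,principal_point
#'   see slots of [CameraIntrinsics-class].
#' @rdname CameraIntrinsics-class
#' @export
cameraIntrinsics <- function(focal_length_mm = 10.0, pixel_pitch_um = 5.5,
                             sensor_width_px = 2336L, sensor_height_px = 1752L,
                             principal_point = NULL) {
  if (is.null(principal_point))
    principal_point <- c(sensor_width_px / 2, sensor_height_px / 2)
  new("CameraIntrinsics",
      focalLengthMm = as.numeric(focal_length_mm),
      pixelPitchUm = as.numeric(pixel_pitch_um),
      sensorWidthPx = as.numeric(sensor_width_px),
      sensorHeightPx = as.numeric(sensor_height_px),
      principalPoint = as.numeric(principal_point))
}

#' Camera extrinsic parameters
#'
#' Pose of the camera relative to the world frame OXYZ, whose origin sits on
#' the ground directly beneath the camera with Z up and X pointing ahead of
#' the vehicle. Pitch `alpha` is measured from the horizontal, so
#' `alpha = 90` is nadir (optical axis pointing straight down); roll and yaw
#' default to zero (flat terrain, correct guidance).
#'
#' @slot pitchAlphaDeg pitch angle in degrees, 0 < alpha <= 90.
#' @slot rollThetaDeg,yawBetaDeg roll/yaw in degrees (default 0).
#' @slot heightHCm camera height above ground in centimetres (> 0).
#' @export
setClass("CameraExtrinsics",
  representation(
    pitchAlphaDeg = "numeric",
    rollThetaDeg  = "numeric",
    yawBetaDeg    = "numeric",
    heightHCm     = "numeric"
  )
)

setValidity("CameraExtrinsics", function(object) {
  msg <- character()
  if (length(object@pitchAlphaDeg) != 1 ||
      object@pitchAlphaDeg <= 0 || object@pitchAlphaDeg > 90)
    msg <- c(msg, "pitchAlphaDeg must satisfy 0 < alpha <= 90 (camera must see the ground ahead)")
  if (length(object@heightHCm) != 1 || object@heightHCm <= 0)
    msg <- c(msg, "heightHCm must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param pitch_alpha_deg,roll_theta_deg,yaw_beta_deg,height_h_cm see slots.
#' @rdname CameraExtrinsics-class
#' @export
cameraExtrinsics <- function(pitch_alpha_deg, height_h_cm,
                             roll_theta_deg = 0, yaw_beta_deg = 0) {
  new("CameraExtrinsics",
      pitchAlphaDeg = as.numeric(pitch_alpha_deg),
      rollThetaDeg = as.numeric(roll_theta_deg),
      yawBetaDeg = as.numeric(yaw_beta_deg),
      heightHCm = as.numeric(height_h_cm))
}

#' Full camera model
#'
#' Bundles [CameraIntrinsics-class] and [CameraExtrinsics-class].
#'
#' @slot intrinsics a `CameraIntrinsics`.
#' @slot extrinsics a `CameraExtrinsics`.
#' @export
setClass("CameraModel",
  representation(intrinsics = "CameraIntrinsics", extrinsics = "CameraExtrinsics"))

#' @param intrinsics,extrinsics the two parameter sets.
#' @rdname CameraModel-class
#' @export
cameraModel <- function(extrinsics, intrinsics = cameraIntrinsics()) {
  new("CameraModel", intrinsics = intrinsics, extrinsics = extrinsics)
}

#' Rectangular region of interest on the ground plane
#'
#' A flat rectangle lying on the ground (z = 0), the software twin of the
#' 1 x 1 m bright-orange cardboard used to count ROI pixels in the field.
#' `distance_d_m` is measured horizontally from the camera's vertical ground
#' projection to the **near edge** of the rectangle; the rectangle is centred
#' laterally unless `lateral_offset_m` shifts it.
#'
#' @slot distanceDM horizontal distance to the near edge, metres (> 0).
#' @slot widthM,depthM lateral width and along-track depth, metres (> 0).
#' @slot lateralOffsetM lateral offset of the centre, metres.
#' @export
setClass("GroundROI",
  representation(distanceDM = "numeric", widthM = "numeric",
                 depthM = "numeric", lateralOffsetM = "numeric"))

setValidity("GroundROI", function(object) {
  msg <- character()
  if (object@distanceDM <= 0) msg <- c(msg, "distanceDM must be > 0")
  if (object@widthM <= 0 || object@depthM <= 0)
    msg <- c(msg, "widthM and depthM must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param distance_d_m,width_m,depth_m,lateral_offset_m see slots.
#' @rdname GroundROI-class
#' @export
groundROI <- function(distance_d_m, width_m = 1.0, depth_m = 1.0,
                      lateral_offset_m = 0.0) {
  new("GroundROI", distanceDM = as.numeric(distance_d_m),
      widthM = as.numeric(width_m), depthM = as.numeric(depth_m),
      lateralOffsetM = as.numeric(lateral_offset_m))
}

setClassUnion("GroundROIOrNULL", c("GroundROI", "NULL"))

#' Projected quadrilateral of a ground ROI
#'
#' The four corners of a [GroundROI-class] mapped through the pinhole camera
#' into pixel space. Corners are ordered counter-clockwise in pixel
#' coordinates; `clipped` records whether any corner fell outside the sensor
#' bounds `[0, W) x [0, H)`.
#'
#' @slot cornersPx 4 x 2 numeric matrix of (u, v) corners.
#' @slot clipped logical flag.
#' @export
setClass("QuadProjection",
  representation(cornersPx = "matrix", clipped = "logical"))

setValidity("QuadProjection", function(object) {
  if (!is.numeric(object@cornersPx) || !all(dim(object@cornersPx) == c(4, 2)))
    return("cornersPx must be a 4 x 2 numeric matrix")
  if (signedPolygonArea(object@cornersPx) < -1e-9)
    return("corners must be ordered counter-clockwise in pixel space")
  TRUE
})

#' Exposure-time controller state
#'
#' Current exposure time together with the control-band parameters of the
#' white-panel feedback loop: the loop aims for `a*M <= H < b*M`, where `H`
#' is the largest of the three mean panel channels and `M` the saturation
#' level; each update multiplies the exposure by `(1 + p)` or `(1 - p)`.
#'
#' @slot exposureTimeUs current exposure time E_t in microseconds (> 0).
#' @slot lowerFrac band lower fraction `a` (default 0.90).
#' @slot upperFrac band upper fraction `b` (default 0.98).
#' @slot adjustFrac adjustment fraction `p` in (0, 1) (default 0.20).
#' @slot maxLevel saturation level `M` (default 255 for 8-bit channels).
#' @export
setClass("ExposureState",
  representation(exposureTimeUs = "numeric", lowerFrac = "numeric",
                 upperFrac = "numeric", adjustFrac = "numeric",
                 maxLevel = "numeric"))

setValidity("ExposureState", function(object) {
  msg <- character()
  if (object@exposureTimeUs <= 0) msg <- c(msg, "exposureTimeUs must be > 0")
  if (!(object@lowerFrac > 0 && object@lowerFrac < object@upperFrac &&
        object@upperFrac <= 1))
    msg <- c(msg, "band fractions must satisfy 0 < lowerFrac < upperFrac <= 1")
  if (!(object@adjustFrac > 0 && object@adjustFrac < 1))
    msg <- c(msg, "adjustFrac must lie strictly between 0 and 1")
  if (object@maxLevel <= 0) msg <- c(msg, "maxLevel must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param exposure_time_us,lower_frac,upper_frac,adjust_frac,max_level see slots.
#' @rdname ExposureState-class
#' @export
exposureState <- function(exposure_time_us, lower_frac = 0.90,
                          upper_frac = 0.98, adjust_frac = 0.20,
                          max_level = 255) {
  new("ExposureState", exposureTimeUs = as.numeric(exposure_time_us),
      lowerFrac = as.numeric(lower_frac), upperFrac = as.numeric(upper_frac),
      adjustFrac = as.numeric(adjust_frac), maxLevel = as.numeric(max_level))
}

#' White-panel sample statistics
#'
#' Per-channel means over the sampled white-panel region and the controller
#' statistic `H = max(meanR, meanG, meanB)`.
#'
#' @slot meanR,meanG,meanB channel means.
#' @slot hStat the maximum of the three means.
#' @export
setClass("PanelSample",
  representation(meanR = "numeric", meanG = "numeric", meanB = "numeric",
                 hStat = "numeric"))

setValidity("PanelSample", function(object) {
  if (!isTRUE(all.equal(object@hStat,
                        max(object@meanR, object@meanG, object@meanB))))
    return("hStat must equal max(meanR, meanG, meanB)")
  TRUE
})

#' Radial vignetting pattern
#'
#' Per-pixel weight matrix P with values in [0, 1]: zero at the pattern
#' centre `(c_x, c_y)` and one at the most distant corner; with the default
#' centred pattern all four corner pixels equal one. The weight is the
#' Euclidean distance to the centre normalised by the largest corner
#' distance.
#'
#' @slot values H x W numeric matrix of weights.
#' @slot center numeric length-2, (c_x, c_y) in continuous pixel coordinates.
#' @export
setClass("VignettingPattern",
  representation(values = "matrix", center = "numeric"))

setValidity("VignettingPattern", function(object) {
  v <- object@values
  if (min(v) < 0 || max(v) > 1 + 1e-12)
    return("pattern values must lie in [0, 1]")
  if (length(object@center) != 2) return("center must have two elements")
  TRUE
})

#' Per-channel vignetting correction gains
#'
#' Strengths of the multiplicative correction
#' `channel_c = (1 + K * P) * channel`. The defaults correct only the red
#' channel (`K_r = 0.3`), matching the red attenuation a UV/IR cut filter
#' induces toward the image corners.
#'
#' @slot kr,kg,kb non-negative gains for R, G, B.
#' @export
setClass("VignettingGains",
  representation(kr = "numeric", kg = "numeric", kb = "numeric"))

setValidity("VignettingGains", function(object) {
  if (object@kr < 0 || object@kg < 0 || object@kb < 0)
    return("gains must be >= 0")
  TRUE
})

#' @param k_r,k_g,k_b the three gains.
#' @rdname VignettingGains-class
#' @export
vignettingGains <- function(k_r = 0.3, k_g = 0.0, k_b = 0.0) {
  new("VignettingGains", kr = as.numeric(k_r), kg = as.numeric(k_g),
      kb = as.numeric(k_b))
}

#' Two-class fuzzy colour-cluster model
#'
#' Result of fuzzy C-means clustering of RGB samples into vegetation and
#' background classes. The vegetation centre is the one with the larger
#' green chromatic coordinate g = G / (R + G + B).
#'
#' @slot centers 2 x 3 matrix of RGB cluster centres, rows named
#'   `"vegetation"` and `"background"`.
#' @slot fuzziness fuzziness exponent m.
#' @slot tol convergence tolerance on centre movement.
#' @slot iterations iterations used.
#' @slot converged logical.
#' @export
setClass("ClusterModel",
  representation(centers = "matrix", fuzziness = "numeric", tol = "numeric",
                 iterations = "numeric", converged = "logical"))

setValidity("ClusterModel", function(object) {
  if (!all(dim(object@centers) == c(2, 3)))
    return("centers must be a 2 x 3 matrix")
  if (!identical(rownames(object@centers), c("vegetation", "background")))
    return("centers rows must be named vegetation, background")
  TRUE
})

#' Confusion counts for binary mask comparison
#'
#' Joint counts of predicted/true pixel states: true whites, true blacks,
#' false whites, false blacks.
#'
#' @slot tw,tb,fw,fb non-negative pixel counts.
#' @export
setClass("ConfusionCounts",
  representation(tw = "numeric", tb = "numeric", fw = "numeric", fb = "numeric"))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tw, object@tb, object@fw, object@fb) < 0))
    return("counts must be non-negative")
  TRUE
})

#' Percentage-of-correct-classification score
#'
#' PCC = (TW + TB) / (TW + TB + FW + FB), kept both as a fraction and on the
#' percent scale.
#'
#' @slot value fraction in [0, 1].
#' @slot percent `value * 100`.
#' @export
setClass("PccScore", representation(value = "numeric", percent = "numeric"))

setValidity("PccScore", function(object) {
  if (object@value < 0 || object@value > 1) return("value must lie in [0, 1]")
  if (!isTRUE(all.equal(object@percent, object@value * 100)))
    return("percent must equal value * 100")
  TRUE
})

#' Synthetic field-scene specification
#'
#' Describes a flat field: parallel crop rows running along the direction of
#' travel (spaced 0.75 m like maize rows), seeded elliptical weed patches
#' between the rows, bare soil elsewhere, and optionally a bright-orange
#' reference cardboard and a four-colour calibration panel lying on the
#' ground. Colours are RGB reflectance triplets in [0, 255]; `colorJitterSd`
#' adds seeded per-pixel Gaussian reflectance texture within each class,
#' emulating the within-class spectral spread of real soil and canopies.
#'
#' @slot rowSpacingM crop-row spacing in metres (default 0.75).
#' @slot rowWidthM width of each crop row, metres.
#' @slot nRows number of crop rows, centred laterally.
#' @slot weedDensity fraction of inter-row ground covered by weed blobs.
#' @slot weedSeed integer seed for weed layout and reflectance texture.
#' @slot cardboard optional [GroundROI-class] for the orange cardboard.
#' @slot panel optional [GroundROI-class] for the four-colour panel.
#' @slot soilColor,cropColor,weedColor,cardboardColor RGB triplets.
#' @slot panelColors 4 x 3 matrix of quadrant colours
#'   (white, red, green, blue).
#' @slot colorJitterSd per-channel reflectance texture s.d. in levels.
#' @slot extentXM forward extent of the modelled field, metres.
#' @export
setClass("SceneSpec",
  representation(rowSpacingM = "numeric", rowWidthM = "numeric",
                 nRows = "numeric", weedDensity = "numeric",
                 weedSeed = "numeric", cardboard = "GroundROIOrNULL",
                 panel = "GroundROIOrNULL",
                 soilColor = "numeric", cropColor = "numeric",
                 weedColor = "numeric", cardboardColor = "numeric",
                 panelColors = "matrix", colorJitterSd = "numeric",
                 extentXM = "numeric"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (object@rowSpacingM <= 0) msg <- c(msg, "rowSpacingM must be > 0")
  if (object@weedDensity < 0 || object@weedDensity >= 1)
    msg <- c(msg, "weedDensity must lie in [0, 1)")
  cols <- rbind(object@soilColor, object@cropColor, object@weedColor,
                object@cardboardColor, object@panelColors)
  if (ncol(cols) != 3 || min(cols) < 0 || max(cols) > 255)
    msg <- c(msg, "colours must be RGB triplets in [0, 255]")
  if (object@colorJitterSd < 0) msg <- c(msg, "colorJitterSd must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param row_spacing_m,row_width_m,n_rows,weed_density,weed_seed,cardboard,panel,soil_color,crop_color,weed_color,cardboard_color,panel_colors,color_jitter_sd,extent_x_m
#'   see slots of [SceneSpec-class].
#' @rdname SceneSpec-class
#' @export
sceneSpec <- function(row_spacing_m = 0.75, row_width_m = 0.15, n_rows = 4,
                      weed_density = 0.04, weed_seed = 1,
                      cardboard = NULL, panel = NULL,
                      soil_color = c(120, 95, 70),
                      crop_color = c(60, 140, 55),
                      weed_color = c(70, 150, 60),
                      cardboard_color = c(240, 120, 30),
                      panel_colors = rbind(white = c(250, 250, 250),
                                           red   = c(200, 40, 40),
                                           green = c(40, 170, 40),
                                           blue  = c(40, 60, 190)),
                      color_jitter_sd = 20, extent_x_m = 12) {
  new("SceneSpec", rowSpacingM = as.numeric(row_spacing_m),
      rowWidthM = as.numeric(row_width_m), nRows = as.numeric(n_rows),
      weedDensity = as.numeric(weed_density), weedSeed = as.numeric(weed_seed),
      cardboard = cardboard, panel = panel,
      soilColor = as.numeric(soil_color), cropColor = as.numeric(crop_color),
      weedColor = as.numeric(weed_color),
      cardboardColor = as.numeric(cardboard_color),
      panelColors = panel_colors, colorJitterSd = as.numeric(color_jitter_sd),
      extentXM = as.numeric(extent_x_m))
}

#' Linear sensor response specification
#'
#' Forward model of the imaging chain used by the renderer: digital level =
#' reflectance * (E_t / fullScaleExposureUs), red channel attenuated by
#' division by `(1 + K_r * P)` (so the package's vignetting correction is its
#' exact inverse), additive Gaussian read noise, rounding, and clipping to
#' `[0, saturationLevel]`.
#'
#' @slot fullScaleExposureUs exposure at which reflectance maps one-to-one
#'   to digital levels, microseconds.
#' @slot saturationLevel clipping level M (255 for 8-bit).
#' @slot vignetting a [VignettingGains-class] holding the forward
#'   attenuation strengths.
#' @slot noiseSd additive noise standard deviation in levels.
#' @slot seed integer seed for the noise stream.
#' @export
setClass("SensorSpec",
  representation(fullScaleExposureUs = "numeric", saturationLevel = "numeric",
                 vignetting = "VignettingGains", noiseSd = "numeric",
                 seed = "numeric"))

setValidity("SensorSpec", function(object) {
  msg <- character()
  if (object@fullScaleExposureUs <= 0)
    msg <- c(msg, "fullScaleExposureUs must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@saturationLevel <= 0) msg <- c(msg, "saturationLevel must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param full_scale_exposure_us,saturation_level,vignetting,noise_sd,seed see slots.
#' @rdname SensorSpec-class
#' @export
sensorSpec <- function(full_scale_exposure_us = 35000, saturation_level = 255,
                       vignetting = vignettingGains(), noise_sd = 2, seed = 1) {
  new("SensorSpec", fullScaleExposureUs = as.numeric(full_scale_exposure_us),
      saturationLevel = as.numeric(saturation_level), vignetting = vignetting,
      noiseSd = as.numeric(noise_sd), seed = as.numeric(seed))
}

#' Rendered synthetic frame
#'
#' An image rendered by [renderScene()] together with the exact ground-truth
#' masks the renderer painted (no noise is applied to the truth) and the
#' parameters used.
#'
#' @slot image H x W x 3 integer array.
#' @slot truthVegetation,truthCardboard,truthPanelWhite logical H x W masks.
#' @slot metadata list of camera/scene/sensor parameters and the exposure.
#' @export
setClass("RenderedFrame",
  representation(image = "array", truthVegetation = "matrix",
                 truthCardboard = "matrix", truthPanelWhite = "matrix",
                 metadata = "list"))

setValidity("RenderedFrame", function(object) {
  d <- dim(object@image)
  if (length(d) != 3 || d[3] != 3) return("image must be H x W x 3")
  for (nm in c("truthVegetation", "truthCardboard", "truthPanelWhite"))
    if (!all(dim(slot(object, nm)) == d[1:2]))
      return("truth masks must match the image dimensions")
  TRUE
})

## show methods -------------------------------------------------------------

setMethod("show", "CameraIntrinsics", function(object) {
  cat(sprintf("CameraIntrinsics: f = %g mm, pitch = %g um, sensor %g x %g px, pp = (%g, %g)\n",
              object@focalLengthMm, object@pixelPitchUm, object@sensorWidthPx,
              object@sensorHeightPx, object@principalPoint[1],
              object@principalPoint[2]))
})

setMethod("show", "CameraExtrinsics", function(object) {
  cat(sprintf("CameraExtrinsics: pitch %g deg, roll %g deg, yaw %g deg, h = %g cm\n",
              object@pitchAlphaDeg, object@rollThetaDeg, object@yawBetaDeg,
              object@heightHCm))
})

setMethod("show", "CameraModel", function(object) {
  show(object@intrinsics); show(object@extrinsics)
})

setMethod("show", "GroundROI", function(object) {
  cat(sprintf("GroundROI: %g x %g m at d = %g m (lateral offset %g m)\n",
              object@widthM, object@depthM, object@distanceDM,
              object@lateralOffsetM))
})

setMethod("show", "QuadProjection", function(object) {
  cat("QuadProjection (counter-clockwise, pixel coordinates):\n")
  print(round(object@cornersPx, 2))
  cat(sprintf("clipped: %s\n", object@clipped))
})

setMethod("show", "ExposureState", function(object) {
  cat(sprintf("ExposureState: E_t = %g us, band [%g, %g) x M = [%g, %g), p = %g\n",
              object@exposureTimeUs, object@lowerFrac, object@upperFrac,
              object@lowerFrac * object@maxLevel,
              object@upperFrac * object@maxLevel, object@adjustFrac))
})

setMethod("show", "PanelSample", function(object) {
  cat(sprintf("PanelSample: R = %.2f, G = %.2f, B = %.2f, H = %.2f\n",
              object@meanR, object@meanG, object@meanB, object@hStat))
})

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel (fuzzy C-means, m = %g, %d iterations, converged: %s)\n",
              object@fuzziness, as.integer(object@iterations), object@converged))
  print(round(object@centers, 1))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TW = %g, TB = %g, FW = %g, FB = %g\n",
              object@tw, object@tb, object@fw, object@fb))
})

setMethod("show", "PccScore", function(object) {
  cat(sprintf("PCC = %.4f (%.2f%%)\n", object@value, object@percent))
})

setMethod("show", "RenderedFrame", function(object) {
  d <- dim(object@image)
  cat(sprintf("RenderedFrame: %d x %d px, E_t = %g us, %d vegetation px, %d cardboard px\n",
              d[2], d[1], object@metadata$exposure_us %||% NA,
              sum(object@truthVegetation), sum(object@truthCardboard)))
})
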