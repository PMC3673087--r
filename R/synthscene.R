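## Synthetic field-scene renderer: per-pixel rays are cast through the
## pinhole camera and intersected with the ground plane z = 0, so flat
## scenes are exact and every rendered frame carries exact ground-truth
## masks. The sensor model is linear in exposure time with red vignetting
## attenuation, additive noise, rounding and clipping.

#' Intrinsics for a reduced-resolution render
#'
#' Returns intrinsics with the requested pixel resolution but the same field
#' of view as the full-resolution reference sensor, by scaling the pixel
#' pitch accordingly. Useful to keep renders cheap without changing the
#' imaging geometry.
#'
#' @param width_px,height_px desired resolution.
#' @param reference full-resolution [CameraIntrinsics-class].
#' @return a [CameraIntrinsics-class].
#' @export
scaledIntrinsics <- function(width_px, height_px,
                             reference = cameraIntrinsics()) {
  cameraIntrinsics(
    focal_length_mm = reference@focalLengthMm,
    pixel_pitch_um = reference@pixelPitchUm * reference@sensorWidthPx / width_px,
    sensor_width_px = width_px, sensor_height_px = height_px)
}

## ground-plane hit coordinates for every pixel; list(X, Y, ground)
castGroundRays <- function(camera) {
  intr <- camera@intrinsics
  W <- intr@sensorWidthPx; H <- intr@sensorHeightPx
  fpx <- intr@focalLengthMm * 1000 / intr@pixelPitchUm
  pp <- intr@principalPoint
  pose <- buildPose(camera@extrinsics)
  Rt <- t(pose$rotation)
  u <- matrix(rep(seq_len(W) - 0.5, each = H), H, W) - pp[1]
  v <- matrix(rep(seq_len(H) - 0.5, W), H, W) - pp[2]
  ## camera-frame ray (u/fpx, v/fpx, 1) rotated into the world frame
  dx <- Rt[1, 1] * u / fpx + Rt[1, 2] * v / fpx + Rt[1, 3]
  dy <- Rt[2, 1] * u / fpx + Rt[2, 2] * v / fpx + Rt[2, 3]
  dz <- Rt[3, 1] * u / fpx + Rt[3, 2] * v / fpx + Rt[3, 3]
  h <- pose$center[3]
  ground <- dz < 0
  t <- ifelse(ground, -h / dz, NA_real_)
  list(X = t * dx, Y = t * dy, ground = ground)
}

insideROIRect <- function(X, Y, roi) {
  !is.na(X) &
    X >= roi@distanceDM & X < roi@distanceDM + roi@depthM &
    Y >= roi@lateralOffsetM - roi@widthM / 2 &
    Y < roi@lateralOffsetM + roi@widthM / 2
}

#' Render a synthetic field scene
#'
#' Casts one ray per pixel against the ground plane, paints soil, crop
#' rows, weed blobs, the optional orange cardboard and the optional
#' four-colour panel (pixels above the horizon get a fixed sky colour),
#' adds the seeded within-class reflectance texture, then applies the
#' sensor model: linear exposure scaling, red-channel vignetting
#' attenuation by division by `(1 + K_r P)`, additive Gaussian noise,
#' rounding and clipping to `[0, M]`. Ground-truth masks are painted with
#' identical geometry and no noise.
#'
#' @param scene a [SceneSpec-class].
#' @param camera a [CameraModel-class]; its sensor size fixes the render
#'   resolution.
#' @param sensor a [SensorSpec-class].
#' @param exposure_us exposure time in microseconds (default: the sensor's
#'   full-scale exposure).
#' @return a [RenderedFrame-class].
#' @export
renderScene <- function(scene, camera, sensor = sensorSpec(),
                        exposure_us = sensor@fullScaleExposureUs) {
  stopifnot(is(scene, "SceneSpec"), is(camera, "CameraModel"),
            is(sensor, "SensorSpec"))
  validObject(scene)
  if (exposure_us <= 0) stop("exposure_us must be > 0", call. = FALSE)
  rays <- castGroundRays(camera)
  X <- rays$X; Y <- rays$Y; ground <- rays$ground
  if (!any(ground))
    stop("camera sees no ground pixel (horizon-only view)", call. = FALSE)
  H <- nrow(X); W <- ncol(X)

  rowCenters <- (seq_len(scene@nRows) - (scene@nRows + 1) / 2) * scene@rowSpacingM
  crop <- matrix(FALSE, H, W)
  for (rc in rowCenters)
    crop <- crop | (ground & !is.na(Y) & abs(Y - rc) < scene@rowWidthM / 2)

  ## seeded weed layout + reflectance texture share the scene seed so a
  ## scene is identical across exposures
  yHalf <- (scene@nRows * scene@rowSpacingM) / 2 + scene@rowSpacingM / 2
  fieldArea <- scene@extentXM * 2 * yHalf
  interArea <- max(fieldArea - scene@nRows * scene@rowWidthM * scene@extentXM, 0)
  nBlobs <- round(scene@weedDensity * interArea / (pi * 0.12^2))
  sceneDraws <- withSeed(scene@weedSeed, {
    blobs <- if (nBlobs > 0)
      cbind(x = stats::runif(nBlobs, 0.5, scene@extentXM),
            y = stats::runif(nBlobs, -yHalf, yHalf),
            rx = stats::runif(nBlobs, 0.06, 0.18),
            ry = stats::runif(nBlobs, 0.06, 0.18))
    else matrix(numeric(0), 0, 4)
    jitter <- if (scene@colorJitterSd > 0)
      array(stats::rnorm(H * W * 3, 0, scene@colorJitterSd), c(H, W, 3))
    else array(0, c(H, W, 3))
    list(blobs = blobs, jitter = jitter)
  })
  weed <- matrix(FALSE, H, W)
  if (nrow(sceneDraws$blobs)) {
    Xs <- ifelse(ground, X, Inf); Ys <- ifelse(ground, Y, Inf)
    for (b in seq_len(nrow(sceneDraws$blobs))) {
      bb <- sceneDraws$blobs[b, ]
      weed <- weed | (((Xs - bb["x"]) / bb["rx"])^2 +
                        ((Ys - bb["y"]) / bb["ry"])^2 < 1)
    }
    weed <- weed & ground & !crop
  }

  cardboard <- if (!is.null(scene@cardboard))
    insideROIRect(X, Y, scene@cardboard) & ground else matrix(FALSE, H, W)
  panel <- if (!is.null(scene@panel))
    insideROIRect(X, Y, scene@panel) & ground else matrix(FALSE, H, W)
  panelWhite <- matrix(FALSE, H, W)
  reflect <- array(0, c(H, W, 3))
  skyColor <- c(170, 190, 220)
  for (ch in 1:3) {
    plane <- matrix(skyColor[ch], H, W)
    plane[ground] <- scene@soilColor[ch]
    plane[crop] <- scene@cropColor[ch]
    plane[weed] <- scene@weedColor[ch]
    plane[cardboard] <- scene@cardboardColor[ch]
    reflect[, , ch] <- plane
  }
  if (any(panel)) {
    p <- scene@panel
    xmid <- p@distanceDM + p@depthM / 2
    near <- !is.na(X) & X < xmid
    left <- !is.na(Y) & Y >= p@lateralOffsetM
    quads <- list(white = panel & near & left, red = panel & near & !left,
                  green = panel & !near & left, blue = panel & !near & !left)
    for (qi in seq_along(quads)) for (ch in 1:3)
      reflect[, , ch][quads[[qi]]] <- scene@panelColors[qi, ch]
    panelWhite <- quads$white
  }
  reflect <- reflect + sceneDraws$jitter

  img <- reflect * (exposure_us / sensor@fullScaleExposureUs)
  ks <- c(sensor@vignetting@kr, sensor@vignetting@kg, sensor@vignetting@kb)
  if (any(ks > 0)) {
    P <- patternValues(vignettingPattern(W, H))
    for (ch in 1:3) if (ks[ch] > 0)
      img[, , ch] <- img[, , ch] / (1 + ks[ch] * P)
  }
  if (sensor@noiseSd > 0)
    img <- img + withSeed(sensor@seed,
                          array(stats::rnorm(H * W * 3, 0, sensor@noiseSd),
                                c(H, W, 3)))
  img <- pmin(pmax(roundHalfUp(img), 0), sensor@saturationLevel)
  storage.mode(img) <- "integer"

  veg <- (crop | weed) & !cardboard & !panel
  new("RenderedFrame", image = img,
      truthVegetation = veg,
      truthCardboard = cardboard & !panel,
      truthPanelWhite = panelWhite,
      metadata = list(exposure_us = exposure_us,
                      camera = camera, scene = scene, sensor = sensor))
}

#' Render the same scene at several exposure times
#'
#' The scene layout, reflectance texture and noise stream are identical
#' across frames (same seeds), so unsaturated digital levels scale linearly
#' with exposure time.
#'
#' @inheritParams renderScene
#' @param exposures vector of exposure times in microseconds (all > 0).
#' @return list of [RenderedFrame-class] objects.
#' @export
renderExposureSeries <- function(scene, camera, sensor = sensorSpec(),
                                 exposures) {
  if (!length(exposures)) stop("exposure list is empty", call. = FALSE)
  if (any(exposures <= 0)) stop("exposures must be > 0", call. = FALSE)
  lapply(exposures, function(e) renderScene(scene, camera, sensor, e))
}

#' Capture contract over a synthetic scene
#'
#' Wraps a scene/camera/sensor into the deterministic capture function the
#' exposure-control loop expects, together with the white-panel sampling
#' region (the renderer's exact white-quadrant mask).
#'
#' @inheritParams renderScene
#' @return list with `capture` (`function(exposure_us)` returning an image)
#'   and `panel_region` (logical mask usable with [sampleWhitePanel()]).
#' @export
sceneSensor <- function(scene, camera, sensor = sensorSpec()) {
  if (is.null(scene@panel))
    stop("scene has no colour panel; add one to drive the exposure loop",
         call. = FALSE)
  probe <- renderScene(scene, camera, sensor)
  if (!any(truthPanelWhite(probe)))
    stop("white panel quadrant is not visible from this camera", call. = FALSE)
  list(capture = function(exposure_us)
         frameImage(renderScene(scene, camera, sensor, exposure_us)),
       panel_region = truthPanelWhite(probe))
}

#' Simulate the 2 x 2 exposure/vignetting accuracy experiment
#'
#' Renders `n_pairs` synthetic field scenes with red vignetting attenuation;
#' for each scene captures an under-exposed frame and a frame at the
#' exposure chosen by the closed-loop controller, then scores the four
#' processing conditions (exposure adjusted? x vignetting corrected?) with
#' [conditionGridReport()] against the renderer's exact vegetation truth.
#'
#' @param n_pairs number of scene pairs (>= 1).
#' @param seed master seed; per-pair scene and noise seeds derive from it.
#' @param under_exposure_us exposure of the deliberately under-exposed
#'   capture.
#' @param image_width,image_height render resolution (field of view is kept
#'   at the full sensor's).
#' @param pitch_alpha_deg,height_h_cm camera arrangement (defaults: the
#'   recommended 20 deg / 220 cm operating point).
#' @param weed_density,n_samples,max_iter forwarded to the scene,
#'   segmentation and exposure loop.
#' @return list with `report` (the condition-grid data.frame), `exposures`
#'   (per-pair under/adjusted exposure times and loop convergence) and
#'   `per_pair` PCC matrix.
#' @export
simulateConditionGrid <- function(n_pairs = 10, seed = 1,
                                  under_exposure_us = 8000,
                                  image_width = 320, image_height = 240,
                                  pitch_alpha_deg = 20, height_h_cm = 220,
                                  weed_density = 0.04, n_samples = 2000,
                                  max_iter = 10) {
  stopifnot(n_pairs >= 1)
  camera <- cameraModel(cameraExtrinsics(pitch_alpha_deg, height_h_cm),
                        scaledIntrinsics(image_width, image_height))
  seeds <- withSeed(seed, matrix(sample.int(1e6, 2 * n_pairs), ncol = 2))
  pairs <- vector("list", n_pairs)
  truths <- vector("list", n_pairs)
  expo <- data.frame(pair = seq_len(n_pairs), under_us = under_exposure_us,
                     adjusted_us = NA_real_, converged = NA)
  for (i in seq_len(n_pairs)) {
    scene <- sceneSpec(weed_seed = seeds[i, 1], weed_density = weed_density,
                       panel = groundROI(distance_d_m = 2.3, width_m = 1.2,
                                         depth_m = 0.6))
    sensor <- sensorSpec(seed = seeds[i, 2])
    ss <- sceneSensor(scene, camera, sensor)
    loop <- exposureControlLoop(ss$capture, ss$panel_region,
                                exposureState(under_exposure_us),
                                max_iter = max_iter)
    under <- renderScene(scene, camera, sensor, under_exposure_us)
    adjusted <- renderScene(scene, camera, sensor,
                            exposureTimeUs(loop$state))
    pairs[[i]] <- list(under = frameImage(under),
                       adjusted = frameImage(adjusted))
    truths[[i]] <- truthVegetation(under)
    expo$adjusted_us[i] <- exposureTimeUs(loop$state)
    expo$converged[i] <- loop$converged
  }
  report <- conditionGridReport(pairs, truths,
                                gains = vignettingGains(),
                                n_samples = n_samples, seed = seed)
  list(report = report, exposures = expo,
       per_pair = attr(report, "per_pair"))
}
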