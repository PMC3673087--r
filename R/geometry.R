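## Pinhole projection of ground regions into pixel coordinates.
##
## World frame OXYZ: origin on the ground directly beneath the camera, X
## forward (direction of travel), Y to the left, Z up. Camera frame: x right,
## y down, z along the optical axis. Rotation composition (world-to-camera):
## yaw about world Z first, then the base axis mapping, then pitch about the
## camera x axis, then roll about the optical axis. Pitch alpha is measured
## from the horizontal, so alpha = 90 deg points the optical axis straight
## down (nadir).

#' Rigid world-to-camera transform from extrinsic parameters
#'
#' Builds the rotation matrix and camera centre that map world coordinates
#' (metres, OXYZ as described in [CameraExtrinsics-class]) into the camera
#' frame: `p_cam = R %*% (p_world - center)`.
#'
#' @param extrinsics a [CameraExtrinsics-class].
#' @return list with `rotation` (3 x 3 orthonormal, det +1), `center`
#'   (camera position in world metres) and `translation` (`-R %*% center`,
#'   so `p_cam = R %*% p_world + translation`).
#' @examples
#' pose <- buildPose(cameraExtrinsics(pitch_alpha_deg = 90, height_h_cm = 200))
#' pose$rotation %*% c(0, 0, 1)  # optical axis (3rd row) antiparallel to Z
#' @export
buildPose <- function(extrinsics) {
  stopifnot(is(extrinsics, "CameraExtrinsics"))
  validObject(extrinsics)
  a <- extrinsics@pitchAlphaDeg * pi / 180
  th <- extrinsics@rollThetaDeg * pi / 180
  be <- extrinsics@yawBetaDeg * pi / 180

  ## base mapping at alpha = 0: optical axis +X, camera right -Y, down -Z
  R0 <- rbind(c(0, -1, 0),
              c(0, 0, -1),
              c(1, 0, 0))
  ## pitch about the camera x (right) axis, tilting the axis toward the ground
  Rx <- rbind(c(1, 0, 0),
              c(0, cos(a), -sin(a)),
              c(0, sin(a), cos(a)))
  ## roll about the optical axis
  Rz <- rbind(c(cos(th), -sin(th), 0),
              c(sin(th), cos(th), 0),
              c(0, 0, 1))
  ## yaw about world Z applied before the base mapping
  Rw <- rbind(c(cos(be), sin(be), 0),
              c(-sin(be), cos(be), 0),
              c(0, 0, 1))
  R <- Rz %*% Rx %*% R0 %*% Rw
  center <- c(0, 0, extrinsics@heightHCm / 100)
  list(rotation = R, center = center,
       translation = as.numeric(-R %*% center))
}

#' Project a world point to pixel coordinates
#'
#' Standard perspective projection: the point is transformed to the camera
#' frame, divided by its depth, scaled by the focal length over the pixel
#' pitch and offset by the principal point.
#'
#' @param point numeric length-3 world coordinates in metres.
#' @param camera a [CameraModel-class].
#' @return numeric length-2 `(u, v)` continuous pixel coordinates.
#' @examples
#' cam <- cameraModel(cameraExtrinsics(90, 200))
#' projectPoint(c(0, 0, 0), cam)  # principal point
#' @export
projectPoint <- function(point, camera) {
  stopifnot(is(camera, "CameraModel"), length(point) == 3)
  pose <- buildPose(camera@extrinsics)
  pc <- as.numeric(pose$rotation %*% (point - pose$center))
  if (pc[3] <= 1e-12)
    stop("point is at or behind the camera plane; not projectable", call. = FALSE)
  fpx <- camera@intrinsics@focalLengthMm * 1000 / camera@intrinsics@pixelPitchUm
  pp <- camera@intrinsics@principalPoint
  c(u = pp[1] + fpx * pc[1] / pc[3],
    v = pp[2] + fpx * pc[2] / pc[3])
}

#' Project a ground ROI into its pixel-space quadrilateral
#'
#' Maps the four corners of a [GroundROI-class] through [projectPoint()] and
#' returns them ordered counter-clockwise, flagging whether any corner falls
#' outside the sensor bounds.
#'
#' @param roi a [GroundROI-class].
#' @param camera a [CameraModel-class].
#' @return a [QuadProjection-class].
#' @export
projectROI <- function(roi, camera) {
  stopifnot(is(roi, "GroundROI"))
  validObject(roi)
  x0 <- roi@distanceDM
  x1 <- roi@distanceDM + roi@depthM
  yl <- roi@lateralOffsetM - roi@widthM / 2
  yr <- roi@lateralOffsetM + roi@widthM / 2
  world <- rbind(c(x0, yl, 0), c(x0, yr, 0), c(x1, yr, 0), c(x1, yl, 0))
  px <- t(apply(world, 1, projectPoint, camera = camera))
  if (signedPolygonArea(px) < 0) px <- px[4:1, , drop = FALSE]
  W <- camera@intrinsics@sensorWidthPx
  H <- camera@intrinsics@sensorHeightPx
  clipped <- any(px[, 1] < 0 | px[, 1] >= W | px[, 2] < 0 | px[, 2] >= H)
  new("QuadProjection", cornersPx = unname(px), clipped = clipped)
}

## Sutherland-Hodgman clipping of a convex-window intersection: clip the
## subject polygon against one half-plane at a time. Window is the sensor
## rectangle [0, W] x [0, H] in continuous coordinates.
clipPolygonToRect <- function(poly, width, height) {
  clipEdge <- function(p, inside, intersect) {
    if (nrow(p) == 0) return(p)
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(p)
    for (i in seq_len(n)) {
      cur <- p[i, ]; prev <- p[if (i == 1) n else i - 1, ]
      ci <- inside(cur); pi <- inside(prev)
      if (ci) {
        if (!pi) out <- rbind(out, intersect(prev, cur))
        out <- rbind(out, cur)
      } else if (pi) {
        out <- rbind(out, intersect(prev, cur))
      }
    }
    out
  }
  ix <- function(a, b, at, coord) {
    t <- (at - a[coord]) / (b[coord] - a[coord])
    a + t * (b - a)
  }
  p <- poly
  p <- clipEdge(p, function(q) q[1] >= 0, function(a, b) ix(a, b, 0, 1))
  p <- clipEdge(p, function(q) q[1] <= width, function(a, b) ix(a, b, width, 1))
  p <- clipEdge(p, function(q) q[2] >= 0, function(a, b) ix(a, b, 0, 2))
  p <- clipEdge(p, function(q) q[2] <= height, function(a, b) ix(a, b, height, 2))
  p
}

## do two closed segments properly cross (shared endpoints excluded)?
segmentsCross <- function(a, b, c, d) {
  orient <- function(p, q, r)
    sign((q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- orient(a, b, c); o2 <- orient(a, b, d)
  o3 <- orient(c, d, a); o4 <- orient(c, d, b)
  (o1 * o2 < 0) && (o3 * o4 < 0)
}

#' Pixel area of a projected quadrilateral
#'
#' Shoelace area of the quadrilateral in continuous pixel units, optionally
#' after clipping the polygon to the sensor rectangle
#' (Sutherland-Hodgman). Self-intersecting (bow-tie) quadrilaterals are
#' rejected; degenerate collinear quads have area zero.
#'
#' @param quad a [QuadProjection-class].
#' @param intrinsics a [CameraIntrinsics-class]; required when
#'   `clip_to_sensor = TRUE` to know the sensor bounds.
#' @param clip_to_sensor clip to `[0, W] x [0, H]` before computing the area?
#' @return non-negative numeric area in pixels.
#' @export
quadPixelArea <- function(quad, intrinsics = cameraIntrinsics(),
                          clip_to_sensor = FALSE) {
  stopifnot(is(quad, "QuadProjection"))
  p <- quad@cornersPx
  if (segmentsCross(p[1, ], p[2, ], p[3, ], p[4, ]) ||
      segmentsCross(p[2, ], p[3, ], p[4, ], p[1, ]))
    stop("self-intersecting quadrilateral has no well-defined area", call. = FALSE)
  if (clip_to_sensor) {
    p <- clipPolygonToRect(p, intrinsics@sensorWidthPx,
                           intrinsics@sensorHeightPx)
    if (nrow(p) < 3) return(0)
  }
  abs(signedPolygonArea(p))
}

#' Sweep camera arrangements over extrinsic-parameter grids
#'
#' Simulates the pixel resolution `n` of a ground ROI for every combination
#' of pitch angle, camera height and ROI distance: each combination projects
#' the ROI corners through the pinhole camera and takes the shoelace area of
#' the resulting trapezoid. The default grid (alpha 10..50 deg by 10, h
#' 210..230 cm by 5, d 3..5 m by 0.5) yields the 125-record layout of the
#' packaged field-measured arrangement table.
#'
#' @param alphas pitch angles, degrees.
#' @param heights camera heights, centimetres.
#' @param distances ROI near-edge distances, metres.
#' @param roi ROI template; its `distance_d_m` is replaced by each grid value.
#' @param intrinsics a [CameraIntrinsics-class].
#' @param clip_to_sensor passed to [quadPixelArea()]; the default keeps the
#'   pure analytic trapezoid area.
#' @return data.frame with columns `alpha_deg`, `height_cm`, `distance_m`,
#'   `n_pixels`, `clipped`, `projectable`; combinations whose ROI cannot be
#'   projected are flagged (`projectable = FALSE`, `n_pixels = NA`), never
#'   dropped.
#' @export
sweepArrangements <- function(alphas = seq(10, 50, by = 10),
                              heights = seq(210, 230, by = 5),
                              distances = seq(3.0, 5.0, by = 0.5),
                              roi = groundROI(distance_d_m = 3),
                              intrinsics = cameraIntrinsics(),
                              clip_to_sensor = FALSE) {
  if (!length(alphas) || !length(heights) || !length(distances))
    stop("parameter grids must be non-empty", call. = FALSE)
  grid <- expand.grid(alpha_deg = alphas, height_cm = heights,
                      distance_m = distances, KEEP.OUT.ATTRS = FALSE)
  ## order records the way the printed table reads: alpha, then d, then h
  grid <- grid[order(grid$alpha_deg, grid$distance_m, grid$height_cm), ]
  rownames(grid) <- NULL
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cam <- cameraModel(
      cameraExtrinsics(pitch_alpha_deg = grid$alpha_deg[i],
                       height_h_cm = grid$height_cm[i]),
      intrinsics)
    r <- groundROI(distance_d_m = grid$distance_m[i], width_m = roi@widthM,
                   depth_m = roi@depthM, lateral_offset_m = roi@lateralOffsetM)
    tryCatch({
      q <- projectROI(r, cam)
      list(n = quadPixelArea(q, intrinsics, clip_to_sensor),
           clipped = isClipped(q), ok = TRUE)
    }, error = function(e) list(n = NA_real_, clipped = NA, ok = FALSE))
  })
  grid$n_pixels <- vapply(res, function(x) x$n, numeric(1))
  grid$clipped <- vapply(res, function(x) as.logical(x$clipped), logical(1))
  grid$projectable <- vapply(res, function(x) x$ok, logical(1))
  grid
}

#' Recommend a camera arrangement from an arrangement table
#'
#' Returns the record maximising (or minimising) the pixel resolution `n`
#' subject to simple constraints on distance, pitch and height. Ties are
#' broken deterministically: smaller distance, then larger height, then
#' larger pitch angle.
#'
#' @param table arrangement data.frame with columns `alpha_deg`, `height_cm`,
#'   `distance_m`, `n_pixels` (e.g. from [sweepArrangements()] or
#'   [table1Arrangements()]).
#' @param min_distance_m optional lower bound on `distance_m`.
#' @param alpha_range,height_range optional length-2 inclusive bounds.
#' @param objective `"max"` (default) or `"min"`.
#' @return single-row data.frame, the chosen record.
#' @export
recommendArrangement <- function(table, min_distance_m = NULL,
                                 alpha_range = NULL, height_range = NULL,
                                 objective = c("max", "min")) {
  objective <- match.arg(objective)
  validateArrangementTable(table)
  keep <- !is.na(table$n_pixels)
  if (!is.null(min_distance_m)) keep <- keep & table$distance_m >= min_distance_m
  if (!is.null(alpha_range))
    keep <- keep & table$alpha_deg >= alpha_range[1] & table$alpha_deg <= alpha_range[2]
  if (!is.null(height_range))
    keep <- keep & table$height_cm >= height_range[1] & table$height_cm <= height_range[2]
  cand <- table[keep, , drop = FALSE]
  if (!nrow(cand))
    stop("no arrangement satisfies the constraints", call. = FALSE)
  target <- if (objective == "max") max(cand$n_pixels) else min(cand$n_pixels)
  cand <- cand[cand$n_pixels == target, , drop = FALSE]
  cand <- cand[order(cand$distance_m, -cand$height_cm, -cand$alpha_deg), ,
               drop = FALSE]
  cand[1, , drop = FALSE]
}
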