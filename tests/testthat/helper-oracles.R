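## Independent oracles and small fixture builders used across test files.

## Count pixel centres (i + 0.5, j + 0.5) inside a convex CCW polygon by the
## half-plane sign test -- the brute-force rasterization oracle for the
## shoelace area.
rasterCountConvex <- function(poly) {
  xr <- range(poly[, 1]); yr <- range(poly[, 2])
  xs <- seq(floor(xr[1]) + 0.5, ceiling(xr[2]) - 0.5, by = 1)
  ys <- seq(floor(yr[1]) + 0.5, ceiling(yr[2]) - 0.5, by = 1)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  inside <- rep(TRUE, length(px))
  n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    ex <- poly[j, 1] - poly[i, 1]; ey <- poly[j, 2] - poly[i, 2]
    inside <- inside & (ex * (py - poly[i, 2]) - ey * (px - poly[i, 1]) >= 0)
  }
  sum(inside)
}

## Random convex quadrilateral with shoelace area above `min_area`:
## four points at separated angles on a random ellipse are convex.
randomConvexQuad <- function(min_area = 10000) {
  repeat {
    ang <- sort(runif(4, 0, 2 * pi))
    if (min(diff(c(ang, ang[1] + 2 * pi))) <= 0.35) next
    cx <- runif(1, 400, 1900); cy <- runif(1, 400, 1300)
    a <- runif(1, 90, 320); b <- runif(1, 90, 320)
    p <- cbind(cx + a * cos(ang), cy + b * sin(ang))
    if (agrocam:::signedPolygonArea(p) < 0) p <- p[4:1, ]
    if (agrocam:::signedPolygonArea(p) > min_area) return(unname(p))
  }
}

## uniform RGB image
uniformImage <- function(h, w, rgb) {
  img <- array(0L, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- as.integer(rgb[ch])
  img
}

## camera with the reference field of view at reduced resolution
smallCamera <- function(alpha = 20, h_cm = 220, W = 96, H = 72) {
  cameraModel(cameraExtrinsics(alpha, h_cm), scaledIntrinsics(W, H))
}

## deterministic noiseless sensor/scene used where exact levels matter
flatSensor <- function(seed = 1)
  sensorSpec(vignetting = vignettingGains(0, 0, 0), noise_sd = 0, seed = seed)
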