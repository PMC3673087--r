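test_that("rotation matrices are orthonormal with determinant +1 over angle grids", {
  set.seed(11)
  cases <- rbind(expand.grid(a = c(10, 30, 50, 90), th = c(0, -5, 12),
                             be = c(0, 8, -20)),
                 data.frame(a = runif(10, 1, 90), th = runif(10, -30, 30),
                            be = runif(10, -30, 30)))
  for (i in seq_len(nrow(cases))) {
    R <- buildPose(cameraExtrinsics(cases$a[i], 220, cases$th[i],
                                    cases$be[i]))$rotation
    expect_lt(max(abs(t(R) %*% R - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("pitch-only pose equals an independently composed elemental-rotation product", {
  a <- 30 * pi / 180
  base <- rbind(c(0, -1, 0), c(0, 0, -1), c(1, 0, 0))
  pitch <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  expect_lt(max(abs(buildPose(cameraExtrinsics(30, 215))$rotation -
                      pitch %*% base)), 1e-12)
})

test_that("nadir pose points the optical axis straight down and projects on-axis points to the principal point", {
  pose <- buildPose(cameraExtrinsics(90, 200))
  expect_equal(as.numeric(pose$rotation[3, ]), c(0, 0, -1), tolerance = 1e-12)

  cam <- cameraModel(cameraExtrinsics(90, 200))
  expect_equal(unname(projectPoint(c(0, 0, 0), cam)), c(1168, 876))
  ## similar triangles: 1 m lateral offset at h = 2 m, f = 10 mm, 5.5 um
  uv <- projectPoint(c(0, 1, 0), cam)
  expect_equal(abs(uv["u"] - 1168), 0.01 * 1 / 2 / 5.5e-6, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(projectPoint(c(0, 0, 3), cam), "behind")
})

test_that("pitch bounds are enforced", {
  expect_error(cameraExtrinsics(0, 220), "pitchAlphaDeg")
  expect_error(cameraExtrinsics(95, 220), "pitchAlphaDeg")
  expect_error(cameraExtrinsics(30, -1), "heightHCm")
})

test_that("ROI projection is corner-consistent, CCW ordered and perspective-foreshortened", {
  cam <- cameraModel(cameraExtrinsics(50, 230))
  roi <- groundROI(3)
  q <- projectROI(roi, cam)
  p <- corners(q)
  ## consistency oracle: every corner re-projects identically
  world <- rbind(c(3, -0.5, 0), c(3, 0.5, 0), c(4, 0.5, 0), c(4, -0.5, 0))
  expected <- t(apply(world, 1, projectPoint, camera = cam))
  for (i in 1:4)
    expect_true(any(apply(p, 1, function(r) max(abs(r - expected[i, ])) < 1e-9)))
  expect_gte(agrocam:::signedPolygonArea(p), 0)
  ## far edge narrower than near edge in pixel width
  vorder <- order(p[, 2])
  farW <- abs(diff(sort(p[p[, 2] <= median(p[, 2]), 1])))
  nearW <- abs(diff(sort(p[p[, 2] > median(p[, 2]), 1])))
  expect_lt(farW, nearW)
})

test_that("a nadir camera over a centred square ROI sees a centred square", {
  cam <- cameraModel(cameraExtrinsics(90, 250))
  q <- corners(projectROI(groundROI(0.5), cam))
  ## nadir: ROI ahead of camera, symmetric about the vertical centreline
  expect_equal(mean(q[, 1]), 1168, tolerance = 1e-9)
  width <- max(q[, 1]) - min(q[, 1])
  height <- max(q[, 2]) - min(q[, 2])
  expect_equal(width, height, tolerance = 1e-9)
})

test_that("mirroring the ROI laterally mirrors the projected quad about the centreline", {
  cam <- cameraModel(cameraExtrinsics(90, 220))
  qr <- corners(projectROI(groundROI(1, lateral_offset_m = 0.4), cam))
  ql <- corners(projectROI(groundROI(1, lateral_offset_m = -0.4), cam))
  mirrored <- cbind(2 * 1168 - ql[, 1], ql[, 2])
  for (i in 1:4)
    expect_true(any(apply(qr, 1, function(r) max(abs(r - mirrored[i, ])) < 1e-9)))
})

test_that("quad area handles squares, degeneracy, self-intersection and sensor clipping", {
  sq <- new("QuadProjection",
            cornersPx = rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
            clipped = FALSE)
  expect_equal(quadPixelArea(sq), 10000)
  flat <- new("QuadProjection",
              cornersPx = rbind(c(0, 0), c(10, 10), c(20, 20), c(30, 30)),
              clipped = FALSE)
  expect_equal(quadPixelArea(flat), 0)
  bow <- new("QuadProjection",
             cornersPx = rbind(c(0, 0), c(100, 100), c(100, 0), c(0, 100)),
             clipped = FALSE)
  expect_error(quadPixelArea(bow), "self-intersecting")
  ## quad half off the sensor loses half its area when clipped
  part <- new("QuadProjection",
              cornersPx = rbind(c(-100, 0), c(100, 0), c(100, 100), c(-100, 100)),
              clipped = TRUE)
  expect_equal(quadPixelArea(part, cameraIntrinsics(), clip_to_sensor = TRUE),
               10000)
  expect_equal(quadPixelArea(part), 20000)
})

test_that("shoelace area matches the rasterization oracle on random convex quads", {
  set.seed(42)
  for (k in 1:10) {
    p <- randomConvexQuad()
    q <- new("QuadProjection", cornersPx = p, clipped = FALSE)
    analytic <- quadPixelArea(q)
    raster <- rasterCountConvex(p)
    expect_lt(abs(raster - analytic) / analytic, 0.015)
  }
})

test_that("arrangement sweep covers the full grid and is strictly monotone in distance", {
  sw <- sweepArrangements()
  expect_equal(nrow(sw), 125)
  expect_true(all(sw$projectable))
  expect_true(all(c("alpha_deg", "height_cm", "distance_m", "n_pixels",
                    "clipped", "projectable") %in% names(sw)))
  for (a in unique(sw$alpha_deg)) for (h in unique(sw$height_cm)) {
    v <- sw[sw$alpha_deg == a & sw$height_cm == h, ]
    v <- v[order(v$distance_m), "n_pixels"]
    expect_true(all(diff(v) < 0))
  }
})

test_that("recommendArrangement maximises with deterministic tie-breaks and honours constraints", {
  t1 <- table1Arrangements()
  best <- recommendArrangement(t1)
  expect_equal(unlist(best[c("alpha_deg", "height_cm", "distance_m", "n_pixels")]),
               c(alpha_deg = 50, height_cm = 230, distance_m = 3, n_pixels = 129423))
  worstFar <- recommendArrangement(t1, min_distance_m = 5, objective = "min")
  expect_equal(unlist(worstFar[c("alpha_deg", "height_cm", "distance_m", "n_pixels")]),
               c(alpha_deg = 30, height_cm = 210, distance_m = 5, n_pixels = 35648))

  one <- t1[7, , drop = FALSE]
  expect_equal(recommendArrangement(one)$n_pixels, one$n_pixels)
  expect_error(recommendArrangement(t1, min_distance_m = 99), "no arrangement")

  ties <- data.frame(alpha_deg = c(10, 20, 20), height_cm = c(210, 230, 210),
                     distance_m = c(4, 3, 3), n_pixels = c(100, 100, 100))
  pick <- recommendArrangement(ties)
  expect_equal(unlist(pick[c("distance_m", "height_cm", "alpha_deg")]),
               c(distance_m = 3, height_cm = 230, alpha_deg = 20))
})
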