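test_that("feature sampling is exhaustive at full size, seeded and bounded", {
  set.seed(2)
  img <- array(sample.int(256, 8 * 9 * 3, replace = TRUE) - 1L, c(8, 9, 3))
  all <- sampleFeatures(img, n_samples = 72, seed = 1)
  expect_equal(nrow(all), 72)
  expect_equal(sort(all[, "G"]), sort(as.vector(img[, , 2])))

  expect_identical(sampleFeatures(img, 20, seed = 7),
                   sampleFeatures(img, 20, seed = 7))
  expect_false(identical(sampleFeatures(img, 20, seed = 7),
                         sampleFeatures(img, 20, seed = 8)))
  expect_error(sampleFeatures(img, 1), "n_samples")
  expect_error(sampleFeatures(img, 73), "n_samples")
})

test_that("two-point samples recover their points as centres", {
  x <- rbind(matrix(rep(c(40, 120, 30), 60), ncol = 3, byrow = TRUE),
             matrix(rep(c(120, 90, 70), 60), ncol = 3, byrow = TRUE))
  C <- clusterCenters(fitFuzzyClusters(x))
  expect_lt(max(abs(C["vegetation", ] - c(40, 120, 30))), 1)
  expect_lt(max(abs(C["background", ] - c(120, 90, 70))), 1)
})

test_that("cluster centres recover two-Gaussian generating means", {
  x <- agrocam:::withSeed(13, rbind(
    cbind(rnorm(1000, 50, 10), rnorm(1000, 140, 10), rnorm(1000, 40, 10)),
    cbind(rnorm(1000, 130, 10), rnorm(1000, 100, 10), rnorm(1000, 80, 10))))
  C <- clusterCenters(fitFuzzyClusters(x))
  expect_lt(max(abs(C["vegetation", ] - c(50, 140, 40))), 3)
  expect_lt(max(abs(C["background", ] - c(130, 100, 80))), 3)
})

test_that("fitting is invariant to sample order and rejects degenerate input", {
  x <- agrocam:::withSeed(3, rbind(
    cbind(rnorm(200, 60, 8), rnorm(200, 150, 8), rnorm(200, 50, 8)),
    cbind(rnorm(200, 130, 8), rnorm(200, 95, 8), rnorm(200, 75, 8))))
  perm <- agrocam:::withSeed(4, sample.int(nrow(x)))
  expect_equal(clusterCenters(fitFuzzyClusters(x)),
               clusterCenters(fitFuzzyClusters(x[perm, ])), tolerance = 1e-6)
  same <- matrix(rep(c(10, 20, 30), 50), ncol = 3, byrow = TRUE)
  expect_error(fitFuzzyClusters(same), "identical")
})

test_that("hand-rolled fuzzy C-means agrees with the e1071 reference implementation", {
  x <- agrocam:::withSeed(21, rbind(
    cbind(rnorm(400, 55, 9), rnorm(400, 145, 9), rnorm(400, 45, 9)),
    cbind(rnorm(400, 125, 9), rnorm(400, 95, 9), rnorm(400, 72, 9))))
  ours <- clusterCenters(fitFuzzyClusters(x))
  init <- rbind(apply(x, 2, quantile, 0.25), apply(x, 2, quantile, 0.75))
  ref <- e1071::cmeans(x, centers = init, m = 2, iter.max = 300)$centers
  ## match reference rows to ours by proximity
  d1 <- sum(abs(ref[1, ] - ours["vegetation", ]))
  d2 <- sum(abs(ref[2, ] - ours["vegetation", ]))
  refVeg <- if (d1 < d2) ref[1, ] else ref[2, ]
  refBg <- if (d1 < d2) ref[2, ] else ref[1, ]
  expect_lt(max(abs(refVeg - ours["vegetation", ])), 1)
  expect_lt(max(abs(refBg - ours["background", ])), 1)
})

test_that("the threshold is the green fraction of the vegetation centre", {
  mk <- function(veg, bg) new("ClusterModel",
    centers = matrix(c(veg, bg), 2, 3, byrow = TRUE,
                     dimnames = list(c("vegetation", "background"),
                                     c("R", "G", "B"))),
    fuzziness = 2, tol = 1e-4, iterations = 1, converged = TRUE)
  expect_equal(deriveThreshold(mk(c(50, 150, 50), c(100, 90, 80))), 0.60)
  expect_equal(deriveThreshold(mk(c(85, 85, 85), c(10, 10, 10))), 1 / 3)
  expect_warning(t0 <- deriveThreshold(mk(c(120, 0, 40), c(10, 5, 5))),
                 "zero green")
  expect_equal(t0, 0)
})

test_that("greenness binarisation matches a per-pixel loop oracle and its invariances", {
  expect_true(binarizeVegetation(uniformImage(1, 1, c(0, 255, 0)), 0.9)[1, 1])
  expect_false(binarizeVegetation(uniformImage(1, 1, c(100, 100, 100)), 0.4)[1, 1])

  set.seed(17)
  img <- array(sample.int(256, 15 * 12 * 3, replace = TRUE) - 1L, c(15, 12, 3))
  img[3, 4, ] <- 0L   # zero-sum pixel stays background
  mask <- binarizeVegetation(img, 0.42)
  oracle <- matrix(FALSE, 15, 12)
  for (r in 1:15) for (cc in 1:12) {
    s <- sum(img[r, cc, ])
    oracle[r, cc] <- s > 0 && img[r, cc, 2] / s > 0.42
  }
  expect_identical(mask, oracle)
  expect_false(mask[3, 4])

  ## scale invariance: doubling a pixel's channels keeps its class
  doubled <- img
  doubled[, , ] <- pmin(img * 2L, 10000L)  # pre-clipping scale, keep exact ratio
  expect_identical(binarizeVegetation(doubled, 0.42), mask)

  ## raising the threshold never turns black pixels white
  higher <- binarizeVegetation(img, 0.55)
  expect_true(all(mask | !higher))
})

test_that("orange-ROI segmentation counts exactly and matches a bound-check oracle", {
  img <- uniformImage(64, 64, c(120, 95, 70))
  for (ch in 1:3) img[11:20, 3:14, ch] <- c(240L, 120L, 30L)[ch]  # 120 px
  img[40:42, 40:40, 1] <- 245L; img[40:42, 40, 2] <- 125L; img[40:42, 40, 3] <- 35L
  res <- segmentOrangeROI(img)
  expect_equal(res$n, 123)

  hsv <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
                                  as.vector(img[, , 3])), maxColorValue = 255)
  oracle <- matrix(hsv[1, ] * 360 >= 15 & hsv[1, ] * 360 <= 40 &
                     hsv[2, ] >= 0.5 & hsv[3, ] >= 0.5, 64, 64)
  expect_identical(res$mask, oracle)

  expect_equal(segmentOrangeROI(uniformImage(8, 8, c(60, 140, 55)))$n, 0)
  expect_error(segmentOrangeROI(img, hue_range = c(40, 15)), "hue_range")
})

test_that("the largest-component filter keeps only the biggest orange blob", {
  img <- uniformImage(32, 32, c(120, 95, 70))
  for (ch in 1:3) {
    img[5:7, 5:7, ch] <- c(240L, 120L, 30L)[ch]    # 9 px blob
    img[20:21, 20:21, ch] <- c(240L, 120L, 30L)[ch] # 4 px blob
  }
  res <- segmentOrangeROI(img, largest_component = TRUE)
  expect_equal(res$n, 9)
})
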