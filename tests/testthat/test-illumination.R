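test_that("white-panel sampling matches a brute-force summation oracle", {
  img <- uniformImage(20, 30, c(200, 210, 190))
  s <- sampleWhitePanel(img, c(5, 5, 10, 8))
  expect_equal(hStat(s), 210)
  expect_equal(hStat(sampleWhitePanel(uniformImage(4, 4, c(255, 255, 255)),
                                      c(0, 0, 4, 4))), 255)

  set.seed(5)
  noisy <- array(sample.int(256, 20 * 30 * 3, replace = TRUE) - 1L, c(20, 30, 3))
  region <- c(3, 2, 7, 9)   # x, y, w, h (0-based)
  s2 <- sampleWhitePanel(noisy, region)
  manual <- numeric(3)
  for (ch in 1:3) {
    acc <- 0
    for (r in (region[2] + 1):(region[2] + region[4]))
      for (cc in (region[1] + 1):(region[1] + region[3]))
        acc <- acc + noisy[r, cc, ch]
    manual[ch] <- acc / (region[3] * region[4])
  }
  expect_equal(unname(channelMeans(s2)), manual)
  ## logical-mask regions agree with the rectangle form
  mask <- matrix(FALSE, 20, 30)
  mask[(region[2] + 1):(region[2] + region[4]),
       (region[1] + 1):(region[1] + region[3])] <- TRUE
  expect_equal(channelMeans(sampleWhitePanel(noisy, mask)), channelMeans(s2))

  expect_error(sampleWhitePanel(noisy, c(25, 0, 10, 5)), "outside")
  expect_error(sampleWhitePanel(noisy, matrix(FALSE, 20, 30)), "empty")
})

test_that("exposure updates take exactly the branch the band rule dictates", {
  st <- exposureState(2e4)
  up <- exposureUpdate(200, st)        # 200 < 0.90 * 255 = 229.5
  expect_equal(up$decision, "raised")
  expect_equal(exposureTimeUs(up$state), 2.4e4)

  dn <- exposureUpdate(255, exposureState(3.5e4))  # 255 > 0.98 * 255 = 249.9
  expect_equal(dn$decision, "lowered")
  expect_equal(exposureTimeUs(dn$state), 2.8e4)

  kp <- exposureUpdate(240, st)
  expect_equal(kp$decision, "kept")
  expect_equal(exposureTimeUs(kp$state), 2e4)

  ## strict monotonicity / idempotence across the H range
  for (H in seq(0, 255, by = 5)) {
    r <- exposureUpdate(H, st)
    if (r$decision == "raised") expect_gt(exposureTimeUs(r$state), 2e4)
    if (r$decision == "lowered") expect_lt(exposureTimeUs(r$state), 2e4)
    if (r$decision == "kept") {
      again <- exposureUpdate(H, r$state)
      expect_equal(exposureTimeUs(again$state), exposureTimeUs(r$state))
    }
  }
})

test_that("the control loop reaches the band for a linear unsaturated sensor", {
  k <- 240 / 3e4    # H(E) = k * E; band reachable by +-20% steps
  sensor <- function(E) array(k * E, c(4, 4, 3))
  out <- exposureControlLoop(sensor, c(0, 0, 4, 4), exposureState(1e4),
                             max_iter = 10)
  expect_true(out$converged)
  finalH <- out$trace$H[nrow(out$trace)]
  expect_gte(finalH, 229.5)
  expect_lt(finalH, 249.9)
  expect_equal(out$trace$decision[nrow(out$trace)], "kept")
})

test_that("a start inside the band performs zero updates", {
  sensor <- function(E) array(240, c(4, 4, 3))
  out <- exposureControlLoop(sensor, c(0, 0, 4, 4), exposureState(2e4))
  expect_true(out$converged)
  expect_equal(nrow(out$trace), 1)
  expect_equal(exposureTimeUs(out$state), 2e4)
})

test_that("a sensor whose +-20% steps straddle the band stops at max_iter unconverged", {
  ## independent oracle: simulate the greedy multiplicative recurrence
  h <- 286
  oracle <- h
  for (i in 1:3) {
    h <- if (h < 229.5) h * 1.2 else if (h > 249.9) h * 0.8 else h
    oracle <- c(oracle, h)
  }
  expect_true(all(oracle < 229.5 | oracle > 249.9))  # straddles for 4 captures

  k <- 286 / 2e4
  sensor <- function(E) array(k * E, c(4, 4, 3))
  out <- exposureControlLoop(sensor, c(0, 0, 4, 4), exposureState(2e4),
                             max_iter = 4)
  expect_false(out$converged)
  expect_equal(nrow(out$trace), 4)
  expect_equal(out$trace$H, oracle, tolerance = 1e-9)
})

test_that("exposure traces serialise to the documented CSV layout", {
  sensor <- function(E) array(240, c(4, 4, 3))
  out <- exposureControlLoop(sensor, c(0, 0, 4, 4), exposureState(2e4))
  path <- withr::local_tempfile(fileext = ".csv")
  writeExposureTrace(out$trace, path)
  expect_identical(readLines(path, n = 1), "iter,exposure_us,H,decision")
})

test_that("the vignetting pattern has the stated boundary values and symmetry", {
  P <- vignettingPattern(101, 101)
  v <- patternValues(P)
  expect_equal(v[51, 51], 0)
  expect_equal(c(v[1, 1], v[1, 101], v[101, 1], v[101, 101]), rep(1, 4))
  expect_equal(v[26, 26], 0.5)     # midpoint of centre and corner
  ## mirror symmetry about both axes for a centred pattern
  expect_equal(v, v[, 101:1])
  expect_equal(v, v[101:1, ])
  expect_error(vignettingPattern(0, 10), ">= 1")
  ## off-centre pattern still normalises to max 1 at the farthest corner
  off <- patternValues(vignettingPattern(50, 40, center = c(10, 10)))
  expect_equal(max(off), 1)
})

test_that("vignetting correction applies its gains exactly and leaves zero-gain channels untouched", {
  img <- uniformImage(3, 3, c(100, 80, 60))
  out <- vignettingCorrect(img, vignettingPattern(3, 3), vignettingGains())
  expect_equal(out[1, 1, 1], 130)          # corner: (1 + 0.3 * 1) * 100
  expect_equal(out[2, 2, 1], 100)          # centre: P = 0
  expect_identical(out[, , 2], img[, , 2])
  expect_identical(out[, , 3], img[, , 3])

  expect_error(vignettingCorrect(img, vignettingPattern(4, 4)), "dimensions")

  ## identity at zero gains; monotone non-decreasing otherwise
  expect_identical(as.vector(vignettingCorrect(img, vignettingPattern(3, 3),
                                               vignettingGains(0, 0, 0))),
                   as.vector(img))
  set.seed(9)
  rnd <- array(sample.int(200, 12 * 10 * 3, replace = TRUE), c(12, 10, 3))
  cor2 <- vignettingCorrect(rnd, vignettingPattern(10, 12),
                            vignettingGains(0.3, 0.1, 0.05))
  expect_true(all(cor2 >= rnd))
})

test_that("correction inverts the forward attenuation within one level where unclipped", {
  set.seed(31)
  truth <- array(sample.int(256, 40 * 60 * 3, replace = TRUE) - 1L, c(40, 60, 3))
  P <- patternValues(vignettingPattern(60, 40))
  attenuated <- truth
  attenuated[, , 1] <- agrocam:::roundHalfUp(truth[, , 1] / (1 + 0.3 * P))
  out <- vignettingCorrect(attenuated, vignettingPattern(60, 40),
                           vignettingGains())
  unclipped <- out[, , 1] < 255
  expect_lte(max(abs(out[, , 1][unclipped] - truth[, , 1][unclipped])), 1)
  expect_identical(out[, , 2], truth[, , 2])
})

test_that("clamping at saturation is counted", {
  img <- uniformImage(3, 3, c(250, 0, 0))
  out <- vignettingCorrect(img, vignettingPattern(3, 3), vignettingGains())
  expect_equal(max(out[, , 1]), 255)
  expect_gt(attr(out, "clamped"), 0)
})
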