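## Illumination control: exposure-time feedback against a white reference
## panel, and radial vignetting correction of the red attenuation a UV/IR
## cut filter produces toward the image corners.

#' Sample the white reference panel
#'
#' Computes per-channel means over a region of the image and the controller
#' statistic `H`, the largest of the three means.
#'
#' @param image integer array H x W x 3.
#' @param region either a numeric `c(x, y, w, h)` rectangle in pixel
#'   coordinates (0-based top-left origin) or a logical H x W mask of the
#'   pixels to sample.
#' @return a [PanelSample-class].
#' @export
sampleWhitePanel <- function(image, region) {
  d <- assertRGBImage(image)
  if (is.logical(region)) {
    assertMask(region, "region")
    if (!all(dim(region) == d[1:2]))
      stop("region mask dimensions must match the image", call. = FALSE)
    if (!any(region)) stop("region is empty", call. = FALSE)
    sel <- region
  } else {
    if (length(region) != 4)
      stop("region must be c(x, y, w, h) or a logical mask", call. = FALSE)
    x <- region[1]; y <- region[2]; w <- region[3]; h <- region[4]
    if (w < 1 || h < 1 || x < 0 || y < 0 || x + w > d[2] || y + h > d[1])
      stop("region is empty or outside the image", call. = FALSE)
    sel <- matrix(FALSE, d[1], d[2])
    sel[(y + 1):(y + h), (x + 1):(x + w)] <- TRUE
  }
  means <- vapply(1:3, function(ch) mean(image[, , ch][sel]), numeric(1))
  new("PanelSample", meanR = means[1], meanG = means[2], meanB = means[3],
      hStat = max(means))
}

#' One exposure-time update step
#'
#' Applies the multiplicative band rule: if `H < a*M` the exposure is raised
#' to `(1 + p) E_t`; if `H > b*M` it is lowered to `(1 - p) E_t`; otherwise
#' it is kept. Exactly one branch is taken.
#'
#' @param sample a [PanelSample-class], or directly the numeric statistic `H`.
#' @param state an [ExposureState-class].
#' @return list with `state` (updated [ExposureState-class]) and `decision`
#'   (`"raised"`, `"lowered"` or `"kept"`).
#' @examples
#' st <- exposureState(2e4)
#' exposureUpdate(200, st)$state  # raised to 2.4e4 us (200 < 0.90 * 255)
#' @export
exposureUpdate <- function(sample, state) {
  stopifnot(is(state, "ExposureState"))
  validObject(state)
  H <- if (is(sample, "PanelSample")) sample@hStat else as.numeric(sample)
  M <- state@maxLevel
  p <- state@adjustFrac
  if (H < state@lowerFrac * M) {
    decision <- "raised"
    et <- (1 + p) * state@exposureTimeUs
  } else if (H > state@upperFrac * M) {
    decision <- "lowered"
    et <- (1 - p) * state@exposureTimeUs
  } else {
    decision <- "kept"
    et <- state@exposureTimeUs
  }
  out <- state
  out@exposureTimeUs <- et
  list(state = out, decision = decision)
}

#' Closed-loop exposure-time control
#'
#' Repeatedly captures an image through the supplied sensor contract,
#' samples the white panel and updates the exposure until the statistic `H`
#' needs no update (the kept branch of [exposureUpdate()], i.e.
#' `a*M <= H <= b*M`) or `max_iter` captures have been made. Termination is
#' always guaranteed by `max_iter`; the full trace is returned for
#' diagnosis. Note the band rule keeps `H = b*M` although the target
#' interval is stated half-open; the update inequalities are applied
#' verbatim.
#'
#' @param sensor function mapping an exposure time in microseconds to an
#'   image (integer array H x W x 3); must be deterministic given `E_t`.
#' @param panel_region region passed to [sampleWhitePanel()].
#' @param state initial [ExposureState-class].
#' @param max_iter maximum number of captures (>= 1).
#' @return list with `state` (final exposure state), `converged` (logical),
#'   and `trace`, a data.frame with columns `iter`, `exposure_us`, `H`,
#'   `decision`.
#' @export
exposureControlLoop <- function(sensor, panel_region, state, max_iter = 10) {
  stopifnot(is.function(sensor), max_iter >= 1)
  trace <- data.frame(iter = integer(), exposure_us = numeric(),
                      H = numeric(), decision = character())
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    img <- sensor(state@exposureTimeUs)
    smp <- sampleWhitePanel(img, panel_region)
    upd <- exposureUpdate(smp, state)
    trace <- rbind(trace, data.frame(iter = i,
                                     exposure_us = state@exposureTimeUs,
                                     H = smp@hStat,
                                     decision = upd$decision))
    if (upd$decision == "kept") { converged <- TRUE; break }
    state <- upd$state
  }
  list(state = state, converged = converged, trace = trace)
}

#' Write an exposure trace as CSV
#'
#' @param trace the trace data.frame from [exposureControlLoop()].
#' @param path output CSV path.
#' @export
writeExposureTrace <- function(trace, path) {
  utils::write.csv(trace[c("iter", "exposure_us", "H", "decision")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Radial vignetting pattern
#'
#' Builds the gray pattern `P` used for vignetting correction: the distance
#' of each pixel centre from the pattern centre, normalised by the largest
#' corner distance, so `P` ranges over `[0, 1]`, is zero at the centre and
#' reaches one at the (most distant) corners; with the default centred
#' pattern all four corner pixels equal one.
#'
#' @param width,height pattern dimensions in pixels (>= 1); the pattern must
#'   be exactly the size of the image it corrects.
#' @param center optional `(c_x, c_y)` in continuous pixel coordinates;
#'   defaults to the image centre `(W/2, H/2)`.
#' @return a [VignettingPattern-class].
#' @examples
#' P <- vignettingPattern(101, 101)
#' patternValues(P)[51, 51]  # 0 at the centre
#' patternValues(P)[1, 1]    # 1 at a corner
#' @export
vignettingPattern <- function(width, height, center = NULL) {
  if (width < 1 || height < 1)
    stop("pattern dimensions must be >= 1", call. = FALSE)
  if (is.null(center)) center <- c(width / 2, height / 2)
  xs <- (seq_len(width) - 0.5) - center[1]
  ys <- (seq_len(height) - 0.5) - center[2]
  d <- sqrt(outer(ys^2, xs^2, `+`))
  cornX <- c(0.5, width - 0.5) - center[1]
  cornY <- c(0.5, height - 0.5) - center[2]
  dmax <- sqrt(max(outer(cornY^2, cornX^2, `+`)))
  if (dmax == 0) dmax <- 1
  new("VignettingPattern", values = d / dmax, center = as.numeric(center))
}

#' Apply multiplicative vignetting correction
#'
#' Corrects each channel pixel-by-pixel as
#' `channel_c = (1 + K * P) * channel`, rounding half-up and clamping to
#' `[0, max_level]`. With the default gains only the red channel changes;
#' channels with a zero gain are returned bit-identical. The number of
#' pixels clamped at the saturation level is attached as attribute
#' `"clamped"`.
#'
#' @param image integer array H x W x 3.
#' @param pattern a [VignettingPattern-class] with the image's dimensions.
#' @param gains a [VignettingGains-class].
#' @param max_level clamp level (default 255).
#' @return corrected integer array with attribute `clamped`.
#' @export
vignettingCorrect <- function(image, pattern, gains = vignettingGains(),
                              max_level = 255) {
  d <- assertRGBImage(image)
  stopifnot(is(pattern, "VignettingPattern"), is(gains, "VignettingGains"))
  P <- pattern@values
  if (!all(dim(P) == d[1:2]))
    stop("pattern dimensions must equal the image dimensions", call. = FALSE)
  ks <- c(gains@kr, gains@kg, gains@kb)
  out <- image
  clamped <- 0L
  for (ch in 1:3) {
    if (ks[ch] == 0) next
    v <- roundHalfUp((1 + ks[ch] * P) * image[, , ch])
    clamped <- clamped + sum(v > max_level)
    out[, , ch] <- pmin(pmax(v, 0), max_level)
  }
  storage.mode(out) <- "integer"
  attr(out, "clamped") <- clamped
  out
}
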