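## Greenness segmentation through a fuzzy-clustering global threshold, and
## bright-orange cardboard extraction with pixel counting.

#' Sample RGB feature vectors from an image
#'
#' Draws `n_samples` pixels uniformly without replacement (every pixel
#' exactly once when `n_samples` equals the pixel count) and returns their
#' RGB triplets. Reproducible given `seed`.
#'
#' @param image integer array H x W x 3.
#' @param n_samples number of pixels, `2 <= n_samples <= H*W`.
#' @param seed integer seed.
#' @return `n_samples` x 3 numeric matrix with columns R, G, B.
#' @export
sampleFeatures <- function(image, n_samples = 2000, seed = 1) {
  d <- assertRGBImage(image)
  npx <- d[1] * d[2]
  if (n_samples < 2 || n_samples > npx)
    stop("n_samples must lie between 2 and the pixel count", call. = FALSE)
  idx <- withSeed(seed, sample.int(npx, n_samples))
  out <- cbind(R = as.vector(image[, , 1])[idx],
               G = as.vector(image[, , 2])[idx],
               B = as.vector(image[, , 3])[idx])
  storage.mode(out) <- "double"
  out
}

#' Fit a two-class fuzzy colour-cluster model
#'
#' Fuzzy C-means with k = 2 on RGB samples: memberships and centres are
#' updated iteratively until the largest centre movement falls below `tol`
#' or `max_iter` is reached. Centres are initialised deterministically from
#' the per-channel 25% and 75% sample quantiles. The centre with the larger
#' green chromatic coordinate g = G/(R+G+B) is labelled vegetation.
#'
#' @param samples n x 3 numeric matrix of RGB triplets (n >= 2, not all
#'   identical).
#' @param fuzziness fuzziness exponent m (default 2).
#' @param tol convergence tolerance on centre movement (default 1e-4).
#' @param max_iter iteration cap (default 300).
#' @return a [ClusterModel-class].
#' @examples
#' x <- rbind(matrix(rep(c(40, 120, 30), 50), ncol = 3, byrow = TRUE),
#'            matrix(rep(c(120, 90, 70), 50), ncol = 3, byrow = TRUE))
#' clusterCenters(fitFuzzyClusters(x))
#' @export
fitFuzzyClusters <- function(samples, fuzziness = 2, tol = 1e-4,
                             max_iter = 300) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3 || nrow(samples) < 2)
    stop("samples must be an n x 3 matrix with n >= 2", call. = FALSE)
  if (all(apply(samples, 2, function(col) max(col) == min(col))))
    stop("all samples are identical; clusters are undefined", call. = FALSE)
  m <- fuzziness
  C <- rbind(apply(samples, 2, stats::quantile, 0.25, names = FALSE),
             apply(samples, 2, stats::quantile, 0.75, names = FALSE))
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    d2 <- cbind(rowSums(sweep(samples, 2, C[1, ])^2),
                rowSums(sweep(samples, 2, C[2, ])^2)) + 1e-12
    u1 <- 1 / (1 + (d2[, 1] / d2[, 2])^(1 / (m - 1)))
    U <- cbind(u1, 1 - u1)^m
    Cn <- rbind(colSums(U[, 1] * samples) / sum(U[, 1]),
                colSums(U[, 2] * samples) / sum(U[, 2]))
    moved <- max(abs(Cn - C))
    C <- Cn
    if (moved < tol) { converged <- TRUE; break }
  }
  g <- C[, 2] / pmax(rowSums(C), 1e-12)
  ord <- order(g, decreasing = TRUE)
  C <- C[ord, , drop = FALSE]
  dimnames(C) <- list(c("vegetation", "background"), c("R", "G", "B"))
  new("ClusterModel", centers = C, fuzziness = m, tol = tol,
      iterations = as.numeric(it), converged = converged)
}

#' Derive the greenness threshold from a cluster model
#'
#' The global segmentation threshold is the percentage of the green spectral
#' component of the vegetation cluster centre with respect to the three:
#' `t = G_veg / (R_veg + G_veg + B_veg)`.
#'
#' @param model a [ClusterModel-class].
#' @return numeric threshold in `[0, 1)`; a degenerate vegetation centre
#'   with no green yields 0 with a warning.
#' @export
deriveThreshold <- function(model) {
  stopifnot(is(model, "ClusterModel"))
  veg <- model@centers["vegetation", ]
  s <- sum(veg)
  if (s <= 0) stop("vegetation centre sums to zero; threshold undefined",
                   call. = FALSE)
  t <- unname(veg["G"] / s)
  if (t == 0) warning("vegetation centre has zero green; threshold is 0")
  t
}

#' Binarise vegetation by green chromatic coordinate
#'
#' A pixel is classified vegetation (white) iff its green chromatic
#' coordinate `g = G / (R + G + B)` strictly exceeds the threshold; pixels
#' with `R + G + B = 0` are background.
#'
#' @param image integer array H x W x 3.
#' @param threshold numeric threshold in (0, 1), e.g. from
#'   [deriveThreshold()].
#' @return logical H x W mask (TRUE = vegetation).
#' @export
binarizeVegetation <- function(image, threshold) {
  d <- assertRGBImage(image)
  G <- matrix(image[, , 2], d[1], d[2])
  s <- matrix(image[, , 1] + image[, , 2] + image[, , 3], d[1], d[2])
  ifelse(s > 0, G / s, 0) > threshold
}

#' Full greenness segmentation of an image
#'
#' Convenience pipeline: sample features, fit the two-class fuzzy cluster
#' model, derive the global threshold and binarise.
#'
#' @inheritParams sampleFeatures
#' @return list with `mask` (logical matrix), `threshold` and `model`.
#' @export
segmentGreen <- function(image, n_samples = 2000, seed = 1) {
  feats <- sampleFeatures(image, n_samples = n_samples, seed = seed)
  model <- fitFuzzyClusters(feats)
  threshold <- deriveThreshold(model)
  list(mask = binarizeVegetation(image, threshold), threshold = threshold,
       model = model)
}

#' Segment the bright-orange cardboard ROI and count its pixels
#'
#' Keeps the pixels whose HSV coordinates fall in the bright-orange bounds
#' (hue interval in degrees, minimum saturation and value); every other
#' pixel is removed. The count of remaining pixels is the ROI's measured
#' pixel resolution `n`.
#'
#' @param image integer array H x W x 3.
#' @param hue_range length-2 hue interval in degrees (default `c(15, 40)`).
#' @param sat_min,val_min minimum saturation / value in `[0, 1]`
#'   (default 0.5).
#' @param largest_component keep only the largest 4-connected component
#'   (needs the EBImage package)?
#' @return list with `mask` (logical matrix) and `n` (pixel count).
#' @export
segmentOrangeROI <- function(image, hue_range = c(15, 40), sat_min = 0.5,
                             val_min = 0.5, largest_component = FALSE) {
  d <- assertRGBImage(image)
  if (length(hue_range) != 2 || hue_range[2] <= hue_range[1])
    stop("hue_range must be an increasing length-2 interval in degrees",
         call. = FALSE)
  hsv <- grDevices::rgb2hsv(rbind(as.vector(image[, , 1]),
                                  as.vector(image[, , 2]),
                                  as.vector(image[, , 3])), maxColorValue = 255)
  keep <- hsv[1, ] * 360 >= hue_range[1] & hsv[1, ] * 360 <= hue_range[2] &
    hsv[2, ] >= sat_min & hsv[3, ] >= val_min
  mask <- matrix(keep, d[1], d[2])
  if (largest_component && any(mask)) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("largest_component = TRUE requires the EBImage package",
           call. = FALSE)
    lab <- EBImage::bwlabel(t(mask) * 1)  # EBImage stores width x height
    lab <- t(EBImage::imageData(lab))
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  list(mask = mask, n = sum(mask))
}
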