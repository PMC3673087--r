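## Segmentation scoring with the percentage-of-correct-classification (PCC)
## index against ground-truth masks, with the bottom-two-thirds evaluation
## window used for row-crop imagery (the top third of the frame is out of
## the treated area).

#' Confusion counts between a predicted mask and ground truth
#'
#' @param mask,truth logical matrices of identical dimensions
#'   (TRUE = white).
#' @return a [ConfusionCounts-class] with true whites, true blacks, false
#'   whites and false blacks.
#' @export
confusionCounts <- function(mask, truth) {
  assertMask(mask); assertMask(truth, "truth")
  if (!all(dim(mask) == dim(truth)))
    stop("mask and truth dimensions differ", call. = FALSE)
  new("ConfusionCounts",
      tw = sum(mask & truth),
      tb = sum(!mask & !truth),
      fw = sum(mask & !truth),
      fb = sum(!mask & truth))
}

#' Percentage of correct classification
#'
#' `PCC = (TW + TB) / (TW + TB + FW + FB)`.
#'
#' @param counts a [ConfusionCounts-class], or a predicted mask (then
#'   `truth` must be given and counts are computed first).
#' @param truth optional ground-truth mask.
#' @return a [PccScore-class].
#' @examples
#' pccPercent(pcc(new("ConfusionCounts", tw = 3, tb = 3, fw = 2, fb = 2)))
#' @export
pcc <- function(counts, truth = NULL) {
  if (!is(counts, "ConfusionCounts")) counts <- confusionCounts(counts, truth)
  total <- counts@tw + counts@tb + counts@fw + counts@fb
  if (total <= 0) stop("no evaluated pixels; PCC undefined", call. = FALSE)
  v <- (counts@tw + counts@tb) / total
  new("PccScore", value = v, percent = v * 100)
}

#' Keep the bottom two thirds of an image or mask
#'
#' Removes the top third of the rows (`floor(H/3)` rows), the part of the
#' frame outside the treated area; the width is unchanged. Works on
#' matrices (masks) and H x W x 3 arrays.
#'
#' @param x matrix or 3-d array with at least 3 rows.
#' @return the cropped object, height `H - floor(H/3)`.
#' @export
cropBottomTwoThirds <- function(x) {
  d <- dim(x)
  H <- d[1]
  if (is.null(H) || H < 3)
    stop("input must have at least 3 rows", call. = FALSE)
  keep <- (floor(H / 3) + 1):H
  if (length(d) == 3) x[keep, , , drop = FALSE] else x[keep, , drop = FALSE]
}

#' Mean PCC over the 2 x 2 exposure/vignetting condition grid
#'
#' Scores a batch of image pairs (under-exposed capture and
#' exposure-adjusted capture of the same scene) under the four processing
#' conditions: with and without exposure adjustment crossed with and without
#' vignetting correction. Each condition image is segmented by the greenness
#' pipeline ([segmentGreen()]) and scored against the pair's ground truth
#' with [pcc()], optionally on the bottom two thirds only.
#'
#' With `crop_top_third = TRUE` (the default) the top third is removed
#' *before* segmentation, so the global threshold is learned from the same
#' below-horizon region the score is computed on; the top of the frame (sky,
#' far field) is outside the treated area and would otherwise contaminate
#' the two-class colour clustering.
#'
#' @param pairs list; each element a list with elements `under` and
#'   `adjusted`, both integer H x W x 3 arrays of the same scene.
#' @param truths list of logical ground-truth vegetation masks, one per
#'   pair.
#' @param gains [VignettingGains-class] used for the corrected conditions.
#' @param n_samples,seed segmentation sampling parameters; each image gets a
#'   deterministic seed derived from `seed` and its pair index.
#' @param crop_top_third segment and evaluate on the bottom two thirds only?
#' @return data.frame with columns `exposure_adjusted`,
#'   `vignetting_corrected` and `mean_pcc_percent` (four rows); the per-pair
#'   percent scores are attached as attribute `"per_pair"` (pairs x 4
#'   matrix).
#' @export
conditionGridReport <- function(pairs, truths, gains = vignettingGains(),
                                n_samples = 2000, seed = 1,
                                crop_top_third = TRUE) {
  if (!length(pairs)) stop("empty batch", call. = FALSE)
  if (length(truths) != length(pairs))
    stop("one ground truth per pair is required", call. = FALSE)
  conditions <- data.frame(
    exposure_adjusted = c(FALSE, FALSE, TRUE, TRUE),
    vignetting_corrected = c(FALSE, TRUE, FALSE, TRUE))
  scores <- matrix(NA_real_, length(pairs), 4)
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    truth <- truths[[i]]
    d <- dim(pr$under)
    pattern <- vignettingPattern(d[2], d[1])
    imgs <- list(pr$under,
                 vignettingCorrect(pr$under, pattern, gains),
                 pr$adjusted,
                 vignettingCorrect(pr$adjusted, pattern, gains))
    if (crop_top_third) {
      imgs <- lapply(imgs, cropBottomTwoThirds)
      truth <- cropBottomTwoThirds(truth)
    }
    for (k in 1:4) {
      segm <- segmentGreen(imgs[[k]], n_samples = n_samples,
                           seed = seed + 1000 * i)
      scores[i, k] <- pccPercent(pcc(segm$mask, truth))
    }
  }
  conditions$mean_pcc_percent <- colMeans(scores)
  attr(conditions, "per_pair") <- scores
  conditions
}

#' Write a condition-grid report
#'
#' CSV (columns `exposure_adjusted,vignetting_corrected,mean_pcc_percent`)
#' or JSON records.
#'
#' @param report data.frame from [conditionGridReport()].
#' @param path output path (`.csv` or `.json`).
#' @export
writeConditionGridReport <- function(report, path) {
  cols <- c("exposure_adjusted", "vignetting_corrected", "mean_pcc_percent")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(report[cols], path, digits = NA)
  } else {
    utils::write.csv(report[cols], path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
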