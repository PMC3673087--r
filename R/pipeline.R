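## Pipeline entry point shared by the `agrocam` command-line script: each
## subcommand is a thin composition of package functions that writes its
## declared artifacts. Identical config and seeds give identical outputs.

#' Run a pipeline subcommand
#'
#' Subcommands:
#' \describe{
#'   \item{`sweep`}{simulate the arrangement grid; writes a CSV arrangement
#'     table (`args$out`). Grids from `args$alphas`, `args$heights`,
#'     `args$distances` (numeric vectors), defaulting to the 5 x 5 x 5
#'     study grid.}
#'   \item{`render`}{render one synthetic frame; writes the image
#'     (`args$out`) and optional truth masks (`args$truth_veg`,
#'     `args$truth_roi`) plus metadata JSON (`args$meta`).}
#'   \item{`autoexpose`}{run the exposure loop on the configured synthetic
#'     scene; writes the trace CSV (`args$out`).}
#'   \item{`devignette`}{vignetting-correct an image file (`args$input` ->
#'     `args$out`).}
#'   \item{`segment-green`}{greenness segmentation of an image; writes the
#'     mask PNG (`args$out`) and a JSON report (`args$report`).}
#'   \item{`count-roi`}{orange-cardboard pixel count; writes JSON
#'     (`args$report`) and optional mask (`args$out`).}
#'   \item{`evaluate`}{PCC of a predicted mask against a truth mask
#'     (`args$pred`, `args$truth`); writes JSON (`args$report`).}
#'   \item{`table2-sim`}{the full 2 x 2 synthetic illumination experiment;
#'     writes the report CSV (`args$out`).}
#' }
#'
#' @param subcommand one of the names above.
#' @param args named list of subcommand arguments (paths, grids).
#' @param config configuration list from [loadConfig()].
#' @param seed integer seed for stochastic subcommands.
#' @return the subcommand's main result, invisibly.
#' @export
runPipeline <- function(subcommand, args = list(), config = loadConfig(),
                        seed = 1) {
  obj <- config$objects
  switch(subcommand,
    "sweep" = {
      table <- sweepArrangements(
        alphas = args$alphas %||% seq(10, 50, by = 10),
        heights = args$heights %||% seq(210, 230, by = 5),
        distances = args$distances %||% seq(3.0, 5.0, by = 0.5),
        intrinsics = obj$camera@intrinsics)
      if (!is.null(args$out)) writeArrangementTable(table, args$out)
      invisible(table)
    },
    "render" = {
      frame <- renderScene(obj$scene, obj$camera, obj$sensor,
                           exposure_us = args$exposure_us %||%
                             obj$sensor@fullScaleExposureUs)
      if (!is.null(args$out)) writeImageRGB(frameImage(frame), args$out)
      if (!is.null(args$truth_veg))
        writeMaskPNG(truthVegetation(frame), args$truth_veg)
      if (!is.null(args$truth_roi))
        writeMaskPNG(truthCardboard(frame), args$truth_roi)
      if (!is.null(args$meta))
        jsonlite::write_json(
          list(exposure_us = frame@metadata$exposure_us,
               pitch_alpha_deg = obj$camera@extrinsics@pitchAlphaDeg,
               height_h_cm = obj$camera@extrinsics@heightHCm,
               seed = seed),
          args$meta, auto_unbox = TRUE, digits = NA)
      invisible(frame)
    },
    "autoexpose" = {
      ss <- sceneSensor(obj$scene, obj$camera, obj$sensor)
      loop <- exposureControlLoop(ss$capture, ss$panel_region,
                                  obj$exposure_state,
                                  max_iter = config$exposure$max_iter)
      if (!is.null(args$out)) writeExposureTrace(loop$trace, args$out)
      invisible(loop)
    },
    "devignette" = {
      img <- readImageRGB(args$input)
      d <- dim(img)
      out <- vignettingCorrect(img, vignettingPattern(d[2], d[1]),
                               obj$gains)
      if (!is.null(args$out)) writeImageRGB(out, args$out)
      invisible(out)
    },
    "segment-green" = {
      img <- readImageRGB(args$input)
      segm <- segmentGreen(img, n_samples = config$segmentation$n_samples,
                           seed = seed)
      if (!is.null(args$out)) writeMaskPNG(segm$mask, args$out)
      if (!is.null(args$report))
        jsonlite::write_json(list(threshold = segm$threshold,
                                  n_pixels = sum(segm$mask)),
                             args$report, auto_unbox = TRUE, digits = NA)
      invisible(segm)
    },
    "count-roi" = {
      img <- readImageRGB(args$input)
      sg <- config$segmentation
      res <- segmentOrangeROI(img, hue_range = c(sg$hue_min, sg$hue_max),
                              sat_min = sg$sat_min, val_min = sg$val_min)
      if (!is.null(args$out)) writeMaskPNG(res$mask, args$out)
      if (!is.null(args$report))
        jsonlite::write_json(list(n_pixels = res$n), args$report,
                             auto_unbox = TRUE, digits = NA)
      invisible(res)
    },
    "evaluate" = {
      pred <- readMaskPNG(args$pred)
      truth <- readMaskPNG(args$truth)
      if (isTRUE(config$evaluation$crop_top_third)) {
        pred <- cropBottomTwoThirds(pred)
        truth <- cropBottomTwoThirds(truth)
      }
      score <- pcc(pred, truth)
      if (!is.null(args$report))
        jsonlite::write_json(list(pcc = pccValue(score),
                                  pcc_percent = pccPercent(score)),
                             args$report, auto_unbox = TRUE, digits = NA)
      invisible(score)
    },
    "table2-sim" = {
      sim <- simulateConditionGrid(
        n_pairs = args$n_pairs %||% 10, seed = seed,
        n_samples = config$segmentation$n_samples,
        max_iter = config$exposure$max_iter)
      if (!is.null(args$out)) writeConditionGridReport(sim$report, args$out)
      invisible(sim)
    },
    stop("unknown subcommand: ", subcommand, call. = FALSE)
  )
}
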