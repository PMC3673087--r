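#' Accessors for package classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("corners", function(object) standardGeneric("corners"))
#' @rdname accessors
#' @export
setMethod("corners", "QuadProjection", function(object) object@cornersPx)

#' @rdname accessors
#' @export
setGeneric("isClipped", function(object) standardGeneric("isClipped"))
#' @rdname accessors
#' @export
setMethod("isClipped", "QuadProjection", function(object) object@clipped)

#' @rdname accessors
#' @export
setGeneric("exposureTimeUs", function(object) standardGeneric("exposureTimeUs"))
#' @rdname accessors
#' @export
setMethod("exposureTimeUs", "ExposureState", function(object) object@exposureTimeUs)

#' @rdname accessors
#' @export
setGeneric("hStat", function(object) standardGeneric("hStat"))
#' @rdname accessors
#' @export
setMethod("hStat", "PanelSample", function(object) object@hStat)

#' @rdname accessors
#' @export
setGeneric("channelMeans", function(object) standardGeneric("channelMeans"))
#' @rdname accessors
#' @export
setMethod("channelMeans", "PanelSample", function(object)
  c(R = object@meanR, G = object@meanG, B = object@meanB))

#' @rdname accessors
#' @export
setGeneric("patternValues", function(object) standardGeneric("patternValues"))
#' @rdname accessors
#' @export
setMethod("patternValues", "VignettingPattern", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("clusterCenters", function(object) standardGeneric("clusterCenters"))
#' @rdname accessors
#' @export
setMethod("clusterCenters", "ClusterModel", function(object) object@centers)

#' @rdname accessors
#' @export
setGeneric("pccValue", function(object) standardGeneric("pccValue"))
#' @rdname accessors
#' @export
setMethod("pccValue", "PccScore", function(object) object@value)

#' @rdname accessors
#' @export
setGeneric("pccPercent", function(object) standardGeneric("pccPercent"))
#' @rdname accessors
#' @export
setMethod("pccPercent", "PccScore", function(object) object@percent)

#' @rdname accessors
#' @export
setGeneric("confusionTotals", function(object) standardGeneric("confusionTotals"))
#' @rdname accessors
#' @export
setMethod("confusionTotals", "ConfusionCounts", function(object)
  c(tw = object@tw, tb = object@tb, fw = object@fw, fb = object@fb))

#' @rdname accessors
#' @export
setGeneric("frameImage", function(object) standardGeneric("frameImage"))
#' @rdname accessors
#' @export
setMethod("frameImage", "RenderedFrame", function(object) object@image)

#' @rdname accessors
#' @export
setGeneric("truthVegetation", function(object) standardGeneric("truthVegetation"))
#' @rdname accessors
#' @export
setMethod("truthVegetation", "RenderedFrame", function(object) object@truthVegetation)

#' @rdname accessors
#' @export
setGeneric("truthCardboard", function(object) standardGeneric("truthCardboard"))
#' @rdname accessors
#' @export
setMethod("truthCardboard", "RenderedFrame", function(object) object@truthCardboard)

#' @rdname accessors
#' @export
setGeneric("truthPanelWhite", function(object) standardGeneric("truthPanelWhite"))
#' @rdname accessors
#' @export
setMethod("truthPanelWhite", "RenderedFrame", function(object) object@truthPanelWhite)

#' @rdname accessors
#' @export
setGeneric("frameMetadata", function(object) standardGeneric("frameMetadata"))
#' @rdname accessors
#' @export
setMethod("frameMetadata", "RenderedFrame", function(object) object@metadata)
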