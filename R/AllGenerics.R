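#' Accessors for image-analysis classes
#'
#' @param object an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("cmPerPixel", function(object) standardGeneric("cmPerPixel"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("maskGrid", function(object) standardGeneric("maskGrid"))

#' @rdname accessors
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @rdname accessors
#' @export
setGeneric("nObjects", function(object) standardGeneric("nObjects"))

#' @rdname accessors
#' @export
setGeneric("calibrationTable", function(object) standardGeneric("calibrationTable"))

#' @rdname accessors
#' @export
setMethod("cmPerPixel", "CalibratedImage", function(object) object@cmPerPixel)

#' @rdname accessors
#' @export
setMethod("imageId", "CalibratedImage", function(object) object@imageId)

#' @rdname accessors
#' @export
setMethod("maskGrid", "BinaryMask", function(object) object@grid)

#' @rdname accessors
#' @export
setMethod("labelMatrix", "LabeledObjects", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("nObjects", "LabeledObjects", function(object) object@count)

#' @rdname accessors
#' @export
setMethod("calibrationTable", "CalibrationMap", function(object) object@table)

setMethod("show", "CalibratedImage", function(object) {
  d <- dim(object@pixels)
  cat("CalibratedImage '", object@imageId, "': ", d[1], " x ", d[2],
      " px, ", signif(object@cmPerPixel, 4), " cm/px (",
      signif(d[2] * object@cmPerPixel, 4), " x ",
      signif(d[1] * object@cmPerPixel, 4), " cm)\n", sep = "")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask ", nrow(object@grid), " x ", ncol(object@grid), " px, ",
      sum(object@grid), " foreground px\n", sep = "")
})

setMethod("show", "LabeledObjects", function(object) {
  cat("LabeledObjects: ", object@count, " objects (connectivity ",
      object@connectivity, "), raster ", nrow(object@labels), " x ",
      ncol(object@labels), " px\n", sep = "")
})

setMethod("show", "CalibrationMap", function(object) {
  ok <- sum(object@table$calibratable)
  cat("CalibrationMap: ", nrow(object@table), " traits fitted on ",
      object@nPairs, " dual-state plants; ", ok,
      " pass the R^2 > ", object@r2Gate, " gate\n", sep = "")
})

setMethod("show", "PredictionModel", function(object) {
  cat("PredictionModel (", object@provenance, "): IDB[g] = ",
      signif(object@slope, 6), " * meanIW[cm] ",
      ifelse(object@intercept < 0, "- ", "+ "),
      signif(abs(object@intercept), 6),
      "; k = ", object@kLongest, " longest, domain meanIW > ",
      object@minMeanIW, " cm\n", sep = "")
})
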