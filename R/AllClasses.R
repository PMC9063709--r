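#' @import methods
NULL

#' CalibratedImage: an RGB raster with a metric scale
#'
#' An 8-bit RGB photograph together with its per-image calibration, the
#' length in centimetres of one (square) pixel edge.  All absolute
#' measurements downstream (lengths in cm, areas in cm^2) derive from this
#' single scale factor.
#'
#' @slot pixels numeric array of dimension rows x cols x 3, values in
#'   0..255 (8-bit levels stored as numerics).
#' @slot cmPerPixel positive numeric scalar, cm per pixel edge.
#' @slot imageId character scalar identifying the source photograph.
#'
#' @section Coordinates:
#' x is the column index, y the row index, origin at the top-left corner,
#' pixel centres at integer coordinates.
#'
#' @seealso [loadImage()], [extractBlueBand()], [segmentScene()]
#' @export
setClass("CalibratedImage",
  representation(pixels = "array", cmPerPixel = "numeric", imageId = "character"))

setValidity("CalibratedImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    return("pixels must be a rows x cols x 3 array (expected 3-channel image)")
  if (d[1] < 1L || d[2] < 1L) return("raster is empty")
  if (length(object@cmPerPixel) != 1L || !is.finite(object@cmPerPixel) ||
      object@cmPerPixel <= 0)
    return("cmPerPixel must be a single positive number")
  if (min(object@pixels) < 0 || max(object@pixels) > 255)
    return("pixel values must lie in 0..255")
  TRUE
})

#' BinaryMask: a foreground/background raster
#'
#' Logical raster with the same shape as its source image; `TRUE` marks
#' object (inflorescence) pixels.
#'
#' @slot grid logical matrix (rows x cols).
#' @seealso [binarize()], [applyEditMask()], [areaOpen()]
#' @export
setClass("BinaryMask", representation(grid = "matrix"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@grid)) return("grid must be a logical matrix")
  if (any(is.na(object@grid))) return("grid must not contain NA")
  TRUE
})

#' LabeledObjects: connected components of a mask
#'
#' Integer raster in which 0 is background and 1..K index the connected
#' objects.  Labels are assigned in raster-scan order of each component's
#' first pixel and are contiguous.
#'
#' @slot labels integer matrix (rows x cols), 0 = background.
#' @slot count integer scalar, the number K of objects.
#' @slot connectivity integer scalar, 4 or 8, the adjacency used.
#' @seealso [labelComponents()], [measureObjects()]
#' @export
setClass("LabeledObjects",
  representation(labels = "matrix", count = "integer", connectivity = "integer"))

setValidity("LabeledObjects", function(object) {
  if (!is.integer(object@labels)) return("labels must be an integer matrix")
  K <- object@count
  if (length(K) != 1L || K < 0L) return("count must be a single non-negative integer")
  lv <- object@labels[object@labels > 0L]
  if (K == 0L) {
    if (length(lv)) return("count is 0 but labels contains positive entries")
  } else if (!setequal(unique(lv), seq_len(K))) {
    return("labels must be contiguous 1..K")
  }
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  TRUE
})

#' CalibrationMap: per-trait fresh/dry linear transforms
#'
#' Ordinary-least-squares trendlines of dry trait values on fresh trait
#' values, fitted on plants imaged in both states.  A trait is usable
#' ("calibratable") only when its trendline R-squared exceeds the gate
#' (0.9 by default); others are retained but flagged.
#'
#' @slot table data.frame with columns `trait`, `slope`, `intercept`,
#'   `r_squared`, `calibratable`.
#' @slot nPairs integer, number of dual-state plants the fit used.
#' @slot r2Gate numeric, the R-squared acceptance gate.
#' @seealso [fitFreshDryCalibration()], [applyCalibration()]
#' @export
setClass("CalibrationMap",
  representation(table = "data.frame", nPairs = "integer", r2Gate = "numeric"))

setValidity("CalibrationMap", function(object) {
  need <- c("trait", "slope", "intercept", "r_squared", "calibratable")
  if (!all(need %in% names(object@table)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (object@nPairs < 3L) return("nPairs must be at least 3")
  TRUE
})

#' PredictionModel: width-based yield predictor
#'
#' Linear model predicting a plant's inflorescence dry biomass (grams)
#' from the mean width of its longest inflorescences:
#' IDB = intercept + slope * meanIW.
#'
#' The shipped study coefficients (slope 59.14 g/cm, intercept -134.97 g,
#' k = 20 longest, fit domain mean IW > 2.5 cm) were estimated under one
#' specific cultivation environment and are expected to lose accuracy under
#' other conditions; refit on local data where possible.
#'
#' @slot slope numeric, grams per cm of mean width.
#' @slot intercept numeric, grams.
#' @slot kLongest integer, how many longest inflorescences to average.
#' @slot minMeanIW numeric, cm; predictions below this are outside the
#'   fitted domain and trigger a warning.
#' @slot provenance character, `"paper_default"` or `"refitted"`.
#' @seealso [predictIdb()], [refitPrediction()], [defaultPredictionModel()]
#' @export
setClass("PredictionModel",
  representation(slope = "numeric", intercept = "numeric", kLongest = "integer",
                 minMeanIW = "numeric", provenance = "character"))

setValidity("PredictionModel", function(object) {
  if (object@kLongest < 1L) return("kLongest must be >= 1")
  if (!object@provenance %in% c("paper_default", "refitted"))
    return("provenance must be 'paper_default' or 'refitted'")
  TRUE
})
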