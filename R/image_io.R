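## Raster and table I/O, scale calibration, montage construction.

.readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: '", ext, "' (expected png/tiff/jpeg)"))
  img
}

## EXIF orientation codes 1..8 applied to a rows x cols x k array
.applyOrientation <- function(a, orientation) {
  flipH <- function(a) a[, ncol(a):1, , drop = FALSE]
  flipV <- function(a) a[nrow(a):1, , , drop = FALSE]
  rot90cw <- function(a) aperm(flipV(a), c(2, 1, 3))
  switch(orientation,
    a,                       # 1: as stored
    flipH(a),                # 2
    flipV(flipH(a)),         # 3: 180
    flipV(a),                # 4
    aperm(a, c(2, 1, 3)),    # 5: transpose
    rot90cw(a),              # 6: 90 CW
    flipH(rot90cw(a)),       # 7
    rot90cw(rot90cw(rot90cw(a))))  # 8: 90 CCW
}

#' Load a calibrated RGB image
#'
#' Reads an 8-bit RGB photograph (PNG, TIFF or JPEG) and attaches its
#' metric calibration: the length in cm of one pixel edge, determined
#' externally for each photograph (e.g. from a scale embedded in the
#' scene).  Pixels are assumed square, so one scale serves both axes.
#'
#' @param path file path of the image.
#' @param cm_per_pixel positive number, cm per pixel edge.
#' @param image_id identifier for the image; defaults to the file name.
#' @param orientation EXIF orientation code 1-8 to apply before any
#'   measurement (default 1, i.e. as stored).  PNG and TIFF files carry no
#'   EXIF metadata, so the code must be supplied by the caller when the
#'   source camera recorded one.
#' @return a [CalibratedImage-class].
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(48), c(4, 4, 3)), f)
#' img <- loadImage(f, cm_per_pixel = 0.05)
#' cmPerPixel(img)
#' @export
loadImage <- function(path, cm_per_pixel, image_id = basename(path),
                      orientation = 1L) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (!is.numeric(cm_per_pixel) || length(cm_per_pixel) != 1L ||
      !is.finite(cm_per_pixel) || cm_per_pixel <= 0)
    stop("cm_per_pixel must be a single positive number")
  if (!orientation %in% 1:8) stop("orientation must be an EXIF code 1..8")
  img <- .readRaster(path)
  if (length(dim(img)) == 2L)
    stop("expected 3-channel image, got a single-channel raster")
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(img)[3] != 3L)
    stop("expected 3-channel image, got ", dim(img)[3], " channels")
  img <- .applyOrientation(img, as.integer(orientation))
  px <- round(img * 255)
  storage.mode(px) <- "double"
  new("CalibratedImage", pixels = px, cmPerPixel = cm_per_pixel,
      imageId = image_id)
}

#' Construct a BinaryMask from a logical matrix
#' @param grid logical matrix, `TRUE` = object.
#' @return a [BinaryMask-class].
#' @export
BinaryMask <- function(grid) {
  storage.mode(grid) <- "logical"
  new("BinaryMask", grid = grid)
}

#' Read / write binary masks as single-channel PNG
#'
#' Masks use the convention 0 = background, 255 = object.
#'
#' @param path file path (PNG).
#' @param mask a [BinaryMask-class].
#' @return `readMask` returns a [BinaryMask-class]; `writeMask` returns
#'   `path` invisibly.
#' @export
readMask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  BinaryMask(img >= 0.5)
}

#' @rdname readMask
#' @export
writeMask <- function(mask, path) {
  stopifnot(is(mask, "BinaryMask"))
  png::writePNG(ifelse(mask@grid, 1, 0), path)
  invisible(path)
}

#' Write / read a label raster as PNG
#'
#' Labels are stored losslessly at 16-bit precision across two 8-bit PNG
#' channels (label = 256*R + G; B unused), supporting up to 65535 objects
#' per scene.
#'
#' @param labels a [LabeledObjects-class].
#' @param path file path (PNG).
#' @param connectivity adjacency recorded in the restored object.
#' @return `readLabels` returns a [LabeledObjects-class].
#' @export
writeLabels <- function(labels, path) {
  stopifnot(is(labels, "LabeledObjects"))
  if (labels@count > 65535L) stop("more than 65535 objects cannot be stored")
  L <- labels@labels
  a <- array(0, c(nrow(L), ncol(L), 3))
  a[, , 1] <- (L %/% 256L) / 255
  a[, , 2] <- (L %% 256L) / 255
  png::writePNG(a, path)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path, connectivity = 8L) {
  a <- png::readPNG(path)
  if (length(dim(a)) != 3L) stop("not a label raster written by writeLabels")
  lab <- matrix(as.integer(round(a[, , 1] * 255) * 256L + round(a[, , 2] * 255)),
                dim(a)[1], dim(a)[2])
  new("LabeledObjects", labels = lab, count = max(0L, max(lab)),
      connectivity = as.integer(connectivity))
}

#' Combine an automatic mask with manual edit masks
#'
#' Manual clean-up of a segmentation (removal of tags, scale remnants or
#' shading picked up as foreground; re-addition of missed object pixels)
#' is expressed as mask algebra: the result is
#' `(mask AND NOT remove) OR add`.
#'
#' @param mask,remove,add [BinaryMask-class] objects of identical shape.
#' @return a [BinaryMask-class].
#' @examples
#' m <- BinaryMask(matrix(TRUE, 2, 2))
#' r <- BinaryMask(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
#' sum(maskGrid(applyEditMask(m, remove = r)))
#' @export
applyEditMask <- function(mask, remove = NULL, add = NULL) {
  stopifnot(is(mask, "BinaryMask"))
  g <- mask@grid
  if (!is.null(remove)) {
    stopifnot(is(remove, "BinaryMask"))
    if (!identical(dim(remove@grid), dim(g)))
      stop("remove mask shape does not match")
    g <- g & !remove@grid
  }
  if (!is.null(add)) {
    stopifnot(is(add, "BinaryMask"))
    if (!identical(dim(add@grid), dim(g)))
      stop("add mask shape does not match")
    g <- g | add@grid
  }
  BinaryMask(g)
}

#' Build a size-sorted composite montage of segmented objects
#'
#' Tiles every object's bounding-box crop into one raster, ordered by
#' decreasing pixel count, left-to-right then top-to-bottom (ties keep
#' label order).  This reproduces, per plant, the "all inflorescences
#' ordered by size" overview image.
#'
#' @param objects a [LabeledObjects-class], or a list of 2-column pixel
#'   coordinate matrices (columns x, y).
#' @param pad padding in pixels around each tile.
#' @param ncol_tiles number of tiles per row; default chooses a near-square
#'   layout.
#' @return a logical matrix montage (TRUE = object pixel) with attribute
#'   `"order"` giving the tile order as indices into the input.
#' @export
buildComposite <- function(objects, pad = 2L, ncol_tiles = NULL) {
  pxsets <- if (is(objects, "LabeledObjects")) objectPixels(objects) else objects
  if (length(pxsets) == 0L) stop("no objects to compose")
  sizes <- vapply(pxsets, nrow, integer(1))
  ord <- order(-sizes)  # stable: ties keep input order
  w <- vapply(pxsets, function(p) diff(range(p[, 1])) + 1L, numeric(1))
  h <- vapply(pxsets, function(p) diff(range(p[, 2])) + 1L, numeric(1))
  cw <- as.integer(max(w) + 2 * pad)
  ch <- as.integer(max(h) + 2 * pad)
  K <- length(pxsets)
  if (is.null(ncol_tiles)) ncol_tiles <- max(1L, ceiling(sqrt(K)))
  nrow_tiles <- ceiling(K / ncol_tiles)
  out <- matrix(FALSE, nrow_tiles * ch, ncol_tiles * cw)
  for (i in seq_len(K)) {
    p <- pxsets[[ord[i]]]
    x <- p[, 1] - min(p[, 1])
    y <- p[, 2] - min(p[, 2])
    tr <- (i - 1L) %/% ncol_tiles
    tc <- (i - 1L) %% ncol_tiles
    out[cbind(tr * ch + y + pad + 1L, tc * cw + x + pad + 1L)] <- TRUE
  }
  attr(out, "order") <- ord
  out
}

#' Read a plant metadata table
#'
#' CSV with a header row, "." decimal separator, UTF-8.  Expected columns:
#' `plant_id`, `genotype_id`, `state` ("fresh" or "dry"), `IDB_g`, and
#' optionally `PH_cm`, `DTM_d`.
#'
#' @param path CSV file path.
#' @return a data.frame.
#' @export
readPlantMeta <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("plant_id", "genotype_id", "state")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("plants table missing columns: ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$state), c("fresh", "dry"))
  if (length(bad)) stop("state must be 'fresh' or 'dry', got: ", paste(bad, collapse = ", "))
  df
}
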