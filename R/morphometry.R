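## Per-object morphometrics: moments, best-fit-ellipse axes, convex hull
## geometry, and conversion to absolute (cm) units.

#' Central moments of a planar point set
#'
#' Zeroth- and second-order moments about the centroid:
#' \eqn{u_{pq} = \sum_i (x_i - \bar x)^p (y_i - \bar y)^q}.
#'
#' @param points 2-column numeric matrix (x, y).
#' @return list with `u00` (point count), centroid `xbar`, `ybar`, and the
#'   central second moments `u20`, `u02`, `u11`.
#' @examples
#' centralMoments(cbind(c(0, 2), c(0, 0)))  # u20 = 2, u02 = u11 = 0
#' @export
centralMoments <- function(points) {
  points <- .asPointMatrix(points)
  if (nrow(points) < 1L) stop("point set is empty")
  xb <- mean(points[, 1]); yb <- mean(points[, 2])
  dx <- points[, 1] - xb; dy <- points[, 2] - yb
  list(u00 = nrow(points), xbar = xb, ybar = yb,
       u20 = sum(dx * dx), u02 = sum(dy * dy), u11 = sum(dx * dy))
}

.asPointMatrix <- function(points) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points) || ncol(points) != 2L)
    stop("points must be a 2-column matrix (x, y)")
  storage.mode(points) <- "double"
  points
}

#' Best-fit-ellipse axis lengths from central moments
#'
#' The object's length and width are the major and minor axis of the
#' ellipse whose second-order central moments match the object's:
#' \deqn{L = 2\sqrt{2}\,\sqrt{(u_{20}+u_{02}+\sqrt{(u_{20}-u_{02})^2+4u_{11}^2})/u_{00}}}
#' and the width replaces the inner + with a -.  For an ideal filled
#' ellipse with semi-axes a >= b these return exactly 2a and 2b.
#'
#' @param m moment set from [centralMoments()].
#' @return numeric vector `c(length, width)` in pixel units,
#'   length >= width >= 0.
#' @export
ellipseAxes <- function(m) {
  if (m$u00 <= 0) stop("u00 must be positive")
  s <- m$u20 + m$u02
  d <- sqrt((m$u20 - m$u02)^2 + 4 * m$u11^2)
  len <- 2 * sqrt(2) * sqrt((s + d) / m$u00)
  wid <- 2 * sqrt(2) * sqrt(pmax(s - d, 0) / m$u00)
  c(length = len, width = wid)
}

#' Boundary pixels of an object
#'
#' Object pixels with at least one background neighbour under 4-adjacency
#' (default); always a subset of the object.
#'
#' @param pixels 2-column integer matrix of object pixel coordinates (x, y).
#' @param connectivity 4 (default) or 8; the adjacency used to probe for
#'   background neighbours.
#' @return 2-column matrix of boundary pixel coordinates.
#' @export
boundaryPixels <- function(pixels, connectivity = 4L) {
  pixels <- .asPointMatrix(pixels)
  if (nrow(pixels) < 1L) stop("object is empty")
  span <- max(pixels[, 2]) - min(pixels[, 2]) + 3
  key <- function(x, y) x * span + y
  inside <- key(pixels[, 1], pixels[, 2])
  offs <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  isBoundary <- rep(FALSE, nrow(pixels))
  for (i in seq_len(nrow(offs))) {
    nk <- key(pixels[, 1] + offs[i, 1], pixels[, 2] + offs[i, 2])
    isBoundary <- isBoundary | !(nk %in% inside)
  }
  pixels[isBoundary, , drop = FALSE]
}

#' Convex hull by Andrew's monotone chain
#'
#' Builds the lower and upper hull chains over the points sorted
#' lexicographically by (x, y), keeping only strict turns so collinear
#' interior points are excluded.  Runs in O(n log n).
#'
#' @param points 2-column numeric matrix.
#' @return 2-column matrix of hull vertices in counter-clockwise order
#'   (in standard right-handed coordinates); 1- or 2-point inputs return
#'   the degenerate polygon as-is.
#' @export
convexHull <- function(points) {
  points <- .asPointMatrix(points)
  points <- unique(points)
  n <- nrow(points)
  if (n == 0L) stop("point set is empty")
  if (n <= 2L) return(points)
  o <- order(points[, 1], points[, 2])
  p <- points[o, , drop = FALSE]
  cross <- function(O, A, B)
    (A[1] - O[1]) * (B[2] - O[2]) - (A[2] - O[2]) * (B[1] - O[1])
  buildChain <- function(idx) {
    chain <- integer(0)
    for (i in idx) {
      while (length(chain) >= 2L &&
             cross(p[chain[length(chain) - 1L], ],
                   p[chain[length(chain)], ], p[i, ]) <= 0)
        chain <- chain[-length(chain)]
      chain <- c(chain, i)
    }
    chain
  }
  lower <- buildChain(seq_len(n))
  upper <- buildChain(rev(seq_len(n)))
  hull <- c(lower[-length(lower)], upper[-length(upper)])
  p[hull, , drop = FALSE]
}

#' Polygon area by the shoelace formula
#'
#' \eqn{A = \frac12 |\sum_i (x_i y_{i+1} - x_{i+1} y_i)|}; degenerate
#' polygons (fewer than 3 vertices) return 0.
#'
#' @param vertices 2-column matrix of polygon vertices in order.
#' @return area in squared input units.
#' @export
polygonArea <- function(vertices) {
  vertices <- .asPointMatrix(vertices)
  n <- nrow(vertices)
  if (n < 3L) return(0)
  x <- vertices[, 1]; y <- vertices[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Polygon perimeter
#'
#' Sum of consecutive vertex distances, closing the loop; a 2-vertex
#' "polygon" measures out-and-back (twice the segment length).
#'
#' @param vertices 2-column matrix of polygon vertices in order.
#' @return perimeter in input units.
#' @export
polygonPerimeter <- function(vertices) {
  vertices <- .asPointMatrix(vertices)
  n <- nrow(vertices)
  if (n < 2L) return(0)
  j <- c(2:n, 1L)
  sum(sqrt((vertices[j, 1] - vertices[, 1])^2 +
           (vertices[j, 2] - vertices[, 2])^2))
}

## Corner points of a pixel set: the 4 corners of every boundary pixel.
## The hull of these encloses the full area of every pixel, so the hull
## area provably dominates the pixel-count area.
.pixelCorners <- function(pixels) {
  b <- boundaryPixels(pixels, 4L)
  unique(rbind(cbind(b[, 1] - 0.5, b[, 2] - 0.5),
               cbind(b[, 1] + 0.5, b[, 2] - 0.5),
               cbind(b[, 1] - 0.5, b[, 2] + 0.5),
               cbind(b[, 1] + 0.5, b[, 2] + 0.5)))
}

#' Measure one segmented object in absolute units
#'
#' Computes the standard per-inflorescence record: size IS (pixel count
#' times cm^2 per pixel), best-fit-ellipse length IL and width IW, convex
#' hull area CH and hull perimeter HP, and shape ISH = IW/IL.
#'
#' @param pixels 2-column integer matrix of the object's pixel
#'   coordinates (x = column, y = row).
#' @param cm_per_pixel cm per pixel edge.
#' @param moment_source `"region"` (default): moments over all object
#'   pixels, for which the moment-ellipse constant is calibrated (exact
#'   axes on ideal filled ellipses); `"boundary"`: moments over boundary
#'   pixels only, retained for comparison (inflates a disk's axes by
#'   sqrt(2)).
#' @param hull_points `"corners"` (default): hull over the 4 corner points
#'   of each boundary pixel, guaranteeing CH >= IS; `"centers"`: hull over
#'   boundary pixel centres, for comparison with other software.
#' @param object_id identifier stored in the record.
#' @return one-row data.frame with columns `object_id`, `pixel_count`,
#'   `IS_cm2`, `IL_cm`, `IW_cm`, `CH_cm2`, `HP_cm`, `ISH`, `centroid_x_px`,
#'   `centroid_y_px`, `degenerate` (TRUE for single-pixel/collinear
#'   objects, whose ISH is NA and which are excluded from shape
#'   statistics).
#' @export
measureObject <- function(pixels, cm_per_pixel,
                          moment_source = c("region", "boundary"),
                          hull_points = c("corners", "centers"),
                          object_id = 1L) {
  moment_source <- match.arg(moment_source)
  hull_points <- match.arg(hull_points)
  if (cm_per_pixel <= 0) stop("cm_per_pixel must be positive")
  pixels <- .asPointMatrix(pixels)
  if (nrow(pixels) < 1L) stop("object is empty")
  n_a <- nrow(pixels)
  mpts <- if (moment_source == "region") pixels else boundaryPixels(pixels, 4L)
  m <- centralMoments(mpts)
  axes <- ellipseAxes(m)
  hpts <- if (hull_points == "corners") .pixelCorners(pixels)
          else boundaryPixels(pixels, 4L)
  hull <- convexHull(hpts)
  IL <- axes[["length"]] * cm_per_pixel
  IW <- axes[["width"]] * cm_per_pixel
  degenerate <- !(IL > 0 && IW > 0)
  data.frame(
    object_id = object_id,
    pixel_count = n_a,
    IS_cm2 = n_a * cm_per_pixel^2,
    IL_cm = IL,
    IW_cm = IW,
    CH_cm2 = polygonArea(hull) * cm_per_pixel^2,
    HP_cm = polygonPerimeter(hull) * cm_per_pixel,
    ISH = if (degenerate) NA_real_ else IW / IL,
    centroid_x_px = m$xbar,
    centroid_y_px = m$ybar,
    degenerate = degenerate)
}

#' Measure every object of a labeled scene
#'
#' @param labels a [LabeledObjects-class].
#' @param cm_per_pixel cm per pixel edge.
#' @param image_id identifier copied into every row.
#' @inheritParams measureObject
#' @return data.frame with one row per object (see [measureObject()]),
#'   prefixed by an `image_id` column.
#' @export
measureObjects <- function(labels, cm_per_pixel, image_id = "image",
                           moment_source = c("region", "boundary"),
                           hull_points = c("corners", "centers")) {
  moment_source <- match.arg(moment_source)
  hull_points <- match.arg(hull_points)
  pxsets <- objectPixels(labels)
  if (length(pxsets) == 0L) {
    out <- measureObject(cbind(1L, 1L), cm_per_pixel)[0, ]
    return(cbind(image_id = character(0), out))
  }
  rows <- lapply(seq_along(pxsets), function(i)
    measureObject(pxsets[[i]], cm_per_pixel, moment_source, hull_points,
                  object_id = i))
  cbind(image_id = image_id, do.call(rbind, rows))
}
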