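## Blue-band minimum-error thresholding, area opening, component labeling.

#' Extract the blue band of a calibrated RGB image
#'
#' Plant matter reflects little blue light while a typical contrasting
#' background is bright in the blue band, so the blue channel alone gives
#' a robust bimodal histogram for thresholding.  The channel is returned
#' unchanged (8-bit levels, no rescaling).
#'
#' @param image a [CalibratedImage-class].
#' @return numeric matrix of gray levels 0..255.
#' @export
extractBlueBand <- function(image) {
  stopifnot(is(image, "CalibratedImage"))
  image@pixels[, , 3]
}

#' Gray-level histogram of a raster
#'
#' @param gray numeric matrix with values 0..255.
#' @return integer vector of 256 counts for levels 0..255.
#' @export
grayHistogram <- function(gray) {
  v <- as.integer(round(gray))
  if (any(v < 0L | v > 255L)) stop("gray levels must lie in 0..255")
  tabulate(v + 1L, nbins = 256L)
}

#' Minimum-error threshold of a gray-level histogram
#'
#' Chooses the threshold T that minimises the two-Gaussian
#' minimum-classification-error criterion
#' \deqn{J(T) = 1 + 2[P_1 \ln\sigma_1 + P_2 \ln\sigma_2]
#'            - 2[P_1 \ln P_1 + P_2 \ln P_2]}
#' where class 1 collects levels \eqn{\le T} and class 2 levels \eqn{> T},
#' with class priors P, means and variances computed from the histogram.
#' The criterion approximates the Bayes-minimum-error boundary of a
#' two-Gaussian mixture fitted to the histogram.
#'
#' All 255 admissible splits are scanned exhaustively (exactness over the
#' classical iterative scheme).  A variance floor of 1/12 gray^2 — the
#' quantisation variance of one gray level — is applied to each class
#' variance before the logarithm so that single-spike classes remain
#' well-defined.
#'
#' @param hist integer vector of 256 gray-level counts (levels 0..255), as
#'   from [grayHistogram()].
#' @return integer threshold T in 0..254; attributes `"J"` (criterion
#'   trace, NA where a class is empty) are attached.
#' @examples
#' h <- integer(256); h[c(11, 201)] <- 500  # spikes at levels 10 and 200
#' minimumErrorThreshold(h)
#' @export
minimumErrorThreshold <- function(hist) {
  if (length(hist) != 256L || any(hist < 0))
    stop("hist must be 256 non-negative counts")
  total <- sum(hist)
  if (total <= 0) stop("degenerate histogram: no mass")
  if (sum(hist > 0) < 2L) stop("degenerate histogram: all mass in one bin")
  lev <- 0:255
  w <- hist / total
  c1 <- cumsum(w)                 # P1 at each T
  m1 <- cumsum(w * lev)           # first-moment partial sums
  s1 <- cumsum(w * lev^2)
  P1 <- c1[1:255]; P2 <- 1 - P1
  mu1 <- m1[1:255] / P1
  mu2 <- (m1[256] - m1[1:255]) / P2
  v1 <- pmax(s1[1:255] / P1 - mu1^2, 1 / 12)
  v2 <- pmax((s1[256] - s1[1:255]) / P2 - mu2^2, 1 / 12)
  J <- 1 + (P1 * log(v1) + P2 * log(v2)) - 2 * (P1 * log(P1) + P2 * log(P2))
  J[P1 <= 0 | P2 <= 0] <- NA_real_
  T <- which.min(J) - 1L
  structure(T, J = J)
}

#' Binarize a gray raster at a threshold
#'
#' @param gray numeric matrix of gray levels.
#' @param T threshold level in 0..255.
#' @param object_side `"below"` marks pixels <= T as object (default:
#'   plant matter is dark in the blue band); `"above"` marks pixels > T.
#' @return a [BinaryMask-class].
#' @export
binarize <- function(gray, T, object_side = c("below", "above")) {
  object_side <- match.arg(object_side)
  if (T < 0 || T > 255) stop("T must lie in 0..255")
  g <- if (object_side == "below") gray <= T else gray > T
  BinaryMask(g)
}

## Run-based union-find connected-component labeling.
## Returns an integer matrix; labels follow raster-scan order (row-major,
## origin top-left) of each component's first pixel.
.labelGrid <- function(grid, connectivity = 8L) {
  nr <- nrow(grid); nc <- ncol(grid)
  runs_row <- integer(0); runs_s <- integer(0); runs_e <- integer(0)
  for (r in seq_len(nr)) {
    v <- grid[r, ]
    d <- diff(c(FALSE, v, FALSE))
    s <- which(d == 1L); e <- which(d == -1L) - 1L
    if (length(s)) {
      runs_row <- c(runs_row, rep.int(r, length(s)))
      runs_s <- c(runs_s, s); runs_e <- c(runs_e, e)
    }
  }
  nRuns <- length(runs_s)
  if (nRuns == 0L)
    return(matrix(0L, nr, nc))
  parent <- seq_len(nRuns)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  slack <- if (connectivity == 8L) 1L else 0L
  row_first <- match(unique(runs_row), runs_row)
  names(row_first) <- unique(runs_row)
  idx_by_row <- split(seq_len(nRuns), runs_row)
  rows_present <- as.integer(names(idx_by_row))
  for (k in seq_along(rows_present)) {
    r <- rows_present[k]
    if (k == 1L || rows_present[k - 1L] != r - 1L) next
    cur <- idx_by_row[[k]]; prev <- idx_by_row[[k - 1L]]
    for (i in cur) {
      touching <- prev[runs_s[prev] <= runs_e[i] + slack &
                       runs_e[prev] >= runs_s[i] - slack]
      for (j in touching) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(nRuns), find, integer(1))
  ## relabel components 1..K by raster-scan order of the first pixel
  first_scan <- (runs_row - 1L) * nc + runs_s  # scan index of each run start
  comp_first <- tapply(first_scan, comp, min)
  ord <- order(comp_first)
  newlab <- integer(max(comp))
  newlab[as.integer(names(comp_first))[ord]] <- seq_along(ord)
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nRuns))
    lab[runs_row[i], runs_s[i]:runs_e[i]] <- newlab[comp[i]]
  lab
}

#' Label connected components of a binary mask
#'
#' @param mask a [BinaryMask-class].
#' @param connectivity 4 or 8 (default 8: diagonal pixels connect, so
#'   touching inflorescences merge unless separated by an edit mask).
#' @return a [LabeledObjects-class]; labels 1..K follow the raster-scan
#'   order of each component's first pixel.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is(mask, "BinaryMask"))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  lab <- .labelGrid(mask@grid, connectivity)
  new("LabeledObjects", labels = lab, count = max(0L, max(lab)),
      connectivity = connectivity)
}

#' Per-object pixel coordinate sets
#'
#' @param labels a [LabeledObjects-class].
#' @return list of K two-column integer matrices (columns `x`, `y`;
#'   x = column index, y = row index), in label order.
#' @export
objectPixels <- function(labels) {
  stopifnot(is(labels, "LabeledObjects"))
  L <- labels@labels
  idx <- which(L > 0L)
  if (!length(idx)) return(list())
  nr <- nrow(L)
  y <- (idx - 1L) %% nr + 1L
  x <- (idx - 1L) %/% nr + 1L
  lv <- L[idx]
  lapply(split(seq_along(idx), lv), function(i)
    cbind(x = x[i], y = y[i]))
}

#' Remove connected components below an absolute-area floor
#'
#' Morphological area opening: deletes every connected foreground
#' component whose pixel count is below `ceil(min_area_cm2 / p_l^2)`
#' (small debris, leaf specks), leaving all other pixels untouched.
#' Idempotent and anti-extensive.
#'
#' @param mask a [BinaryMask-class].
#' @param min_area_cm2 non-negative area floor in cm^2 (default 1, the
#'   standard debris cutoff for trimmed inflorescences).
#' @param cm_per_pixel cm per pixel edge.
#' @param connectivity 4 or 8.
#' @return a [BinaryMask-class].
#' @examples
#' # at 0.5 cm/px a 1 cm^2 floor is 4 px: 3-px blobs vanish, 4-px stay
#' @export
areaOpen <- function(mask, min_area_cm2 = 1, cm_per_pixel, connectivity = 8L) {
  stopifnot(is(mask, "BinaryMask"))
  if (cm_per_pixel <= 0) stop("cm_per_pixel must be positive")
  if (min_area_cm2 < 0) stop("min_area_cm2 must be non-negative")
  floor_px <- as.integer(ceiling(min_area_cm2 / cm_per_pixel^2))
  if (floor_px <= 1L) return(mask)
  lab <- .labelGrid(mask@grid, as.integer(connectivity))
  if (max(lab) == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- c(FALSE, sizes >= floor_px)[lab + 1L]
  BinaryMask(matrix(keep, nrow(lab), ncol(lab)))
}

#' Segment a calibrated scene into labeled inflorescence objects
#'
#' Full segmentation pipeline: blue band -> minimum-error threshold ->
#' binarize -> optional manual edit masks -> area opening -> connected
#' component labeling.
#'
#' @param image a [CalibratedImage-class].
#' @param min_area_cm2 area-opening floor in cm^2 (default 1).
#' @param connectivity 4 or 8 (default 8).
#' @param object_side which side of the threshold is object; default
#'   `"below"` (dark objects on a blue-bright background).
#' @param remove_mask,add_mask optional [BinaryMask-class] manual edits,
#'   applied between binarization and area opening.
#' @return a [LabeledObjects-class] with attribute `"threshold"` (the
#'   chosen T) and `"floor_px"` (the area floor in pixels).
#' @export
segmentScene <- function(image, min_area_cm2 = 1, connectivity = 8L,
                         object_side = c("below", "above"),
                         remove_mask = NULL, add_mask = NULL) {
  object_side <- match.arg(object_side)
  gray <- extractBlueBand(image)
  T <- minimumErrorThreshold(grayHistogram(gray))
  mask <- binarize(gray, T, object_side)
  mask <- applyEditMask(mask, remove = remove_mask, add = add_mask)
  mask <- areaOpen(mask, min_area_cm2, cmPerPixel(image), connectivity)
  out <- labelComponents(mask, connectivity)
  attr(out, "threshold") <- as.integer(T)
  attr(out, "floor_px") <- as.integer(ceiling(min_area_cm2 / cmPerPixel(image)^2))
  out
}
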