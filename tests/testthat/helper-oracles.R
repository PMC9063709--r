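## Independent brute-force oracles used to check the package's
## implementations.  Deliberately naive: none of them share code with
## the package internals.

## breadth-first flood-fill labeling; labels in raster-scan order of the
## first pixel of each component
floodLabel <- function(grid, connectivity = 8L) {
  nr <- nrow(grid); nc <- ncol(grid)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 4L)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  k <- 0L
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!grid[r, cc] || lab[r, cc] != 0L) next
    k <- k + 1L
    queue <- matrix(c(r, cc), 1)
    lab[r, cc] <- k
    while (nrow(queue)) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (i in seq_len(nrow(offs))) {
        rr <- cur[1] + offs[i, 1]; ccc <- cur[2] + offs[i, 2]
        if (rr >= 1 && rr <= nr && ccc >= 1 && ccc <= nc &&
            grid[rr, ccc] && lab[rr, ccc] == 0L) {
          lab[rr, ccc] <- k
          queue <- rbind(queue, c(rr, ccc))
        }
      }
    }
  }
  lab
}

## brute-force area opening: flood-label then delete small components
bruteAreaOpen <- function(grid, floor_px, connectivity = 8L) {
  lab <- floodLabel(grid, connectivity)
  if (max(lab) == 0L) return(grid)
  sizes <- tabulate(lab[lab > 0L])
  keep <- lab > 0L & sizes[pmax(lab, 1L)] >= floor_px
  keep & grid
}

## brute-force extreme-point test: p_i is a hull vertex iff some
## half-plane through it and one other point has all points on one side
## (strictly, up to ties at the two defining points).  O(n^3).
bruteHullVertices <- function(points) {
  points <- unique(points)
  n <- nrow(points)
  if (n <= 2L) return(points)
  isVert <- rep(FALSE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j == i) next
      ax <- points[j, 1] - points[i, 1]; ay <- points[j, 2] - points[i, 2]
      cr <- ax * (points[, 2] - points[i, 2]) -
            ay * (points[, 1] - points[i, 1])
      if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
        ## i-j is a supporting line; i is a vertex unless it lies strictly
        ## between two collinear points on that line
        on <- which(abs(cr) <= 1e-9)
        t <- (points[on, 1] - points[i, 1]) * ax +
             (points[on, 2] - points[i, 2]) * ay
        if (all(t >= -1e-9) || all(t <= 1e-9)) { isVert[i] <- TRUE; break }
      }
    }
  }
  points[isVert, , drop = FALSE]
}

## fan-triangulation polygon area (anchor at vertex 1)
fanArea <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(0)
  s <- 0
  for (i in 2:(n - 1L)) {
    s <- s + ((v[i, 1] - v[1, 1]) * (v[i + 1L, 2] - v[1, 2]) -
              (v[i + 1L, 1] - v[1, 1]) * (v[i, 2] - v[1, 2])) / 2
  }
  abs(s)
}

## digitize a filled rotated ellipse: pixel centers at integer coords
digitizeEllipse <- function(a_px, b_px, theta = 0, cx = 0, cy = 0) {
  r <- ceiling(max(a_px, b_px)) + 2
  g <- expand.grid(x = round(cx - r):round(cx + r),
                   y = round(cy - r):round(cy + r))
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a_px
  v <- (-dx * sin(theta) + dy * cos(theta)) / b_px
  as.matrix(g[u^2 + v^2 <= 1, ])
}

## equal-posterior boundary of a two-Gaussian mixture (Bayes threshold)
bayesBoundary <- function(p1, mu1, s1, mu2, s2) {
  f <- function(x) p1 * dnorm(x, mu1, s1) - (1 - p1) * dnorm(x, mu2, s2)
  uniroot(f, c(mu1, mu2))$root
}

## random logical mask with tunable fill
randomMask <- function(nr, nc, fill = 0.4) {
  matrix(runif(nr * nc) < fill, nr, nc)
}
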