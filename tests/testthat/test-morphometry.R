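test_that("central moments match hand enumeration", {
  m1 <- centralMoments(cbind(5, 7))
  expect_equal(m1$u00, 1)
  expect_equal(c(m1$xbar, m1$ybar), c(5, 7))
  expect_equal(c(m1$u20, m1$u02, m1$u11), c(0, 0, 0))

  m2 <- centralMoments(cbind(c(0, 2), c(0, 0)))
  expect_equal(c(m2$xbar, m2$ybar), c(1, 0))
  expect_equal(c(m2$u20, m2$u02, m2$u11), c(2, 0, 0))

  # 3x3 pixel block centered at (1,1): u20 = u02 = sum over {-1,0,1}^2 = 6
  blk <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  m3 <- centralMoments(blk)
  expect_equal(m3$u00, 9)
  expect_equal(c(m3$u20, m3$u02, m3$u11), c(6, 6, 0))
  expect_error(centralMoments(cbind(numeric(0), numeric(0))), "empty")
})

test_that("moment-ellipse axes are exact on closed forms and digitized shapes", {
  blk <- as.matrix(expand.grid(x = 0:2, y = 0:2))
  ax <- ellipseAxes(centralMoments(blk))
  expect_equal(unname(ax), rep(2 * sqrt(2) * sqrt(12 / 9), 2), tolerance = 1e-12)

  # filled disk R = 50 px: both axes within 2% of 100
  d <- digitizeEllipse(50, 50)
  axd <- ellipseAxes(centralMoments(d))
  expect_lt(abs(axd[["length"]] - 100) / 100, 0.02)
  expect_lt(abs(axd[["width"]] - 100) / 100, 0.02)

  # rotated filled ellipse a=60, b=25 at 30 degrees
  e <- digitizeEllipse(60, 25, pi / 6)
  axe <- ellipseAxes(centralMoments(e))
  expect_lt(abs(axe[["length"]] - 120) / 120, 0.02)
  expect_lt(abs(axe[["width"]] - 50) / 50, 0.02)

  # boundary-only moments inflate a disk by sqrt(2) (documented behavior)
  b <- boundaryPixels(d, 4L)
  axb <- ellipseAxes(centralMoments(b))
  expect_equal(axb[["length"]] / 100, sqrt(2), tolerance = 0.03)
})

test_that("axes are stable under rotation for adequately sampled ellipses", {
  lens <- sapply(seq(0, 170, by = 10), function(deg) {
    ax <- ellipseAxes(centralMoments(digitizeEllipse(40, 20, deg * pi / 180)))
    c(ax[["length"]], ax[["width"]])
  })
  expect_lt(diff(range(lens[1, ])) / 80, 0.02)
  expect_lt(diff(range(lens[2, ])) / 40, 0.02)
})

test_that("boundary pixels are the rim of the object", {
  expect_equal(nrow(boundaryPixels(cbind(4, 9))), 1)          # single pixel
  blk3 <- as.matrix(expand.grid(x = 1:3, y = 1:3))
  expect_equal(nrow(boundaryPixels(blk3)), 8)                 # interior excluded
  blk10 <- as.matrix(expand.grid(x = 1:10, y = 1:10))
  b10 <- boundaryPixels(blk10)
  expect_equal(nrow(b10), 36)                                 # 4*10 - 4 corners
  # boundary is a subset of the object
  expect_true(all(paste(b10[, 1], b10[, 2]) %in% paste(blk10[, 1], blk10[, 2])))
})

test_that("monotone-chain hull matches the brute-force extreme-point oracle", {
  tri <- cbind(c(0, 4, 1), c(0, 0, 3))
  expect_equal(nrow(convexHull(tri)), 3)

  sq <- cbind(c(0, 1, 1, 0, 0.5), c(0, 0, 1, 1, 0.5))  # corners + center
  h <- convexHull(sq)
  expect_equal(nrow(h), 4)
  expect_false(any(h[, 1] == 0.5))

  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:120, 1)
    pts <- cbind(runif(n), runif(n))
    got <- convexHull(pts)
    want <- bruteHullVertices(pts)
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
    # counter-clockwise orientation: signed shoelace sum is positive
    x <- got[, 1]; y <- got[, 2]; j <- c(2:nrow(got), 1)
    expect_gt(sum(x * y[j] - x[j] * y), 0)
  }
})

test_that("shoelace area and perimeter match closed forms and triangulation", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygonArea(sq), 1)
  expect_equal(polygonPerimeter(sq), 4)
  expect_equal(polygonArea(cbind(c(0, 4, 0), c(0, 0, 3))), 6)
  expect_equal(polygonPerimeter(cbind(c(0, 3), c(0, 4))), 10)  # out and back
  expect_equal(polygonArea(cbind(c(0, 1), c(0, 1))), 0)        # degenerate

  set.seed(23)
  for (i in 1:20) {
    pts <- cbind(rnorm(50), rnorm(50))
    h <- convexHull(pts)
    expect_equal(polygonArea(h), fanArea(h), tolerance = 1e-9)
    # isoperimetric inequality
    expect_gte(polygonPerimeter(h)^2 * (1 + 1e-6), 4 * pi * polygonArea(h))
  }
})

test_that("measureObject converts to absolute units with exact scaling laws", {
  d <- digitizeEllipse(30, 15, pi / 5, 40, 40)
  rec <- measureObject(d, cm_per_pixel = 0.05)
  expect_equal(rec$IS_cm2, nrow(d) * 0.05^2)
  expect_equal(rec$ISH, rec$IW_cm / rec$IL_cm)
  expect_gte(rec$CH_cm2, rec$IS_cm2)  # corner hull encloses all pixel area
  expect_gte(rec$HP_cm^2 * (1 + 1e-6), 4 * pi * rec$CH_cm2)
  expect_lte(rec$IW_cm, rec$IL_cm)

  # doubling the scale doubles lengths, quadruples areas, fixes shape
  rec2 <- measureObject(d, cm_per_pixel = 0.10)
  expect_equal(rec2$IL_cm, 2 * rec$IL_cm)
  expect_equal(rec2$IW_cm, 2 * rec$IW_cm)
  expect_equal(rec2$HP_cm, 2 * rec$HP_cm)
  expect_equal(rec2$IS_cm2, 4 * rec$IS_cm2)
  expect_equal(rec2$CH_cm2, 4 * rec$CH_cm2)
  expect_equal(rec2$ISH, rec$ISH)

  # single-pixel object: degenerate, ISH undefined
  one <- measureObject(cbind(3, 3), 0.05)
  expect_true(one$degenerate)
  expect_equal(one$IL_cm, 0)
  expect_true(is.na(one$ISH))
})

test_that("a generated 3 x 1.5 cm ellipse measures to its known axes", {
  p <- 0.025
  d <- digitizeEllipse(3 / p, 1.5 / p, pi / 7, 200, 200)
  rec <- measureObject(d, p)
  expect_lt(abs(rec$IL_cm - 6) / 6, 0.02)
  expect_lt(abs(rec$IW_cm - 3) / 3, 0.02)
  expect_lt(abs(rec$ISH - 0.5) / 0.5, 0.02)
})
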