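mkRecords <- function(IS, IL = IS, IW = IS / 2, ISH = IW / IL) {
  data.frame(object_id = seq_along(IS), pixel_count = round(IS * 400),
             IS_cm2 = IS, IL_cm = IL, IW_cm = IW,
             CH_cm2 = IS * 1.05, HP_cm = IL * 3,
             ISH = ISH, degenerate = FALSE)
}

test_that("plant summaries aggregate exactly", {
  rec <- mkRecords(c(2, 3, 5))
  s <- summarizePlant(rec, "p1", "g1", "dry", IDB_g = 100)
  expect_equal(s$IN, 3)
  expect_equal(s$TIC_cm2, 10)
  expect_equal(s$IS_cm2_mean, 10 / 3)
  expect_equal(s$IS_cm2_sd, sd(c(2, 3, 5)))  # n-1 denominator

  # single object: sd undefined
  s1 <- summarizePlant(mkRecords(4), "p2", "g1", "fresh")
  expect_true(is.na(s1$IS_cm2_sd))
  expect_error(summarizePlant(mkRecords(1)[0, ], "p", "g", "dry"),
               "at least one")

  # degenerate objects excluded from ISH only
  rec$degenerate[2] <- TRUE; rec$ISH[2] <- NA
  s2 <- summarizePlant(rec, "p3", "g1", "dry")
  expect_equal(s2$IN, 3)
  expect_equal(s2$ISH_mean, mean(rec$ISH[c(1, 3)]))
  expect_equal(s2$IS_cm2_mean, 10 / 3)  # size still uses all records

  # TIC additivity across batches
  sA <- summarizePlant(rec[1:2, ], "p", "g", "dry")
  sB <- summarizePlant(rec[3, , drop = FALSE], "p", "g", "dry")
  expect_identical(sA$TIC_cm2 + sB$TIC_cm2, s2$TIC_cm2)

  # mean/sd agree with a direct recomputation on many records
  set.seed(31)
  big <- mkRecords(rlnorm(300, 1, 0.6))
  sb <- summarizePlant(big, "p", "g", "dry")
  expect_equal(sb$IL_cm_mean, sum(big$IL_cm) / 300, tolerance = 1e-12)
  expect_equal(sb$IL_cm_sd,
               sqrt(sum((big$IL_cm - mean(big$IL_cm))^2) / 299),
               tolerance = 1e-12)
})

test_that("fresh/dry calibration recovers a known linear relation and gates on R^2", {
  set.seed(41)
  n <- 14
  fresh <- data.frame(plant_id = sprintf("p%02d", 1:n),
                      IW_cm_mean = runif(n, 2, 5))
  dry <- data.frame(plant_id = fresh$plant_id,
                    IW_cm_mean = 0.8 * fresh$IW_cm_mean - 0.1 +
                      rnorm(n, 0, 0.01))
  cal <- fitFreshDryCalibration(fresh, dry)
  tab <- calibrationTable(cal)
  expect_lt(abs(tab$slope[tab$trait == "IW_cm_mean"] - 0.8), 0.05)
  expect_true(tab$calibratable[tab$trait == "IW_cm_mean"])

  # exact identity: slope 1, intercept 0, R^2 = 1
  cal2 <- suppressWarnings(fitFreshDryCalibration(fresh, fresh))  # exact fit intended
  t2 <- calibrationTable(cal2)
  expect_equal(t2$slope, 1); expect_equal(t2$intercept, 0)
  expect_equal(t2$r_squared, 1)

  # independent noise: near-zero R^2, trait flagged
  dryN <- data.frame(plant_id = fresh$plant_id, IW_cm_mean = rnorm(n, 3, 1))
  calN <- fitFreshDryCalibration(fresh, dryN)
  expect_false(calibrationTable(calN)$calibratable)

  expect_error(fitFreshDryCalibration(fresh[1:2, ], dry[1:2, ]), "3 dual-state")
})

test_that("calibration maps values and round-trips through its inverse", {
  tab <- data.frame(trait = "IW_cm_mean", slope = 0.8, intercept = -0.1,
                    r_squared = 0.98, calibratable = TRUE)
  cal <- new("CalibrationMap", table = tab, nPairs = 14L, r2Gate = 0.9)
  s <- data.frame(plant_id = "p1", state = "fresh", IW_cm_mean = 4.0)
  out <- applyCalibration(s, cal, "fresh_to_dry")
  expect_equal(out$IW_cm_mean, 3.1)
  expect_equal(out$state, "dry")
  back <- applyCalibration(out, cal, "dry_to_fresh")
  expect_equal(back$IW_cm_mean, 4.0, tolerance = 1e-9)
  expect_equal(back$state, "fresh")

  # gate enforcement
  tab$calibratable <- FALSE
  calBad <- new("CalibrationMap", table = tab, nPairs = 14L, r2Gate = 0.9)
  expect_error(applyCalibration(s, calBad, "fresh_to_dry"), "not calibratable")
  # wrong state
  expect_error(applyCalibration(out, cal, "fresh_to_dry"), "state")
})

test_that("broad-sense heritability hits its exact edge cases", {
  # zero within-genotype variance, distinct means -> H2 = 1
  t1 <- data.frame(genotype_id = rep(c("a", "b", "c"), each = 3),
                   y = rep(c(1, 5, 9), each = 3))
  expect_equal(broadSenseHeritability(t1, "y")$H2, 1)

  # identical genotype means, positive within variance -> truncated to 0
  t2 <- data.frame(genotype_id = rep(c("a", "b"), each = 4),
                   y = rep(c(-1, 1, -1, 1), 2))
  expect_equal(broadSenseHeritability(t2, "y")$H2, 0)

  # affine invariance
  set.seed(51)
  t3 <- generateTraitPopulation(G = 40L, V_G = 0.3, V_E = 0.7, seed = 8)
  h <- broadSenseHeritability(t3, "value")
  t3$value <- 100 + 7 * t3$value
  expect_equal(broadSenseHeritability(t3, "value")$H2, h$H2, tolerance = 1e-12)

  # no replication anywhere is an error
  t4 <- data.frame(genotype_id = c("a", "b", "c"), y = 1:3)
  expect_error(broadSenseHeritability(t4, "y"), "replication")
})

test_that("heritability estimator recovers simulated variance components", {
  set.seed(61)
  est <- replicate(40, {
    pop <- generateTraitPopulation(G = 100L, clones = 4L, V_G = 0.4,
                                   V_E = 0.6, seed = sample.int(1e6, 1))
    broadSenseHeritability(pop, "value")$H2
  })
  expect_lt(abs(mean(est) - 0.4), 0.05)
})

test_that("correlation matrix blanks insignificant entries", {
  set.seed(71)
  n <- 60
  tab <- data.frame(x = rnorm(n))
  tab$y <- 2 * tab$x + 1                   # exact line
  tab$z <- rnorm(n)                        # independent
  cm <- correlationMatrix(tab, c("x", "y", "z"))
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r["x", "y"], 1)
  expect_true(isSymmetric(cm$r))
  expect_true(is.na(cm$r_signif["x", "z"]) || abs(cm$r["x", "z"]) > 0.25)

  # TIC-IDB style coupling gives near-unity significant correlation
  TIC <- rlnorm(n, 6, 0.5)
  IDB <- 0.1 * TIC * (1 + rnorm(n, 0, 0.04))
  tab2 <- data.frame(TIC = TIC, IDB = IDB)
  cm2 <- correlationMatrix(tab2, c("TIC", "IDB"))
  expect_gt(cm2$r_signif["TIC", "IDB"], 0.95)

  # constant trait: flagged undefined
  tab$c <- 5
  cm3 <- correlationMatrix(tab, c("x", "c"))
  expect_true(is.na(cm3$r["x", "c"]))
})
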