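test_that("biomass apportioning is proportional and conservative", {
  rec <- data.frame(object_id = 1:3, IS_cm2 = c(2, 3, 5))
  w <- apportionWeights(rec, IDB_g = 100)
  expect_equal(w$weight_g, c(20, 30, 50))
  expect_equal(attr(w, "density_g_cm2"), 10)

  one <- apportionWeights(data.frame(object_id = 1, IS_cm2 = 7), 42)
  expect_equal(one$weight_g, 42)

  set.seed(81)
  big <- data.frame(object_id = 1:300, IS_cm2 = rlnorm(300, 1, 0.7))
  wb <- apportionWeights(big, IDB_g = 123.4)
  expect_equal(sum(wb$weight_g), 123.4, tolerance = 1e-9)
  expect_true(all(wb$weight_g >= 0))

  expect_error(apportionWeights(big, NA), "missing")
  expect_error(apportionWeights(data.frame(object_id = 1, IS_cm2 = 0), 10),
               "TIC")
})

test_that("yield-threshold fractions match prefix-sum brute force", {
  expect_equal(yieldThresholdFraction(rep(1, 10), 0.5)$percent, 50)
  expect_equal(yieldThresholdFraction(c(9, 1), 0.75)$percent, 50)
  expect_equal(yieldThresholdFraction(c(9, 1), 1)$percent, 100)

  bruteFraction <- function(w, q) {
    sw <- sort(w, decreasing = TRUE)
    for (k in seq_along(sw)) if (sum(sw[1:k]) >= q * sum(w) - 1e-12) return(100 * k / length(w))
  }
  set.seed(91)
  for (i in 1:20) {
    w <- rlnorm(200, 0, 1)
    ks <- sapply(c(0.5, 0.75, 0.9), function(q) {
      got <- yieldThresholdFraction(w, q)$percent
      expect_equal(got, bruteFraction(w, q))
      got
    })
    expect_true(all(diff(ks) >= 0))  # monotone in q
  }
})

test_that("top-longest selection averages the right widths", {
  rec <- data.frame(object_id = 1:20, IL_cm = 20:1, IW_cm = 5.0)
  expect_equal(topLongestMeanWidth(rec, 20)$mean_IW, 5.0)

  # 25 records where the 20 longest have a constructed width mean
  rec25 <- data.frame(object_id = 1:25, IL_cm = c(rep(10, 20), rep(1, 5)),
                      IW_cm = c(rep(4.2, 20), rep(9, 5)))
  expect_equal(topLongestMeanWidth(rec25, 20)$mean_IW, 4.2)

  # k = N is the plain mean; k > N warns and uses all
  expect_equal(topLongestMeanWidth(rec, 20)$mean_IW, mean(rec$IW_cm))
  expect_warning(out <- topLongestMeanWidth(rec[1:5, ], 20), "using all")
  expect_equal(out$k_used, 5)

  # deterministic tie-break: equal lengths ranked by larger width then id
  tie <- data.frame(object_id = 1:3, IL_cm = c(7, 7, 7), IW_cm = c(1, 3, 2))
  expect_equal(topLongestMeanWidth(tie, 1)$records$object_id, 2)
})

test_that("prediction is affine with the published defaults", {
  m <- defaultPredictionModel()
  expect_equal(predictIdb(4.0, m) - predictIdb(3.0, m), 59.14)
  expect_equal(predictIdb(3.0, m), 42.45)
  flat <- new("PredictionModel", slope = 0, intercept = 7, kLongest = 20L,
              minMeanIW = 2.5, provenance = "refitted")
  expect_equal(predictIdb(10, flat), 7)
  expect_error(predictIdb(-1, m), "positive")
  expect_warning(predictIdb(2.0, m), "domain")
})

test_that("refitting recovers known coefficients and degenerates correctly", {
  set.seed(101)
  n <- 400
  IW <- runif(n, 2.6, 6)
  tab <- data.frame(mean_IW = IW, IDB_g = 60 * IW - 130 + rnorm(n, 0, 5))
  fit <- refitPrediction(tab)
  expect_lt(abs(fit$model@slope - 60), 2)
  expect_lt(abs(fit$model@intercept + 130), 8)
  expect_equal(fit$df, c(1, n - 2))
  expect_equal(fit$model@provenance, "refitted")

  # noiseless line: R^2 = 1
  tab2 <- data.frame(mean_IW = IW, IDB_g = 60 * IW - 130)
  expect_equal(suppressWarnings(refitPrediction(tab2))$r_squared, 1)

  # filter removing everything is an error
  expect_error(refitPrediction(tab, min_mean_IW = 100), "fewer than 3")
  # dry summaries are refused
  tab$state <- "dry"
  expect_error(refitPrediction(tab), "fresh")
})

test_that("subsampling simulation is seeded, bounded and narrows with m", {
  w <- c(4.5, 4.7, 5.0, 5.2, 5.5, 5.1, 4.9, 5.3, 5.6, 4.8,
         5.4, 5.0, 4.6, 5.2, 5.7, 4.95, 5.05, 5.15, 5.25, 5.35)
  # m = k reproduces the full mean in every round
  full <- samplingSimulation(w, m = 20L, rounds = 10L, seed = 3)
  expect_true(all(full$means == mean(w)))
  expect_equal(full$max_rel_dev, 0)

  # constant widths: zero dispersal for any m
  cst <- samplingSimulation(rep(5, 20), m = 5L, rounds = 10L, seed = 3)
  expect_equal(cst$max_rel_dev, 0)

  # m = 19: every round's mean is one of the 20 leave-one-out means
  loo <- sapply(1:20, function(i) mean(w[-i]))
  s19 <- samplingSimulation(w, m = 19L, rounds = 10L, seed = 7)
  expect_true(all(sapply(s19$means, function(m)
    any(abs(m - loo) < 1e-12))))

  # reproducibility
  a <- samplingSimulation(w, 5L, seed = 11)
  b <- samplingSimulation(w, 5L, seed = 11)
  expect_identical(a$means, b$means)
  expect_error(samplingSimulation(w, 21L), "1..k")

  # expected dispersal shrinks as the subsample grows (narrowing pattern)
  disp <- sapply(c(5L, 10L, 15L), function(m)
    mean(sapply(1:60, function(s)
      samplingSimulation(w, m, rounds = 10L, seed = s)$max_rel_dev)))
  expect_true(all(diff(disp) < 0))
})
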