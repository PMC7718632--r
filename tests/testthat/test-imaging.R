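# Segmentation, areas, volumes, volume-weight regression.

test_that("achromatic images contain no plant or flower pixels", {
  gray <- array(0.5, c(20, 20, 3))
  m <- segmentPixels(gray)
  expect_equal(sum(m$plant), 0)
  expect_equal(sum(m$flower), 0)
  expect_error(segmentPixels(matrix(0.5, 10, 10)), "RGB")
})

test_that("swapping the hue windows swaps the two classes", {
  # two-colour test card: left half green, right half yellow
  card <- array(0.5, c(10, 10, 3))
  cols <- phenomicStress:::plantColours()
  for (k in 1:3) {
    card[, 1:5, k] <- cols$plant[k]
    card[, 6:10, k] <- cols$flower[k]
  }
  thr <- segmentationThresholds()
  m1 <- segmentPixels(card, thr)
  swapped <- segmentationThresholds(greenHue = thr$yellowHue,
                                    yellowHue = thr$greenHue)
  m2 <- segmentPixels(card, swapped)
  expect_identical(m1$plant, m2$flower)
  expect_identical(m1$flower, m2$plant)
})

test_that("view area is pixel count times squared scale", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(viewArea(empty, 1), 0)
  mask <- matrix(FALSE, 20, 20); mask[1:10, 1:10] <- TRUE  # 100 px
  expect_equal(viewArea(mask, 0.5), 25)
  expect_equal(viewArea(mask, 1.0), 4 * viewArea(mask, 0.5))
  expect_error(viewArea(mask, 0), "mmPerPixel")
})

test_that("volume estimator obeys product form, annihilation and homogeneity", {
  expect_equal(plantVolume(10, 20, 30), 6000)
  expect_equal(plantVolume(0, 20, 30), 0)
  expect_equal(plantVolume(10, 0, 30), 0)
  # degree-3 homogeneity of the product estimator
  c0 <- 2.7
  expect_equal(plantVolume(10 * c0, 20 * c0, 30 * c0),
               c0^3 * plantVolume(10, 20, 30))
  # alternative estimators are monotone transforms of the product
  expect_equal(plantVolume(10, 20, 30, "geometric_mean"), 6000^(1/2))
  expect_equal(plantVolume(10, 20, 30, "cube_root"), 6000^(1/3))
  expect_error(plantVolume(-1, 2, 3), ">= 0")
})

test_that("volume-weight regression matches the closed-form OLS solution", {
  # perfectly linear data: r = 1
  fw <- seq(100, 500, length.out = 10)
  reg <- volumeVsWeightRegression(3 * fw + 7, fw)
  expect_equal(reg$r, 1)
  expect_equal(reg$slope, 3)
  expect_equal(reg$intercept, 7)
  # degenerate: constant weight is flagged, not fabricated
  regD <- volumeVsWeightRegression(rnorm(5), rep(2, 5))
  expect_true(regD$degenerate)
  expect_true(is.na(regD$r))
  # random 20-point set against the hand-written normal equations
  set.seed(99)
  x <- runif(20, 50, 800); y <- 2.5 * x + rnorm(20, 0, 40)
  reg2 <- volumeVsWeightRegression(y, x)
  n <- 20
  slopeOracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    (n * sum(x^2) - sum(x)^2)
  expect_equal(reg2$slope, slopeOracle, tolerance = 1e-12)
  expect_equal(reg2$intercept, mean(y) - slopeOracle * mean(x),
               tolerance = 1e-12)
})

test_that("image set areas respect the pixel scale", {
  d <- designSpec(genotypes = c("A", "B"), nBlocks = 1)
  cfg <- smallConfig(mmPerPixel = 0.5)
  pr <- genotypeProfiles(d, cfg)
  out <- renderPlantImages(d, pr, cfg, days = 7)
  ar <- imageSetAreas(out$images[[1]])
  expect_equal(ar$plantArea, ar$plantPx * 0.25)
  expect_equal(ar$flowerArea, ar$flowerPx * 0.25)
})
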