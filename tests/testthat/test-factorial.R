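# Factorial mixed-model ANOVA and derived temperature traits.

test_that("temperature differences and their identity", {
  td <- tempDifferences(30, 28, 29)
  expect_equal(unlist(td), c(T1 = 1, T2 = -1, T3 = 2))
  expect_equal(unlist(tempDifferences(20, 20, 20)), c(T1 = 0, T2 = 0, T3 = 0))
  set.seed(7)
  b <- rnorm(50, 25, 3); l <- rnorm(50, 24, 3); a <- rnorm(50, 23, 1)
  td2 <- tempDifferences(b, l, a)
  expect_equal(td2$T1 - td2$T2 - td2$T3, rep(0, 50))
})

test_that("residual df follows the fixed-rank convention", {
  expect_identical(residualDf(12, 3), 96L)   # full in-cabinet design
  expect_identical(residualDf(12, 2), 48L)   # two-block FW design
  # single factor with g levels and n replicates: n*g - g
  expect_identical(residualDf(5, 4, nHeat = 1, nDrought = 1), 15L)
  expect_error(residualDf(12, 3, nObs = 10), "rank exceeds")
})

# balanced factorial dataset with genotype/heat/drought effects,
# optional block effects, optional exactly-zero block contrasts
makeFactorial <- function(seed, g = 6, b = 3, blockSd = 1,
                          equalBlockSums = FALSE) {
  set.seed(seed)
  grid <- expand.grid(genotype = sprintf("G%d", seq_len(g)),
                      block = seq_len(b), heat = 0:1, drought = 0:1,
                      stringsAsFactors = FALSE)
  gEff <- rnorm(g, 0, 2)[match(grid$genotype, sprintf("G%d", seq_len(g)))]
  mu <- 50 + gEff + 3 * grid$heat - 2 * grid$drought
  if (equalBlockSums) {
    # each block receives a permutation of one residual vector: block
    # sums are identical, so the REML block variance lands exactly on
    # its zero boundary and the fit must equal the block-free OLS
    e1 <- rnorm(g * 4)
    perms <- list(seq_along(e1), c(seq_along(e1)[-1], 1), rev(seq_along(e1)))
    eps <- numeric(nrow(grid))
    for (bi in seq_len(b)) eps[grid$block == bi] <- e1[perms[[bi]]]
  } else {
    eps <- rnorm(nrow(grid)) + rnorm(b, 0, blockSd)[grid$block]
  }
  grid$value <- mu + eps
  grid$trait <- "y"; grid$dat <- 1
  grid
}

test_that("zero block variance reproduces the fixed-effects OLS ANOVA", {
  tab <- makeFactorial(31, equalBlockSums = TRUE)
  res <- fitFactorialLmm(tab, "y", 1)
  expect_equal(attr(res, "blockVar"), 0, tolerance = 1e-10)
  ols <- anova(lm(value ~ genotype * heat * drought,
                  transform(tab, heat = factor(heat),
                            drought = factor(drought))))
  expect_equal(res$F, ols$`F value`[-nrow(ols)], tolerance = 1e-8)
  expect_equal(attr(res, "residualDf"), ols$Df[nrow(ols)])
})

test_that("balanced designs give sequential = marginal mean squares", {
  # with balance, the Wald (marginal) mean squares must equal the
  # sequential ANOVA mean squares regardless of the block variance
  tab <- makeFactorial(32, blockSd = 3)
  res <- fitFactorialLmm(tab, "y", 1)
  ols <- anova(lm(value ~ genotype * heat * drought,
                  transform(tab, heat = factor(heat),
                            drought = factor(drought))))
  expect_equal(res$meanSq, ols$`Mean Sq`[-nrow(ols)], tolerance = 1e-6)
  # df bookkeeping: sum of term dfs + residual + intercept = N
  expect_equal(sum(res$df) + attr(res, "residualDf") + 1, nrow(tab))
})

test_that("the DAT0 covariate consumes exactly one residual df", {
  tab <- makeFactorial(33)
  base <- makeFactorial(34)[, c("genotype", "block", "heat", "drought", "value")]
  res0 <- fitFactorialLmm(tab, "y", 1)
  res1 <- fitFactorialLmm(tab, "y", 1, covariate = base)
  expect_equal(attr(res1, "residualDf"), attr(res0, "residualDf") - 1)
  expect_true("DAT0" %in% res1$term)
})

test_that("star codes follow the two-threshold convention", {
  expect_equal(phenomicStress:::starCode(c(0.005, 0.03, 0.2, NA)),
               c("**", "*", "", ""))
})

test_that("log transform validates positivity and names offenders", {
  tab <- makeFactorial(35)
  tab$value[c(3, 8)] <- -1
  expect_error(fitFactorialLmm(tab, "y", 1, transform = "log"),
               "offending rows")
})

test_that("heterogeneity screen selects multiplicative-noise traits", {
  set.seed(44)
  grid <- expand.grid(genotype = sprintf("G%d", 1:6), block = 1:3,
                      heat = 0:1, drought = 0:1, stringsAsFactors = FALSE)
  mu <- 20 * exp(0.8 * grid$heat + 0.5 * grid$drought)
  hom <- cbind(grid, dat = 1, trait = "hom",
               value = 10 + grid$heat + rnorm(nrow(grid), 0, 0.5))
  het <- cbind(grid, dat = 1, trait = "het",
               value = mu * exp(rnorm(nrow(grid), 0, 0.3)))
  tab <- rbind(hom, het)
  out <- heterogeneityTransform(tab, "auto")
  expect_true("het" %in% attr(out, "logTraits"))
  expect_false("hom" %in% attr(out, "logTraits"))
  # post-transform, the screen no longer rejects
  again <- heterogeneityTransform(out, "auto")
  expect_false("het" %in% attr(again, "logTraits"))
  # identity policy
  same <- heterogeneityTransform(tab, "none")
  expect_equal(same$value, tab$value)
  # explicit policy refuses non-positive values
  tab$value[1] <- 0
  expect_error(heterogeneityTransform(tab, "explicit", traits = "hom"),
               "non-positive")
})

test_that("ANOVA on seeded synthetic data finds the planted structure", {
  d <- designSpec()
  cfg <- simulationConfig(seed = 77)
  tt <- simulateTraitTable(d, genotypeProfiles(d, cfg), cfg)
  res <- fitFactorialLmm(deriveTemperatureTraits(tt), "T2", 7)
  # drought raises leaf temperature strongly by DAT7
  expect_lt(res$p[res$term == "D"], 0.01)
  expect_equal(attr(res, "residualDf"), 96)
})
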