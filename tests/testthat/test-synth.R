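# Synthetic-data generator: watering, trait tables, curves, outcomes.

test_that("watering update follows the replacement rule", {
  s <- potWaterState(4000)
  # full replacement is the identity
  s1 <- simulateWatering(s, 200, 1.0)
  expect_equal(waterContent(s1), 4000)
  expect_equal(swc(s1), 100)
  # zero loss leaves any state unchanged
  expect_equal(waterContent(simulateWatering(s, 0, 0.3)), 4000)
  # telescoping: 7 days at 50% replacement of a constant 200 g loss
  st <- potWaterState(4000)
  for (i in 1:7) st <- simulateWatering(st, 200, 0.5)
  expect_equal(waterContent(st), 4000 - 7 * 100)  # 3300
  expect_equal(swc(st), 82.5)
  # validation
  expect_error(simulateWatering(s, -5, 0.5), "dailyLoss")
  expect_error(simulateWatering(s, 100, 1.5), "fraction")
  # loss exceeding available water is clamped and flagged
  dry <- simulateWatering(potWaterState(4000, 50), 100, 0)
  expect_true(attr(dry, "clamped"))
  expect_gte(waterContent(dry), 0)
})

test_that("SWC is invariant under full replacement and declines under deficit", {
  cfg <- smallConfig()
  ww <- swcTrajectory(cfg, heat = 0, drought = 0)
  expect_true(all(ww$swc == 100))
  dr <- swcTrajectory(cfg, heat = 0, drought = 1)
  expect_true(all(diff(dr$swc) < 0))
  hd <- swcTrajectory(cfg, heat = 1, drought = 1)
  # heat dries faster, and the day-7 minima sit in the mid-30s to low-40s
  expect_true(all(hd$swc[-1] < dr$swc[-1]))
  expect_gt(dr$swc[8], 35); expect_lt(dr$swc[8], 50)
  expect_gt(hd$swc[8], 28); expect_lt(hd$swc[8], 42)
})

test_that("generator output is deterministic given the seed", {
  d <- smallDesign()
  cfg <- smallConfig(seed = 9)
  pr <- genotypeProfiles(d, cfg)
  expect_identical(pr, genotypeProfiles(d, cfg))
  expect_identical(simulateTraitTable(d, pr, cfg),
                   simulateTraitTable(d, pr, cfg))
  a1 <- simulateAciCurves(d, pr, cfg)
  a2 <- simulateAciCurves(d, pr, cfg)
  expect_identical(a1$truth, a2$truth)
  expect_identical(aValues(a1$curves[[5]]), aValues(a2$curves[[5]]))
  im1 <- renderPlantImages(d, pr, cfg, days = 7)
  im2 <- renderPlantImages(d, pr, cfg, days = 7)
  expect_identical(im1$images[[3]]@top, im2$images[[3]]@top)
  expect_identical(simulateOutcomes(d, pr, cfg),
                   simulateOutcomes(d, pr, cfg))
  # a different seed changes the data
  expect_false(identical(simulateTraitTable(d, pr, smallConfig(seed = 10)),
                         simulateTraitTable(d, pr, cfg)))
})

test_that("null configuration collapses to a constant per trait", {
  d <- smallDesign()
  cfg <- smallConfig(noiseSd = c(LC = 0, Tbud = 0, Tleaf = 0, Tambient = 0,
                                 PRI = 0, Qy = 0))
  pr <- genotypeProfiles(d, cfg)
  tt <- simulateTraitTable(d, pr, cfg, nullEffects = TRUE)
  spread <- tapply(tt$value, tt$trait, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("drought drives the seeded stomatal-conductance decline", {
  d <- designSpec()
  cfg <- simulationConfig(seed = 5)
  tt <- simulateTraitTable(d, genotypeProfiles(d, cfg), cfg)
  lc <- tt[tt$trait == "LC", ]
  m <- function(h, dr, day) mean(lc$value[lc$heat == h & lc$drought == dr &
                                            lc$dat == day])
  expect_lt(m(0, 1, 7), m(0, 1, 1))      # D declines over the week
  expect_lte(m(1, 1, 3), m(0, 1, 3))     # H+D at least as low as D at DAT3
  expect_lt(m(1, 1, 7), m(0, 1, 7))      # and clearly lower by DAT7
  # well-watered conductance is stable
  expect_gt(m(1, 0, 7), 0.85 * m(1, 0, 1))
})

test_that("simulated A/Ci curves carry their generating truth", {
  d <- smallDesign()
  cfg <- smallConfig(aciNoiseSd = 0)
  pr <- genotypeProfiles(d, cfg)
  sim <- simulateAciCurves(d, pr, cfg)
  expect_true(all(vapply(sim$curves, function(cv) length(ciValues(cv)),
                         numeric(1)) == 8))
  # noiseless round trip: the forward model on the stored truth
  # reproduces every curve exactly
  for (i in seq_along(sim$curves)) {
    tr <- sim$truth[i, ]
    p <- FvCBParameters(vcmax = tr$vcmax, j = tr$j, tpu = tr$tpu,
                        rd = tr$rd, temp = tr$leafTemp,
                        gammaStar = 42.75 * arrheniusFactor(37830, tr$leafTemp),
                        kc = 404.9 * arrheniusFactor(79430, tr$leafTemp),
                        ko = 278.4 * arrheniusFactor(36380, tr$leafTemp))
    dev <- max(abs(aValues(sim$curves[[i]]) - forwardAci(ciValues(sim$curves[[i]]), p)))
    expect_lt(dev, 1e-9)
  }
  # heat curves are generated at 35 C leaf temperature, controls at 23 C
  expect_setequal(unique(sim$truth$leafTemp[sim$truth$heat == 1]), 35)
  expect_setequal(unique(sim$truth$leafTemp[sim$truth$heat == 0]), 23)
})

test_that("heat more than doubles the true Vcmax at leaf temperature", {
  d <- designSpec()
  cfg <- simulationConfig(seed = 21)
  pr <- genotypeProfiles(d, cfg)
  ratios <- sapply(seq_len(nrow(pr)), function(i)
    vcmax(trueParametersAt(pr[i, ], 1, 0, 1, cfg)) /
      vcmax(trueParametersAt(pr[i, ], 0, 0, 1, cfg)))
  expect_true(all(ratios > 2))
  # independent Arrhenius arithmetic for the no-interaction genotype
  base <- exp(65330 / 8.314 * (1 / 296.15 - 1 / 308.15))
  expect_equal(median(ratios) / base, 1, tolerance = 0.15)
})

test_that("outcome calibration matches the configured treatment structure", {
  d <- designSpec()
  cfg <- simulationConfig(seed = 13)
  pr <- genotypeProfiles(d, cfg)
  oc <- simulateOutcomes(d, pr, cfg)
  fw <- function(h, dr) mean(oc$value[oc$trait == "FW" & oc$heat == h &
                                        oc$drought == dr])
  expect_equal(fw(0, 0), 427.9, tolerance = 0.08)
  expect_equal(1 - fw(0, 1) / fw(0, 0), 0.482, tolerance = 0.12)
  expect_equal(1 - fw(1, 1) / fw(0, 0), 0.694, tolerance = 0.08)
  sy <- function(h, dr) mean(oc$value[oc$trait == "SY" & oc$heat == h &
                                        oc$drought == dr])
  expect_equal(sy(0, 0), 3.0, tolerance = 0.1)
  expect_lt(sy(1, 0), sy(0, 0))
})

test_that("seeded yield-Vcmax correlation is exact in-sample", {
  d <- designSpec()
  for (seed in c(3, 14)) {
    cfg <- simulationConfig(seed = seed)
    pr <- genotypeProfiles(d, cfg)
    oc <- simulateOutcomes(d, pr, cfg)
    vTrue <- sapply(seq_len(nrow(pr)), function(i)
      vcmax(trueParametersAt(pr[i, ], 1, 0, 1, cfg)))
    syH <- oc$value[oc$trait == "SY" & oc$heat == 1 & oc$drought == 0]
    expect_equal(cor(syH, vTrue), 0.878, tolerance = 1e-10)
  }
  # null case: rho = 0 gives exactly zero in-sample correlation
  cfg0 <- simulationConfig(seed = 3, yieldVcmaxRho = 0)
  pr0 <- genotypeProfiles(d, cfg0)
  oc0 <- simulateOutcomes(d, pr0, cfg0)
  v0 <- sapply(seq_len(nrow(pr0)), function(i)
    vcmax(trueParametersAt(pr0[i, ], 1, 0, 1, cfg0)))
  sy0 <- oc0$value[oc0$trait == "SY" & oc0$heat == 1 & oc0$drought == 0]
  expect_lt(abs(cor(sy0, v0)), 1e-10)
  expect_error(simulateOutcomes(d, pr0, simulationConfig(yieldVcmaxRho = 1.2)))
})

test_that("rendered images have exact ground-truth pixel counts", {
  d <- designSpec(genotypes = c("G1", "G2", "G3"), nBlocks = 1)
  cfg <- smallConfig()
  pr <- genotypeProfiles(d, cfg)
  out <- renderPlantImages(d, pr, cfg, days = c(0, 7))
  for (i in seq_along(out$images)) {
    im <- out$images[[i]]
    tr <- out$truth[out$truth$plantId == im@plantId & out$truth$dat == im@dat, ]
    for (v in c("top", "side0", "side90")) {
      m <- segmentPixels(slot(im, v))
      expect_identical(sum(m$plant), as.integer(tr$plantPx[tr$view == v]))
      expect_identical(sum(m$flower), as.integer(tr$flowerPx[tr$view == v]))
    }
  }
  # zero biomass renders zero plant pixels
  empty <- phenomicStress:::renderView(80, 0, 0, "top")
  expect_equal(sum(empty$plantMask), 0)
  expect_equal(sum(empty$flowerMask), 0)
})
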