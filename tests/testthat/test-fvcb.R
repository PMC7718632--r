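# FvCB forward model: branch formulas, min rule, temperature scaling.

test_that("limitation branch formulas match direct arithmetic", {
  p <- FvCBParameters(vcmax = 100, j = 150, tpu = 9, rd = 1.5,
                      gammaStar = 42.75, kc = 404.9, ko = 278.4, o2 = 210)
  # hand-evaluated from the rate equations
  expect_equal(assimilationRubisco(400, p),
               100 * (400 - 42.75) / (400 + 404.9 * (1 + 210 / 278.4)) - 1.5)
  expect_equal(assimilationRubp(800, p),
               150 * (800 - 42.75) / (4 * 800 + 8 * 42.75) - 1.5)
  expect_equal(assimilationTpu(p), 3 * 9 - 1.5)  # 25.5
  # at the compensation point both carboxylation branches return -Rd
  expect_equal(assimilationRubisco(p@gammaStar, p), -1.5)
  expect_equal(assimilationRubp(p@gammaStar, p), -1.5)
  # linearity in Vcmax: doubling vcmax doubles Ac + Rd
  p2 <- FvCBParameters(vcmax = 200, j = 150, tpu = 9, rd = 1.5)
  expect_equal(assimilationRubisco(400, p2) + 1.5,
               2 * (assimilationRubisco(400, p) + 1.5))
  # RuBP asymptote: J/4 - Rd at saturating Ci
  expect_equal(assimilationRubp(1e9, p), 150 / 4 - 1.5, tolerance = 1e-6)
})

test_that("forward model equals the branch minimum and stays ordered", {
  set.seed(101)
  for (rep in 1:200) {
    p <- FvCBParameters(vcmax = runif(1, 30, 200), j = runif(1, 50, 300),
                        tpu = runif(1, 3, 20), rd = runif(1, 0, 4))
    ci <- sort(runif(8, 0, 1800))
    ci <- ci[!duplicated(round(ci, 6))]
    a <- forwardAci(ci, p)
    # oracle equality against the independent arithmetic implementation
    expect_equal(a, oracleForward(ci, p@vcmax, p@j, p@tpu, p@rd),
                 tolerance = 1e-12)
    # above the compensation point the model is the naive branch minimum
    hi <- ci >= p@gammaStar
    if (any(hi)) {
      naive <- pmin(assimilationRubisco(ci, p), assimilationRubp(ci, p),
                    assimilationTpu(p))
      expect_equal(a[hi], naive[hi], tolerance = 1e-12)
      expect_true(all(a[hi] <= assimilationRubisco(ci, p)[hi] + 1e-12))
      expect_true(all(a[hi] <= assimilationRubp(ci, p)[hi] + 1e-12))
      expect_true(all(a[hi] <= assimilationTpu(p) + 1e-12))
    }
    # limitation labels contiguous and ordered along ascending Ci
    ord <- c(rubisco = 1, rubp = 2, tpu = 3)[limitationStates(ci, p)]
    expect_true(all(diff(ord) >= 0))
  }
})

test_that("forward model reduces to the rubisco branch when it binds everywhere", {
  p <- FvCBParameters(vcmax = 20, j = 500, tpu = 50, rd = 1)
  ci <- ciSteps()
  expect_equal(forwardAci(ci, p), assimilationRubisco(ci, p))
  expect_true(all(limitationStates(ci, p) == "rubisco"))
})

test_that("temperature adjustment is Arrhenius with identity at 25 C", {
  p <- FvCBParameters()
  expect_equal(temperatureAdjust(p, 25)@vcmax, p@vcmax)
  expect_equal(temperatureAdjust(p, 25)@kc, p@kc)
  # hand-evaluated Arrhenius ratio for vcmax, Ha = 65330 J/mol
  ratio <- vcmax(temperatureAdjust(p, 35)) / vcmax(temperatureAdjust(p, 23))
  expect_equal(ratio, exp(65330 / 8.314 * (1 / 296.15 - 1 / 308.15)))
  expect_gt(ratio, 2)
  # monotone increasing on [15, 40]
  v <- sapply(seq(15, 40, by = 1), function(t) vcmax(temperatureAdjust(p, t)))
  expect_true(all(diff(v) > 0))
})

test_that("validity catches malformed parameters and curves", {
  expect_error(FvCBParameters(vcmax = -1), "vcmax")
  expect_error(FvCBParameters(gammaStar = 500, kc = 400), "gammaStar")
  expect_error(aciCurve(c(1, 2, 3, 4), c(1, 2, 3, 4)), "at least 5")
  expect_error(aciCurve(c(5, 4, 3, 2, 1), 1:5), "increasing")
  expect_error(aciCurve(1:5, c(1, 2, NA, 4, 5)), "finite")
})
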