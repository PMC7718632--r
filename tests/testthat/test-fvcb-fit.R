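# A/Ci fitting: exact recovery, degenerate regimes, oracle bounds.

test_that("noiseless self-generated curves are recovered exactly", {
  sets <- list(
    refParams(),                                        # split (5,2,1)
    FvCBParameters(vcmax = 90, j = 150, tpu = 9, rd = 1.2),
    FvCBParameters(vcmax = 60, j = 110, tpu = 7.5, rd = 0.8),
    FvCBParameters(vcmax = 100, j = 120, tpu = 12, rd = 1.0))
  for (p in sets) {
    cv <- refCurve(p)
    truthLab <- limitationStates(cv@ci, p)
    fit <- fitAci(cv)
    expect_lt(sse(fit), 1e-12)
    expect_equal(limitation(fit), truthLab)
    expect_equal(vcmax(fit), p@vcmax, tolerance = 1e-6)
    expect_equal(fit@params@rd, p@rd, tolerance = 1e-6)
    if (fit@jIdentifiable) expect_equal(etr(fit), p@j, tolerance = 1e-6)
    if (fit@tpuIdentifiable) expect_equal(tpu(fit), p@tpu, tolerance = 1e-6)
    expect_true(fit@consistent)
  }
})

test_that("an entirely RuBP-limited curve flags vcmax unidentifiable", {
  # huge vcmax: the rubp branch binds at every design point
  p <- FvCBParameters(vcmax = 2000, j = 100, tpu = NA, rd = 1)
  ci <- ciSteps()
  expect_true(all(limitationStates(ci, p) == "rubp"))
  fit <- fitAci(aciCurve(ci, forwardAci(ci, p)))
  expect_false(fit@vcmaxIdentifiable)
  expect_true(is.na(vcmax(fit)))
  expect_true(fit@jIdentifiable)
  expect_equal(etr(fit), 100, tolerance = 1e-6)
})

test_that("fit input validation works", {
  expect_error(fitAci(aciCurve(1:5, c(1, 2, Inf, 4, 5))), "finite")
  cv <- refCurve()
  expect_error(fitAci(cv, minSegment = c(rubisco = 9L, rubp = 2L, tpu = 0L)),
               "fewer points")
})

test_that("rd estimates outside bounds are clamped and flagged", {
  # curve from strongly negative respiration offset: data above the model
  p <- refParams()
  ci <- ciSteps()
  a <- forwardAci(ci, p) + 5    # looks like rd ~ -3.5
  fit <- fitAci(aciCurve(ci, a))
  expect_true(fit@rdClamped)
  expect_gte(fit@params@rd, 0)
})

test_that("fitAci never loses to the brute-force grid oracle", {
  set.seed(202)
  ci <- ciSteps()
  grid <- list(vcmax = seq(60, 140, by = 10), j = seq(100, 180, by = 10),
               tpu = seq(6, 14, by = 1), rd = c(0.5, 1.5, 2.5))
  for (rep in 1:20) {
    p <- FvCBParameters(vcmax = runif(1, 70, 130), j = runif(1, 110, 170),
                        tpu = runif(1, 7, 13), rd = runif(1, 0.5, 2.5))
    a <- forwardAci(ci, p) + rnorm(length(ci), 0, 0.5)
    cv <- aciCurve(ci, a)
    expect_lte(sse(fitAci(cv)), sse(bruteForceFit(cv, grid)) + 1e-9)
  }
  # a grid containing the exact truth reaches SSE 0 on a noiseless curve
  pTrue <- refParams()
  cvTrue <- refCurve(pTrue)
  gridTrue <- list(vcmax = c(80, 100, 120), j = c(120, 140, 160),
                   tpu = c(8, 10, 12), rd = c(1, 1.5, 2))
  bf <- bruteForceFit(cvTrue, gridTrue)
  expect_lt(sse(bf), 1e-18)
  # and fitAci picks the same limitation assignment as the oracle
  expect_equal(limitation(fitAci(cvTrue)), limitation(bf))
})

test_that("noisy recovery is accurate at the instrument noise level", {
  set.seed(303)
  p <- refParams()
  ci <- ciSteps()
  aTrue <- forwardAci(ci, p)
  errs <- replicate(60, {
    fit <- fitAci(aciCurve(ci, aTrue + rnorm(length(ci), 0, 0.5)))
    abs(vcmax(fit) - p@vcmax) / p@vcmax
  })
  expect_lt(median(errs), 0.05)
})
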