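# Shared fixtures: all built in code at test time.

# Instrument Ci program used throughout.
ciSteps <- function() c(0, 50, 75, 100, 150, 400, 800, 1600)

# A parameter set whose noiseless 8-point curve has >= 2 points in the
# rubisco and rubp regimes and a TPU point: split (5, 2, 1).
refParams <- function() FvCBParameters(vcmax = 100, j = 140, tpu = 10, rd = 1.5)

# Noiseless reference curve.
refCurve <- function(p = refParams(), ci = ciSteps(), leafTemp = p@temp) {
  aciCurve(ci, forwardAci(ci, p), curveId = "ref", leafTemp = leafTemp)
}

# Small factorial design for pipeline-level tests.
smallDesign <- function() {
  designSpec(genotypes = sprintf("G%02d", 1:6), nBlocks = 3,
             inCabinetDays = c(1, 7), imagingDays = c(0, 7),
             gasExchangeDays = c(1, 7))
}

smallConfig <- function(seed = 42, ...) {
  simulationConfig(seed = seed, imageSize = 100L, ...)
}

# Independent arithmetic evaluation of the FvCB forward model, written
# directly from the rate equations (gross-rate minimum, TPU cap); used
# as the oracle against forwardAci.
oracleForward <- function(ci, vcmax, j, tpu, rd, gammaStar = 42.75,
                          kc = 404.9, ko = 278.4, o2 = 210) {
  kmEff <- kc * (1 + o2 / ko)
  sapply(ci, function(c1) {
    wc <- vcmax * c1 / (c1 + kmEff)
    wj <- j * c1 / (4 * c1 + 8 * gammaStar)
    useC <- if (c1 == 0) vcmax / kmEff <= j / (8 * gammaStar) else wc <= wj
    ac <- vcmax * (c1 - gammaStar) / (c1 + kmEff) - rd
    aj <- j * (c1 - gammaStar) / (4 * c1 + 8 * gammaStar) - rd
    min(if (useC) ac else aj, 3 * tpu - rd)
  })
}
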