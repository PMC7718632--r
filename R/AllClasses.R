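#' @import methods
NULL

#' FvCB photosynthesis parameter set
#'
#' Holds the biochemical parameters of the Farquhar-von Caemmerer-Berry
#' (FvCB) model of C3 photosynthesis at a stated leaf temperature:
#' the maximum Rubisco carboxylation rate \code{vcmax}, the electron
#' transport rate \code{j} (the ETR of gas-exchange practice), the rate of
#' triose phosphate use \code{tpu}, day respiration \code{rd}, and the
#' Rubisco kinetic constants: the CO2 compensation point without day
#' respiration \code{gammaStar}, the Michaelis constants \code{kc} (CO2)
#' and \code{ko} (O2), and the O2 mole fraction \code{o2}.
#'
#' \code{j} and \code{tpu} may be \code{NA} to represent parameters that a
#' fit could not identify (for example a curve with no RuBP-regeneration
#' segment); all non-missing rates must be strictly positive.
#'
#' @slot vcmax maximum carboxylation rate, umol m-2 s-1
#' @slot j electron transport rate (ETR), umol m-2 s-1, or NA
#' @slot tpu triose phosphate use, umol m-2 s-1, or NA
#' @slot rd day respiration, umol m-2 s-1 (>= 0)
#' @slot gammaStar CO2 compensation point without Rd, umol mol-1
#' @slot kc Michaelis constant for CO2, umol mol-1
#' @slot ko Michaelis constant for O2, mmol mol-1
#' @slot o2 O2 mole fraction, mmol mol-1
#' @slot temp leaf temperature the parameters refer to, degrees C
#' @export
setClass("FvCBParameters",
  representation(
    vcmax = "numeric", j = "numeric", tpu = "numeric", rd = "numeric",
    gammaStar = "numeric", kc = "numeric", ko = "numeric",
    o2 = "numeric", temp = "numeric"
  ),
  prototype(
    vcmax = 100, j = 170, tpu = 12, rd = 1.5,
    gammaStar = 42.75, kc = 404.9, ko = 278.4, o2 = 210, temp = 25
  )
)

setValidity("FvCBParameters", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L
  if (!all(vapply(list(object@vcmax, object@j, object@tpu, object@rd,
                       object@gammaStar, object@kc, object@ko,
                       object@o2, object@temp), one, logical(1))))
    msg <- c(msg, "all slots must have length 1")
  else {
    if (!is.na(object@vcmax) && object@vcmax <= 0)
      msg <- c(msg, "vcmax must be > 0")
    if (!is.na(object@j) && object@j <= 0) msg <- c(msg, "j must be > 0")
    if (!is.na(object@tpu) && object@tpu <= 0) msg <- c(msg, "tpu must be > 0")
    if (is.na(object@rd) || object@rd < 0) msg <- c(msg, "rd must be >= 0")
    if (object@gammaStar <= 0 || object@kc <= 0 || object@ko <= 0 ||
        object@o2 <= 0)
      msg <- c(msg, "kinetic constants and o2 must be > 0")
    if (object@gammaStar >= object@kc)
      msg <- c(msg, "gammaStar must be smaller than kc")
    if (object@temp < 0 || object@temp > 50)
      msg <- c(msg, "temp must lie in [0, 50] degrees C")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an FvCB parameter set
#'
#' @param vcmax,j,tpu,rd rates in umol m-2 s-1 (\code{j}, \code{tpu} may be
#'   \code{NA} when unidentified)
#' @param gammaStar,kc,ko,o2 kinetic constants (defaults are standard
#'   tobacco-derived values at 25 degrees C)
#' @param temp leaf temperature, degrees C
#' @return an object of class \code{FvCBParameters}
#' @examples
#' p <- FvCBParameters(vcmax = 100, j = 170, tpu = 12, rd = 1.5)
#' vcmax(p)
#' @export
FvCBParameters <- function(vcmax = 100, j = 170, tpu = 12, rd = 1.5,
                           gammaStar = 42.75, kc = 404.9, ko = 278.4,
                           o2 = 210, temp = 25) {
  new("FvCBParameters", vcmax = as.numeric(vcmax), j = as.numeric(j),
      tpu = as.numeric(tpu), rd = as.numeric(rd),
      gammaStar = as.numeric(gammaStar), kc = as.numeric(kc),
      ko = as.numeric(ko), o2 = as.numeric(o2), temp = as.numeric(temp))
}

#' A/Ci gas-exchange curve
#'
#' One CO2-response curve: net assimilation \code{a} measured at an
#' ascending series of intercellular CO2 mole fractions \code{ci}, at a
#' stated leaf temperature.
#'
#' @slot curveId character identifier
#' @slot ci intercellular CO2, umol mol-1, strictly increasing, length >= 5
#' @slot a net assimilation, umol m-2 s-1, same length as \code{ci}
#' @slot leafTemp leaf temperature, degrees C, in [0, 50]
#' @slot o2 O2 mole fraction, mmol mol-1
#' @export
setClass("AciCurve",
  representation(curveId = "character", ci = "numeric", a = "numeric",
                 leafTemp = "numeric", o2 = "numeric"),
  prototype(curveId = "curve", ci = numeric(), a = numeric(),
            leafTemp = 25, o2 = 210)
)

setValidity("AciCurve", function(object) {
  msg <- character()
  if (length(object@ci) != length(object@a))
    msg <- c(msg, "ci and a must have equal length")
  if (length(object@ci) < 5L)
    msg <- c(msg, "a curve needs at least 5 points")
  if (any(!is.finite(object@ci)) || any(object@ci < 0))
    msg <- c(msg, "ci must be finite and >= 0")
  if (any(diff(object@ci) <= 0))
    msg <- c(msg, "ci must be strictly increasing")
  if (any(!is.finite(object@a)))
    msg <- c(msg, "a must be finite")
  if (length(object@leafTemp) != 1L || object@leafTemp < 0 ||
      object@leafTemp > 50)
    msg <- c(msg, "leafTemp must be a single value in [0, 50]")
  if (length(msg)) msg else TRUE
})

#' Construct an A/Ci curve
#'
#' @param ci ascending intercellular CO2 series, umol mol-1
#' @param a matching net assimilation series, umol m-2 s-1
#' @param curveId identifier
#' @param leafTemp leaf temperature, degrees C
#' @param o2 O2 mole fraction, mmol mol-1
#' @return an \code{AciCurve}
#' @export
aciCurve <- function(ci, a, curveId = "curve", leafTemp = 25, o2 = 210) {
  new("AciCurve", curveId = as.character(curveId), ci = as.numeric(ci),
      a = as.numeric(a), leafTemp = as.numeric(leafTemp),
      o2 = as.numeric(o2))
}

#' Result of fitting the FvCB model to an A/Ci curve
#'
#' @slot params fitted \code{FvCBParameters} at leaf temperature
#' @slot limitation per-point label in \code{{"rubisco","rubp","tpu"}},
#'   contiguous and ordered along ascending Ci
#' @slot sse residual sum of squares, (umol m-2 s-1)^2
#' @slot vcmaxIdentifiable,jIdentifiable,tpuIdentifiable segment-support flags
#' @slot nPerSegment named integer counts per segment
#' @slot rdClamped TRUE when the Rd estimate was clamped to its bounds
#' @slot consistent TRUE when the selected partition's fitted min-rule
#'   agrees with its limitation assignment at every point
#' @slot curveId identifier of the fitted curve
#' @export
setClass("AciFit",
  representation(params = "FvCBParameters", limitation = "character",
                 sse = "numeric", vcmaxIdentifiable = "logical",
                 jIdentifiable = "logical", tpuIdentifiable = "logical",
                 nPerSegment = "integer", rdClamped = "logical",
                 consistent = "logical", curveId = "character")
)

setValidity("AciFit", function(object) {
  msg <- character()
  lab <- object@limitation
  if (!all(lab %in% c("rubisco", "rubp", "tpu")))
    msg <- c(msg, "limitation labels must be rubisco/rubp/tpu")
  ord <- c(rubisco = 1L, rubp = 2L, tpu = 3L)[lab]
  if (length(lab) > 1L && any(diff(ord) < 0))
    msg <- c(msg, "limitation labels must be contiguous rubisco->rubp->tpu")
  if (length(object@sse) != 1L || is.na(object@sse) || object@sse < 0)
    msg <- c(msg, "sse must be a single value >= 0")
  if (length(msg)) msg else TRUE
})

#' Pot water state for deficit-irrigation simulation
#'
#' Water mass in a pot relative to its saturated capacity. Soil water
#' content (SWC, percent) is derived as \code{100 * water / capacity}, so
#' it is consistent with the stored state by construction.
#'
#' @slot capacity g of water at saturation
#' @slot water g of water currently held
#' @export
setClass("PotWaterState",
  representation(capacity = "numeric", water = "numeric"),
  prototype(capacity = 4000, water = 4000)
)

setValidity("PotWaterState", function(object) {
  msg <- character()
  if (length(object@capacity) != 1L || object@capacity <= 0)
    msg <- c(msg, "capacity must be a single value > 0")
  if (length(object@water) != 1L || object@water < 0 ||
      object@water > object@capacity + 1e-9)
    msg <- c(msg, "water must lie in [0, capacity]")
  if (length(msg)) msg else TRUE
})

#' Construct a pot water state
#'
#' @param capacity saturated water mass, g
#' @param water current water mass, g (defaults to saturation)
#' @return a \code{PotWaterState}
#' @export
potWaterState <- function(capacity = 4000, water = capacity) {
  new("PotWaterState", capacity = as.numeric(capacity),
      water = as.numeric(water))
}

#' Factorial experiment design
#'
#' The layout of a genotype x heat x drought factorial with randomized
#' complete blocks and per-trait-family measurement days (DAT, days after
#' treatment onset).
#'
#' @slot genotypes unique genotype identifiers
#' @slot heatLevels,droughtLevels factor level names (two each)
#' @slot nBlocks number of complete blocks
#' @slot inCabinetDays,imagingDays,gasExchangeDays DAT vectors per family
#' @export
setClass("DesignSpec",
  representation(genotypes = "character", heatLevels = "character",
                 droughtLevels = "character", nBlocks = "integer",
                 inCabinetDays = "numeric", imagingDays = "numeric",
                 gasExchangeDays = "numeric")
)

setValidity("DesignSpec", function(object) {
  msg <- character()
  if (anyDuplicated(object@genotypes))
    msg <- c(msg, "genotype identifiers must be unique")
  if (length(object@genotypes) < 2L)
    msg <- c(msg, "at least two genotypes are required")
  if (object@nBlocks < 1L) msg <- c(msg, "nBlocks must be >= 1")
  days <- c(object@inCabinetDays, object@imagingDays, object@gasExchangeDays)
  if (any(days < 0)) msg <- c(msg, "all measurement days must be >= 0")
  if (length(object@heatLevels) != 2L || length(object@droughtLevels) != 2L)
    msg <- c(msg, "heat and drought must each have two levels")
  if (length(msg)) msg else TRUE
})

#' Construct a factorial design
#'
#' Defaults reproduce the study layout this package emulates: 12 genotypes
#' x 2 heat levels x 2 drought levels x 3 blocks, with in-cabinet traits
#' scored at DAT 1/3/5/7, imaging at DAT 0/3/7 and gas exchange at
#' DAT 1/3/7.
#'
#' @param genotypes character vector of genotype ids
#' @param nBlocks number of complete blocks
#' @param inCabinetDays,imagingDays,gasExchangeDays measurement days
#' @return a \code{DesignSpec}
#' @examples
#' design <- designSpec()
#' nlevels(factor(design@genotypes))
#' @export
designSpec <- function(genotypes = sprintf("G%02d", 1:12), nBlocks = 3,
                       inCabinetDays = c(1, 3, 5, 7),
                       imagingDays = c(0, 3, 7),
                       gasExchangeDays = c(1, 3, 7)) {
  new("DesignSpec", genotypes = as.character(genotypes),
      heatLevels = c("normal", "high"),
      droughtLevels = c("well_watered", "stressed"),
      nBlocks = as.integer(nBlocks),
      inCabinetDays = as.numeric(inCabinetDays),
      imagingDays = as.numeric(imagingDays),
      gasExchangeDays = as.numeric(gasExchangeDays))
}

#' Simulation configuration
#'
#' All tunables of the synthetic-data generator. The defaults are the
#' study conditions the package emulates: 50 percent replacement of the
#' previous day's water loss in stressed pots (100 percent in well-watered
#' pots), A/Ci measurement noise 0.5 umol m-2 s-1, and a seeded genotypic
#' correlation of 0.878 between heat-stress Vcmax at DAT1 and seed yield.
#'
#' @slot seed integer RNG seed
#' @slot noiseSd named per-trait residual SDs, trait units
#' @slot aciNoiseSd gas-exchange noise SD, umol m-2 s-1
#' @slot gxhEffect,gxdEffect interaction effect-size multipliers (0 = null)
#' @slot yieldVcmaxRho target genotypic correlation between heat-stress
#'   Vcmax at DAT1 and seed yield
#' @slot wateringFractionStressed,wateringFractionWatered replacement
#'   fractions of the previous day's water loss
#' @slot mmPerPixel image scale, mm per pixel
#' @slot potCapacity pot water capacity, g
#' @slot dailyLoss named daily evapotranspiration, g, per temperature level
#' @slot blockSdFrac block-effect SD as a fraction of the trait noise SD
#' @slot imageSize raster side length, pixels
#' @slot imageNoiseSd,hueJitter optional pixel noise (0 disables; the
#'   default, so segmentation can be tested for exact recovery)
#' @slot calibration named list of trait-model calibration constants
#' @export
setClass("SimulationConfig",
  representation(seed = "integer", noiseSd = "numeric", aciNoiseSd = "numeric",
                 gxhEffect = "numeric", gxdEffect = "numeric",
                 yieldVcmaxRho = "numeric",
                 wateringFractionStressed = "numeric",
                 wateringFractionWatered = "numeric",
                 mmPerPixel = "numeric", potCapacity = "numeric",
                 dailyLoss = "numeric", blockSdFrac = "numeric",
                 imageSize = "integer", imageNoiseSd = "numeric",
                 hueJitter = "numeric", calibration = "list")
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (any(object@noiseSd < 0) || object@aciNoiseSd < 0)
    msg <- c(msg, "noise SDs must be >= 0")
  fr <- c(object@wateringFractionStressed, object@wateringFractionWatered)
  if (any(fr < 0 | fr > 1))
    msg <- c(msg, "watering fractions must lie in [0, 1]")
  if (abs(object@yieldVcmaxRho) > 1)
    msg <- c(msg, "|yieldVcmaxRho| must be <= 1")
  if (object@mmPerPixel <= 0) msg <- c(msg, "mmPerPixel must be > 0")
  if (object@potCapacity <= 0) msg <- c(msg, "potCapacity must be > 0")
  if (!all(c("normal", "high") %in% names(object@dailyLoss)))
    msg <- c(msg, "dailyLoss needs entries 'normal' and 'high'")
  if (any(object@dailyLoss < 0)) msg <- c(msg, "dailyLoss must be >= 0")
  if (object@imageNoiseSd < 0 || object@hueJitter < 0)
    msg <- c(msg, "image noise settings must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' See \code{\linkS4class{SimulationConfig}} for slot meaning. Trait noise
#' SDs default to values on the order of the residual variances typical of
#' this kind of experiment; the water-balance defaults land the minimum
#' soil water content near 43 percent (drought) and 34 percent
#' (heat+drought) after seven days of 50 percent replacement.
#'
#' @param seed RNG seed
#' @param noiseSd named per-trait residual SDs (partial overrides allowed)
#' @param aciNoiseSd A/Ci measurement noise SD, umol m-2 s-1
#' @param gxhEffect,gxdEffect interaction effect multipliers
#' @param yieldVcmaxRho seeded genotypic correlation, heat-stress
#'   Vcmax_DAT1 vs seed yield
#' @param wateringFractionStressed,wateringFractionWatered replacement
#'   fractions
#' @param mmPerPixel image scale
#' @param potCapacity pot capacity, g water
#' @param dailyLoss named c(normal=, high=) daily loss, g
#' @param blockSdFrac block SD as fraction of trait noise SD
#' @param imageSize raster side, px
#' @param imageNoiseSd,hueJitter optional image noise (default 0)
#' @param calibration overrides for trait-model calibration constants
#' @return a \code{SimulationConfig}
#' @export
simulationConfig <- function(seed = 1L,
                             noiseSd = NULL,
                             aciNoiseSd = 0.5,
                             gxhEffect = 1, gxdEffect = 1,
                             yieldVcmaxRho = 0.878,
                             wateringFractionStressed = 0.5,
                             wateringFractionWatered = 1,
                             mmPerPixel = 1,
                             potCapacity = 4000,
                             dailyLoss = c(normal = 655, high = 750),
                             blockSdFrac = 0.5,
                             imageSize = 150L,
                             imageNoiseSd = 0, hueJitter = 0,
                             calibration = list()) {
  defNoise <- c(LC = 70, Tbud = 1.6, Tleaf = 1.6, Tambient = 0.3,
                PRI = 0.01, Qy = 0.03)
  if (!is.null(noiseSd)) defNoise[names(noiseSd)] <- noiseSd
  defCal <- list(
    lcBase = 400, lcFloor = 0.25, swcUpper = 60, swcLower = 30,
    vpdOffset = 8,               # SWC offset for stressed pots under heat

    droughtPhotoMax = 0.4,       # max fractional loss of Vcmax/J/TPU at swcLower
    heatRise = list(bud = 0, leaf = 0),
    droughtRise = list(bud = 2.0, leaf = 3.5),  # deg C at swcLower
    budOffset = -4.6, leafOffset = -6.2,
    genotypeSd = list(LC = 45, Tbud = 0.8, Tleaf = 0.8, PRI = 0.012,
                      Qy = 0.02),
    heatShift = list(LC = 0, PRI = -0.005, Qy = -0.02),
    droughtShift = list(PRI = -0.01, Qy = -0.08),  # at swcLower
    priBase = 0.02, qyBase = 0.75,
    vcmax25Mean = 100, vcmax25Sd = 18, jvRatio = 1.7, tpuJRatio = 1/14,
    rdMean = 1.5, rdSd = 0.25,
    gxhPhotoSd = 0.10, gxdPhotoSd = 0.15,
    sizeLogSd = 0.5, fwControlMean = 427.9,
    fwDecline = c(D = 0.482, H = 0.114, HD = 0.694),
    syControlMean = 3.0,
    syDecline = c(D = 0.408, H = 0.573, HD = 0.573),
    syGenotypeCv = 0.45, swMean = 0.35, swSd = 0.07,
    flowerFrac = 0.05, volfDecline = c(D = 0.32, H = 0, HD = 0.70),
    gxhFlowerSd = 0.2, gxdFlowerSd = 0.2,
    fwNoiseCv = 0.05, areaScale = 9
  )
  if (length(calibration)) defCal[names(calibration)] <- calibration
  new("SimulationConfig", seed = as.integer(seed), noiseSd = defNoise,
      aciNoiseSd = as.numeric(aciNoiseSd), gxhEffect = as.numeric(gxhEffect),
      gxdEffect = as.numeric(gxdEffect),
      yieldVcmaxRho = as.numeric(yieldVcmaxRho),
      wateringFractionStressed = as.numeric(wateringFractionStressed),
      wateringFractionWatered = as.numeric(wateringFractionWatered),
      mmPerPixel = as.numeric(mmPerPixel),
      potCapacity = as.numeric(potCapacity),
      dailyLoss = dailyLoss, blockSdFrac = as.numeric(blockSdFrac),
      imageSize = as.integer(imageSize),
      imageNoiseSd = as.numeric(imageNoiseSd),
      hueJitter = as.numeric(hueJitter), calibration = defCal)
}

#' Genotype-level correlation matrix
#'
#' Pearson correlations between trait_DAT columns computed across genotype
#' means within one treatment, with two-sided p-values from the t
#' transform, per-pair sample sizes and significance star codes
#' ("*" for 0.01 < p < 0.05, "**" for p < 0.01).
#'
#' @slot r,p,n,stars square matrices (r symmetric, unit diagonal)
#' @slot treatment treatment label
#' @export
setClass("CorrelationMatrix",
  representation(r = "matrix", p = "matrix", n = "matrix",
                 stars = "matrix", treatment = "character")
)

setValidity("CorrelationMatrix", function(object) {
  msg <- character()
  r <- object@r
  if (nrow(r) != ncol(r)) msg <- c(msg, "r must be square")
  if (!isTRUE(all.equal(r, t(r), tolerance = 1e-12, check.attributes = FALSE)))
    msg <- c(msg, "r must be symmetric to 1e-12")
  d <- diag(r)
  if (any(!is.na(d) & abs(d - 1) > 1e-12))
    msg <- c(msg, "diagonal of r must be 1")
  if (any(!is.na(r) & abs(r) > 1 + 1e-12))
    msg <- c(msg, "|r| must be <= 1")
  if (length(msg)) msg else TRUE
})
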