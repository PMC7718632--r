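# Synthetic-data generator: factorial design, pot water balance, trait
# time courses, A/Ci curves, outcomes. Images live in synth-images.R.

#' One day of deficit irrigation
#'
#' Applies a day's evapotranspiration loss and the replacement rule: a
#' fraction of the water lost in the last 24 h is supplied back (1.0 for
#' well-watered pots, 0.5 for water-stressed pots).
#'
#' @param state a \code{PotWaterState}
#' @param dailyLoss g of water lost over the day (>= 0); losses exceeding
#'   the available water are clamped to it and flagged via the
#'   \code{"clamped"} attribute of the result
#' @param fraction replacement fraction in [0, 1]
#' @return the updated \code{PotWaterState}
#' @examples
#' s <- potWaterState(4000)
#' swc(simulateWatering(s, 200, 0.5))  # 97.5
#' @export
simulateWatering <- function(state, dailyLoss, fraction) {
  stopifnot(is(state, "PotWaterState"))
  if (length(fraction) != 1 || is.na(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]")
  if (length(dailyLoss) != 1 || is.na(dailyLoss) || dailyLoss < 0)
    stop("dailyLoss must be >= 0")
  clamped <- dailyLoss > state@water
  loss <- min(dailyLoss, state@water)
  w <- state@water - loss + fraction * loss
  w <- min(max(w, 0), state@capacity)
  out <- potWaterState(state@capacity, w)
  attr(out, "clamped") <- clamped
  out
}

#' Soil water content trajectory under a treatment
#'
#' Iterates \code{\link{simulateWatering}} with the configured daily loss
#' for the temperature level and the replacement fraction for the
#' watering level. Returns both the post-watering SWC and the pre-watering
#' SWC (the previous day's low, the stress the plant experienced before
#' the morning water supply).
#'
#' @param config a \code{SimulationConfig}
#' @param heat,drought 0/1 indicators
#' @param maxDay last day (default 7)
#' @return data frame with columns day, swc (post-watering), swcPre
#' @export
swcTrajectory <- function(config, heat, drought, maxDay = 7) {
  loss <- config@dailyLoss[[if (heat > 0) "high" else "normal"]]
  frac <- if (drought > 0) config@wateringFractionStressed
          else config@wateringFractionWatered
  st <- potWaterState(config@potCapacity)
  out <- data.frame(day = 0:maxDay, swc = NA_real_, swcPre = NA_real_)
  out$swc[1] <- swc(st); out$swcPre[1] <- swc(st)
  for (d in seq_len(maxDay)) {
    pre <- 100 * max(waterContent(st) - loss, 0) / config@potCapacity
    st <- simulateWatering(st, min(loss, waterContent(st)), frac)
    out$swc[d + 1] <- swc(st)
    out$swcPre[d + 1] <- pre
  }
  out
}

# Stress driver in [0, 1]: 0 above the upper SWC threshold, 1 at/below
# the lower one. Heat adds an evaporative-demand offset for stressed pots
# (the same soil dryness bites harder at high VPD).
stressDeficit <- function(swcPre, heat, drought, cal) {
  drv <- swcPre - if (heat > 0 && drought > 0) cal$vpdOffset else 0
  pmin(1, pmax(0, (cal$swcUpper - drv) / (cal$swcUpper - cal$swcLower)))
}

# Stomatal-conductance multiplier: 1 above swcUpper, linear to lcFloor
# at swcLower, floored there.
lcMultiplier <- function(deficit, cal) {
  pmax(cal$lcFloor, 1 - (1 - cal$lcFloor) * deficit)
}

#' Generate genotype ground-truth profiles
#'
#' Draws, deterministically from the configuration seed, the latent
#' per-genotype truth the generator builds every observation from:
#' photosynthetic capacities at 25 C, plant size, baseline trait levels
#' and latent tolerance scores that drive the seeded genotype-by-heat and
#' genotype-by-drought interactions. Genotype deviations are standardized
#' within the panel (sum-to-zero contrasts; multiplicative effects have
#' in-sample mean 1) so that treatment-level calibration targets are met
#' exactly in expectation.
#'
#' @param design a \code{DesignSpec}
#' @param config a \code{SimulationConfig}
#' @return data frame, one row per genotype
#' @export
genotypeProfiles <- function(design, config) {
  withSeed(subSeed(config@seed, 1), {
    g <- length(design@genotypes)
    cal <- config@calibration
    rel1 <- function(sd) {  # multiplicative deviations, in-sample mean 1
      x <- 1 + sd * standardize(stats::rnorm(g))
      pmax(x, 0.05)
    }
    data.frame(
      genotype = design@genotypes,
      vcmax25 = cal$vcmax25Mean * rel1(cal$vcmax25Sd / cal$vcmax25Mean),
      rd25 = pmax(0.2, cal$rdMean + cal$rdSd * standardize(stats::rnorm(g))),
      zHeat = standardize(stats::rnorm(g)),    # drives G x H
      zDrought = standardize(stats::rnorm(g)), # drives G x D
      zYield = standardize(stats::rnorm(g)),   # residual yield deviation
      size = rel1(cal$sizeLogSd),
      lcBase = cal$lcBase * rel1(cal$genotypeSd$LC / cal$lcBase),
      budOffset = cal$budOffset + cal$genotypeSd$Tbud * standardize(stats::rnorm(g)),
      leafOffset = cal$leafOffset + cal$genotypeSd$Tleaf * standardize(stats::rnorm(g)),
      priBase = cal$priBase + cal$genotypeSd$PRI * standardize(stats::rnorm(g)),
      qyBase = cal$qyBase + cal$genotypeSd$Qy * standardize(stats::rnorm(g)),
      swBase = pmax(0.1, cal$swMean + cal$swSd * standardize(stats::rnorm(g))),
      stringsAsFactors = FALSE)
  })
}

# j25 and tpu25 derive from vcmax25 by fixed ratios.
profileParams25 <- function(profile, cal) {
  FvCBParameters(vcmax = profile$vcmax25,
                 j = profile$vcmax25 * cal$jvRatio,
                 tpu = profile$vcmax25 * cal$jvRatio * cal$tpuJRatio,
                 rd = profile$rd25)
}

#' Ground-truth FvCB parameters for one plant and day
#'
#' Temperature-adjusts the genotype's 25 C parameters to the cabinet leaf
#' temperature (23 C normal, 35 C heat), applies the genotype-by-heat
#' interaction (genotypes differ in how strongly heat scales their
#' capacities) and, from DAT3 onward, the drought multiplier proportional
#' to the soil-water deficit with its genotype-by-drought interaction.
#'
#' @param profile one row of \code{\link{genotypeProfiles}}
#' @param heat,drought 0/1 indicators
#' @param dat day after treatment onset
#' @param config a \code{SimulationConfig}
#' @return an \code{FvCBParameters} at leaf temperature
#' @export
trueParametersAt <- function(profile, heat, drought, dat, config) {
  cal <- config@calibration
  leafT <- if (heat > 0) 35 else 23
  p <- temperatureAdjust(profileParams25(profile, cal), leafT)
  scale <- 1
  if (heat > 0)
    scale <- scale * max(0.05, 1 + config@gxhEffect * cal$gxhPhotoSd * profile$zHeat)
  if (drought > 0 && dat >= 3) {
    traj <- swcTrajectory(config, heat, drought, maxDay = max(7, dat))
    def <- stressDeficit(traj$swcPre[traj$day == dat], heat, drought, cal)
    gx <- max(0.05, 1 + config@gxdEffect * cal$gxdPhotoSd * profile$zDrought)
    scale <- scale * max(0.05, 1 - cal$droughtPhotoMax * def * gx)
  }
  FvCBParameters(vcmax = p@vcmax * scale, j = p@j * scale,
                 tpu = p@tpu * scale, rd = p@rd,
                 gammaStar = p@gammaStar, kc = p@kc, ko = p@ko,
                 o2 = p@o2, temp = leafT)
}

#' Simulate the in-cabinet trait table
#'
#' One row per (genotype, block, heat, drought, DAT, trait) for the six
#' in-cabinet traits LC, Tbud, Tleaf, Tambient, PRI and Qy. Each value is
#' baseline + heat effect + drought effect (driven by the soil-water
#' deficit from the watering simulation) + block effect + Gaussian noise;
#' bud, leaf and ambient temperatures of one plant share the same ambient
#' realization so the derived differences T1/T2/T3 are meaningful.
#' Deterministic given the configuration seed.
#'
#' @param design a \code{DesignSpec}
#' @param profiles data frame from \code{\link{genotypeProfiles}},
#'   aligned 1:1 with \code{design@genotypes}
#' @param config a \code{SimulationConfig}
#' @param nullEffects if TRUE, suppress all genotype, heat and drought
#'   effects (grand mean + block + noise only); used for type-I error
#'   calibration of the downstream ANOVA
#' @return long-format data frame (genotype, block, heat, drought, dat,
#'   trait, value)
#' @export
simulateTraitTable <- function(design, profiles, config,
                               nullEffects = FALSE) {
  if (!identical(profiles$genotype, design@genotypes))
    stop("profiles must align 1:1 with design genotypes")
  cal <- config@calibration
  grid <- expand.grid(genotype = design@genotypes,
                      block = seq_len(design@nBlocks),
                      heat = 0:1, drought = 0:1,
                      dat = design@inCabinetDays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  traits <- c("LC", "Tbud", "Tleaf", "Tambient", "PRI", "Qy")
  withSeed(subSeed(config@seed, 2), {
    blockEff <- matrix(stats::rnorm(design@nBlocks * length(traits)),
                       design@nBlocks, length(traits),
                       dimnames = list(NULL, traits))
    blockEff <- sweep(blockEff, 2, config@blockSdFrac * config@noiseSd[traits], `*`)
    # deficits per (heat, drought, dat)
    defKey <- function(h, d, dat) {
      traj <- swcTrajectory(config, h, d, maxDay = max(design@inCabinetDays))
      stressDeficit(traj$swcPre[match(dat, traj$day)], h, d, cal)
    }
    defs <- array(NA_real_, c(2, 2, length(design@inCabinetDays)))
    for (h in 0:1) for (d in 0:1)
      defs[h + 1, d + 1, ] <- defKey(h, d, design@inCabinetDays)
    n <- nrow(grid)
    prof <- profiles[match(grid$genotype, profiles$genotype), ]
    def <- defs[cbind(grid$heat + 1, grid$drought + 1,
                      match(grid$dat, design@inCabinetDays))]
    amb <- ifelse(grid$heat > 0, 35, 23) +
      stats::rnorm(n, 0, config@noiseSd[["Tambient"]])
    rise <- function(part) ifelse(grid$drought > 0,
                                  cal$droughtRise[[part]] * def, 0)
    base <- function(x, null) if (nullEffects) rep(null, n) else x
    vals <- list(
      LC = base(prof$lcBase * lcMultiplier(def, cal) +
                  cal$heatShift$LC * grid$heat, cal$lcBase) +
        blockEff[grid$block, "LC"] +
        stats::rnorm(n, 0, config@noiseSd[["LC"]]),
      Tambient = if (nullEffects) 23 + stats::rnorm(n, 0, config@noiseSd[["Tambient"]]) +
                   blockEff[grid$block, "Tambient"] else amb,
      Tbud = base(amb + prof$budOffset + rise("bud"), 23 + cal$budOffset) +
        blockEff[grid$block, "Tbud"] +
        stats::rnorm(n, 0, config@noiseSd[["Tbud"]]),
      Tleaf = base(amb + prof$leafOffset + rise("leaf"), 23 + cal$leafOffset) +
        blockEff[grid$block, "Tleaf"] +
        stats::rnorm(n, 0, config@noiseSd[["Tleaf"]]),
      PRI = base(prof$priBase + cal$heatShift$PRI * grid$heat +
                   cal$droughtShift$PRI * def, cal$priBase) +
        blockEff[grid$block, "PRI"] +
        stats::rnorm(n, 0, config@noiseSd[["PRI"]]),
      Qy = base(prof$qyBase + cal$heatShift$Qy * grid$heat +
                  cal$droughtShift$Qy * def, cal$qyBase) +
        blockEff[grid$block, "Qy"] +
        stats::rnorm(n, 0, config@noiseSd[["Qy"]])
    )
    do.call(rbind, lapply(traits, function(tr) {
      cbind(grid, trait = tr, value = vals[[tr]], stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate A/Ci gas-exchange curves with known truth
#'
#' For every (genotype, block, heat, drought, gas-exchange DAT) cell,
#' evaluates the forward FvCB model at the instrument's programmed Ci
#' steps (0, 50, 75, 100, 150, 400, 800, 1600 umol mol-1) under the
#' plant's ground-truth parameters (see \code{\link{trueParametersAt}})
#' and adds Gaussian measurement noise.
#'
#' @inheritParams simulateTraitTable
#' @param ciSteps instrument Ci program, umol mol-1
#' @return list with \code{curves} (list of \code{AciCurve}) and
#'   \code{truth} (data frame of generating parameters per curve)
#' @export
simulateAciCurves <- function(design, profiles, config,
                              ciSteps = c(0, 50, 75, 100, 150, 400, 800, 1600)) {
  if (!identical(profiles$genotype, design@genotypes))
    stop("profiles must align 1:1 with design genotypes")
  grid <- expand.grid(genotype = design@genotypes,
                      block = seq_len(design@nBlocks),
                      heat = 0:1, drought = 0:1,
                      dat = design@gasExchangeDays,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withSeed(subSeed(config@seed, 3), {
    curves <- vector("list", nrow(grid))
    truth <- grid
    truth$curveId <- sprintf("%s_B%d_H%d_D%d_DAT%d", grid$genotype,
                             grid$block, grid$heat, grid$drought, grid$dat)
    truth$vcmax <- truth$j <- truth$tpu <- truth$rd <- truth$leafTemp <- NA_real_
    for (i in seq_len(nrow(grid))) {
      pr <- profiles[profiles$genotype == grid$genotype[i], ]
      p <- trueParametersAt(pr, grid$heat[i], grid$drought[i],
                            grid$dat[i], config)
      a <- forwardAci(ciSteps, p) +
        stats::rnorm(length(ciSteps), 0, config@aciNoiseSd)
      curves[[i]] <- aciCurve(ciSteps, a, curveId = truth$curveId[i],
                              leafTemp = p@temp, o2 = p@o2)
      truth$vcmax[i] <- p@vcmax; truth$j[i] <- p@j
      truth$tpu[i] <- p@tpu; truth$rd[i] <- p@rd
      truth$leafTemp[i] <- p@temp
    }
    list(curves = curves, truth = truth)
  })
}

# Whole-plant biomass index: in-sample control mean 1 at DAT7.
biomassIndex <- function(profile, heat, drought, dat, config) {
  cal <- config@calibration
  trt <- treatmentLabel(heat, drought)
  dec <- c(C = 0, cal$fwDecline)[[trt]]
  gx <- 1
  if (heat > 0) gx <- gx * (1 + config@gxhEffect * 0.05 * profile$zHeat)
  if (drought > 0) gx <- gx * (1 + config@gxdEffect * 0.10 * profile$zDrought)
  growth <- (0.6 + 0.4 * dat / 7)  # plants keep growing over the week
  profile$size * growth / 1 * (max(1 - dec, 0.02) * max(gx, 0.05))^(dat / 7)
}

# Flower index: drives flower pixel area; volume-scale declines are
# converted to the index scale (volume ~ index^2 under the product
# volume estimator with area ~ index^(2/3)).
flowerIndex <- function(profile, heat, drought, dat, config) {
  cal <- config@calibration
  trt <- treatmentLabel(heat, drought)
  dec <- c(C = 0, cal$volfDecline)[[trt]]
  gx <- 1
  if (heat > 0) gx <- gx * (1 + config@gxhEffect * cal$gxhFlowerSd * profile$zHeat)
  if (drought > 0) gx <- gx * (1 + config@gxdEffect * cal$gxdFlowerSd * profile$zDrought)
  open <- 0.25 + 0.75 * dat / 7    # flowering progresses over the week
  idx <- cal$flowerFrac * profile$size * open *
    (sqrt(max(1 - dec, 0.02)) * max(gx, 0.05))^(dat / 7)
  max(idx, 0)
}

#' Simulate destructive outcomes: fresh weight, seed yield, seed weight
#'
#' Fresh weight (FW, g) is measured at DAT7 on blocks 1 and 2 and is
#' proportional to the simulated biomass (the same index that drives the
#' imaged plant area, so FW and whole-plant volume are correlated by
#' construction). Seed yield (SY, g) and 100-seed weight (SW, g) come
#' from the block-3 plants grown to maturity. Under the heat-stressed
#' treatments the genotype-level SY deviations are constructed so the
#' genotypic correlation between true Vcmax at DAT1 and SY equals the
#' configured target \code{yieldVcmaxRho} exactly in-sample; treatment
#' means follow the configured control means and percentage declines.
#'
#' @inheritParams simulateTraitTable
#' @return long-format data frame (genotype, block, heat, drought, dat,
#'   trait, value) with traits FW, SY, SW
#' @export
simulateOutcomes <- function(design, profiles, config) {
  if (abs(config@yieldVcmaxRho) > 1) stop("|yieldVcmaxRho| must be <= 1")
  cal <- config@calibration
  g <- length(design@genotypes)
  # true heat-stress Vcmax at DAT1 (leaf temperature), standardized
  vTrue <- vapply(seq_len(g), function(i)
    vcmax(trueParametersAt(profiles[i, ], 1, 0, 1, config)), numeric(1))
  zV <- standardize(vTrue)
  withSeed(subSeed(config@seed, 4), {
    rows <- list()
    fwBlocks <- seq_len(min(2L, design@nBlocks))
    syBlock <- design@nBlocks
    rho <- config@yieldVcmaxRho
    zE <- orthoStandardize(stats::rnorm(g), vTrue)     # heat treatments
    wHeat <- rho * zV + sqrt(max(0, 1 - rho^2)) * zE
    for (h in 0:1) for (d in 0:1) {
      trt <- treatmentLabel(h, d)
      decF <- c(C = 0, cal$fwDecline)[[trt]]
      decS <- c(C = 0, cal$syDecline)[[trt]]
      for (i in seq_len(g)) {
        pr <- profiles[i, ]
        for (b in fwBlocks) {
          fw <- cal$fwControlMean * biomassIndex(pr, h, d, 7, config) *
            (1 + cal$fwNoiseCv * stats::rnorm(1))
          rows[[length(rows) + 1L]] <- data.frame(
            genotype = pr$genotype, block = b, heat = h, drought = d,
            dat = 7, trait = "FW", value = max(fw, 0.1),
            stringsAsFactors = FALSE)
        }
        w <- if (h > 0) wHeat[i] else profiles$zYield[i]
        sy <- cal$syControlMean * max(1 - decS, 0.02) *
          max(1 + cal$syGenotypeCv * w, 0.02)
        sw <- pr$swBase + stats::rnorm(1, 0, 0.01)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = pr$genotype, block = syBlock, heat = h, drought = d,
          dat = NA_real_, trait = "SY", value = sy, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          genotype = pr$genotype, block = syBlock, heat = h, drought = d,
          dat = NA_real_, trait = "SW", value = max(sw, 0.05),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
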