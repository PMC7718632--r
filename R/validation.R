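# Monte-Carlo validation studies: parameter recovery, temperature
# consistency, test calibration and power, seeded-correlation recovery.
# These run the generator and the analysis machinery end to end and are
# what the package's own acceptance checks are built on.

#' A/Ci parameter-recovery study at the study conditions
#'
#' Simulates the full set of gas-exchange curves of one factorial
#' experiment (8-point Ci program, measurement noise from the
#' configuration), fits every curve and summarises the relative errors
#' of Vcmax, J (ETR) and TPU against the generating truth.
#'
#' @param seed RNG seed
#' @param design,config experiment layout and generator settings
#' @return list with \code{medianRelErr} (named: vcmax, j, tpu),
#'   \code{identifiedFrac}, \code{n} curves, and the per-curve error
#'   table in \code{errors}
#' @export
validateRecovery <- function(seed = 1, design = designSpec(),
                             config = simulationConfig(seed = seed)) {
  pr <- genotypeProfiles(design, config)
  sim <- simulateAciCurves(design, pr, config)
  fits <- lapply(sim$curves, fitAci)
  err <- data.frame(
    curveId = sim$truth$curveId,
    vcmax = abs(vapply(fits, vcmax, numeric(1)) - sim$truth$vcmax) /
      sim$truth$vcmax,
    j = abs(vapply(fits, etr, numeric(1)) - sim$truth$j) / sim$truth$j,
    tpu = abs(vapply(fits, tpu, numeric(1)) - sim$truth$tpu) /
      sim$truth$tpu)
  list(medianRelErr = c(vcmax = stats::median(err$vcmax, na.rm = TRUE),
                        j = stats::median(err$j, na.rm = TRUE),
                        tpu = stats::median(err$tpu, na.rm = TRUE)),
       identifiedFrac = c(vcmax = mean(!is.na(err$vcmax)),
                          j = mean(!is.na(err$j)),
                          tpu = mean(!is.na(err$tpu))),
       n = nrow(err), errors = err)
}

#' Heat-doubling consistency of fitted Vcmax
#'
#' Simulates paired curves for the same plants at 23 C (control) and
#' 35 C (heat) at DAT1, fits both, and reports how often the fitted
#' Vcmax at 35 C is at least twice the fitted Vcmax at 23 C.
#'
#' @param nPairs number of plant pairs
#' @param seed RNG seed
#' @param config generator settings template (per-replicate seeds are
#'   derived from \code{seed})
#' @return list with \code{fracDoubled}, \code{medianRatio},
#'   \code{ratios}
#' @export
validateTemperatureConsistency <- function(nPairs = 100, seed = 1,
                                           config = simulationConfig()) {
  ci <- c(0, 50, 75, 100, 150, 400, 800, 1600)
  ratios <- numeric(0)
  rep <- 0
  design <- designSpec()
  while (length(ratios) < nPairs) {
    rep <- rep + 1
    cfg <- simulationConfig(seed = subSeed(seed, 7000 + rep),
                            aciNoiseSd = config@aciNoiseSd)
    pr <- genotypeProfiles(design, cfg)
    rr <- withSeed(subSeed(cfg@seed, 8), {
      vapply(seq_len(nrow(pr)), function(i) {
        fitOne <- function(h) {
          p <- trueParametersAt(pr[i, ], h, 0, 1, cfg)
          a <- forwardAci(ci, p) + stats::rnorm(length(ci), 0, cfg@aciNoiseSd)
          vcmax(fitAci(aciCurve(ci, a, leafTemp = p@temp)))
        }
        fitOne(1) / fitOne(0)
      }, numeric(1))
    })
    ratios <- c(ratios, rr)
  }
  ratios <- ratios[seq_len(nPairs)]
  list(fracDoubled = mean(ratios >= 2),
       medianRatio = stats::median(ratios), ratios = ratios)
}

#' Type-I error calibration of the factorial ANOVA
#'
#' Simulates null experiments (no genotype, heat or drought effects;
#' block and residual noise only), runs the mixed-model ANOVA and
#' reports the rejection rate of every fixed term at \code{alpha}.
#'
#' @param nSim number of null simulations
#' @param seed RNG seed
#' @param alpha nominal level
#' @return list with \code{rates} (named per term) and \code{nSim}
#' @export
validateTypeI <- function(nSim = 500, seed = 1, alpha = 0.05) {
  design <- designSpec(inCabinetDays = 1)
  pmat <- NULL
  for (i in seq_len(nSim)) {
    cfg <- simulationConfig(seed = subSeed(seed, 10000 + i))
    tt <- simulateTraitTable(design, genotypeProfiles(design, cfg), cfg,
                             nullEffects = TRUE)
    a <- fitFactorialLmm(tt, "LC", 1)
    if (is.null(pmat)) pmat <- matrix(NA_real_, nSim, nrow(a),
                                      dimnames = list(NULL, a$term))
    pmat[i, ] <- a$p
  }
  list(rates = colMeans(pmat < alpha), nSim = nSim, p = pmat)
}

#' Power for the seeded genotype-by-heat interaction
#'
#' Simulates complete experiments at the default effect sizes, fits all
#' DAT1 gas-exchange curves, runs the factorial ANOVA on the fitted
#' Vcmax and reports how often the genotype-by-heat term is significant
#' at \code{alpha}.
#'
#' @param nSim number of simulated experiments
#' @param seed RNG seed
#' @param alpha nominal level
#' @param term ANOVA term to monitor (default \code{"GxH"})
#' @return list with \code{power}, \code{nSim}, \code{p}
#' @export
validatePower <- function(nSim = 200, seed = 1, alpha = 0.05,
                          term = "GxH") {
  design <- designSpec(gasExchangeDays = 1)
  p <- numeric(nSim)
  for (i in seq_len(nSim)) {
    cfg <- simulationConfig(seed = subSeed(seed, 20000 + i))
    pr <- genotypeProfiles(design, cfg)
    sim <- simulateAciCurves(design, pr, cfg)
    v <- vapply(sim$curves, function(cv) vcmax(fitAci(cv)), numeric(1))
    tab <- cbind(sim$truth[c("genotype", "block", "heat", "drought", "dat")],
                 trait = "Vcmax", value = v)
    a <- fitFactorialLmm(tab, "Vcmax", 1)
    p[i] <- a$p[a$term == term]
  }
  list(power = mean(p < alpha), nSim = nSim, p = p)
}

#' Recovery of the seeded yield-Vcmax genotypic correlation
#'
#' Replicates the generator, computes genotype means under heat stress
#' for a panel of traits (the fitted Vcmax at DAT1 among them), runs the
#' genotypic-correlation module and reports the mean recovered
#' correlation between Vcmax_DAT1 and seed yield, plus how often that
#' pair sits on adjacent leaves of the clustered heatmap ordering.
#'
#' @param nRep replicate simulations
#' @param seed RNG seed
#' @param fitCurves fit Vcmax from simulated noisy curves (TRUE) or use
#'   the generating truth (FALSE)
#' @return list with \code{meanR}, \code{adjacencyFrac}, \code{r} per
#'   replicate
#' @export
validateRhoRecovery <- function(nRep = 200, seed = 1, fitCurves = TRUE) {
  ci <- c(0, 50, 75, 100, 150, 400, 800, 1600)
  design <- designSpec(inCabinetDays = c(3, 7))
  rs <- adj <- rep(NA_real_, nRep)
  for (i in seq_len(nRep)) {
    cfg <- simulationConfig(seed = subSeed(seed, 30000 + i))
    pr <- genotypeProfiles(design, cfg)
    tt <- simulateTraitTable(design, pr, cfg)
    oc <- simulateOutcomes(design, pr, cfg)
    # fitted (or true) Vcmax under heat at DAT1, one curve per block
    vc <- withSeed(subSeed(cfg@seed, 9), {
      vapply(seq_len(nrow(pr)), function(g) {
        p <- trueParametersAt(pr[g, ], 1, 0, 1, cfg)
        if (!fitCurves) return(p@vcmax)
        mean(vapply(seq_len(design@nBlocks), function(b) {
          a <- forwardAci(ci, p) + stats::rnorm(length(ci), 0, cfg@aciNoiseSd)
          vcmax(fitAci(aciCurve(ci, a, leafTemp = p@temp)))
        }, numeric(1)))
      }, numeric(1))
    })
    vcRows <- data.frame(genotype = pr$genotype, block = 1, heat = 1,
                         drought = 0, dat = 1, trait = "Vcmax", value = vc)
    gm <- genotypeMeans(rbind(tt, oc, vcRows), "H")
    keep <- colnames(gm)[apply(gm, 2, function(x)
      sum(is.finite(x)) >= 3 && stats::sd(x, na.rm = TRUE) > 0)]
    cmx <- correlate(gm[, keep, drop = FALSE])
    rs[i] <- corValues(cmx)["Vcmax_DAT1", "SY"]
    ord <- clusterOrder(cmx)
    adj[i] <- abs(diff(match(c("Vcmax_DAT1", "SY"), ord))) == 1
  }
  list(meanR = mean(rs), adjacencyFrac = mean(adj), r = rs)
}
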