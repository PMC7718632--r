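# End-to-end orchestration: simulate (or ingest), fit curves, compute
# volumes, run ANOVA and genotypic correlations, write a report bundle.

#' Run configuration
#'
#' Bundles everything one end-to-end run needs. The seed governs every
#' source of randomness and is recorded, with a hash of the
#' configuration, in the header of every CSV output.
#'
#' @param outDir output directory
#' @param design a \code{DesignSpec}
#' @param sim a \code{SimulationConfig} (its seed is the run seed)
#' @param volumeEstimator see \code{\link{plantVolume}}
#' @param thresholds segmentation thresholds
#' @param transform ANOVA transform policy ("none" or "log")
#' @param writeImages also write the rendered PNGs (slower; off by default)
#' @return a list of class \code{"phenomicsRunConfig"}
#' @export
runConfig <- function(outDir, design = designSpec(),
                      sim = simulationConfig(),
                      volumeEstimator = "product",
                      thresholds = segmentationThresholds(),
                      transform = "none", writeImages = FALSE) {
  structure(list(outDir = outDir, design = design, sim = sim,
                 volumeEstimator = volumeEstimator,
                 thresholds = thresholds, transform = transform,
                 writeImages = writeImages),
            class = "phenomicsRunConfig")
}

stageMsg <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

# Analysis stages shared by the synthetic and ingest entry points.
analyseStudy <- function(cfg, traitTable, curves, areas, outcomes, hash,
                         quiet) {
  out <- cfg$outDir
  seed <- cfg$sim@seed
  wcsv <- function(df, name) writeTableCsv(df, file.path(out, name), seed, hash)

  stageMsg(quiet, "[fit-aci] fitting %d curves", length(curves))
  curves <- curves[order(vapply(curves, function(cv) cv@curveId,
                                character(1)))]
  fits <- lapply(curves, fitAci)
  fitTab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(curveId = f@curveId, vcmax = vcmax(f), etr = etr(f),
               tpu = tpu(f), rd = f@params@rd, sse = sse(f),
               vcmaxIdentifiable = f@vcmaxIdentifiable,
               jIdentifiable = f@jIdentifiable,
               tpuIdentifiable = f@tpuIdentifiable,
               limitation = paste(limitation(f), collapse = "|"),
               stringsAsFactors = FALSE)
  }))
  wcsv(fitTab, "aci_fits.csv")

  # fitted photosynthetic parameters become traits
  meta <- do.call(rbind, strsplit(fitTab$curveId, "_"))
  photo <- data.frame(
    genotype = meta[, 1], block = as.integer(sub("B", "", meta[, 2])),
    heat = as.integer(sub("H", "", meta[, 3])),
    drought = as.integer(sub("D", "", meta[, 4])),
    dat = as.numeric(sub("DAT", "", meta[, 5])), stringsAsFactors = FALSE)
  photoLong <- rbind(
    cbind(photo, trait = "Vcmax", value = fitTab$vcmax),
    cbind(photo, trait = "ETR", value = fitTab$etr),
    cbind(photo, trait = "TPU", value = fitTab$tpu))
  photoLong <- photoLong[is.finite(photoLong$value), ]

  stageMsg(quiet, "[phenovol] volumes for %d captures", nrow(areas) / 3)
  vols <- areasToVolumes(areas, cfg$volumeEstimator)
  wcsv(vols, "volumes.csv")
  volLong <- rbind(
    cbind(vols[c("genotype", "block", "heat", "drought", "dat")],
          trait = "VolWP", value = vols$volWP),
    cbind(vols[c("genotype", "block", "heat", "drought", "dat")],
          trait = "VolF", value = vols$volF))

  full <- rbind(deriveTemperatureTraits(traitTable), photoLong, volLong,
                outcomes)
  wcsv(full, "trait_table_full.csv")

  stageMsg(quiet, "[anova] factorial mixed models")
  anova <- anovaAllTraits(full, transform = cfg$transform)
  wcsv(anova, "anova.csv")

  stageMsg(quiet, "[gcorr] genotypic correlations")
  pairs <- list(); orders <- list()
  for (trt in c("C", "D", "H", "HD")) {
    gm <- genotypeMeans(full, trt)
    keep <- colnames(gm)[apply(gm, 2, function(x) sum(is.finite(x)) >= 3 &&
                                 stats::sd(x, na.rm = TRUE) > 0)]
    cmx <- correlate(gm[, keep, drop = FALSE])
    cmx@treatment <- trt
    pairs[[trt]] <- correlationPairs(cmx)
    ord <- suppressWarnings(clusterOrder(cmx))
    orders[[trt]] <- ord
    renderHeatmap(cmx, ord, file.path(out, sprintf("heatmap_%s.png", trt)))
  }
  wcsv(do.call(rbind, pairs), "gcorr_pairs.csv")

  # volume-weight regression across all treatments at DAT7
  fw <- full[full$trait == "FW", ]
  v7 <- vols[vols$dat == 7, ]
  key <- function(d) paste(d$genotype, d$block, d$heat, d$drought)
  fw$key <- key(fw); v7$key <- key(v7)
  mrg <- merge(fw[c("key", "value")], v7[c("key", "volWP")], by = "key")
  reg <- volumeVsWeightRegression(mrg$volWP, mrg$value)
  wcsv(data.frame(slope = reg$slope, intercept = reg$intercept,
                  r = reg$r, n = reg$n), "volume_fw_regression.csv")

  list(traitTable = full, fits = fitTab, volumes = vols, anova = anova,
       gcorr = do.call(rbind, pairs), gcorrOrders = orders,
       volumeFwRegression = reg)
}

# Areas table (long, one row per capture x view) -> per-capture volumes.
areasToVolumes <- function(areas, estimator = "product") {
  key <- c("genotype", "block", "heat", "drought", "dat")
  wide <- stats::reshape(areas[c(key, "view", "plantArea", "flowerArea")],
                         idvar = key, timevar = "view", direction = "wide")
  data.frame(
    wide[key],
    volWP = plantVolume(wide$plantArea.top, wide$plantArea.side0,
                        wide$plantArea.side90, estimator),
    volF = plantVolume(wide$flowerArea.top, wide$flowerArea.side0,
                       wide$flowerArea.side90, estimator),
    stringsAsFactors = FALSE)
}

#' Run the full synthetic study
#'
#' Generates the factorial experiment with known ground truth, runs every
#' analysis stage (A/Ci fitting, segmentation and volumes, factorial
#' ANOVA, genotypic correlations, volume-weight regression) and writes
#' the report bundle: CSV tables (each headed by the seed and config
#' hash), heatmap PNGs and a markdown run summary comparing seeded truth
#' with recovered estimates. Fully reproducible from the seed.
#'
#' @param cfg a \code{\link{runConfig}}
#' @param quiet suppress stage messages
#' @return (invisibly) a list with all intermediate and final tables
#' @export
runSyntheticStudy <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "phenomicsRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(cfg[setdiff(names(cfg), "outDir")])
  seed <- cfg$sim@seed
  wcsv <- function(df, name)
    writeTableCsv(df, file.path(cfg$outDir, name), seed, hash)

  stageMsg(quiet, "[simulate] design %d x 2 x 2 x %d, seed %d",
           length(cfg$design@genotypes), cfg$design@nBlocks, seed)
  profiles <- genotypeProfiles(cfg$design, cfg$sim)
  wcsv(profiles, "ground_truth_profiles.csv")
  traitTable <- simulateTraitTable(cfg$design, profiles, cfg$sim)
  wcsv(traitTable, "trait_table_incabinet.csv")
  aci <- simulateAciCurves(cfg$design, profiles, cfg$sim)
  curveTab <- do.call(rbind, lapply(aci$curves, function(cv)
    data.frame(curveId = cv@curveId, ci = cv@ci, a = cv@a,
               leafTemp = cv@leafTemp, o2 = cv@o2, stringsAsFactors = FALSE)))
  wcsv(curveTab, "aci_curves.csv")
  wcsv(aci$truth, "ground_truth_aci.csv")

  stageMsg(quiet, "[render] plant images")
  img <- renderPlantImages(cfg$design, profiles, cfg$sim)
  wcsv(img$truth, "ground_truth_pixels.csv")
  if (cfg$writeImages)
    for (im in img$images)
      writeImageSet(im, file.path(cfg$outDir, "images"))

  stageMsg(quiet, "[segment] %d image sets", length(img$images))
  areas <- do.call(rbind, lapply(img$images, function(im) {
    ar <- imageSetAreas(im, cfg$thresholds)
    info <- img$truth[img$truth$plantId == im@plantId &
                        img$truth$dat == im@dat, ][1, ]
    cbind(info[c("genotype", "block", "heat", "drought")],
          dat = im@dat, ar, row.names = NULL)
  }))
  wcsv(areas, "areas.csv")

  outcomes <- simulateOutcomes(cfg$design, profiles, cfg$sim)
  wcsv(outcomes, "outcomes.csv")

  res <- analyseStudy(cfg, traitTable, aci$curves, areas, outcomes, hash,
                      quiet)
  res$profiles <- profiles
  res$aciTruth <- aci$truth
  res$pixelTruth <- img$truth

  writeRunSummary(cfg, res, hash)
  invisible(res)
}

#' Re-run the analysis from exported inputs
#'
#' Reads the raw inputs a previous run (or an external experiment in the
#' same formats) exported — in-cabinet trait table, A/Ci curves, per-view
#' areas, outcomes — and runs the identical analysis stages. Ingesting a
#' synthetic run's own exports reproduces its analysis outputs exactly.
#'
#' @param cfg a \code{\link{runConfig}}; \code{inDir} defaults to its
#'   \code{outDir}
#' @param inDir directory with trait_table_incabinet.csv, aci_curves.csv,
#'   areas.csv, outcomes.csv
#' @param quiet suppress stage messages
#' @return (invisibly) the analysis bundle, as
#'   \code{\link{runSyntheticStudy}}
#' @export
runIngest <- function(cfg, inDir = cfg$outDir, quiet = FALSE) {
  stopifnot(inherits(cfg, "phenomicsRunConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- configHash(cfg[setdiff(names(cfg), "outDir")])
  need <- c("trait_table_incabinet.csv", "aci_curves.csv", "areas.csv",
            "outcomes.csv")
  missing <- need[!file.exists(file.path(inDir, need))]
  if (length(missing))
    stop("missing input files: ", paste(missing, collapse = ", "))
  readChecked <- function(name, cols) {
    df <- readTableCsv(file.path(inDir, name))
    bad <- setdiff(cols, names(df))
    if (length(bad))
      stop(sprintf("%s: missing columns %s", name,
                   paste(bad, collapse = ", ")))
    if (nrow(df) == 0) stop(sprintf("%s: no rows", name))
    df
  }
  traitTable <- readChecked("trait_table_incabinet.csv",
                            c("genotype", "block", "heat", "drought",
                              "dat", "trait", "value"))
  curveTab <- readChecked("aci_curves.csv",
                          c("curveId", "ci", "a", "leafTemp", "o2"))
  curves <- lapply(split(curveTab, curveTab$curveId), function(d)
    aciCurve(d$ci, d$a, curveId = d$curveId[1], leafTemp = d$leafTemp[1],
             o2 = d$o2[1]))
  curves <- curves[order(names(curves))]
  areas <- readChecked("areas.csv",
                       c("genotype", "block", "heat", "drought", "dat",
                         "view", "plantArea", "flowerArea"))
  outcomes <- readChecked("outcomes.csv",
                          c("genotype", "block", "heat", "drought", "dat",
                            "trait", "value"))
  res <- analyseStudy(cfg, traitTable, curves, areas, outcomes, hash, quiet)
  writeRunSummary(cfg, res, hash)
  invisible(res)
}

# Markdown run summary: seeded truth vs recovered estimates.
writeRunSummary <- function(cfg, res, hash) {
  p <- file.path(cfg$outDir, "run_summary.md")
  lines <- c(
    "# Phenomics run summary", "",
    sprintf("- seed: %d", cfg$sim@seed),
    sprintf("- config hash: %s", hash),
    sprintf("- curves fitted: %d", nrow(res$fits)),
    sprintf("- image captures: %d", nrow(res$volumes)),
    sprintf("- ANOVA tables: %d trait x DAT combinations",
            length(unique(paste(res$anova$trait, res$anova$dat)))),
    "")
  if (!is.null(res$aciTruth)) {
    mrg <- merge(res$aciTruth, res$fits, by = "curveId",
                 suffixes = c(".true", ".fit"))
    relerr <- function(a, b) stats::median(abs(a - b) / abs(b), na.rm = TRUE)
    lines <- c(lines, "## Ground truth vs recovered", "",
      sprintf("- median |Vcmax error| / truth: %.4f",
              relerr(mrg$vcmax.fit, mrg$vcmax.true)),
      sprintf("- median |ETR error| / truth: %.4f",
              relerr(mrg$etr, mrg$j)),
      sprintf("- median |TPU error| / truth: %.4f",
              relerr(mrg$tpu.fit, mrg$tpu.true)), "")
  }
  if (!is.null(res$volumeFwRegression))
    lines <- c(lines,
      sprintf("- VolWP-FW regression: r = %.3f (n = %d)",
              res$volumeFwRegression$r, res$volumeFwRegression$n))
  writeLines(lines, p)
  invisible(p)
}
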