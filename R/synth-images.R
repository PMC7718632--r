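# Three-view RGB plant image rendering with exact ground truth.

#' Three-view plant image set
#'
#' The top, 0-degree side and 90-degree side RGB captures of one plant at
#' one imaging day, with the pixel scale.
#'
#' @slot plantId identifier
#' @slot dat imaging day
#' @slot mmPerPixel mm per pixel (> 0)
#' @slot top,side0,side90 numeric arrays h x w x 3 with values in [0, 1]
#' @export
setClass("PlantImageSet",
  representation(plantId = "character", dat = "numeric",
                 mmPerPixel = "numeric", top = "array", side0 = "array",
                 side90 = "array")
)

setValidity("PlantImageSet", function(object) {
  msg <- character()
  for (v in c("top", "side0", "side90")) {
    a <- slot(object, v)
    if (length(dim(a)) != 3L || dim(a)[3] != 3L)
      msg <- c(msg, sprintf("%s must be an h x w x 3 array", v))
  }
  if (object@mmPerPixel <= 0) msg <- c(msg, "mmPerPixel must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PlantImageSet", function(object) {
  d <- dim(object@top)
  cat(sprintf("PlantImageSet '%s' DAT%g: 3 views %dx%d px, %.3g mm/px\n",
              object@plantId, object@dat, d[1], d[2], object@mmPerPixel))
})

# Reference colours: hue 120 deg (plant green), hue 55 deg (flower
# yellow), achromatic background.
plantColours <- function() {
  list(plant = as.numeric(grDevices::col2rgb(grDevices::hsv(120/360, 0.80, 0.55)) / 255),
       flower = as.numeric(grDevices::col2rgb(grDevices::hsv(55/360, 0.85, 0.80)) / 255),
       background = c(0.5, 0.5, 0.5))
}

# Elliptical mask of approximately `areaPx` pixels, centred at (cy, cx),
# aspect = semi-axis ratio (rows : cols).
ellipseMask <- function(nrow, ncol, cy, cx, areaPx, aspect = 1) {
  m <- matrix(FALSE, nrow, ncol)
  if (areaPx <= 0) return(m)
  b <- sqrt(areaPx / (pi * aspect))   # col semi-axis
  a <- aspect * b                     # row semi-axis
  rows <- matrix(seq_len(nrow), nrow, ncol)
  cols <- matrix(seq_len(ncol), nrow, ncol, byrow = TRUE)
  ((rows - cy) / a)^2 + ((cols - cx) / b)^2 <= 1
}

# One rendered view: plant blob plus flower blobs (flower pixels replace
# plant pixels). Returns the raster and the exact class masks.
renderView <- function(size, plantPx, flowerPx, view, noiseSd = 0) {
  cen <- (size + 1) / 2
  aspect <- if (view == "top") 1 else 0.75      # side views sit squatter
  plantMask <- ellipseMask(size, size, cen, cen, plantPx, aspect)
  fmask <- matrix(FALSE, size, size)
  if (flowerPx > 0 && any(plantMask)) {
    # flowers sit in the upper half of the canopy, split over two blobs
    off <- sqrt(plantPx / pi) * 0.45
    f1 <- ellipseMask(size, size, cen - off, cen - off / 2, flowerPx * 0.55)
    f2 <- ellipseMask(size, size, cen - off / 2, cen + off, flowerPx * 0.45)
    fmask <- (f1 | f2) & plantMask
  }
  pmask <- plantMask & !fmask
  cols <- plantColours()
  img <- array(0, c(size, size, 3))
  for (k in 1:3) {
    ch <- matrix(cols$background[k], size, size)
    ch[pmask] <- cols$plant[k]
    ch[fmask] <- cols$flower[k]
    img[, , k] <- ch
  }
  if (noiseSd > 0)
    img <- pmin(1, pmax(0, img + array(stats::rnorm(length(img), 0, noiseSd),
                                       dim(img))))
  list(img = img, plantMask = pmask, flowerMask = fmask)
}

#' Render three-view plant images with ground truth
#'
#' Draws, for every plant and imaging day, a top view, a 0-degree side
#' view and a 90-degree side view: the plant as a green elliptical blob
#' whose area tracks the simulated biomass, flowers as yellow blobs whose
#' area tracks the simulated flowering, on an achromatic background.
#' Exact per-view plant and flower pixel counts are recorded as ground
#' truth. Pixel noise is off by default so segmentation can be tested
#' for exact recovery.
#'
#' @inheritParams simulateTraitTable
#' @param days imaging days (default from the design)
#' @return list with \code{images} (list of \code{PlantImageSet}) and
#'   \code{truth} (data frame: plantId, genotype, block, heat, drought,
#'   dat, view, plantPx, flowerPx)
#' @export
renderPlantImages <- function(design, profiles, config,
                              days = design@imagingDays) {
  if (!identical(profiles$genotype, design@genotypes))
    stop("profiles must align 1:1 with design genotypes")
  cal <- config@calibration
  grid <- expand.grid(genotype = design@genotypes,
                      block = seq_len(design@nBlocks),
                      heat = 0:1, drought = 0:1, dat = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  withSeed(subSeed(config@seed, 5), {
    images <- vector("list", nrow(grid))
    truth <- vector("list", nrow(grid))
    size <- config@imageSize
    for (i in seq_len(nrow(grid))) {
      pr <- profiles[profiles$genotype == grid$genotype[i], ]
      b <- biomassIndex(pr, grid$heat[i], grid$drought[i], grid$dat[i], config)
      f <- flowerIndex(pr, grid$heat[i], grid$drought[i], grid$dat[i], config)
      plantPx <- cal$areaScale * 100 * max(b, 0)^(2/3)
      flowerPx <- cal$areaScale * 100 * max(f, 0)^(2/3)
      id <- sprintf("%s_B%d_H%d_D%d", grid$genotype[i], grid$block[i],
                    grid$heat[i], grid$drought[i])
      views <- lapply(c(top = "top", side0 = "side0", side90 = "side90"),
                      function(v) renderView(size, plantPx, flowerPx, v,
                                             config@imageNoiseSd))
      images[[i]] <- new("PlantImageSet", plantId = id, dat = grid$dat[i],
                         mmPerPixel = config@mmPerPixel,
                         top = views$top$img, side0 = views$side0$img,
                         side90 = views$side90$img)
      truth[[i]] <- data.frame(
        plantId = id, genotype = grid$genotype[i], block = grid$block[i],
        heat = grid$heat[i], drought = grid$drought[i], dat = grid$dat[i],
        view = c("top", "side0", "side90"),
        plantPx = vapply(views, function(v) sum(v$plantMask), numeric(1)),
        flowerPx = vapply(views, function(v) sum(v$flowerMask), numeric(1)),
        stringsAsFactors = FALSE)
    }
    list(images = images, truth = do.call(rbind, truth))
  })
}

#' Write a plant image set as PNG files
#'
#' @param imageSet a \code{PlantImageSet}
#' @param dir output directory
#' @return character vector of file paths, invisibly
#' @export
writeImageSet <- function(imageSet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(c("top", "side0", "side90"), function(v) {
    f <- file.path(dir, sprintf("%s_DAT%g_%s.png", imageSet@plantId,
                                imageSet@dat, v))
    png::writePNG(slot(imageSet, v), f)
    f
  }, character(1))
  invisible(paths)
}

#' Read a plant image set from PNG files
#'
#' @param dir directory holding files written by \code{\link{writeImageSet}}
#' @param plantId,dat identify the capture
#' @param mmPerPixel pixel scale
#' @return a \code{PlantImageSet}
#' @export
readImageSet <- function(dir, plantId, dat, mmPerPixel = 1) {
  rd <- function(v) {
    a <- png::readPNG(file.path(dir, sprintf("%s_DAT%g_%s.png", plantId, dat, v)))
    if (length(dim(a)) == 3L && dim(a)[3] == 4L) a <- a[, , 1:3]
    a
  }
  new("PlantImageSet", plantId = plantId, dat = as.numeric(dat),
      mmPerPixel = as.numeric(mmPerPixel), top = rd("top"),
      side0 = rd("side0"), side90 = rd("side90"))
}
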