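# Segmentation of plant/flower pixels and volume estimation from
# three-view images.

#' Default segmentation thresholds
#'
#' HSV windows for the three pixel classes: green plant tissue, yellow
#' flowers, and implicit achromatic background. Hue in degrees [0, 360),
#' saturation in [0, 1].
#'
#' @param greenHue,yellowHue half-open hue windows, degrees
#' @param minSaturation minimum saturation for non-background pixels
#' @return named list of thresholds
#' @export
segmentationThresholds <- function(greenHue = c(70, 160),
                                   yellowHue = c(40, 70),
                                   minSaturation = 0.15) {
  list(greenHue = greenHue, yellowHue = yellowHue,
       minSaturation = minSaturation)
}

#' Classify pixels of an RGB raster
#'
#' Assigns every pixel to exactly one class: \code{flower} (hue in the
#' yellow window), \code{plant} (hue in the green window), otherwise
#' \code{background}; pixels below the minimum saturation are background
#' regardless of hue. Deterministic.
#'
#' @param image numeric array h x w x 3 with values in [0, 1]
#' @param thresholds from \code{\link{segmentationThresholds}}
#' @return list of logical matrices \code{plant} and \code{flower}
#'   (mutually exclusive)
#' @export
segmentPixels <- function(image, thresholds = segmentationThresholds()) {
  if (length(dim(image)) != 3L || dim(image)[3] < 3L)
    stop("image must be an RGB array (h x w x 3)")
  d <- dim(image)
  rgb <- rbind(as.vector(image[, , 1]), as.vector(image[, , 2]),
               as.vector(image[, , 3]))
  hsvM <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hue <- hsvM[1, ] * 360
  sat <- hsvM[2, ]
  inWin <- function(h, w) h >= w[1] & h < w[2]
  chromatic <- sat >= thresholds$minSaturation
  flower <- chromatic & inWin(hue, thresholds$yellowHue)
  plant <- chromatic & inWin(hue, thresholds$greenHue) & !flower
  list(plant = matrix(plant, d[1], d[2]),
       flower = matrix(flower, d[1], d[2]))
}

#' Projected area of a mask
#'
#' @param mask logical matrix
#' @param mmPerPixel pixel scale, mm (> 0)
#' @return area in mm^2 (pixel count times mmPerPixel squared)
#' @export
viewArea <- function(mask, mmPerPixel) {
  stopifnot(mmPerPixel > 0)
  sum(mask) * mmPerPixel^2
}

#' Per-view plant and flower areas of an image set
#'
#' @param imageSet a \code{PlantImageSet}
#' @param thresholds segmentation thresholds
#' @return data frame: view, plantArea, flowerArea (mm^2), plantPx,
#'   flowerPx
#' @export
imageSetAreas <- function(imageSet, thresholds = segmentationThresholds()) {
  out <- lapply(c("top", "side0", "side90"), function(v) {
    m <- segmentPixels(slot(imageSet, v), thresholds)
    data.frame(view = v, plantPx = sum(m$plant), flowerPx = sum(m$flower),
               plantArea = viewArea(m$plant, imageSet@mmPerPixel),
               flowerArea = viewArea(m$flower, imageSet@mmPerPixel),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plant (or flower) volume from three view areas
#'
#' The default estimator is the literal product of the three projected
#' areas, \code{top * side0 * side90} — the form used by common
#' three-view phenotyping platforms. Note its dimension is mm^6, not
#' mm^3; the \code{"geometric_mean"} estimator (product^(1/2)) and the
#' \code{"cube_root"} estimator (product^(1/3), dimensionally an area)
#' are offered as alternatives. All three are monotone transformations
#' of one another, so rank-based and correlation analyses downstream are
#' essentially invariant to the choice.
#'
#' @param top,side0,side90 view areas, mm^2 (>= 0)
#' @param estimator one of \code{"product"}, \code{"geometric_mean"},
#'   \code{"cube_root"}
#' @return volume index (zero iff any view area is zero)
#' @examples
#' plantVolume(10, 20, 30)  # 6000
#' @export
plantVolume <- function(top, side0, side90,
                        estimator = c("product", "geometric_mean",
                                      "cube_root")) {
  estimator <- match.arg(estimator)
  if (any(c(top, side0, side90) < 0)) stop("view areas must be >= 0")
  prod <- top * side0 * side90
  switch(estimator, product = prod, geometric_mean = prod^(1/2),
         cube_root = prod^(1/3))
}

#' Whole-plant and flower volumes for a set of image captures
#'
#' Segments every view of every image set and applies
#' \code{\link{plantVolume}} to the plant and flower areas.
#'
#' @param images list of \code{PlantImageSet}
#' @param thresholds segmentation thresholds
#' @param estimator volume estimator, see \code{\link{plantVolume}}
#' @return data frame: plantId, dat, volWP, volF and the per-view areas
#' @export
plantVolumes <- function(images, thresholds = segmentationThresholds(),
                         estimator = "product") {
  out <- lapply(images, function(im) {
    ar <- imageSetAreas(im, thresholds)
    data.frame(plantId = im@plantId, dat = im@dat,
               volWP = plantVolume(ar$plantArea[1], ar$plantArea[2],
                                   ar$plantArea[3], estimator),
               volF = plantVolume(ar$flowerArea[1], ar$flowerArea[2],
                                  ar$flowerArea[3], estimator),
               topPlant = ar$plantArea[1], side0Plant = ar$plantArea[2],
               side90Plant = ar$plantArea[3], topFlower = ar$flowerArea[1],
               side0Flower = ar$flowerArea[2], side90Flower = ar$flowerArea[3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Regression of plant volume on fresh weight
#'
#' Ordinary least squares of volume against fresh weight with the Pearson
#' correlation, the usual check that image-derived volume is a surrogate
#' for destructive biomass.
#'
#' @param vol,fw equal-length numeric vectors (n >= 3)
#' @return list with slope, intercept, r, n; r is NA (flagged via
#'   \code{degenerate = TRUE}) when either input has zero variance
#' @export
volumeVsWeightRegression <- function(vol, fw) {
  stopifnot(length(vol) == length(fw), length(vol) >= 3)
  ok <- is.finite(vol) & is.finite(fw)
  vol <- vol[ok]; fw <- fw[ok]
  if (stats::sd(fw) == 0 || stats::sd(vol) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
                n = length(vol), degenerate = TRUE))
  fit <- stats::lm(vol ~ fw)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(vol, fw), n = length(vol), degenerate = FALSE)
}
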