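#' Integer pixels inside an ellipse
#'
#' All integer pixel coordinates `(px, py)` with
#' `((px - x)/a)^2 + ((py - y)/b)^2 <= 1`, clipped to the image bounds.
#'
#' @param center numeric `c(x, y)`, ellipse centre (0-based, sub-pixel).
#' @param semiAxes numeric `c(a, b)`: semi-axis along x and along y, both > 0.
#' @param imageShape integer `c(height, width)`.
#' @return integer matrix with columns `x`, `y`, one row per member pixel,
#'   ordered by y then x.
#' @export
ellipsePixels <- function(center, semiAxes, imageShape) {
  a <- semiAxes[[1]]; b <- semiAxes[[2]]
  stopifnot(a > 0, b > 0)
  h <- imageShape[[1]]; w <- imageShape[[2]]
  cx <- center[[1]]; cy <- center[[2]]
  if (cx + a < 0 || cx - a > w - 1L || cy + b < 0 || cy - b > h - 1L)
    stopGeometry("quantification", "ROI outside image")
  xlo <- max(0, ceiling(cx - a)); xhi <- min(w - 1, floor(cx + a))
  ylo <- max(0, ceiling(cy - b)); yhi <- min(h - 1, floor(cy + b))
  if (xlo > xhi || ylo > yhi)
    stopGeometry("quantification", "ROI outside image")
  g <- expand.grid(x = xlo:xhi, y = ylo:yhi)
  keep <- ((g$x - cx) / a)^2 + ((g$y - cy) / b)^2 <= 1
  g <- g[keep, , drop = FALSE]
  if (!nrow(g)) stopGeometry("quantification", "ROI outside image")
  g <- g[order(g$y, g$x), , drop = FALSE]
  cbind(x = as.integer(g$x), y = as.integer(g$y))
}

#' Median luminance of one spot
#'
#' Median of the pixel values inside the elliptical ROI; with an even pixel
#' count the mean of the two middle values. The median makes the readout
#' robust to bright or dark outlier pixels covering less than half the ROI.
#'
#' @param img GrayImage matrix.
#' @param center,semiAxes ellipse as for [ellipsePixels()].
#' @return list with `median` and `nPixels`.
#' @export
measureSpot <- function(img, center, semiAxes) {
  px <- ellipsePixels(center, semiAxes, dim(img))
  vals <- img[cbind(px[, "y"] + 1L, px[, "x"] + 1L)]
  list(median = stats::median(vals), nPixels = nrow(px))
}

#' Measure every spot of the standardized grid
#'
#' One measurement per layout position, each at its reference centroid with
#' the layout ROI ellipse. Expects an image in standardized coordinates
#' (see [standardizeChip()]).
#'
#' @param img standardized GrayImage.
#' @param layout an [ArrayLayout-class].
#' @return data.frame with columns `row`, `col`, `role`, `x`, `y`,
#'   `nPixels`, `median`.
#' @export
measureGrid <- function(img, layout) {
  refs <- referenceCentroids(layout)
  e <- roiEllipse(layout)
  res <- lapply(seq_len(nrow(refs)), function(i) {
    m <- tryCatch(
      measureSpot(img, c(refs$x[i], refs$y[i]), c(e[["a"]], e[["b"]])),
      error = function(err) stopGeometry("quantification",
        sprintf("ROI for grid position (%d, %d) lies outside the image",
                refs$row[i], refs$col[i])))
    data.frame(row = refs$row[i], col = refs$col[i], role = refs$role[i],
               x = refs$x[i], y = refs$y[i],
               nPixels = m$nPixels, median = m$median)
  })
  do.call(rbind, res)
}

#' Aggregate replicate spots per role
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator, 0 for a
#' single spot) of the per-spot medians for each role. By default only the
#' inner rectangle enters: the outer control ring serves geometry only,
#' while the inner POS/NEG replicates carry the chip's quality-control and
#' normalization levels.
#'
#' @param measurements data.frame from [measureGrid()].
#' @param layout an [ArrayLayout-class].
#' @param innerOnly restrict to [innerPositions()] (default `TRUE`).
#' @return data.frame with columns `role`, `mean`, `sd`, `n`.
#' @export
aggregateRoles <- function(measurements, layout, innerOnly = TRUE) {
  scope <- measurements
  if (innerOnly) {
    inner <- innerPositions(layout)
    keep <- paste(scope$row, scope$col) %in% paste(inner$row, inner$col)
    scope <- scope[keep, , drop = FALSE]
  }
  wanted <- intersect(spotRoles(), unique(measurements$role))
  absent <- setdiff(wanted, unique(scope$role))
  if (length(absent))
    stopQC("quantification",
           sprintf("role(s) absent from aggregation scope: %s",
                   paste(absent, collapse = ", ")))
  out <- do.call(rbind, lapply(wanted, function(r) {
    v <- scope$median[scope$role == r]
    data.frame(role = r, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Background-corrected, positive-control-normalized values
#'
#' For every role, `(mean_role - mean_NEG) / (mean_POS - mean_NEG)`: the
#' negative-control background is subtracted and the span up to the positive
#' control on the same chip becomes the unit. POS maps to 1 and NEG to 0 by
#' construction; biomarker values may be negative when a spot reads below
#' background. Because gain and offset cancel, values are comparable across
#' chips with different illumination.
#'
#' @param aggregates data.frame from [aggregateRoles()].
#' @return list with `normalized` (named numeric over all roles) and `qc`
#'   (`posMean`, `negMean`, `posMinusNeg`).
#' @export
normalizeChip <- function(aggregates) {
  pos <- aggregates$mean[aggregates$role == "POS"]
  neg <- aggregates$mean[aggregates$role == "NEG"]
  if (!length(pos) || !length(neg))
    stopQC("qc", "POS and NEG aggregates are required for normalization")
  if (pos <= neg)
    stopQC("qc", "chip QC failure: positive control not above background")
  vals <- (aggregates$mean - neg) / (pos - neg)
  names(vals) <- aggregates$role
  list(normalized = vals,
       qc = list(posMean = pos, negMean = neg, posMinusNeg = pos - neg))
}

#' Round half away from zero
#'
#' Reporting convention for normalized luminance units: fixed decimals with
#' ties rounded away from zero (so -0.0015 reports as -0.002 and 0.0185 as
#' 0.019), unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfOut <- function(x, digits = 3L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Average normalized values over replicate runs
#'
#' Chip-to-chip / day-to-day replicate measurements of the same sample are
#' combined by the arithmetic mean, reported to three decimals with ties
#' rounded away from zero.
#'
#' @param values numeric vector of normalized luminance units (>= 1 value).
#' @param digits reported decimals.
#' @return the rounded mean.
#' @examples
#' combineRuns(c(0.766, 0.658))  # 0.712
#' combineRuns(c(0.004, -0.007)) # -0.002
#' @export
combineRuns <- function(values, digits = 3L) {
  if (!length(values)) stopConfig("combine", "no values to combine")
  roundHalfOut(mean(values), digits)
}

#' Default analysis configuration
#'
#' @param thresholdMethod bright-pixel segmentation, see [thresholdMask()].
#' @param thresholdValue threshold parameter (`NULL` = automatic).
#' @param minArea minimum blob area in px (`NULL` = a quarter of the ROI
#'   ellipse area).
#' @param marginFrac crop margin around the grid, in pitch units.
#' @param interpolation `"bilinear"` or `"nearest"` resampling.
#' @param luminanceMode RGB-to-luminance convention, see [toLuminance()].
#' @param innerOnly aggregate only the inner rectangle (default `TRUE`).
#' @return a named list understood by [standardizeChip()] and
#'   [analyzeChip()].
#' @export
defaultConfig <- function(thresholdMethod = "otsu", thresholdValue = NULL,
                          minArea = NULL, marginFrac = 0.75,
                          interpolation = "bilinear",
                          luminanceMode = "red_only", innerOnly = TRUE) {
  list(thresholdMethod = thresholdMethod, thresholdValue = thresholdValue,
       minArea = minArea, marginFrac = marginFrac,
       interpolation = interpolation, luminanceMode = luminanceMode,
       innerOnly = innerOnly)
}

#' Analyze one chip image end to end
#'
#' Composition of the full pipeline: image loading and luminance conversion,
#' two-stage geometric standardization, per-spot median quantification,
#' replicate aggregation and control-based normalization. Deterministic for
#' fixed inputs and configuration.
#'
#' @param image path to a PNG/TIFF/JPEG, or an in-memory GrayImage matrix /
#'   RGBImage array on the `[0, 255]` scale.
#' @param layout an [ArrayLayout-class].
#' @param config see [defaultConfig()].
#' @return a [ChipResult-class].
#' @export
analyzeChip <- function(image, layout = buildDefaultLayout(),
                        config = defaultConfig()) {
  t0 <- proc.time()[["elapsed"]]
  src <- NULL; hash <- NULL
  if (is.character(image)) {
    src <- image
    hash <- unname(tools::md5sum(image))
    image <- loadImage(image)
  }
  gray <- if (is.matrix(image)) image else toLuminance(image, config$luminanceMode)
  std <- standardizeChip(gray, layout, config, details = TRUE)
  t1 <- proc.time()[["elapsed"]]
  meas <- measureGrid(std$image, layout)
  agg <- aggregateRoles(meas, layout, config$innerOnly)
  norm <- normalizeChip(agg)
  t2 <- proc.time()[["elapsed"]]
  new("ChipResult",
      spots = meas, aggregates = agg,
      normalized = norm$normalized[biomarkerRoles()
        [biomarkerRoles() %in% names(norm$normalized)]],
      qc = norm$qc,
      metadata = list(
        source = src, md5 = hash, config = config,
        anchorsRaw = nrow(anchorPairs(std$matchRaw)),
        anchorsAffine = nrow(anchorPairs(std$matchAffine)),
        affineResidual = anchorResidual(std$matchRaw),
        quadResidual = std$quadResidual,
        timings = c(geometry = t1 - t0, quantification = t2 - t1)))
}

#' @rdname chipAccessors
#' @export
setGeneric("spotMeasurements", function(x) standardGeneric("spotMeasurements"))
#' ChipResult accessors
#'
#' @param x a [ChipResult-class].
#' @return `spotMeasurements()`: per-spot data.frame; `roleAggregates()`:
#'   per-role mean/sd/n; `normalizedValues()`: named numeric of normalized
#'   biomarker values; `chipQC()`: list with `posMean`, `negMean`,
#'   `posMinusNeg`.
#' @name chipAccessors
#' @export
setMethod("spotMeasurements", "ChipResult", function(x) x@spots)

#' @rdname chipAccessors
#' @export
setGeneric("roleAggregates", function(x) standardGeneric("roleAggregates"))
#' @rdname chipAccessors
#' @export
setMethod("roleAggregates", "ChipResult", function(x) x@aggregates)

#' @rdname chipAccessors
#' @export
setGeneric("normalizedValues", function(x) standardGeneric("normalizedValues"))
#' @rdname chipAccessors
#' @export
setMethod("normalizedValues", "ChipResult", function(x) x@normalized)

#' @rdname chipAccessors
#' @export
setGeneric("chipQC", function(x) standardGeneric("chipQC"))
#' @rdname chipAccessors
#' @export
setMethod("chipQC", "ChipResult", function(x) x@qc)

setMethod("show", "ChipResult", function(object) {
  cat("ChipResult\n")
  cat(sprintf("  QC: POS %.2f, NEG %.2f (span %.2f)\n",
              object@qc$posMean, object@qc$negMean, object@qc$posMinusNeg))
  cat("  normalized luminance units:\n")
  for (r in names(object@normalized))
    cat(sprintf("    %-9s %8.3f\n", r, object@normalized[[r]]))
})
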