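#' Apply a 2-D transform to coordinates
#'
#' @param transform an [AffineTransform2D-class] or
#'   [QuadraticTransform2D-class].
#' @param xy numeric matrix with columns x, y (0-based pixel coordinates).
#' @return matrix of mapped coordinates, same shape as `xy`.
#' @export
setGeneric("applyTransform", function(transform, xy)
  standardGeneric("applyTransform"))

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "AffineTransform2D", function(transform, xy) {
  xy <- rbind(xy)
  k <- transform@coef
  cbind(k[[1]] * xy[, 1L] + k[[2]] * xy[, 2L] + k[[3]],
        k[[4]] * xy[, 1L] + k[[5]] * xy[, 2L] + k[[6]])
})

## monomial basis {1, x, y, x^2, xy, y^2}
.quadBasis <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "QuadraticTransform2D", function(transform, xy) {
  xy <- rbind(xy)
  B <- .quadBasis(xy[, 1L], xy[, 2L])
  cbind(drop(B %*% transform@px), drop(B %*% transform@py))
})

setMethod("show", "AffineTransform2D", function(object) {
  k <- object@coef
  cat(sprintf(paste0("AffineTransform2D: x' = %.4g x + %.4g y + %.4g; ",
                     "y' = %.4g x + %.4g y + %.4g\n"),
              k[[1]], k[[2]], k[[3]], k[[4]], k[[5]], k[[6]]))
})

setMethod("show", "QuadraticTransform2D", function(object) {
  cat("QuadraticTransform2D\n  px:", signif(object@px, 4),
      "\n  py:", signif(object@py, 4), "\n")
})

#' Least-squares affine transform from point correspondences
#'
#' Fits the 6-coefficient map minimizing the summed squared distance between
#' mapped source points and targets. With exactly three non-collinear pairs
#' the fit interpolates (residual zero).
#'
#' @param src,dst numeric matrices with columns x, y; `src` maps onto `dst`.
#' @return an [AffineTransform2D-class].
#' @export
estimateAffine <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) < 3L || nrow(src) != nrow(dst))
    stopGeometry("geometry", "underdetermined affine: need >= 3 point pairs")
  X <- cbind(src[, 1L], src[, 2L], 1)
  qx <- qr(X)
  if (qx$rank < 3L)
    stopGeometry("geometry", "underdetermined affine: source points collinear")
  cf <- qr.coef(qx, dst)
  new("AffineTransform2D",
      coef = c(a = cf[1L, 1L], b = cf[2L, 1L], c = cf[3L, 1L],
               d = cf[1L, 2L], e = cf[2L, 2L], f = cf[3L, 2L]))
}

#' Least-squares quadratic polynomial transform
#'
#' Fits the 12-coefficient degree-2 map over the monomial basis
#' `{1, x, y, x^2, xy, y^2}`, independently for the x' and y' outputs. With
#' exactly six rank-complete pairs the fit interpolates; applied to data
#' generated by an affine map the quadratic coefficients vanish.
#'
#' @param src,dst numeric matrices with columns x, y; `src` maps onto `dst`.
#' @return a [QuadraticTransform2D-class].
#' @export
fitQuadratic <- function(src, dst) {
  src <- rbind(src); dst <- rbind(dst)
  if (nrow(src) < 6L || nrow(src) != nrow(dst))
    stopGeometry("geometry", "underdetermined quadratic: need >= 6 point pairs")
  X <- .quadBasis(src[, 1L], src[, 2L])
  qx <- qr(X)
  if (qx$rank < 6L)
    stopGeometry("geometry", "underdetermined quadratic: rank-deficient design")
  cf <- qr.coef(qx, dst)
  new("QuadraticTransform2D", px = unname(cf[, 1L]), py = unname(cf[, 2L]))
}

#' Invert an affine transform
#'
#' @param transform an [AffineTransform2D-class].
#' @return the inverse [AffineTransform2D-class].
#' @export
invertAffine <- function(transform) {
  k <- transform@coef
  det <- k[[1]] * k[[5]] - k[[2]] * k[[4]]
  ia <- k[[5]] / det; ib <- -k[[2]] / det
  id <- -k[[4]] / det; ie <- k[[1]] / det
  new("AffineTransform2D",
      coef = c(a = ia, b = ib, c = -(ia * k[[3]] + ib * k[[6]]),
               d = id, e = ie, f = -(id * k[[3]] + ie * k[[6]])))
}

## affine part of a quadratic map (used to seed Newton inversion)
.affinePart <- function(tq) {
  new("AffineTransform2D",
      coef = c(a = tq@px[[2]], b = tq@px[[3]], c = tq@px[[1]],
               d = tq@py[[2]], e = tq@py[[3]], f = tq@py[[1]]))
}

## Newton inversion of a QuadraticTransform2D at target coordinates.
## Returns list(x, y, converged). Vectorized over all targets; the 2x2
## Jacobian is inverted in closed form.
.invertQuadratic <- function(tq, tx, ty, tol = 1e-6, maxIter = 20L) {
  seed <- applyTransform(invertAffine(.affinePart(tq)), cbind(tx, ty))
  x <- seed[, 1L]; y <- seed[, 2L]
  p <- tq@px; q <- tq@py
  for (i in seq_len(maxIter)) {
    fx <- p[[1]] + p[[2]] * x + p[[3]] * y + p[[4]] * x^2 + p[[5]] * x * y +
      p[[6]] * y^2 - tx
    fy <- q[[1]] + q[[2]] * x + q[[3]] * y + q[[4]] * x^2 + q[[5]] * x * y +
      q[[6]] * y^2 - ty
    ## diverged pixels go NaN; they are flagged unconverged at the end
    resid <- abs(c(fx, fy))
    resid <- resid[is.finite(resid)]
    if (!length(resid) || max(resid) < tol) break
    j11 <- p[[2]] + 2 * p[[4]] * x + p[[5]] * y
    j12 <- p[[3]] + p[[5]] * x + 2 * p[[6]] * y
    j21 <- q[[2]] + 2 * q[[4]] * x + q[[5]] * y
    j22 <- q[[3]] + q[[5]] * x + 2 * q[[6]] * y
    det <- j11 * j22 - j12 * j21
    det[abs(det) < 1e-12] <- NA
    x <- x - (j22 * fx - j12 * fy) / det
    y <- y - (-j21 * fx + j11 * fy) / det
  }
  fx <- applyTransform(tq, cbind(x, y)) - cbind(tx, ty)
  conv <- is.finite(x) & is.finite(y) &
    abs(fx[, 1L]) < 10 * tol & abs(fx[, 2L]) < 10 * tol
  list(x = x, y = y, converged = conv)
}

#' Resample an image through a geometric transform
#'
#' The transform maps input-image coordinates to output coordinates; each
#' output pixel is filled with the interpolated input value at the
#' inverse-mapped position (closed-form inverse for affine maps, per-pixel
#' Newton iteration seeded at the affine-part inverse for quadratic maps).
#' Positions falling outside the input are filled with 0, the dark
#' background of fluorescence imaging.
#'
#' @param img GrayImage matrix.
#' @param transform [AffineTransform2D-class] or
#'   [QuadraticTransform2D-class], mapping input to output coordinates.
#' @param outShape integer `c(height, width)` of the output.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return GrayImage matrix of shape `outShape`.
#' @export
warpImage <- function(img, transform, outShape = dim(img),
                      interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  h <- as.integer(outShape[[1]]); w <- as.integer(outShape[[2]])
  ox <- rep(0:(w - 1L), each = h)
  oy <- rep(0:(h - 1L), times = w)
  if (is(transform, "AffineTransform2D")) {
    s <- applyTransform(invertAffine(transform), cbind(ox, oy))
    sx <- s[, 1L]; sy <- s[, 2L]
  } else if (is(transform, "QuadraticTransform2D")) {
    inv <- .invertQuadratic(transform, ox, oy)
    if (mean(!inv$converged) > 0.01)
      stopGeometry("geometry",
        sprintf("non-invertible warp over domain: %.1f%% of pixels failed",
                100 * mean(!inv$converged)))
    sx <- inv$x; sy <- inv$y
    sx[!inv$converged] <- -1e6; sy[!inv$converged] <- -1e6
  } else {
    stopGeometry("geometry", "unsupported transform type")
  }
  v <- if (interpolation == "bilinear") .sampleBilinear(img, sx, sy)
       else .sampleNearest(img, sx, sy)
  matrix(v, h, w)
}

#' Crop an image to the area containing the spots
#'
#' Maps the reference grid into image coordinates through the inverse of the
#' anchor-match affine, takes the bounding box of the mapped grid, extends
#' it by `marginFrac` of the pitch on each side and clamps it to the image.
#'
#' @param img GrayImage matrix.
#' @param match an [AnchorMatch-class] (its transform maps image to
#'   reference coordinates).
#' @param layout an [ArrayLayout-class].
#' @param marginFrac margin in pitch units added on every side.
#' @return list with `image` (the cropped GrayImage) and `window`
#'   (`c(xmin, ymin, xmax, ymax)`, integer pixel bounds in the input image).
#' @export
cropToSpots <- function(img, match, layout, marginFrac = 0.75) {
  refs <- referenceCentroids(layout)
  inImg <- applyTransform(invertAffine(match@transform),
                          cbind(refs$x, refs$y))
  mx <- marginFrac * spotPitch(layout)[["col"]]
  my <- marginFrac * spotPitch(layout)[["row"]]
  ## guard floor/ceiling against floating-point jitter at integer bounds
  xmin <- as.integer(max(0, floor(min(inImg[, 1L]) - mx + 1e-9)))
  xmax <- as.integer(min(ncol(img) - 1, ceiling(max(inImg[, 1L]) + mx - 1e-9)))
  ymin <- as.integer(max(0, floor(min(inImg[, 2L]) - my + 1e-9)))
  ymax <- as.integer(min(nrow(img) - 1, ceiling(max(inImg[, 2L]) + my - 1e-9)))
  if (xmin >= xmax || ymin >= ymax)
    stopGeometry("geometry", "crop window collapsed to zero area")
  list(image = img[(ymin:ymax) + 1L, (xmin:xmax) + 1L, drop = FALSE],
       window = c(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax))
}

#' Standardize an aberrated chip image
#'
#' The full two-stage geometric correction. Bright anchors are detected and
#' matched to the positive-control layout positions; an affine transform
#' (detected to reference coordinates) removes shear, rotation, scale and
#' translation while resampling directly into the standardized window (the
#' grid bounding box plus margin, which realizes the "cut to the spot area"
#' step); POS anchors are then re-detected in the corrected image and a
#' quadratic polynomial transform removes the residual smooth curvature.
#' In the result, spot centroids sit at [referenceCentroids()].
#'
#' @param img GrayImage matrix of the raw (aberrated) chip.
#' @param layout an [ArrayLayout-class].
#' @param config analysis configuration, see [defaultConfig()].
#' @param details if `TRUE` return diagnostics along with the image.
#' @return the standardized GrayImage, or (with `details = TRUE`) a list
#'   with `image`, `affine`, `quadratic`, `matchRaw`, `matchAffine`,
#'   `postAffine` (intermediate image) and `quadResidual` (RMS px of the
#'   quadratic fit).
#' @export
standardizeChip <- function(img, layout = buildDefaultLayout(),
                            config = defaultConfig(), details = FALSE) {
  minArea <- if (is.null(config$minArea)) .defaultMinArea(layout)
             else config$minArea
  stdSh <- standardShape(layout, config$marginFrac)
  detect <- function(im) {
    mask <- thresholdMask(im, config$thresholdMethod, config$thresholdValue,
                          layout)
    findBlobs(mask, minArea)
  }
  m1 <- matchAnchors(detect(img), layout)
  p1 <- anchorPairs(m1)
  if (nrow(p1) < 3L)
    stopDetection("detection", "fewer than 3 POS anchors matched")
  aff <- estimateAffine(cbind(p1$obsX, p1$obsY), cbind(p1$refX, p1$refY))
  imgA <- warpImage(img, aff, stdSh, config$interpolation)
  m2 <- matchAnchors(detect(imgA), layout)
  p2 <- anchorPairs(m2)
  if (nrow(p2) < 6L)
    stopGeometry("geometry",
      sprintf("only %d POS anchors matched after affine correction; need 6",
              nrow(p2)))
  quad <- fitQuadratic(cbind(p2$obsX, p2$obsY), cbind(p2$refX, p2$refY))
  out <- warpImage(imgA, quad, stdSh, config$interpolation)
  if (!details) return(out)
  fitted <- applyTransform(quad, cbind(p2$obsX, p2$obsY))
  qres <- sqrt(mean((fitted[, 1L] - p2$refX)^2 + (fitted[, 2L] - p2$refY)^2))
  list(image = out, affine = aff, quadratic = quad,
       matchRaw = m1, matchAffine = m2, postAffine = imgA,
       quadResidual = qres)
}
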