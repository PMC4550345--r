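#' Threshold an image into a bright-pixel mask
#'
#' Separates "illuminating" pixels from background. Otsu's method is the
#' default: it finds the threshold between the background mode and the
#' bright-spot mode of the intensity histogram and is insensitive to how
#' many spots are actually lit and to smooth background gradients.
#' `"fixed"` marks every pixel `>= value`; `"quantile"` uses the empirical
#' `value` quantile of all pixels as the threshold (pixels `>=` threshold),
#' and when `value` is `NULL` defaults to `1 - 1.5 *` (total spot-ROI area /
#' image area) for the supplied layout.
#'
#' @param img GrayImage matrix.
#' @param method `"otsu"`, `"fixed"` or `"quantile"`.
#' @param value threshold for `"fixed"` (in `[0, 255]`) or probability for
#'   `"quantile"` (in (0, 1)).
#' @param layout optional [ArrayLayout-class], used only for the automatic
#'   quantile probability.
#' @return logical matrix of the same shape, `TRUE` for bright pixels.
#' @export
thresholdMask <- function(img, method = c("otsu", "fixed", "quantile"),
                          value = NULL, layout = NULL) {
  method <- match.arg(method)
  if (method == "otsu") {
    if (diff(range(img)) < .Machine$double.eps)
      stopDetection("detection", "constant image: no bimodal separation for Otsu")
    thr <- EBImage::otsu(EBImage::Image(img / 255), range = c(0, 1),
                         levels = 256L) * 255
    return(img > thr)
  }
  if (method == "fixed") {
    if (is.null(value) || value < 0 || value > 255)
      stopConfig("detection", "fixed threshold requires value in [0, 255]")
    return(img >= value)
  }
  if (is.null(value)) {
    if (is.null(layout))
      stopConfig("detection", "quantile threshold needs a value or a layout")
    e <- roiEllipse(layout)
    frac <- nSpots(layout) * pi * e[["a"]] * e[["b"]] / length(img)
    value <- min(max(1 - 1.5 * frac, 0.5), 0.995)
  }
  if (value <= 0 || value >= 1)
    stopConfig("detection", "quantile threshold requires value in (0, 1)")
  img >= stats::quantile(img, value, names = FALSE)
}

#' Find connected bright regions
#'
#' Labels 8-connected components of a binary mask and returns one blob per
#' component with at least `minArea` pixels. The centroid is the unweighted
#' mean of the member pixel coordinates; blobs are ordered by centroid
#' y, then x, so the result is independent of labeling order.
#'
#' @param mask logical matrix from [thresholdMask()].
#' @param minArea minimum pixel count for a component to be kept (>= 1).
#' @return data.frame with one row per blob: centroid `x`, `y` (0-based,
#'   sub-pixel), `area`, and bounding box `xmin`, `ymin`, `xmax`, `ymax`.
#'   Zero rows when nothing qualifies.
#' @export
findBlobs <- function(mask, minArea = 1L) {
  stopifnot(is.matrix(mask), minArea >= 1)
  empty <- data.frame(x = numeric(), y = numeric(), area = integer(),
                      xmin = integer(), ymin = integer(),
                      xmax = integer(), ymax = integer())
  idx <- which(mask)
  if (!length(idx)) return(empty)
  h <- nrow(mask); w <- ncol(mask)
  ## 8-connectivity as a graph over bright pixels: four forward offsets
  edgeSet <- function(sel, off) {
    a <- which(sel & mask)
    a <- a[mask[a + off]]
    cbind(a, a + off)
  }
  notLastRow <- row(mask) < h
  notLastCol <- col(mask) < w
  notFirstCol <- col(mask) > 1L
  edges <- rbind(
    edgeSet(notLastRow, 1L),                    # down
    edgeSet(notLastCol, h),                     # right
    edgeSet(notLastRow & notLastCol, h + 1L),   # down-right
    edgeSet(notLastRow & notFirstCol, -h + 1L)  # down-left
  )
  vid <- match(idx, idx)
  g <- igraph::graph_from_edgelist(
    cbind(match(edges[, 1L], idx), match(edges[, 2L], idx)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[vid]
  x0 <- (idx - 1L) %/% h          # 0-based column
  y0 <- (idx - 1L) %% h           # 0-based row
  cx <- tapply(x0, comp, mean); cy <- tapply(y0, comp, mean)
  out <- data.frame(
    x = as.numeric(cx), y = as.numeric(cy),
    area = as.integer(tapply(idx, comp, length)),
    xmin = as.integer(tapply(x0, comp, min)),
    ymin = as.integer(tapply(y0, comp, min)),
    xmax = as.integer(tapply(x0, comp, max)),
    ymax = as.integer(tapply(y0, comp, max))
  )
  out <- out[out$area >= minArea, , drop = FALSE]
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## default minimum blob area: a quarter of the ROI ellipse pixel count
.defaultMinArea <- function(layout) {
  e <- roiEllipse(layout)
  max(1L, as.integer(round(0.25 * pi * e[["a"]] * e[["b"]])))
}

#' Match detected blobs to positive-control layout positions
#'
#' Establishes the blob-to-grid correspondence used to estimate the
#' geometric correction. Only POS positions are targeted: the positive
#' control is always labelled and therefore reliably bright, while negative
#' controls sit at background level. The strategy is corner-first:
#'
#' 1. the four blobs most extreme in the four diagonal directions from the
#'    blob-cloud centroid are assigned to the four POS corner positions,
#'    preserving orientation (top-left to top-left, etc.);
#' 2. a provisional affine map (image to reference coordinates) is fitted
#'    on those four pairs;
#' 3. remaining blobs are greedily matched to the nearest unclaimed POS
#'    reference centroid within `0.4 * min(pitch)` of their mapped position;
#'    unmatched references are allowed and each blob is used at most once.
#'
#' @param blobs data.frame from [findBlobs()] (>= 4 rows).
#' @param layout an [ArrayLayout-class].
#' @return an [AnchorMatch-class] with all matched pairs, the provisional
#'   affine and the RMS residual (px) under it.
#' @export
matchAnchors <- function(blobs, layout) {
  if (nrow(blobs) < 4L)
    stopDetection("detection",
      sprintf("insufficient anchors: %d blob(s) found, need at least 4",
              nrow(blobs)))
  refs <- referenceCentroids(layout)
  posRefs <- refs[refs$role == "POS", , drop = FALSE]
  corners <- data.frame(
    row = c(0L, 0L, layout@nRows - 1L, layout@nRows - 1L),
    col = c(0L, layout@nCols - 1L, layout@nCols - 1L, 0L))
  ## quadrant scores relative to the blob-cloud centroid
  dx <- blobs$x - mean(blobs$x); dy <- blobs$y - mean(blobs$y)
  scores <- cbind(-dx - dy, dx - dy, dx + dy, -dx + dy)  # TL TR BR BL
  pick <- integer(4L)
  for (k in 1:4) {
    s <- scores[, k]
    o <- order(s, decreasing = TRUE)
    if (length(s) > 1L && s[o[1L]] - s[o[2L]] < 1)
      stopDetection("detection",
        "degenerate anchor geometry: ambiguous corner candidate")
    pick[k] <- o[1L]
  }
  if (anyDuplicated(pick))
    stopDetection("detection",
      "degenerate anchor geometry: one blob claims two corners")
  cref <- merge(corners, refs, sort = FALSE)
  cref <- cref[match(paste(corners$row, corners$col),
                     paste(cref$row, cref$col)), ]
  prov <- estimateAffine(cbind(blobs$x[pick], blobs$y[pick]),
                         cbind(cref$x, cref$y))
  ## greedy global-minimum matching of all blobs to POS references
  mapped <- applyTransform(prov, cbind(blobs$x, blobs$y))
  d <- outer(seq_len(nrow(blobs)), seq_len(nrow(posRefs)),
             function(i, j) sqrt((mapped[i, 1L] - posRefs$x[j])^2 +
                                 (mapped[i, 2L] - posRefs$y[j])^2))
  radius <- 0.4 * min(spotPitch(layout))
  pairs <- list()
  repeat {
    if (!any(is.finite(d)) || min(d, na.rm = TRUE) > radius) break
    hit <- which(d == min(d, na.rm = TRUE), arr.ind = TRUE)
    ## deterministic tie-break: reference order, then blob order
    hit <- hit[order(hit[, 2L], hit[, 1L]), , drop = FALSE][1L, ]
    bi <- hit[[1L]]; ri <- hit[[2L]]
    pairs[[length(pairs) + 1L]] <- data.frame(
      row = posRefs$row[ri], col = posRefs$col[ri],
      refX = posRefs$x[ri], refY = posRefs$y[ri],
      obsX = blobs$x[bi], obsY = blobs$y[bi])
    d[bi, ] <- Inf; d[, ri] <- Inf
  }
  if (!length(pairs))
    stopDetection("detection", "no blob matched any positive-control position")
  pairs <- do.call(rbind, pairs)
  pairs <- pairs[order(pairs$row, pairs$col), , drop = FALSE]
  rownames(pairs) <- NULL
  m <- applyTransform(prov, cbind(pairs$obsX, pairs$obsY))
  rms <- sqrt(mean((m[, 1L] - pairs$refX)^2 + (m[, 2L] - pairs$refY)^2))
  new("AnchorMatch", pairs = pairs, residual = rms, transform = prov)
}

setMethod("show", "AnchorMatch", function(object) {
  cat(sprintf("AnchorMatch: %d matched POS anchors, RMS residual %.3f px\n",
              nrow(object@pairs), object@residual))
})

#' @rdname anchorAccessors
#' @export
setGeneric("anchorPairs", function(x) standardGeneric("anchorPairs"))
#' AnchorMatch accessors
#'
#' @param x an [AnchorMatch-class].
#' @return `anchorPairs()`: the matched-pair data.frame;
#'   `anchorResidual()`: the RMS residual in px.
#' @name anchorAccessors
#' @export
setMethod("anchorPairs", "AnchorMatch", function(x) x@pairs)

#' @rdname anchorAccessors
#' @export
setGeneric("anchorResidual", function(x) standardGeneric("anchorResidual"))
#' @rdname anchorAccessors
#' @export
setMethod("anchorResidual", "AnchorMatch", function(x) x@residual)
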