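## Synthetic smartphone-like chip images with known ground truth.
##
## The aberration maps reference (standardized) coordinates to image
## coordinates as an affine map (rotation, shear, scale, translation about
## the grid/image centres) followed by a quadratic "bow" in the image frame.
## Because the bow is a degree-2 polynomial of an affine map, the full
## forward map is itself an exact QuadraticTransform2D, so ground-truth
## centroids are available in closed form.

.defaultAmplitudes <- c(RBST = 120, IGF1_100 = 60, IGF1_250 = 90,
                        POS = 180, NEG = 5)

#' Build a synthetic scene specification
#'
#' Fixes every ingredient of a rendered chip image: spot amplitudes on top
#' of the background, a flat-ellipse spot profile with Gaussian edge
#' softening, a background made of a base level, a linear gradient and a
#' corner vignette, a mild geometric aberration (the images this emulates
#' were all slightly sheared and curved), and a two-component noise model
#' (additive read noise plus a signal-proportional term approximating shot
#' noise under a high-gain night-mode camera).
#'
#' @param layout an [ArrayLayout-class].
#' @param amplitudes named numeric per role, intensity above background in
#'   `[0, 255]`.
#' @param spotOverrides data.frame (`row`, `col`, `amplitude`) overriding
#'   single spots (e.g. to occlude an anchor).
#' @param profile list `type` (`"flat_ellipse"` or `"gaussian"`), `blurSd`
#'   (edge softening, px) and `spotScale`: printed-spot semi-axes as a
#'   multiple of the ROI ellipse (spots overfill the quantification ROI, so
#'   the ROI samples the plateau, not the blurred edge).
#' @param background list `base`, `gradient` (`c(gx, gy)` total drop across
#'   the image), `vignette` (corner darkening).
#' @param aberration list `rotation` and `shear` (degrees), `scale`
#'   (`c(sx, sy)`), `translation` (`c(tx, ty)` px), `bow` (`c(bx, by)` px of
#'   corner displacement from the quadratic term).
#' @param noise list `sd` (additive Gaussian) and `scale`
#'   (signal-proportional).
#' @param imageShape integer `c(height, width)`; default 1.25 x the
#'   standardized shape.
#' @param greenBleed fraction of red signal copied into the green channel.
#' @param seed integer fixing all randomness of [renderScene()].
#' @return a validated [SceneSpec-class].
#' @export
sceneSpec <- function(layout = buildDefaultLayout(),
                      amplitudes = .defaultAmplitudes,
                      spotOverrides = NULL,
                      profile = list(type = "flat_ellipse", blurSd = 1.5,
                                     spotScale = 1.25),
                      background = list(base = 25, gradient = c(6, 4),
                                        vignette = 8),
                      aberration = list(rotation = 2, shear = 4,
                                        scale = c(1.02, 0.98),
                                        translation = c(5, -4),
                                        bow = c(4, -3)),
                      noise = list(sd = 3, scale = 0.05),
                      imageShape = NULL, greenBleed = 0.1, seed = 1L) {
  amps <- .defaultAmplitudes
  amps[names(amplitudes)] <- amplitudes
  if (is.null(spotOverrides))
    spotOverrides <- data.frame(row = integer(), col = integer(),
                                amplitude = numeric())
  if (is.null(imageShape)) {
    sh <- standardShape(layout)
    imageShape <- as.integer(round(sh * 1.25))
  }
  spec <- new("SceneSpec",
    layout = layout, amplitudes = amps, spotOverrides = spotOverrides,
    profile = profile, background = background, aberration = aberration,
    noise = noise, imageShape = as.integer(imageShape),
    greenBleed = greenBleed, seed = as.integer(seed))
  .validateScene(spec)
  spec
}

.validateScene <- function(spec) {
  bgMax <- spec@background$base + sum(abs(spec@background$gradient))
  if (max(spec@amplitudes) + bgMax > 255)
    stopConfig("simulate",
      "amplitudes plus background exceed 255 before noise")
  if (any(spec@amplitudes < 0))
    stopConfig("simulate", "amplitudes must be non-negative")
  scl <- if (is.null(spec@profile$spotScale)) 1.25 else spec@profile$spotScale
  e <- roiEllipse(spec@layout); p <- spotPitch(spec@layout)
  if (scl * e[["a"]] >= p[["col"]] / 2 || scl * e[["b"]] >= p[["row"]] / 2)
    stopConfig("simulate", "spotScale makes printed spots overlap")
  fwd <- .sceneForwardMap(spec)
  ## invertibility of the forward map over the reference canvas
  sh <- standardShape(spec@layout)
  gx <- seq(0, sh[["width"]] - 1, length.out = 9)
  gy <- seq(0, sh[["height"]] - 1, length.out = 9)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  p <- fwd@px; q <- fwd@py
  j11 <- p[[2]] + 2 * p[[4]] * g[, 1] + p[[5]] * g[, 2]
  j12 <- p[[3]] + p[[5]] * g[, 1] + 2 * p[[6]] * g[, 2]
  j21 <- q[[2]] + 2 * q[[4]] * g[, 1] + q[[5]] * g[, 2]
  j22 <- q[[3]] + q[[5]] * g[, 1] + 2 * q[[6]] * g[, 2]
  if (any(j11 * j22 - j12 * j21 < 0.1))
    stopConfig("simulate",
      "aberration bow too strong: forward map not invertible over the grid")
  invisible(TRUE)
}

## Forward aberration as an exact QuadraticTransform2D
## (reference coords -> image coords).
.sceneForwardMap <- function(spec) {
  ab <- spec@aberration
  sh <- standardShape(spec@layout)
  h <- spec@imageShape[[1]]; w <- spec@imageShape[[2]]
  th <- ab$rotation * pi / 180
  shr <- tan(ab$shear * pi / 180)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L)
  S <- matrix(c(1, 0, shr, 1), 2L)
  M <- R %*% S %*% diag(ab$scale)
  cRef <- c((sh[["width"]] - 1) / 2, (sh[["height"]] - 1) / 2)
  cImg <- c((w - 1) / 2, (h - 1) / 2)
  ## affine part: p -> M (p - cRef) + cImg + t
  aff <- c(M[1, 1], M[1, 2], cImg[1] + ab$translation[[1]] -
             sum(M[1, ] * cRef),
           M[2, 1], M[2, 2], cImg[2] + ab$translation[[2]] -
             sum(M[2, ] * cRef))
  ## bow in the image frame:
  ##   x' = X + bx ((Y - cy)/hy)^2,  y' = Y + by ((X - cx)/hx)^2
  hx <- (w - 1) / 2; hy <- (h - 1) / 2
  bx <- ab$bow[[1]] / hy^2; by <- ab$bow[[2]] / hx^2
  A <- aff
  ## X = A1 x + A2 y + A3 ; Y = A4 x + A5 y + A6 (reference coords x, y);
  ## the bow is centred on the image centre, so substituting the affine into
  ## the squared terms expands to an exact degree-2 polynomial
  u <- c(A[4], A[5], A[6] - cImg[2])      # Y - cy
  px <- c(A[3] + bx * u[3]^2,
          A[1] + bx * 2 * u[1] * u[3],
          A[2] + bx * 2 * u[2] * u[3],
          bx * u[1]^2, bx * 2 * u[1] * u[2], bx * u[2]^2)
  v <- c(A[1], A[2], A[3] - cImg[1])      # X - cx
  py <- c(A[6] + by * v[3]^2,
          A[4] + by * 2 * v[1] * v[3],
          A[5] + by * 2 * v[2] * v[3],
          by * v[1]^2, by * 2 * v[1] * v[2], by * v[2]^2)
  new("QuadraticTransform2D", px = px, py = py)
}

## per-spot amplitudes after overrides, aligned with referenceCentroids()
.spotAmplitudes <- function(spec) {
  refs <- referenceCentroids(spec@layout)
  amp <- unname(spec@amplitudes[refs$role])
  ov <- spec@spotOverrides
  if (nrow(ov)) {
    i <- match(paste(ov$row, ov$col), paste(refs$row, refs$col))
    if (anyNA(i)) stopConfig("simulate", "spot override outside the grid")
    amp[i] <- ov$amplitude
  }
  amp
}

#' Ground-truth normalized values of a scene
#'
#' `(amplitude_role - amplitude_NEG) / (amplitude_POS - amplitude_NEG)` per
#' biomarker role; POS is 1 and NEG is 0 by construction.
#'
#' @param spec a [SceneSpec-class].
#' @return named numeric over the biomarker roles.
#' @export
sceneTruthNormalized <- function(spec) {
  a <- spec@amplitudes
  out <- (a[biomarkerRoles()] - a[["NEG"]]) / (a[["POS"]] - a[["NEG"]])
  out
}

#' Render a synthetic chip image
#'
#' Draws the reference-grid spots (flat ellipses, optionally Gaussian
#' profiles), maps them through the aberration, softens edges with a
#' Gaussian blur, adds the background field and sensor noise, clips to
#' `[0, 255]` and quantizes to 8 bit. The QD signal is placed in the red
#' channel with a configurable green bleed. Identical seed, identical image.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `image` (RGBImage array, `[0, 255]`), `gray` (the red
#'   channel as GrayImage) and `truth`: per-spot data.frame (grid position,
#'   role, reference and post-aberration image centroids, amplitude), the
#'   normalized truth per biomarker role, and the forward map.
#' @export
renderScene <- function(spec) {
  stopifnot(is(spec, "SceneSpec"))
  orng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(orng)) assign(".Random.seed", orng, globalenv()))
  set.seed(spec@seed)

  layout <- spec@layout
  refs <- referenceCentroids(layout)
  amp <- .spotAmplitudes(spec)
  sh <- standardShape(layout)
  e <- roiEllipse(layout)

  ## reference-frame signal canvas (spots only, no background)
  refCanvas <- matrix(0, sh[["height"]], sh[["width"]])
  scl <- if (is.null(spec@profile$spotScale)) 1.25 else spec@profile$spotScale
  sa <- scl * e[["a"]]; sb <- scl * e[["b"]]
  for (i in seq_len(nrow(refs))) {
    if (amp[i] <= 0) next
    if (identical(spec@profile$type, "gaussian")) {
      xs <- 0:(sh[["width"]] - 1); ys <- 0:(sh[["height"]] - 1)
      gx <- exp(-2 * ((xs - refs$x[i]) / sa)^2)
      gy <- exp(-2 * ((ys - refs$y[i]) / sb)^2)
      refCanvas <- refCanvas + amp[i] * outer(gy, gx)
    } else {
      px <- ellipsePixels(c(refs$x[i], refs$y[i]), c(sa, sb), dim(refCanvas))
      refCanvas[cbind(px[, "y"] + 1L, px[, "x"] + 1L)] <- amp[i]
    }
  }

  fwd <- .sceneForwardMap(spec)
  signal <- warpImage(refCanvas, fwd, spec@imageShape, "bilinear")
  if (spec@profile$blurSd > 0)
    signal <- EBImage::gblur(signal, sigma = spec@profile$blurSd)

  h <- spec@imageShape[[1]]; w <- spec@imageShape[[2]]
  xs <- matrix(rep(0:(w - 1L), each = h), h, w)
  ys <- matrix(rep(0:(h - 1L), times = w), h, w)
  bg <- spec@background$base +
    spec@background$gradient[[1]] * xs / (w - 1) +
    spec@background$gradient[[2]] * ys / (h - 1) -
    spec@background$vignette *
      (((xs / (w - 1) - 0.5) * 2)^2 + ((ys / (h - 1) - 0.5) * 2)^2) / 2
  clean <- signal + bg
  noisy <- clean +
    stats::rnorm(length(clean), 0, spec@noise$sd) +
    stats::rnorm(length(clean), 0, spec@noise$scale * sqrt(pmax(clean, 0)))
  red <- matrix(pmin(pmax(round(noisy), 0), 255), h, w)
  green <- matrix(pmin(pmax(round(spec@greenBleed * noisy), 0), 255), h, w)
  img <- array(0, c(h, w, 3L))
  img[, , 1L] <- red; img[, , 2L] <- green

  imgXY <- applyTransform(fwd, cbind(refs$x, refs$y))
  truthSpots <- data.frame(refs, imgX = imgXY[, 1L], imgY = imgXY[, 2L],
                           amplitude = amp)
  list(image = img, gray = red,
       truth = list(spots = truthSpots,
                    normalized = sceneTruthNormalized(spec),
                    forward = fwd))
}

#' Ladder of scenes spanning a truth range
#'
#' `nChips` scene specifications whose biomarker truth values evenly span
#' `truthRange` (all three biomarker roles of a chip share its truth value),
#' each with a randomized mild aberration drawn from the seed: rotation
#' within 3 degrees, shear within 5, per-axis scale 0.95-1.05, translation
#' within 8 px and bow within 4 px per axis. Used for end-to-end
#' parameter-recovery validation.
#'
#' @param seed integer; fixes the aberration draws and per-chip render seeds.
#' @param nChips number of chips (>= 1).
#' @param truthRange numeric `c(lo, hi)` of normalized truth values.
#' @param layout an [ArrayLayout-class].
#' @param noiseSd additive noise level passed to every chip.
#' @return list of [SceneSpec-class] objects.
#' @export
sceneLadder <- function(seed, nChips, truthRange = c(0, 1),
                        layout = buildDefaultLayout(), noiseSd = 3) {
  stopifnot(nChips >= 1)
  orng <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(orng)) assign(".Random.seed", orng, globalenv()))
  set.seed(as.integer(seed))
  truths <- if (nChips == 1L) mean(truthRange)
            else seq(truthRange[[1]], truthRange[[2]], length.out = nChips)
  chipSeeds <- sample.int(.Machine$integer.max - 1L, nChips)
  base <- .defaultAmplitudes
  lapply(seq_len(nChips), function(i) {
    t <- truths[[i]]
    amp <- base
    amp[biomarkerRoles()] <- base[["NEG"]] +
      t * (base[["POS"]] - base[["NEG"]])
    sceneSpec(
      layout = layout, amplitudes = amp,
      aberration = list(
        rotation = stats::runif(1, -3, 3),
        shear = stats::runif(1, -5, 5),
        scale = stats::runif(2, 0.95, 1.05),
        translation = stats::runif(2, -8, 8),
        bow = stats::runif(2, -4, 4)),
      noise = list(sd = noiseSd, scale = 0.05),
      seed = chipSeeds[[i]])
  })
}

setMethod("show", "SceneSpec", function(object) {
  cat(sprintf("SceneSpec: %d x %d grid, image %d x %d px, seed %d\n",
              object@layout@nRows, object@layout@nCols,
              object@imageShape[[1]], object@imageShape[[2]], object@seed))
  cat("  amplitudes:", paste(sprintf("%s=%g", names(object@amplitudes),
                                     object@amplitudes), collapse = " "), "\n")
  cat(sprintf("  aberration: rot %.2f deg, shear %.2f deg, bow (%.2f, %.2f) px\n",
              object@aberration$rotation, object@aberration$shear,
              object@aberration$bow[[1]], object@aberration$bow[[2]]))
})
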