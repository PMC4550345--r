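#' @import methods
NULL

## Shared pixel-coordinate convention:
##   x runs along columns, y along rows; the origin is the top-left pixel,
##   y increases downward; pixel centers sit at integer coordinates, 0-based.
##   A GrayImage is stored as a plain numeric matrix m with m[y + 1, x + 1].

#' Spot roles on the array
#'
#' The five roles a microarray position can carry: the anti-rbST antibody
#' capture spots (`RBST`), the two anti-IGF-1 capture concentrations
#' (`IGF1_100`, `IGF1_250`), and the sheep-IgG positive (`POS`) and ovalbumin
#' negative (`NEG`) controls. `POS` and `NEG` are quality controls; the other
#' three carry the biomarker signal.
#'
#' @return `spotRoles()` returns the character vector of all five role names;
#'   `biomarkerRoles()` the three non-control roles.
#' @examples
#' spotRoles()
#' @export
spotRoles <- function() c("RBST", "IGF1_100", "IGF1_250", "POS", "NEG")

#' @rdname spotRoles
#' @export
biomarkerRoles <- function() c("RBST", "IGF1_100", "IGF1_250")

## single-letter codes used in layout files
.roleCodes <- c(R = "RBST", I = "IGF1_100", J = "IGF1_250", P = "POS", N = "NEG")

#' ArrayLayout: geometry and role map of a microarray chip
#'
#' An `ArrayLayout` describes the regular reference grid every image is
#' registered onto: grid dimensions, the role spotted at each position, the
#' spot pitch and grid origin in standardized pixels, and the semi-axes of
#' the elliptical region of interest used for quantification.
#'
#' @slot nRows,nCols integer grid dimensions.
#' @slot roles character matrix (`nRows` x `nCols`) of role names, see
#'   [spotRoles()].
#' @slot pitch named numeric, `c(row=, col=)`, spot spacing in standardized
#'   pixels (both > 0).
#' @slot origin named numeric, `c(row=, col=)`, standardized (y, x) coordinate
#'   of grid position (0, 0).
#' @slot ellipse named numeric, `c(a=, b=)`: ROI semi-axis along x (columns)
#'   and along y (rows); each must be smaller than half the corresponding
#'   pitch so that neighbouring ROIs never overlap.
#'
#' @seealso [buildDefaultLayout()], [readLayoutFile()]
#' @export
setClass("ArrayLayout",
  representation(
    nRows = "integer", nCols = "integer", roles = "matrix",
    pitch = "numeric", origin = "numeric", ellipse = "numeric"
  )
)

setValidity("ArrayLayout", function(object) {
  r <- object@nRows; c <- object@nCols
  if (length(r) != 1L || length(c) != 1L || r < 2L || c < 2L)
    return("grid must be at least 2 x 2")
  if (!identical(dim(object@roles), c(r, c)))
    return("roles matrix does not match nRows x nCols")
  if (!all(object@roles %in% spotRoles()))
    return("roles contains an unknown role name")
  if (length(object@pitch) != 2L || any(object@pitch <= 0))
    return("pitch must be two positive numbers")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    return("origin must be two finite numbers")
  if (length(object@ellipse) != 2L || any(object@ellipse <= 0))
    return("ellipse semi-axes must be positive")
  ## ellipse["a"] spans columns (x), ellipse["b"] spans rows (y)
  if (object@ellipse[["a"]] >= object@pitch[["col"]] / 2 ||
      object@ellipse[["b"]] >= object@pitch[["row"]] / 2)
    return("ellipse semi-axes must be below half the pitch (ROIs would overlap)")
  ring <- c(object@roles[c(1L, r), ], object@roles[, c(1L, c)])
  if (!all(ring %in% c("POS", "NEG")))
    return("outer ring must contain only POS and NEG controls")
  corners <- c(object@roles[1L, 1L], object@roles[1L, c],
               object@roles[r, 1L], object@roles[r, c])
  if (!all(corners == "POS"))
    return("all four corner positions must be POS")
  TRUE
})

#' AffineTransform2D: six-coefficient planar map
#'
#' Maps `(x, y)` to `(a x + b y + c, d x + e y + f)`. Used as the first-stage
#' geometric correction that removes shear, rotation, scale and translation.
#'
#' @slot coef named numeric of length 6 (`a, b, c, d, e, f`).
#' @seealso [estimateAffine()], [applyTransform()]
#' @export
setClass("AffineTransform2D", representation(coef = "numeric"))

setValidity("AffineTransform2D", function(object) {
  k <- object@coef
  if (length(k) != 6L || any(!is.finite(k)))
    return("coef must be 6 finite numbers")
  if (abs(k[[1]] * k[[5]] - k[[2]] * k[[4]]) < 1e-12)
    return("transform is singular (determinant ~ 0)")
  TRUE
})

#' QuadraticTransform2D: twelve-coefficient degree-2 planar map
#'
#' Maps `(x, y)` to
#' `x' = p0 + p1 x + p2 y + p3 x^2 + p4 x y + p5 y^2` and likewise
#' `y'` with coefficients `q0..q5`. Used as the second-stage correction
#' that removes the residual smooth curvature left after the affine step;
#' with `p3..p5 = q3..q5 = 0` it reduces to an affine map.
#'
#' @slot px,py numeric length-6 coefficient vectors for the x' and y' output.
#' @seealso [fitQuadratic()], [applyTransform()]
#' @export
setClass("QuadraticTransform2D", representation(px = "numeric", py = "numeric"))

setValidity("QuadraticTransform2D", function(object) {
  if (length(object@px) != 6L || length(object@py) != 6L ||
      any(!is.finite(c(object@px, object@py))))
    return("px and py must each hold 6 finite coefficients")
  TRUE
})

#' AnchorMatch: correspondence between detected blobs and layout positions
#'
#' @slot pairs data.frame with one matched anchor per row: grid `row`, `col`,
#'   reference centroid `refX`, `refY`, and the detected blob centroid
#'   `obsX`, `obsY` in image coordinates.
#' @slot residual RMS distance (px) between mapped blob centroids and their
#'   reference centroids under `transform`.
#' @slot transform the provisional [AffineTransform2D-class] (image to
#'   reference coordinates) used during matching.
#' @seealso [matchAnchors()]
#' @export
setClass("AnchorMatch",
  representation(pairs = "data.frame", residual = "numeric",
                 transform = "AffineTransform2D")
)

setValidity("AnchorMatch", function(object) {
  p <- object@pairs
  need <- c("row", "col", "refX", "refY", "obsX", "obsY")
  if (!all(need %in% names(p))) return("pairs lacks required columns")
  if (nrow(p) < 3L) return("at least 3 anchor pairs are required")
  if (anyDuplicated(p[, c("row", "col")])) return("duplicated grid positions")
  if (anyDuplicated(p[, c("obsX", "obsY")])) return("duplicated blob centroids")
  TRUE
})

#' SceneSpec: full description of a synthetic chip image
#'
#' A `SceneSpec` fixes everything needed to render a smartphone-like
#' fluorescence microarray image with known ground truth: the layout, the
#' per-role spot amplitudes (with optional per-spot overrides), the spot
#' profile, the background model, the geometric aberration and the noise
#' model, plus a seed that makes rendering fully reproducible.
#'
#' @slot layout an [ArrayLayout-class].
#' @slot amplitudes named numeric, intensity in `[0, 255]` for each role.
#' @slot spotOverrides data.frame (`row`, `col`, `amplitude`) of per-spot
#'   amplitude overrides; may have zero rows.
#' @slot profile list: `type` (`"flat_ellipse"` or `"gaussian"`) and
#'   `blurSd` (edge softening, px).
#' @slot background list: `base`, `gradient` (`c(gx, gy)`, total drop across
#'   the image in x and y) and `vignette` (corner darkening, intensity units).
#' @slot aberration list: `rotation`, `shear` (degrees), `scale` (`c(sx, sy)`),
#'   `translation` (`c(tx, ty)`, px) and `bow` (`c(bx, by)`, px of quadratic
#'   corner displacement).
#' @slot noise list: `sd` (additive Gaussian, intensity units) and `scale`
#'   (signal-proportional component).
#' @slot imageShape integer `c(height, width)` of the rendered image.
#' @slot greenBleed fraction of the red signal bleeding into the green channel.
#' @slot seed integer seed fixing all randomness of [renderScene()].
#' @seealso [sceneSpec()], [renderScene()], [sceneLadder()]
#' @export
setClass("SceneSpec",
  representation(
    layout = "ArrayLayout", amplitudes = "numeric",
    spotOverrides = "data.frame", profile = "list", background = "list",
    aberration = "list", noise = "list", imageShape = "integer",
    greenBleed = "numeric", seed = "integer"
  )
)

#' ChipResult: per-spot, per-role and normalized chip readout
#'
#' The complete result of analysing one chip image: every spot's median
#' luminance, per-role aggregates over the inner rectangle, and the
#' background-corrected, positive-control-normalized values for the
#' biomarker roles. Access with [spotMeasurements()], [roleAggregates()],
#' [normalizedValues()] and [chipQC()].
#'
#' @slot spots data.frame of per-spot measurements (one row per grid
#'   position): `row`, `col`, `role`, `x`, `y`, `nPixels`, `median`.
#' @slot aggregates data.frame of per-role mean/sd/n over the aggregation
#'   scope.
#' @slot normalized named numeric: `(mean_role - mean_NEG) /
#'   (mean_POS - mean_NEG)` per role (POS maps to 1, NEG to 0).
#' @slot qc list with `posMean`, `negMean`, `posMinusNeg`.
#' @slot metadata list: configuration echo, image source and hash, geometry
#'   diagnostics, timings.
#' @seealso [analyzeChip()]
#' @export
setClass("ChipResult",
  representation(
    spots = "data.frame", aggregates = "data.frame", normalized = "numeric",
    qc = "list", metadata = "list"
  )
)

setValidity("ChipResult", function(object) {
  if (!all(c("posMean", "negMean", "posMinusNeg") %in% names(object@qc)))
    return("qc must contain posMean, negMean, posMinusNeg")
  TRUE
})
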