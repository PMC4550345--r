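#' Construct an ArrayLayout
#'
#' Low-level constructor; most users want [buildDefaultLayout()] or
#' [readLayoutFile()].
#'
#' @param roles character matrix of role names (rows x columns of the grid).
#' @param pitch numeric `c(row, col)` spot spacing in standardized px.
#' @param origin numeric `c(row, col)` standardized (y, x) of position (0, 0).
#' @param ellipse numeric `c(a, b)` ROI semi-axes (a along x, b along y).
#' @return a validated [ArrayLayout-class].
#' @export
arrayLayout <- function(roles, pitch = c(row = 40, col = 40),
                        origin = c(row = 30, col = 30),
                        ellipse = c(a = 12, b = 9)) {
  new("ArrayLayout",
      nRows = nrow(roles), nCols = ncol(roles), roles = roles,
      pitch = c(row = unname(pitch[[1]]), col = unname(pitch[[2]])),
      origin = c(row = unname(origin[[1]]), col = unname(origin[[2]])),
      ellipse = c(a = unname(ellipse[[1]]), b = unname(ellipse[[2]])))
}

#' Canonical 48-spot chip layout
#'
#' Builds the default 6-row x 8-column layout: 48 spots of which the three
#' biomarker conditions (RBST, IGF1_100, IGF1_250) occupy 6 replicate spots
#' each in the inner rectangle, and the positive and negative controls 15
#' spots each. The outer ring carries only controls (12 POS + 12 NEG, POS at
#' all four corners) and is used solely to locate the grid; the inner
#' rectangle additionally holds 3 POS and 3 NEG spots that enter the
#' reported aggregates.
#'
#' @return an [ArrayLayout-class]; deterministic, the same layout every call.
#' @examples
#' layout <- buildDefaultLayout()
#' table(layoutRoles(layout))
#' @export
buildDefaultLayout <- function() {
  roles <- matrix(NA_character_, 6L, 8L)
  ## ring: POS corners, per-side alternation giving 12 POS / 12 NEG
  roles[1L, ] <- c("POS", "NEG", "POS", "NEG", "NEG", "POS", "NEG", "POS")
  roles[6L, ] <- c("POS", "NEG", "POS", "NEG", "NEG", "POS", "NEG", "POS")
  roles[2:5, 1L] <- c("NEG", "POS", "NEG", "POS")
  roles[2:5, 8L] <- c("POS", "NEG", "POS", "NEG")
  ## inner 4 x 6 rectangle: biomarkers in column-major runs of 6,
  ## then the 6 inner controls
  inner <- c(rep("RBST", 6L), rep("IGF1_100", 6L), rep("IGF1_250", 6L),
             c("POS", "NEG", "POS", "NEG", "POS", "NEG"))
  roles[2:5, 2:7] <- matrix(inner, nrow = 4L)
  arrayLayout(roles)
}

#' @rdname layoutAccessors
#' @export
setGeneric("layoutRoles", function(x) standardGeneric("layoutRoles"))
#' Layout accessors
#'
#' @param x an [ArrayLayout-class].
#' @return `layoutRoles()`: the role matrix; `spotPitch()`, `gridOrigin()`,
#'   `roiEllipse()`: the corresponding named numeric slots; `nSpots()`: the
#'   total position count.
#' @name layoutAccessors
#' @aliases layoutRoles,ArrayLayout-method
#' @export
setMethod("layoutRoles", "ArrayLayout", function(x) x@roles)

#' @rdname layoutAccessors
#' @export
setGeneric("spotPitch", function(x) standardGeneric("spotPitch"))
#' @rdname layoutAccessors
#' @export
setMethod("spotPitch", "ArrayLayout", function(x) x@pitch)

#' @rdname layoutAccessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname layoutAccessors
#' @export
setMethod("gridOrigin", "ArrayLayout", function(x) x@origin)

#' @rdname layoutAccessors
#' @export
setGeneric("roiEllipse", function(x) standardGeneric("roiEllipse"))
#' @rdname layoutAccessors
#' @export
setMethod("roiEllipse", "ArrayLayout", function(x) x@ellipse)

#' @rdname layoutAccessors
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))
#' @rdname layoutAccessors
#' @export
setMethod("nSpots", "ArrayLayout", function(x) x@nRows * x@nCols)

setMethod("show", "ArrayLayout", function(object) {
  cat(sprintf("ArrayLayout: %d x %d grid (%d spots)\n",
              object@nRows, object@nCols, nSpots(object)))
  cat("  roles:", paste(sprintf("%s=%d", names(table(object@roles)),
                                table(object@roles)), collapse = " "), "\n")
  cat(sprintf("  pitch (row, col): %g, %g px; origin (row, col): %g, %g px\n",
              object@pitch[["row"]], object@pitch[["col"]],
              object@origin[["row"]], object@origin[["col"]]))
  cat(sprintf("  ROI ellipse semi-axes (a, b): %g, %g px\n",
              object@ellipse[["a"]], object@ellipse[["b"]]))
})

#' Reference centroids of the standardized grid
#'
#' The regular, axis-aligned lattice of spot centres every image is warped
#' onto: spot `(r, c)` sits at `(origin_x + c * pitch_col,
#' origin_y + r * pitch_row)`.
#'
#' @param layout an [ArrayLayout-class].
#' @return data.frame with columns `row`, `col` (0-based grid indices),
#'   `role`, `x`, `y` (standardized pixel coordinates), ordered row-major.
#' @export
referenceCentroids <- function(layout) {
  stopifnot(is(layout, "ArrayLayout"))
  g <- expand.grid(col = seq_len(layout@nCols) - 1L,
                   row = seq_len(layout@nRows) - 1L)
  data.frame(
    row = g$row, col = g$col,
    role = layout@roles[cbind(g$row + 1L, g$col + 1L)],
    x = layout@origin[["col"]] + g$col * layout@pitch[["col"]],
    y = layout@origin[["row"]] + g$row * layout@pitch[["row"]]
  )
}

#' Inner-rectangle grid positions
#'
#' All positions not on the outer ring. Only these spots enter the reported
#' aggregates; for the canonical layout the set holds the 18 biomarker spots
#' plus 3 POS and 3 NEG controls.
#'
#' @param layout an [ArrayLayout-class] with at least 3 rows and 3 columns.
#' @return data.frame with 0-based `row`, `col` columns.
#' @export
innerPositions <- function(layout) {
  stopifnot(is(layout, "ArrayLayout"))
  if (layout@nRows < 3L || layout@nCols < 3L)
    stopConfig("layout", "grid smaller than 3 x 3 has no inner rectangle")
  expand.grid(col = seq.int(1L, layout@nCols - 2L),
              row = seq.int(1L, layout@nRows - 2L))[, c("row", "col")]
}

#' Standardized image shape for a layout
#'
#' Height and width of the standardized image: the grid bounding box plus a
#' symmetric margin of `marginFrac` times the pitch on every side (the grid
#' origin is repositioned to that margin, so the default layout with
#' `marginFrac = 0.75` keeps its stated origin).
#'
#' @param layout an [ArrayLayout-class].
#' @param marginFrac margin around the grid bounding box, as fraction of
#'   the pitch.
#' @return integer `c(height, width)` in pixels.
#' @export
standardShape <- function(layout, marginFrac = 0.75) {
  w <- layout@origin[["col"]] + (layout@nCols - 1L) * layout@pitch[["col"]] +
    marginFrac * layout@pitch[["col"]]
  h <- layout@origin[["row"]] + (layout@nRows - 1L) * layout@pitch[["row"]] +
    marginFrac * layout@pitch[["row"]]
  c(height = as.integer(ceiling(h)) + 1L, width = as.integer(ceiling(w)) + 1L)
}

## ---- layout files ----------------------------------------------------------

#' Read or write a layout file
#'
#' Layout files are YAML (or JSON) with keys `n_rows`, `n_cols`, `pitch`
#' (`row`, `col`), `origin` (`row`, `col`), `ellipse` (`a`, `b`) and `roles`:
#' `n_rows` strings of `n_cols` single-letter codes
#' (`R` = RBST, `I` = IGF1_100, `J` = IGF1_250, `P` = POS, `N` = NEG).
#' All [ArrayLayout-class] invariants are validated on load and the first
#' violated one is reported.
#'
#' @param path file to read or write.
#' @param layout an [ArrayLayout-class] (for writing).
#' @return `readLayoutFile()` returns an [ArrayLayout-class];
#'   `writeLayoutFile()` returns `path` invisibly.
#' @export
readLayoutFile <- function(path) {
  if (!file.exists(path)) stopIO("layout", sprintf("layout file not found: %s", path))
  spec <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stopConfig("layout",
                     sprintf("cannot parse layout file: %s", conditionMessage(e))))
  need <- c("n_rows", "n_cols", "pitch", "origin", "ellipse", "roles")
  miss <- setdiff(need, names(spec))
  if (length(miss))
    stopConfig("layout", sprintf("layout file lacks key(s): %s",
                                 paste(miss, collapse = ", ")))
  nr <- as.integer(spec$n_rows); nc <- as.integer(spec$n_cols)
  if (length(spec$roles) != nr)
    stopConfig("layout", sprintf("roles block must have %d strings, found %d",
                                 nr, length(spec$roles)))
  rows <- lapply(spec$roles, function(s) strsplit(s, "")[[1]])
  if (any(lengths(rows) != nc))
    stopConfig("layout", sprintf("every roles string must have %d characters", nc))
  codes <- do.call(rbind, rows)
  bad <- setdiff(unique(as.vector(codes)), names(.roleCodes))
  if (length(bad))
    stopConfig("layout", sprintf("unknown role code(s): %s",
                                 paste(bad, collapse = ", ")))
  roles <- matrix(.roleCodes[codes], nr, nc)
  out <- tryCatch(
    arrayLayout(roles,
                pitch = c(spec$pitch$row, spec$pitch$col),
                origin = c(spec$origin$row, spec$origin$col),
                ellipse = c(spec$ellipse$a, spec$ellipse$b)),
    error = function(e) stopConfig("layout", conditionMessage(e)))
  out
}

#' @rdname readLayoutFile
#' @export
writeLayoutFile <- function(layout, path) {
  stopifnot(is(layout, "ArrayLayout"))
  codes <- matrix(names(.roleCodes)[match(layout@roles, .roleCodes)],
                  layout@nRows, layout@nCols)
  spec <- list(
    n_rows = layout@nRows, n_cols = layout@nCols,
    pitch = list(row = layout@pitch[["row"]], col = layout@pitch[["col"]]),
    origin = list(row = layout@origin[["row"]], col = layout@origin[["col"]]),
    ellipse = list(a = layout@ellipse[["a"]], b = layout@ellipse[["b"]]),
    roles = apply(codes, 1L, paste, collapse = "")
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}
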