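## Stage-tagged error conditions. Every pipeline failure carries the stage
## that produced it so callers (and the CLI exit-code mapping) can react
## without parsing message text.

.stageStop <- function(stage, msg, class) {
  stop(structure(
    class = c(class, "microspotError", "error", "condition"),
    list(message = sprintf("[%s] %s", stage, msg), call = sys.call(-1),
         stage = stage)
  ))
}

stopIO        <- function(stage, msg) .stageStop(stage, msg, "microspotIOError")
stopConfig    <- function(stage, msg) .stageStop(stage, msg, "microspotConfigError")
stopDetection <- function(stage, msg) .stageStop(stage, msg, "microspotDetectionError")
stopGeometry  <- function(stage, msg) .stageStop(stage, msg, "microspotGeometryError")
stopQC        <- function(stage, msg) .stageStop(stage, msg, "microspotQCError")

#' Stage of a pipeline failure
#'
#' Pipeline errors raised by this package carry the name of the stage that
#' failed (`"detection"`, `"geometry"`, `"quantification"`, `"qc"`, ...).
#'
#' @param cond a condition object caught from a pipeline call.
#' @return the stage name, or `NA_character_` for foreign conditions.
#' @export
errorStage <- function(cond) {
  s <- cond$stage
  if (is.null(s)) NA_character_ else s
}
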