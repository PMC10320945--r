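#' @describeIn PatientCase-class CT volume accessor (HU).
#' @param object,x a \code{PatientCase}.
#' @export
setGeneric("ctVolume", function(object) standardGeneric("ctVolume"))

#' @describeIn PatientCase-class planned dose volume accessor (cGy).
#' @export
setGeneric("doseVolume", function(object) standardGeneric("doseVolume"))

#' @describeIn PatientCase-class fluence stack accessor (MU), rows x cols x
#'   beams ordered by ascending gantry angle.
#' @export
setGeneric("fluenceStack", function(object) standardGeneric("fluenceStack"))

#' @describeIn PatientCase-class named prescription levels (cGy).
#' @export
setGeneric("prescriptions", function(object) standardGeneric("prescriptions"))

#' @describeIn PatientCase-class one OAR mask by canonical name.
#' @param name structure name.
#' @export
setGeneric("oarMask", function(object, name) standardGeneric("oarMask"))

#' @describeIn PatientCase-class one PTV mask by canonical name.
#' @export
setGeneric("ptvMask", function(object, name) standardGeneric("ptvMask"))

#' @describeIn PatientCase-class prescription-filled PTV mask (cGy).
#' @export
setGeneric("ptvDoseMask", function(object) standardGeneric("ptvDoseMask"))

setMethod("ctVolume", "PatientCase", function(object) object@ct)
setMethod("doseVolume", "PatientCase", function(object) object@dose)
setMethod("fluenceStack", "PatientCase", function(object) object@fluence)
setMethod("prescriptions", "PatientCase", function(object) object@prescriptions)
setMethod("oarMask", "PatientCase", function(object, name) {
  if (!name %in% names(object@oarMasks)) stop("unknown OAR: ", name)
  object@oarMasks[[name]]
})
setMethod("ptvMask", "PatientCase", function(object, name) {
  if (!name %in% names(object@ptvMasks)) stop("unknown PTV: ", name)
  object@ptvMasks[[name]]
})
setMethod("ptvDoseMask", "PatientCase", function(object) object@ptvDose)

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d x %d voxels at %s mm, origin (%s) mm\n",
              object@dims[1], object@dims[2], object@dims[3],
              paste(object@spacing, collapse = " x "),
              paste(sprintf("%.1f", object@origin), collapse = ", ")))
})

setMethod("show", "BeamGeometry", function(object) {
  cat(sprintf(
    "BeamGeometry: %d beams at {%s} deg, SAD %.0f mm, plane %d x %d @ %.2f mm\n",
    length(object@gantryAngles),
    paste(object@gantryAngles, collapse = ", "), object@sad,
    object@planeRows, object@planeCols, object@planePitch))
})

setMethod("show", "ProjectionOperator", function(object) {
  cat(sprintf(
    "ProjectionOperator: beam %d (%.0f deg), %d x %d sparse (%d entries)%s\n",
    object@beamIndex, object@gantryAngle, nrow(object@P), ncol(object@P),
    length(object@P@x), if (object@truncated) ", truncated" else ""))
  cat(sprintf("  slices %d..%d -> plane rows %d..%d\n",
              object@sliceRange[1], object@sliceRange[2],
              object@rowRange[1], object@rowRange[2]))
})

setMethod("show", "PatientCase", function(object) {
  d <- object@grid@dims
  cat(sprintf("PatientCase: grid %d x %d x %d, %d beams, seed %s\n",
              d[1], d[2], d[3], length(object@beams@gantryAngles),
              ifelse(is.na(object@seed), "NA", object@seed)))
  cat(sprintf("  prescriptions (cGy): %s\n",
              paste(sprintf("%s=%g", names(object@prescriptions),
                            object@prescriptions), collapse = ", ")))
  cat(sprintf("  dose range %.0f..%.0f cGy, fluence max %.1f MU\n",
              min(object@dose), max(object@dose), max(object@fluence)))
})

setMethod("show", "SharedEncoderModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, 0L))
  cat(sprintf(
    "SharedEncoderModel: %d input channels, base %d, %d parameters\n",
    cfg$in_channels, cfg$base_channels, np))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: %d fluence rows, %d dose-index rows, %d summary rows\n",
              nrow(object@fluence), nrow(object@doseIndices),
              nrow(object@summary)))
})
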