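#' @import methods
#' @importFrom Matrix sparseMatrix crossprod t Diagonal
NULL

#' Canonical organ-at-risk channel names
#'
#' The seventeen organs at risk carried by every case, in the canonical
#' (alphabetical) channel order used for network inputs: body, brainstem,
#' chiasm, paired lenses, mandibles, optic nerves, parotid glands, spinal
#' cord, temporal lobes, temporomandibular joints, and tongue.
#'
#' @return Character vector of length 17.
#' @export
#' @examples
#' oarNames()
oarNames <- function() {
  c("body", "brainstem", "chiasm", "lens_l", "lens_r",
    "mandible_l", "mandible_r", "optic_nerve_l", "optic_nerve_r",
    "parotid_l", "parotid_r", "spinal_cord",
    "temporal_lobe_l", "temporal_lobe_r", "tmj_l", "tmj_r", "tongue")
}

#' Canonical target-volume names
#'
#' The five planning target volumes of a nasopharyngeal plan: the nested
#' primary targets (PTV-GTV inside PTV-1 inside PTV-2) and the two lateral
#' nodal targets.
#'
#' @return Character vector of length 5.
#' @export
ptvNames <- function() {
  c("PTV-GTV", "PTV-1", "PTV-2", "PTV-LN-L", "PTV-LN-R")
}

#' Volumetric grid specification
#'
#' A regular voxel grid in the patient frame. Coordinates are millimetres in
#' a (left, posterior, superior) frame with the plan isocenter at the
#' origin; axis 1 (x) runs toward the patient's left, axis 2 (y) posterior,
#' axis 3 (z) superior (the slice axis). Arrays on the grid have dim
#' \code{c(nx, ny, nz)}. \code{origin} is the position of the center of
#' voxel (1,1,1); the default centers the grid on the isocenter.
#'
#' @slot dims integer(3), voxels per axis (width, height, slices).
#' @slot spacing numeric(3), mm per voxel (default 2.5 isotropic).
#' @slot origin numeric(3), mm position of the first voxel center.
#' @export
setClass("GridSpec", representation(
  dims = "integer", spacing = "numeric", origin = "numeric"))

setValidity("GridSpec", function(object) {
  if (length(object@dims) != 3L || any(object@dims < 1L))
    return("dims must be three positive integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers")
  if (length(object@origin) != 3L) return("origin must have length 3")
  lo <- object@origin - object@spacing / 2
  hi <- object@origin + (object@dims - 1L + 0.5) * object@spacing
  if (any(lo > 0) || any(hi < 0))
    return("isocenter (0,0,0) must lie inside the grid")
  TRUE
})

#' @rdname GridSpec-class
#' @param nx,ny,nz grid extents in voxels (transverse slice size ny x nx).
#' @param spacing mm per voxel, recycled to length 3.
#' @param origin mm position of the first voxel center; defaults to an
#'   isocenter-centered grid.
#' @return A \code{GridSpec}.
#' @export
#' @examples
#' gridSpec(224, 224, 64)
gridSpec <- function(nx = 224L, ny = 224L, nz = 64L, spacing = 2.5,
                     origin = NULL) {
  dims <- as.integer(c(nx, ny, nz))
  spacing <- rep_len(as.numeric(spacing), 3L)
  if (is.null(origin)) origin <- -(dims - 1L) / 2 * spacing
  new("GridSpec", dims = dims, spacing = spacing, origin = as.numeric(origin))
}

#' Beam arrangement and fluence-plane geometry
#'
#' Nine coplanar 6 MV beams rotating about the superior-inferior axis.
#' Gantry angle 0 places the source on the anterior side of the patient and
#' angles increase toward the patient's left; this convention is fixed.
#' The fluence plane of every beam is the isocenter plane, perpendicular to
#' the beam central axis, with its row axis parallel to the
#' superior-inferior axis and pixel pitch \code{planePitch} mm.
#'
#' @slot gantryAngles numeric, gantry angles in degrees (default the nine
#'   equally spaced angles 0, 40, ..., 320).
#' @slot sad numeric(1), source-axis distance in mm (default 1000).
#' @slot planeRows,planeCols integer(1), fluence-map size (default 160).
#' @slot planePitch numeric(1), fluence pixel pitch in mm (default 2.5).
#' @export
setClass("BeamGeometry", representation(
  gantryAngles = "numeric", sad = "numeric",
  planeRows = "integer", planeCols = "integer", planePitch = "numeric"))

setValidity("BeamGeometry", function(object) {
  a <- object@gantryAngles
  if (any(a < 0 | a >= 360)) return("gantry angles must lie in [0, 360)")
  if (anyDuplicated(a)) return("gantry angles must be unique")
  if (is.unsorted(a)) return("gantry angles must be ascending")
  if (object@sad <= 0) return("sad must be positive")
  if (object@planeRows < 1L || object@planeCols < 1L)
    return("fluence plane must be non-empty")
  if (object@planePitch <= 0) return("planePitch must be positive")
  TRUE
})

#' @rdname BeamGeometry-class
#' @param gantryAngles,sad,planeRows,planeCols,planePitch see slots.
#' @return A \code{BeamGeometry}.
#' @export
#' @examples
#' beamGeometry()
beamGeometry <- function(gantryAngles = seq(0, 320, by = 40), sad = 1000,
                         planeRows = 160L, planeCols = 160L,
                         planePitch = 2.5) {
  new("BeamGeometry", gantryAngles = as.numeric(gantryAngles),
      sad = as.numeric(sad), planeRows = as.integer(planeRows),
      planeCols = as.integer(planeCols), planePitch = as.numeric(planePitch))
}

#' Sparse divergent-beam projection operator
#'
#' The voxel-to-beamlet geometric projection matrix P of one beam. Row i
#' corresponds to voxel i of the grid (R column-major order, x fastest) and
#' column j to fluence-plane pixel j (column-major over a rows x cols
#' matrix). A stored entry P_ij is the inverse-square weight
#' (sad / source-voxel distance)^2 of the beamlet hit by the ray cast from
#' the source through the voxel; with nearest-neighbor splatting each row
#' has at most one entry. \code{sliceRange}/\code{rowRange} document which
#' grid slices and plane rows the operator covers (patch-restricted
#' operators are sliced from the full-volume operator, so a patch near the
#' volume edge keeps the truncated-projection behavior of the parent).
#'
#' @slot beamIndex integer(1), 1-based beam index.
#' @slot gantryAngle numeric(1), degrees.
#' @slot P a \code{dgCMatrix}, n_voxels x n_beamlets.
#' @slot grid the \code{GridSpec} the rows refer to.
#' @slot beam the \code{BeamGeometry} the columns refer to.
#' @slot sliceRange integer(2), covered grid slices (half-open on neither
#'   end; \code{c(1, nz)} for a full-volume operator).
#' @slot rowRange integer(2), covered fluence-plane rows.
#' @slot truncated logical(1), TRUE if any voxel ray exits the plane.
#' @export
setClass("ProjectionOperator", representation(
  beamIndex = "integer", gantryAngle = "numeric", P = "ANY",
  grid = "GridSpec", beam = "BeamGeometry", sliceRange = "integer",
  rowRange = "integer", truncated = "logical"))

setValidity("ProjectionOperator", function(object) {
  if (!methods::is(object@P, "sparseMatrix"))
    return("P must be a sparse Matrix")
  if (any(object@P@x <= 0)) return("all stored entries must be positive")
  TRUE
})

#' Multi-leaf collimator transmission model
#'
#' Leaf/jaw parameters used to turn control-point apertures into fluence.
#' Leaves travel along the crossplane (column) axis; leaf pair p covers the
#' inplane band \code{leafBoundaries[p]..leafBoundaries[p+1]} mm. The
#' dosimetric leaf gap widens every opening by dlg/2 per leaf end to model
#' rounded leaf ends. Transmission values are unitless fractions; jaws are
#' treated as opaque by default. The clinical values are machine
#' calibration data, so both are configuration, not constants.
#'
#' @slot transmission numeric(1) in [0,1), MLC transmission (default 0.015).
#' @slot dlg numeric(1), dosimetric leaf gap in mm (default 1.4).
#' @slot leafBoundaries numeric, strictly increasing inplane leaf-pair
#'   edges in mm (length n_pairs + 1).
#' @slot jawTransmission numeric(1), transmission outside the jaws
#'   (default 0).
#' @export
setClass("MlcModel", representation(
  transmission = "numeric", dlg = "numeric", leafBoundaries = "numeric",
  jawTransmission = "numeric"))

setValidity("MlcModel", function(object) {
  if (object@transmission < 0 || object@transmission >= 1)
    return("transmission must lie in [0, 1)")
  if (object@dlg < 0) return("dlg must be >= 0")
  if (length(object@leafBoundaries) < 2L ||
      any(diff(object@leafBoundaries) <= 0))
    return("leafBoundaries must be strictly increasing with >= 2 entries")
  if (object@jawTransmission < 0 || object@jawTransmission >= 1)
    return("jawTransmission must lie in [0, 1)")
  TRUE
})

#' @rdname MlcModel-class
#' @param transmission,dlg,leafBoundaries,jawTransmission see slots.
#' @return An \code{MlcModel}.
#' @export
#' @examples
#' mlcModel(leafBoundaries = seq(-200, 200, by = 5))
mlcModel <- function(transmission = 0.015, dlg = 1.4,
                     leafBoundaries = seq(-200, 200, by = 5),
                     jawTransmission = 0) {
  new("MlcModel", transmission = as.numeric(transmission),
      dlg = as.numeric(dlg), leafBoundaries = as.numeric(leafBoundaries),
      jawTransmission = as.numeric(jawTransmission))
}

#' MLC control-point sequence of one field
#'
#' A delivery sequence: K machine snapshots, each with a cumulative
#' meterset weight (non-decreasing from 0 to 1), per-leaf-pair left/right
#' positions (mm at the isocenter plane along the crossplane axis), and
#' jaw positions (x1, x2, y1, y2) mm, plus the field meterset in MU.
#'
#' @slot weights numeric(K), cumulative meterset weights.
#' @slot mlcLeft,mlcRight K x n_pairs matrices of leaf positions (mm).
#' @slot jaws K x 4 matrix, columns x1, x2, y1, y2 (mm).
#' @slot mu numeric(1), field meterset (MU).
#' @export
setClass("ControlPointSequence", representation(
  weights = "numeric", mlcLeft = "matrix", mlcRight = "matrix",
  jaws = "matrix", mu = "numeric"))

setValidity("ControlPointSequence", function(object) {
  w <- object@weights
  if (length(w) < 2L) return("need at least 2 control points")
  if (abs(w[1L]) > 1e-9 || abs(w[length(w)] - 1) > 1e-9)
    return("cumulative weights must start at 0 and end at 1")
  if (any(diff(w) < -1e-12)) return("cumulative weights must be non-decreasing")
  if (!all(dim(object@mlcLeft) == dim(object@mlcRight)) ||
      nrow(object@mlcLeft) != length(w))
    return("leaf position matrices must be K x n_pairs")
  if (any(object@mlcLeft > object@mlcRight + 1e-9))
    return("left leaf position must not exceed right leaf position")
  if (nrow(object@jaws) != length(w) || ncol(object@jaws) != 4L)
    return("jaws must be a K x 4 matrix")
  if (any(object@jaws[, 1L] >= object@jaws[, 2L]) ||
      any(object@jaws[, 3L] >= object@jaws[, 4L]))
    return("jaws must satisfy x1 < x2 and y1 < y2")
  if (object@mu < 0) return("field MU must be non-negative")
  TRUE
})

#' @rdname ControlPointSequence-class
#' @param weights,mlcLeft,mlcRight,jaws,mu see slots.
#' @return A \code{ControlPointSequence}.
#' @export
controlPointSequence <- function(weights, mlcLeft, mlcRight, jaws, mu) {
  if (is.null(dim(jaws))) jaws <- matrix(jaws, nrow = length(weights),
                                         ncol = 4L, byrow = TRUE)
  new("ControlPointSequence", weights = as.numeric(weights),
      mlcLeft = as.matrix(mlcLeft), mlcRight = as.matrix(mlcRight),
      jaws = as.matrix(jaws), mu = as.numeric(mu))
}

#' One treatment-planning case
#'
#' All per-case volumetric data on a shared isocenter-centered grid: the CT
#' (HU), the PTV prescription mask (cGy; every voxel carries the maximum
#' prescription among the targets covering it, 0 outside all targets), the
#' five individual PTV masks, the seventeen OAR masks, the planned dose
#' (cGy), and the per-beam fluence stack (MU) as a rows x cols x 9 array
#' ordered by ascending gantry angle. Network inputs are formed from the
#' PTV prescription mask, the 17 OAR masks, and the CT: 19 channels.
#'
#' @slot grid a \code{GridSpec}.
#' @slot beams a \code{BeamGeometry}.
#' @slot ct numeric array (nx, ny, nz), HU.
#' @slot ptvDose numeric array, prescription-filled PTV mask (cGy).
#' @slot ptvMasks named list of 5 binary arrays (see \code{ptvNames}).
#' @slot oarMasks named list of 17 binary arrays (see \code{oarNames}).
#' @slot dose numeric array, planned dose (cGy).
#' @slot fluence numeric array (planeRows, planeCols, 9), MU.
#' @slot prescriptions named numeric, prescription levels (cGy).
#' @slot seed integer(1), generator seed (NA for ingested cases).
#' @export
setClass("PatientCase", representation(
  grid = "GridSpec", beams = "BeamGeometry", ct = "array",
  ptvDose = "array", ptvMasks = "list", oarMasks = "list", dose = "array",
  fluence = "array", prescriptions = "numeric", seed = "integer"))

setValidity("PatientCase", function(object) {
  d <- object@grid@dims
  arrs <- list(ct = object@ct, ptvDose = object@ptvDose, dose = object@dose)
  for (nm in names(arrs))
    if (!all(dim(arrs[[nm]]) == d))
      return(sprintf("'%s' does not match the grid dims", nm))
  if (!identical(sort(names(object@oarMasks)), sort(oarNames())))
    return("oarMasks must contain exactly the 17 canonical OARs")
  if (!identical(sort(names(object@ptvMasks)), sort(ptvNames())))
    return("ptvMasks must contain exactly the 5 canonical PTVs")
  for (nm in names(object@oarMasks))
    if (!all(dim(object@oarMasks[[nm]]) == d))
      return(sprintf("OAR mask '%s' does not match the grid dims", nm))
  for (nm in names(object@ptvMasks))
    if (!all(dim(object@ptvMasks[[nm]]) == d))
      return(sprintf("PTV mask '%s' does not match the grid dims", nm))
  body <- object@oarMasks[["body"]]
  for (nm in names(object@oarMasks))
    if (any(object@oarMasks[[nm]] > body))
      return(sprintf("OAR '%s' extends outside the body", nm))
  for (nm in names(object@ptvMasks))
    if (any(object@ptvMasks[[nm]] > body))
      return(sprintf("PTV '%s' extends outside the body", nm))
  pm <- object@ptvMasks
  if (any(pm[["PTV-GTV"]] > pm[["PTV-1"]]) || any(pm[["PTV-1"]] > pm[["PTV-2"]]))
    return("PTV nesting violated: need PTV-GTV within PTV-1 within PTV-2")
  lv <- unique(as.vector(object@ptvDose))
  ok <- c(0, unname(object@prescriptions))
  if (!all(lv %in% ok))
    return("ptvDose values must be 0 or one of the prescription levels")
  nb <- length(object@beams@gantryAngles)
  fd <- dim(object@fluence)
  if (length(fd) != 3L || fd[1L] != object@beams@planeRows ||
      fd[2L] != object@beams@planeCols || fd[3L] != nb)
    return("fluence must be a planeRows x planeCols x n_beams array")
  TRUE
})

#' Shared-encoder dose/fluence prediction model
#'
#' Configuration plus learned parameters of the dual-decoder network: one
#' encoder (five resolution levels), a dose decoder and a fluence decoder
#' (four levels each, the fluence decoder also fed by the dose decoder's
#' feature maps), the fluence head ending in the geometric projection.
#'
#' @slot config named list, see \code{\link{modelConfig}}.
#' @slot params named list of parameter arrays.
#' @export
setClass("SharedEncoderModel", representation(
  config = "list", params = "list"))

#' Cohort evaluation report
#'
#' Per-case and cohort metrics: per-beam fluence MAE%, SSIM and gamma pass
#' rates, per-structure clinical dose indices (Gy) for the ground-truth,
#' predicted and predicted-fluence-generated doses, cohort mean +/- SD, and
#' paired-test p-values.
#'
#' @slot fluence data.frame of per-case, per-beam fluence metrics.
#' @slot doseIndices data.frame of per-case, per-structure indices (Gy).
#' @slot summary data.frame of cohort means and SDs with p-values.
#' @slot fluenceSummary data.frame of cohort fluence-metric means and SDs.
#' @export
setClass("EvalReport", representation(
  fluence = "data.frame", doseIndices = "data.frame",
  summary = "data.frame", fluenceSummary = "data.frame"))
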