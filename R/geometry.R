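## Beam geometry and the divergent-beam 3D -> 2D projection operator.
##
## Frame convention (fixed, do not change): millimetres in
## (left, posterior, superior), isocenter at the origin. Gantry angle 0
## places the source anterior; angles increase toward the patient's left.
## The fluence-plane row axis is the superior-inferior axis, so at equal
## pitch plane rows align 1:1 with CT slices at the isocenter plane.

#' Source position for a gantry angle
#'
#' Position of the radiation source in the patient frame (mm,
#' left/posterior/superior, isocenter origin). Angle 0 is anterior; angles
#' increase toward the patient's left; the source rotates in the axial
#' plane about the superior-inferior axis.
#'
#' @param angleDeg gantry angle in degrees (taken mod 360).
#' @param sad source-axis distance in mm (> 0).
#' @return numeric(3), mm.
#' @export
#' @examples
#' gantrySourcePosition(0, 1000)    # (0, -1000, 0): anterior
#' gantrySourcePosition(180, 1000)  # (0, +1000, 0): posterior
gantrySourcePosition <- function(angleDeg, sad = 1000) {
  stopifnot(sad > 0)
  th <- (angleDeg %% 360) * pi / 180
  c(sad * sin(th), -sad * cos(th), 0)
}

## crossplane (column-axis) unit vector of the fluence plane for an angle
beamColAxis <- function(angleDeg) {
  th <- (angleDeg %% 360) * pi / 180
  c(cos(th), sin(th), 0)
}

## offset such that grid slice s maps to fluence-plane row s + offset;
## requires slice spacing == plane pitch and a z-centered arrangement
planeRowOffset <- function(grid, beam) {
  if (abs(grid@spacing[3] - beam@planePitch) > 1e-9)
    stop("slice spacing must equal the fluence-plane pitch for row alignment")
  off <- (beam@planeRows - grid@dims[3]) / 2
  zoff <- grid@origin[3] + (grid@dims[3] - 1) / 2 * grid@spacing[3]
  if (abs(zoff) > 1e-6)
    stop("grid must be z-centered on the isocenter for row alignment")
  if (abs(off - round(off)) > 1e-9)
    stop("planeRows - n_slices must be even for row alignment")
  as.integer(round(off))
}

#' Build the sparse projection operator of one beam
#'
#' Casts a ray from the beam source through every voxel center, intersects
#' it with the isocenter fluence plane, and assigns the voxel to the
#' nearest beamlet pixel (ties broken toward the lower pixel index) with
#' weight (sad / source-voxel distance)^2 -- the inverse-square effect
#' only. Voxels whose ray leaves the fluence plane produce no entry and
#' mark the operator as truncated.
#'
#' @param grid a \code{\link{gridSpec}}.
#' @param beam a \code{\link{beamGeometry}}.
#' @param beamIndex 1-based index into \code{beam@gantryAngles}.
#' @param splat \code{"nearest"} (default) or \code{"bilinear"}; bilinear
#'   spreads each voxel over the 4 surrounding pixels for smoother
#'   gradients.
#' @return A \code{\link{ProjectionOperator-class}}.
#' @export
#' @examples
#' op <- buildProjectionOperator(gridSpec(8, 8, 4), beamGeometry(
#'   planeRows = 16L, planeCols = 16L), 1L)
buildProjectionOperator <- function(grid, beam, beamIndex,
                                    splat = c("nearest", "bilinear")) {
  splat <- match.arg(splat)
  stopifnot(beamIndex >= 1L, beamIndex <= length(beam@gantryAngles))
  angle <- beam@gantryAngles[beamIndex]
  src <- gantrySourcePosition(angle, beam@sad)
  eu <- beamColAxis(angle)
  d0 <- -src / beam@sad                       # unit vector source -> isocenter
  nx <- grid@dims[1]; ny <- grid@dims[2]; nz <- grid@dims[3]
  px <- grid@origin[1] + (seq_len(nx) - 1) * grid@spacing[1]
  py <- grid@origin[2] + (seq_len(ny) - 1) * grid@spacing[2]
  pz <- grid@origin[3] + (seq_len(nz) - 1) * grid@spacing[3]
  X <- rep(px, times = ny * nz)
  Y <- rep(rep(py, each = nx), times = nz)
  Z <- rep(pz, each = nx * ny)
  vx <- X - src[1]; vy <- Y - src[2]; vz <- Z - src[3]
  denom <- vx * d0[1] + vy * d0[2] + vz * d0[3]
  denom[denom <= 1e-9] <- NA   # voxels at or behind the source: no entry
  tpar <- beam@sad / denom                    # ray parameter at the plane
  qx <- src[1] + tpar * vx
  qy <- src[2] + tpar * vy
  qz <- src[3] + tpar * vz
  u <- qx * eu[1] + qy * eu[2] + qz * eu[3]   # crossplane mm
  w <- (beam@sad^2) / (vx^2 + vy^2 + vz^2)    # inverse-square weight
  pitch <- beam@planePitch
  colc <- u / pitch + (beam@planeCols + 1) / 2
  rowc <- qz / pitch + (beam@planeRows + 1) / 2
  nvox <- nx * ny * nz
  if (splat == "nearest") {
    ic <- ceiling(colc - 0.5)                 # ties toward the lower index
    ir <- ceiling(rowc - 0.5)
    keep <- !is.na(ic) & !is.na(ir) & ic >= 1L & ic <= beam@planeCols &
      ir >= 1L & ir <= beam@planeRows
    trunc <- !all(keep)
    P <- Matrix::sparseMatrix(
      i = which(keep), j = (ic[keep] - 1L) * beam@planeRows + ir[keep],
      x = w[keep], dims = c(nvox, beam@planeRows * beam@planeCols))
  } else {
    c0 <- floor(colc - 0.5); r0 <- floor(rowc - 0.5)
    fc <- colc - 0.5 - c0;   fr <- rowc - 0.5 - r0
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    dropped <- FALSE
    for (dc in 0:1) for (dr in 0:1) {
      cc <- c0 + dc + 1L; rr <- r0 + dr + 1L
      ww <- w * (if (dc) fc else 1 - fc) * (if (dr) fr else 1 - fr)
      keep <- !is.na(cc) & !is.na(rr) & cc >= 1L & cc <= beam@planeCols &
        rr >= 1L & rr <= beam@planeRows & ww > 0
      keep[is.na(keep)] <- FALSE
      dropped <- dropped || any(ww > 0 & !keep, na.rm = TRUE)
      ii <- c(ii, which(keep))
      jj <- c(jj, (cc[keep] - 1L) * beam@planeRows + rr[keep])
      xx <- c(xx, ww[keep])
    }
    trunc <- dropped
    P <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                              dims = c(nvox, beam@planeRows * beam@planeCols))
  }
  new("ProjectionOperator", beamIndex = as.integer(beamIndex),
      gantryAngle = angle, P = P, grid = grid, beam = beam,
      sliceRange = c(1L, nz),
      rowRange = c(1L, beam@planeRows), truncated = trunc)
}

#' Build the operators of all beams
#'
#' @inheritParams buildProjectionOperator
#' @return A list of \code{ProjectionOperator}s, one per gantry angle in
#'   ascending-angle order.
#' @export
buildPlanOperators <- function(grid, beam, splat = "nearest") {
  lapply(seq_along(beam@gantryAngles), function(b)
    buildProjectionOperator(grid, beam, b, splat = splat))
}

#' Restrict an operator to a contiguous slice patch
#'
#' Slices the full-volume operator to grid slices z1..z2 and the matching
#' fluence-plane rows, preserving the parent's truncated-projection edge
#' behavior: voxels outside the patch that would contribute to the kept
#' rows are simply absent, which is why the outermost patch rows are only
#' partially covered (beam divergence).
#'
#' @param op a full-volume \code{ProjectionOperator}.
#' @param z1,z2 1-based inclusive slice range.
#' @return A patch-restricted \code{ProjectionOperator}.
#' @export
patchOperator <- function(op, z1, z2) {
  grid <- op@grid; beam <- op@beam
  stopifnot(z1 >= 1L, z2 <= grid@dims[3], z1 <= z2)
  off <- planeRowOffset(grid, beam)
  r1 <- z1 + off; r2 <- z2 + off
  nxy <- grid@dims[1] * grid@dims[2]
  vox <- ((z1 - 1L) * nxy + 1L):(z2 * nxy)
  cols <- as.vector(outer(r1:r2, (seq_len(beam@planeCols) - 1L) *
                            beam@planeRows, `+`))
  methods::initialize(op, P = op@P[vox, cols, drop = FALSE],
                      sliceRange = c(as.integer(z1), as.integer(z2)),
                      rowRange = c(as.integer(r1), as.integer(r2)))
}

## dims of the (sub)volume an operator's rows refer to
opVolumeDims <- function(op) {
  c(op@grid@dims[1], op@grid@dims[2], op@sliceRange[2] - op@sliceRange[1] + 1L)
}

#' Project a feature volume to the fluence plane
#'
#' Computes f = t(P) \%*\% v: the beam's-eye-view projection of a feature
#' volume onto the fluence plane. Linear in v; the exact adjoint is
#' \code{\link{backprojectPlane}}, which is what gradient propagation
#' through the projection head uses.
#'
#' @param op a \code{ProjectionOperator} (full or patch-restricted).
#' @param v numeric array conforming to the operator's covered slices
#'   (nx, ny, n_covered_slices), or a vector of that length.
#' @return A rows x cols matrix on the covered fluence-plane rows.
#' @export
projectVolume <- function(op, v) {
  dd <- opVolumeDims(op)
  if (length(v) != prod(dd))
    stop("feature volume does not conform to the operator (need ",
         paste(dd, collapse = " x "), ")")
  f <- Matrix::crossprod(op@P, as.vector(v))
  matrix(as.vector(f), nrow = op@rowRange[2] - op@rowRange[1] + 1L,
         ncol = op@beam@planeCols)
}

#' Adjoint of \code{projectVolume}
#'
#' Computes P \%*\% f, spreading a fluence-plane map back into the voxel
#' grid. Satisfies the adjoint identity
#' \code{sum(projectVolume(op, v) * f) == sum(v * backprojectPlane(op, f))}.
#'
#' @param op a \code{ProjectionOperator}.
#' @param f a rows x cols matrix on the operator's covered plane rows.
#' @return numeric array (nx, ny, n_covered_slices).
#' @export
backprojectPlane <- function(op, f) {
  dd <- opVolumeDims(op)
  nr <- op@rowRange[2] - op@rowRange[1] + 1L
  if (length(f) != nr * op@beam@planeCols)
    stop("plane map does not conform to the operator")
  array(as.vector(op@P %*% as.vector(f)), dim = dd)
}

#' Beam's-eye-view target mask with margin
#'
#' Pixels of the fluence plane receiving any projection from target
#' voxels, dilated by a Euclidean disc of radius \code{marginMm} (2 pixels
#' at the default 5 mm margin and 2.5 mm pitch). Used to restrict fluence
#' losses and fluence evaluation metrics to the projected PTV.
#'
#' @param ptvMask binary volume conforming to \code{op}'s covered slices.
#' @param op a \code{ProjectionOperator}.
#' @param marginMm margin in mm (>= 0, default 5).
#' @return Logical rows x cols matrix.
#' @export
bevTargetMask <- function(ptvMask, op, marginMm = 5) {
  stopifnot(marginMm >= 0)
  if (!any(ptvMask != 0)) {
    warning("empty PTV mask: beam's-eye-view target mask is empty")
    return(matrix(FALSE, op@rowRange[2] - op@rowRange[1] + 1L,
                  op@beam@planeCols))
  }
  foot <- projectVolume(op, as.numeric(ptvMask != 0)) > 0
  r <- marginMm / op@beam@planePitch
  dilateDisc(foot, r)
}

## binary dilation by a Euclidean disc of radius r pixels
dilateDisc <- function(mask, r) {
  if (r <= 0) return(mask)
  ri <- floor(r)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (dr in -ri:ri) for (dc in -ri:ri) {
    if (dr * dr + dc * dc > r * r + 1e-9 || (dr == 0 && dc == 0)) next
    sr <- intersect(seq_len(nr), seq_len(nr) - dr)
    sc <- intersect(seq_len(nc), seq_len(nc) - dc)
    out[sr + dr, sc + dc] <- out[sr + dr, sc + dc] | mask[sr, sc]
  }
  out
}
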