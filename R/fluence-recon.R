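## Ground-truth fluence reconstruction from MLC control-point sequences:
## weighted summation of intermediate MLC/jaw transmission masks.

## fluence-plane pixel-center coordinates (mm): columns = crossplane (leaf
## travel) axis, rows = inplane (superior-inferior) axis
planePixelCenters <- function(beam) {
  list(u = (seq_len(beam@planeCols) - (beam@planeCols + 1) / 2) * beam@planePitch,
       v = (seq_len(beam@planeRows) - (beam@planeRows + 1) / 2) * beam@planePitch)
}

#' Aperture/transmission mask of one machine snapshot
#'
#' Per fluence-plane pixel center: 1 inside the jaw rectangle and between
#' the (DLG-widened) leaf tips of the pixel's leaf pair, the MLC
#' transmission value inside the jaws but under a leaf, and the jaw
#' transmission outside the jaws. Pixel-center sampling; an optional 4x
#' supersampling flag anti-aliases region edges by area-averaging.
#'
#' @param mlcLeft,mlcRight numeric vectors of per-pair leaf tip positions
#'   (mm at the isocenter plane, crossplane axis), left <= right.
#' @param jaws numeric(4): x1, x2, y1, y2 jaw positions (mm).
#' @param model an \code{\link{mlcModel}}.
#' @param beam a \code{\link{beamGeometry}} defining the plane.
#' @param supersample logical; if TRUE, sample each pixel at 4x4 subpixel
#'   centers and average.
#' @return rows x cols matrix with values in [0, 1].
#' @export
apertureTransmissionMask <- function(mlcLeft, mlcRight, jaws, model, beam,
                                     supersample = FALSE) {
  stopifnot(length(mlcLeft) == length(mlcRight),
            all(mlcLeft <= mlcRight + 1e-9), length(jaws) == 4L)
  if (length(mlcLeft) != length(model@leafBoundaries) - 1L)
    stop("leaf position count does not match the model's leaf boundaries")
  if (supersample) {
    sub <- (seq_len(4) - 2.5) / 4 * beam@planePitch
    acc <- 0
    for (dv in sub) for (du in sub)
      acc <- acc + apertureSample(mlcLeft, mlcRight, jaws, model, beam, du, dv)
    return(acc / 16)
  }
  apertureSample(mlcLeft, mlcRight, jaws, model, beam, 0, 0)
}

apertureSample <- function(mlcLeft, mlcRight, jaws, model, beam, du, dv) {
  pc <- planePixelCenters(beam)
  u <- pc$u + du; v <- pc$v + dv
  pair <- findInterval(v, model@leafBoundaries, left.open = FALSE,
                       rightmost.closed = TRUE)
  if (any(pair < 1L | pair > length(mlcLeft)))
    stop("fluence-plane rows not covered by any leaf pair; extend ",
         "leafBoundaries in the MLC model")
  inJawU <- u >= jaws[1] & u <= jaws[2]
  inJawV <- v >= jaws[3] & v <= jaws[4]
  half <- model@dlg / 2
  lo <- mlcLeft[pair] - half   # per-row opening, recycled down columns
  hi <- mlcRight[pair] + half
  U <- matrix(u, nrow = length(v), ncol = length(u), byrow = TRUE)
  open <- U > lo & U < hi
  jaw <- outer(inJawV, inJawU, `&`)
  out <- matrix(model@jawTransmission, length(v), length(u))
  out[jaw] <- model@transmission
  out[jaw & open] <- 1
  out
}

#' Fluence map of one field from its control-point sequence
#'
#' For every adjacent pair of control points, takes the midpoint
#' interpolation of leaf and jaw positions, forms its
#' aperture/transmission mask, weights it by the meterset increment, sums
#' over segments, and scales by the field MU. Static fields (two identical
#' control points) reduce to MU times the aperture mask, and
#' re-partitioning segments with unchanged positions leaves the fluence
#' unchanged.
#'
#' @param cps a \code{\link{controlPointSequence}}.
#' @param model an \code{\link{mlcModel}}.
#' @param beam a \code{\link{beamGeometry}}.
#' @param supersample passed to \code{\link{apertureTransmissionMask}}.
#' @return rows x cols fluence map in MU.
#' @export
fluenceFromControlPoints <- function(cps, model, beam, supersample = FALSE) {
  stopifnot(methods::is(cps, "ControlPointSequence"))
  methods::validObject(cps)
  K <- length(cps@weights)
  acc <- matrix(0, beam@planeRows, beam@planeCols)
  for (k in seq_len(K - 1L)) {
    dw <- cps@weights[k + 1L] - cps@weights[k]
    if (dw <= 0) next
    ml <- (cps@mlcLeft[k, ] + cps@mlcLeft[k + 1L, ]) / 2
    mr <- (cps@mlcRight[k, ] + cps@mlcRight[k + 1L, ]) / 2
    jw <- (cps@jaws[k, ] + cps@jaws[k + 1L, ]) / 2
    acc <- acc + dw * apertureTransmissionMask(ml, mr, jw, model, beam,
                                               supersample = supersample)
  }
  cps@mu * acc
}

#' Stack per-field fluence maps into a plan fluence stack
#'
#' Orders the maps by ascending gantry angle from 0 and concatenates them
#' into a rows x cols x n_beams array (9 x 160 x 160 in
#' slices-first notation at the default plane).
#'
#' @param maps list of per-field rows x cols fluence matrices.
#' @param gantryAngles numeric vector, the gantry angle of each map; the
#'   stack is ordered by ascending angle.
#' @param beam a \code{\link{beamGeometry}}; the maps must match its plane
#'   and angle set.
#' @return numeric array (planeRows, planeCols, n_beams).
#' @export
stackPlanFluence <- function(maps, gantryAngles, beam = beamGeometry()) {
  nb <- length(beam@gantryAngles)
  if (length(maps) != nb)
    stop("need exactly ", nb, " fluence maps (one per beam)")
  if (length(gantryAngles) != nb ||
      !isTRUE(all.equal(sort(gantryAngles %% 360), beam@gantryAngles)))
    stop("map gantry angles must match the beam geometry's angle set")
  ord <- order(gantryAngles %% 360)
  out <- array(0, dim = c(beam@planeRows, beam@planeCols, nb))
  for (b in seq_len(nb)) {
    m <- maps[[ord[b]]]
    if (!all(dim(m) == c(beam@planeRows, beam@planeCols)))
      stop("fluence map ", ord[b], " has the wrong shape")
    out[, , b] <- m
  }
  out
}

#' Simulate a nine-field sliding-window control-point plan
#'
#' Generates a synthetic but machine-plausible control-point sequence per
#' beam: a leaf aperture sweeping across the field in \code{nSegments}
#' steps with per-pair jitter, jaws enclosing the swept region, and a
#' random field meterset. Deterministic given the seed. Useful as input to
#' \code{\link{fluenceFromControlPoints}} when no DICOM plan is available.
#'
#' @param seed integer seed.
#' @param beam a \code{\link{beamGeometry}}.
#' @param model an \code{\link{mlcModel}}.
#' @param nSegments segments per field (>= 1).
#' @param fieldMu mean field meterset in MU.
#' @return list of \code{ControlPointSequence}, one per gantry angle.
#' @export
simulatePlanControlPoints <- function(seed, beam = beamGeometry(),
                                      model = mlcModel(), nSegments = 5L,
                                      fieldMu = 200) {
  withSeed(seed, {
    npair <- length(model@leafBoundaries) - 1L
    half <- beam@planeCols * beam@planePitch / 2
    lapply(seq_along(beam@gantryAngles), function(b) {
      width <- stats::runif(1, 0.15, 0.3) * 2 * half
      span <- stats::runif(1, 0.5, 0.7) * 2 * half
      x0 <- -span / 2
      K <- nSegments + 1L
      starts <- seq(x0, x0 + span - width, length.out = K)
      jitL <- matrix(stats::runif(K * npair, -4, 4), K, npair)
      jitR <- matrix(stats::runif(K * npair, -4, 4), K, npair)
      left <- starts + jitL
      right <- starts + width + jitR
      bad <- left > right
      if (any(bad)) {
        mid <- (left + right) / 2
        left[bad] <- mid[bad] - 0.5
        right[bad] <- mid[bad] + 0.5
      }
      vext <- stats::runif(1, 0.3, 0.45) * beam@planeRows * beam@planePitch
      jaws <- c(x0 - 10, x0 + span + 10, -vext, vext)
      controlPointSequence(
        weights = seq(0, 1, length.out = K),
        mlcLeft = left, mlcRight = right,
        jaws = matrix(jaws, K, 4, byrow = TRUE),
        mu = fieldMu * stats::runif(1, 0.7, 1.3))
    })
  })
}
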