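## Whole-volume prediction: sliding windows along the slice axis with
## logarithmic overlap blending, denormalization and coverage
## renormalization.

#' Plan sliding windows along the slice axis
#'
#' Windows of \code{patch} slices at the given stride (reference values:
#' patch 32, stride 24, i.e. 8 overlap slices), starting at 0; if the
#' last regular window would overshoot the volume it is replaced by an
#' end-aligned window (n - patch, n). Returned as 0-based half-open
#' \code{c(start, end)} pairs whose union covers every slice.
#'
#' @param nSlices total slice count (>= patch).
#' @param patch window length in slices.
#' @param stride window stride in slices.
#' @return list of integer pairs.
#' @export
#' @examples
#' planWindows(56)   # [(0,32), (24,56)]
#' planWindows(70)   # [(0,32), (24,56), (38,70)]
planWindows <- function(nSlices, patch = 32L, stride = 24L) {
  stopifnot(stride >= 1L, patch >= 1L)
  if (nSlices < patch)
    stop("volume has fewer slices (", nSlices, ") than the window (",
         patch, ")")
  starts <- seq(0L, nSlices, by = stride)
  starts <- starts[starts + patch <= nSlices | seq_along(starts) == 1L]
  if (starts[length(starts)] + patch < nSlices)
    starts <- c(starts, nSlices - patch)
  starts[length(starts)] <- min(starts[length(starts)], nSlices - patch)
  starts <- unique(starts)
  lapply(starts, function(s) c(s, s + patch))
}

## per-window, per-slice blending weights: w(t) = ln(1+t)/ln(1+tmax) with
## t the slice's distance from the nearer window edge capped at the
## overlap width; across windows the weights are normalized to sum to 1
## (a slice covered by exactly one window is copied verbatim)
windowWeights <- function(plan, nSlices, overlap,
                          profile = c("log", "linear")) {
  profile <- match.arg(profile)
  tmax <- max(overlap, 1L)
  W <- matrix(0, length(plan), nSlices)
  for (i in seq_along(plan)) {
    w <- plan[[i]]
    L <- w[2] - w[1]
    o <- seq_len(L) - 1L
    t <- pmin(o, L - 1L - o, tmax)
    W[i, (w[1] + 1L):w[2]] <- if (profile == "log")
      log(1 + t) / log(1 + tmax) else t / tmax
  }
  tot <- colSums(W)
  bare <- tot <= 0
  if (any(bare)) {
    cover <- matrix(0, length(plan), nSlices)
    for (i in seq_along(plan)) {
      w <- plan[[i]]
      cover[i, (w[1] + 1L):w[2]] <- 1
    }
    W[, bare] <- cover[, bare, drop = FALSE]
    tot <- colSums(W)
  }
  sweep(W, 2L, tot, `/`)
}

#' Blend per-window outputs into a whole volume
#'
#' Per-slice weighted average of overlapping window outputs using the
#' logarithmic weight ramp (or a linear ramp). Weights form a partition
#' of unity at every slice; non-overlapped slices are copied verbatim.
#'
#' @param patches list of window outputs; each either a volume
#'   (nx, ny, patch) / (nx, ny, patch, C) or a fluence patch
#'   (patch, cols, beams) when \code{sliceDim = 1}.
#' @param plan the \code{\link{planWindows}} result.
#' @param nSlices total output slices.
#' @param overlap overlap width in slices used to cap the ramp (8 at
#'   reference scale).
#' @param profile "log" (default) or "linear" weight ramp.
#' @param sliceDim which array dimension indexes slices (3 for volumes,
#'   1 for fluence patches).
#' @return blended array.
#' @export
blendWindows <- function(patches, plan, nSlices, overlap = 8L,
                         profile = "log", sliceDim = 3L) {
  stopifnot(length(patches) == length(plan))
  W <- windowWeights(plan, nSlices, overlap, profile)
  d <- dim(patches[[1]])
  dOut <- d
  dOut[sliceDim] <- nSlices
  out <- array(0, dOut)
  idx <- lapply(dOut, seq_len)
  for (i in seq_along(plan)) {
    w <- plan[[i]]
    sl <- (w[1] + 1L):w[2]
    wt <- W[i, sl]
    p <- patches[[i]]
    if (sliceDim == 3L) {
      scaled <- sweep(p, 3L, wt, `*`)
      if (length(d) == 3L) out[, , sl] <- out[, , sl] + scaled
      else out[, , sl, ] <- out[, , sl, ] + scaled
    } else {
      scaled <- sweep(p, 1L, wt, `*`)
      out[sl, , ] <- out[sl, , ] + scaled
    }
  }
  out
}

#' Predict whole-case dose and fluence
#'
#' Normalizes the case inputs, runs the network on sliding windows
#' (stride 24, 8-slice overlap at reference scale), blends the window
#' outputs with the logarithmic ramp, and denormalizes (x 7000 cGy,
#' x 2000 MU). Fluence rows outside the covered plane rows stay zero.
#' Negative predictions are clamped to zero and counted. Deterministic
#' given the checkpoint.
#'
#' @param model a trained \code{SharedEncoderModel}.
#' @param case a \code{PatientCase}.
#' @param ops full-volume projection operators for the case grid.
#' @param config the \code{\link{trainConfig}} used in training.
#' @param stride window stride (defaults to patch - 8).
#' @return list with \code{dose} (cGy volume), \code{fluence} (MU stack
#'   on the full plane), \code{negClamped} (count), \code{plan}.
#' @export
predictCase <- function(model, case, ops = NULL, config = trainConfig("tiny"),
                        stride = NULL) {
  if (is.null(ops)) ops <- buildPlanOperators(case@grid, case@beams)
  ps <- config$patch_slices
  if (is.null(stride)) stride <- max(1L, ps - 8L)
  overlap <- ps - stride
  prep <- prepareCase(case, ops, config)
  nz <- case@grid@dims[3]
  plan <- planWindows(nz, ps, stride)
  dosePatches <- list(); fluPatches <- list()
  for (i in seq_along(plan)) {
    w <- plan[[i]]
    patch <- extractPatch(prep, w[1] + 1L, config)
    fw <- modelForward(model, patch$x, patch$ops, train = FALSE)
    dosePatches[[i]] <- fw$dose
    fluPatches[[i]] <- fw$fluence
  }
  doseN <- blendWindows(dosePatches, plan, nz, overlap, sliceDim = 3L)
  fluRows <- blendWindows(fluPatches, plan, nz, overlap, sliceDim = 1L)
  beams <- case@beams
  flu <- array(0, c(beams@planeRows, beams@planeCols,
                    length(beams@gantryAngles)))
  ro <- prep$rowOffset
  flu[(1L + ro):(nz + ro), , ] <- fluRows
  dose <- denormalizeValues(doseN, "dose", config)
  flu <- denormalizeValues(flu, "fluence", config)
  neg <- sum(dose < 0) + sum(flu < 0)
  dose[dose < 0] <- 0
  flu[flu < 0] <- 0
  list(dose = dose, fluence = flu, negClamped = neg, plan = plan)
}

#' Rescale a dose to match a reference's target coverage
#'
#' Finds the scale s (bisection on [0.5, 2]) such that the fractional
#' volume of the high-dose target receiving at least \code{level} in
#' s * dose equals that in the reference dose (volume-fraction tolerance
#' 1e-4), mirroring the clinical re-normalization of an imported plan to
#' the original target prescription coverage.
#'
#' @param dose dose volume to rescale (cGy).
#' @param gtvMask binary high-dose target mask (non-empty).
#' @param refDose reference dose volume (cGy).
#' @param level coverage dose level (cGy), typically the target
#'   prescription.
#' @param tol volume-fraction tolerance.
#' @return list(dose = scaled volume, scale = s).
#' @export
renormalizeToCoverage <- function(dose, gtvMask, refDose, level,
                                  tol = 1e-4) {
  m <- gtvMask > 0
  if (!any(m)) stop("empty target mask")
  dv <- dose[m]; rv <- refDose[m]
  target <- mean(rv >= level)
  cov <- function(s) mean(s * dv >= level)
  if (abs(cov(1) - target) <= tol)
    return(list(dose = dose, scale = 1))   # already matching coverage
  lo <- 0.5; hi <- 2.0
  if (cov(hi) < target - tol || cov(lo) > target + tol)
    stop("target coverage unreachable within scale bounds [0.5, 2]")
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (abs(cov(mid) - target) <= tol) { lo <- mid; hi <- mid; break }
    if (cov(mid) < target) lo <- mid else hi <- mid
  }
  s <- hi   # smallest scale meeting the coverage within tolerance
  if (abs(cov(lo) - target) <= abs(cov(hi) - target)) s <- lo
  list(dose = s * dose, scale = s)
}
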