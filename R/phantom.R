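## Synthetic nasopharyngeal-like digital phantoms: parametric anatomy,
## a simple forward dose engine (inverse square x exponential attenuation
## x Gaussian blur), and a projected-gradient reference-plan optimizer.
## The engine is deliberately simple -- enough to create a learnable
## anatomy -> dose/fluence mapping; fidelity to a clinical dose algorithm
## is a non-goal.

#' Phantom and dose-engine configuration
#'
#' Bundles the grid, beam geometry and generator parameters for one of
#' three scale profiles: \code{"default"} (64 slices of 224 x 224 voxels,
#' 160 x 160 fluence planes, all at 2.5 mm), \code{"tiny"} (32 x 96 x 96,
#' 9 x 64 x 64 fluence) and \code{"micro"} (16 x 48 x 48, 9 x 32 x 32) for
#' fast tests. Forward-engine parameters: \code{muEff} (effective linear
#' attenuation, mm^-1, default 0.004 for a 6 MV beam), \code{smoothSigmaMm}
#' (Gaussian dose blur, default 3 mm). Optimizer parameters: iteration
#' count, step scale (fraction of the inverse Lipschitz constant), and the
#' OAR/body quadratic penalty weights relative to the PTV term.
#'
#' @param profile one of "default", "tiny", "micro".
#' @param nSlices optional slice-count override (the per-case slice count
#'   varies in the clinic; the generator accepts 48-96 at default scale).
#' @param ... named overrides of any config field.
#' @return A named list.
#' @export
#' @examples
#' cfg <- phantomConfig("tiny")
phantomConfig <- function(profile = c("default", "tiny", "micro"),
                          nSlices = NULL, ...) {
  profile <- match.arg(profile)
  base <- switch(profile,
    default = list(nx = 224L, ny = 224L, nz = 64L, planeRows = 160L,
                   planeCols = 160L),
    tiny = list(nx = 96L, ny = 96L, nz = 32L, planeRows = 64L,
                planeCols = 64L),
    micro = list(nx = 48L, ny = 48L, nz = 16L, planeRows = 32L,
                 planeCols = 32L))
  if (!is.null(nSlices)) {
    if (profile == "default" && (nSlices < 48L || nSlices > 96L))
      stop("default-profile slice count must lie in 48..96")
    base$nz <- as.integer(nSlices)
  }
  cfg <- c(base, list(
    profile = profile,
    spacing = 2.5, planePitch = 2.5, sad = 1000,
    gantryAngles = seq(0, 320, by = 40),
    muEff = 0.004,
    smoothSigmaMm = switch(profile, default = 3, tiny = 2, micro = 1.5),
    engineGain = 2,
    optIterations = if (profile == "default") 80L else 300L,
    optStepScale = 1.0, optWOar = 0.05, optWBody = 0.005,
    ctNoiseHu = 20,
    prescriptionCombos = list(c(7000, 6400, 5800), c(7000, 6000, 5400)),
    nodalLevels = seq(6000, 7000, by = 200)))
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown phantom config field: ", nm)
    cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

phantomGrid <- function(cfg) gridSpec(cfg$nx, cfg$ny, cfg$nz, cfg$spacing)

phantomBeams <- function(cfg)
  beamGeometry(cfg$gantryAngles, cfg$sad, cfg$planeRows, cfg$planeCols,
               cfg$planePitch)

## axis-aligned ellipsoid mask; center/radii in mm; optional z clamp (mm)
ellipsoidMask <- function(grid, center, radii, zlim = NULL) {
  ax <- gridAxes(grid); d <- grid@dims
  q <- expandX((ax[[1]] - center[1])^2 / radii[1]^2, d) +
    expandY((ax[[2]] - center[2])^2 / radii[2]^2, d) +
    expandZ((ax[[3]] - center[3])^2 / radii[3]^2, d)
  m <- q <= 1
  if (!is.null(zlim)) {
    Z <- expandZ(ax[[3]], d)
    m <- m & Z >= zlim[1] & Z <= zlim[2]
  }
  array(as.numeric(m), dim = d)
}

## z-axis elliptic cylinder mask
cylinderMask <- function(grid, center, radii, zlim) {
  ax <- gridAxes(grid); d <- grid@dims
  q <- expandX((ax[[1]] - center[1])^2 / radii[1]^2, d) +
    expandY((ax[[2]] - center[2])^2 / radii[2]^2, d)
  Z <- expandZ(ax[[3]], d)
  array(as.numeric(q <= 1 & Z >= zlim[1] & Z <= zlim[2]), dim = d)
}

#' Hounsfield units to relative electron density
#'
#' Fixed two-segment linear ramp: air (-1000 HU) maps to 0, water (0 HU)
#' to 1 with slope 1/1000 below water, and bone-like values with slope
#' 1/1500 above water (1500 HU maps to 2.0); clamped at 0.
#'
#' @param hu numeric HU values.
#' @return relative densities, same shape.
#' @export
hounsfieldToDensity <- function(hu) {
  d <- ifelse(hu < 0, 1 + hu / 1000, 1 + hu / 1500)
  d[d < 0] <- 0
  if (!is.null(dim(hu))) dim(d) <- dim(hu)
  d
}

#' Generate phantom anatomy
#'
#' Builds one synthetic case (CT, five nested/lateral PTVs, seventeen
#' OARs, sampled prescriptions) deterministically from a seed. The body is
#' an elliptic cylinder of soft tissue with bone-like inserts; structures
#' are parametric ellipsoids/cylinders at anatomically plausible relative
#' positions (nested primary targets, lateral nodal targets, parotids
#' overlapping the outer target laterally, cord/brainstem
#' posterior-central, paired organs mirrored), with seeded jitter on
#' centers and radii. Dose and fluence are left zero.
#'
#' @param seed integer seed.
#' @param config a \code{\link{phantomConfig}}.
#' @return A \code{\link{PatientCase-class}} with zero dose and fluence.
#' @export
#' @examples
#' case <- generateAnatomy(1, phantomConfig("micro"))
generateAnatomy <- function(seed, config = phantomConfig()) {
  grid <- phantomGrid(config)
  beams <- phantomBeams(config)
  withSeed(seed, {
    d <- grid@dims
    Rx <- d[1] * grid@spacing[1] / 2
    Ry <- d[2] * grid@spacing[2] / 2
    Rz <- d[3] * grid@spacing[3] / 2
    axb <- 0.78 * Rx; ayb <- 0.72 * Ry   # body semi-axes
    jit <- function(x, f = 0.08) x * stats::runif(length(x), 1 - f, 1 + f)
    sh <- function(s) stats::runif(length(s), -1, 1) * s  # center shift (mm)

    body <- cylinderMask(grid, c(0, 0, 0), c(axb, ayb), c(-Rz, Rz))

    ## nested primary targets (built by union so nesting holds exactly)
    cG <- c(sh(0.03 * axb), -0.15 * ayb + sh(0.03 * ayb), sh(0.05 * Rz))
    rG <- jit(c(0.20 * axb, 0.16 * ayb, 0.28 * Rz))
    gtv <- ellipsoidMask(grid, cG, rG)
    ptv1 <- pmax(gtv, ellipsoidMask(grid, cG, jit(rG * 1.3, 0.04)))
    ptv2 <- pmax(ptv1, ellipsoidMask(grid, cG, jit(rG * 1.6, 0.04)))
    lnz <- c(-0.35 * Rz, 0.25 * Rz)
    lnL <- cylinderMask(grid, c(0.45 * axb + sh(0.03 * axb),
                                0.05 * ayb + sh(0.03 * ayb)),
                        jit(c(0.12, 0.12)) * min(axb, ayb), lnz)
    lnR <- cylinderMask(grid, c(-0.45 * axb + sh(0.03 * axb),
                                0.05 * ayb + sh(0.03 * ayb)),
                        jit(c(0.12, 0.12)) * min(axb, ayb), lnz)

    mm <- min(axb, ayb)
    oar <- list()
    oar$brainstem <- cylinderMask(grid, c(0, -0.45 * ayb),
                                  jit(c(0.09, 0.09)) * mm, c(0, 0.95 * Rz))
    oar$spinal_cord <- cylinderMask(grid, c(0, -0.45 * ayb),
                                    jit(c(0.06, 0.06)) * mm, c(-Rz, 0))
    oar$chiasm <- ellipsoidMask(grid, c(0, -0.2 * ayb, 0.55 * Rz),
                                jit(c(0.10, 0.05, 0.1)) * c(mm, mm, Rz))
    oar$tongue <- ellipsoidMask(grid, c(0, 0.45 * ayb, -0.3 * Rz),
                                jit(c(0.2 * axb, 0.16 * ayb, 0.3 * Rz)))
    for (s in c(1, -1)) {
      side <- if (s > 0) "l" else "r"
      oar[[paste0("optic_nerve_", side)]] <- ellipsoidMask(
        grid, c(s * 0.14 * axb, -0.05 * ayb, 0.55 * Rz),
        jit(c(0.1 * axb, 0.04 * ayb, 0.06 * Rz)))
      oar[[paste0("lens_", side)]] <- ellipsoidMask(
        grid, c(s * 0.2 * axb, 0.7 * ayb, 0.55 * Rz),
        jit(c(0.045, 0.045, 0.08)) * c(mm, mm, Rz))
      oar[[paste0("temporal_lobe_", side)]] <- ellipsoidMask(
        grid, c(s * 0.52 * axb, -0.15 * ayb, 0.6 * Rz),
        jit(c(0.18 * axb, 0.2 * ayb, 0.32 * Rz)))
      oar[[paste0("mandible_", side)]] <- ellipsoidMask(
        grid, c(s * 0.38 * axb, 0.45 * ayb, -0.55 * Rz),
        jit(c(0.16 * axb, 0.13 * ayb, 0.32 * Rz)))
      oar[[paste0("tmj_", side)]] <- ellipsoidMask(
        grid, c(s * 0.55 * axb, 0.1 * ayb, -0.05 * Rz),
        jit(c(0.06, 0.06, 0.1)) * c(mm, mm, Rz))
      oar[[paste0("parotid_", side)]] <- ellipsoidMask(
        grid, c(s * 0.52 * axb, 0.0, -0.15 * Rz),
        jit(c(0.22 * axb, 0.2 * ayb, 0.32 * Rz)))
    }
    ## clip everything to the body
    oar <- lapply(oar, function(m) m * body)
    ptvs <- lapply(list(`PTV-GTV` = gtv, `PTV-1` = ptv1, `PTV-2` = ptv2,
                        `PTV-LN-L` = lnL, `PTV-LN-R` = lnR),
                   function(m) m * body)
    if (any(vapply(ptvs, sum, 0) == 0) || any(vapply(oar, sum, 0) == 0))
      stop("grid too small to place all structures")
    oar <- c(list(body = body), oar)[oarNames()]

    ## CT: air background, soft-tissue body, bone-like inserts, smooth noise
    ct <- array(-1000, dim = d)
    ct[body > 0] <- 40
    ct[oar$tongue > 0] <- 60
    spine <- cylinderMask(grid, c(0, -0.45 * ayb), c(0.12, 0.12) * mm,
                          c(-Rz, Rz))
    for (bone in list(spine, oar$mandible_l, oar$mandible_r, oar$tmj_l,
                      oar$tmj_r))
      ct[bone > 0] <- 700
    if (config$ctNoiseHu > 0) {
      n <- cpp_gauss_blur(array(stats::rnorm(prod(d)), dim = d), rep(1.5, 3))
      ct <- ct + (n / stats::sd(n)) * config$ctNoiseHu * body
    }

    combo <- config$prescriptionCombos[[sample.int(2, 1)]]
    presc <- c(combo, sample(config$nodalLevels, 1), sample(config$nodalLevels, 1))
    names(presc) <- ptvNames()
    ptvDose <- zeroVolume(grid)
    for (nm in ptvNames())
      ptvDose <- pmax(ptvDose, ptvs[[nm]] * presc[[nm]])

    new("PatientCase", grid = grid, beams = beams, ct = ct,
        ptvDose = ptvDose, ptvMasks = ptvs, oarMasks = oar,
        dose = zeroVolume(grid),
        fluence = array(0, c(beams@planeRows, beams@planeCols,
                             length(beams@gantryAngles))),
        prescriptions = presc, seed = as.integer(seed))
  })
}

## per-beam dose transfer matrices: the projection operator with each
## voxel's inverse-square weight further scaled by exponential attenuation
## along the radiological depth from the source
doseTransferMatrices <- function(ct, grid, beams, ops, muEff, gain = 2) {
  dens <- hounsfieldToDensity(ct)
  step <- min(grid@spacing)
  lapply(seq_along(ops), function(b) {
    src <- gantrySourcePosition(beams@gantryAngles[b], beams@sad)
    depth <- cpp_ray_depth(dens, grid@spacing, grid@origin, src, step)
    att <- exp(-muEff * as.vector(depth))
    D <- ops[[b]]@P
    D@x <- gain * D@x * att[D@i + 1L]
    D
  })
}

#' Phantom forward dose engine
#'
#' Desk-scale stand-in for a clinical dose algorithm:
#' dose(voxel) = sum over beams of fluence at the voxel's beamlet times the
#' inverse-square weight times exp(-muEff * radiological depth), followed
#' by a 3D Gaussian blur (sigma \code{smoothSigmaMm}); radiological depth
#' is the path integral of \code{\link{hounsfieldToDensity}} along the
#' source-voxel ray. Linear and non-negative in the fluence.
#'
#' @param fluence rows x cols x n_beams stack (MU).
#' @param ct HU volume on the operators' grid.
#' @param ops list of full-volume \code{ProjectionOperator}s (one per beam).
#' @param muEff effective attenuation (mm^-1).
#' @param smoothSigmaMm Gaussian blur sigma in mm (0 disables).
#' @param gain engine calibration in cGy per MU of beamlet fluence at the
#'   isocenter (default 2), chosen so clinical-range target doses are
#'   reached with per-beam fluences well inside the 2000 MU scale.
#' @param transfer optional precomputed \code{doseTransferMatrices} output
#'   (they depend on ct/ops/muEff only and are reused by the optimizer).
#' @return dose volume (cGy), dims of the grid.
#' @export
forwardDose <- function(fluence, ct, ops, muEff = 0.004, smoothSigmaMm = 3,
                        gain = 2, transfer = NULL) {
  if (length(ops) == 0) stop("no projection operators supplied")
  grid <- ops[[1]]@grid; beams <- ops[[1]]@beam
  nb <- length(ops)
  stopifnot(dim(fluence)[3] == nb)
  if (is.null(transfer))
    transfer <- doseTransferMatrices(ct, grid, beams, ops, muEff, gain)
  dose <- numeric(prod(grid@dims))
  for (b in seq_len(nb))
    dose <- dose + as.vector(transfer[[b]] %*% as.vector(fluence[, , b]))
  dose <- array(dose, dim = grid@dims)
  if (smoothSigmaMm > 0)
    dose <- cpp_gauss_blur(dose, smoothSigmaMm / grid@spacing)
  dose
}

#' Optimize a reference fluence for a phantom case
#'
#' Projected-gradient descent (non-negativity projection each step) on a
#' weighted least-squares objective: (dose - prescription)^2 inside the
#' PTVs, plus down-weighted (dose - 0)^2 penalties inside OARs and the
#' rest of the body, with the dose given by the un-smoothed forward
#' engine. The step size is \code{optStepScale} divided by a
#' power-iteration estimate of the objective's Lipschitz constant, which
#' keeps the objective non-increasing; five consecutive increases raise a
#' step-size error.
#'
#' @param case a \code{PatientCase} (anatomy is used; dose/fluence ignored).
#' @param ops list of full-volume projection operators.
#' @param config a \code{\link{phantomConfig}}.
#' @param transfer optional precomputed transfer matrices.
#' @return list with \code{fluence} (rows x cols x beams, MU),
#'   \code{objective} (per-iteration values), and \code{transfer}.
#' @export
optimizeReferenceFluence <- function(case, ops, config = phantomConfig(),
                                     transfer = NULL) {
  grid <- case@grid; beams <- case@beams
  nb <- length(ops)
  if (is.null(transfer))
    transfer <- doseTransferMatrices(case@ct, grid, beams, ops, config$muEff,
                                     config$engineGain)
  D <- do.call(cbind, transfer)
  tgt <- as.vector(case@ptvDose)
  ptv <- tgt > 0
  oarAny <- Reduce(`|`, lapply(case@oarMasks[setdiff(oarNames(), "body")],
                               function(m) as.vector(m) > 0))
  body <- as.vector(case@oarMasks[["body"]]) > 0
  w <- numeric(length(tgt))
  w[body] <- config$optWBody
  w[oarAny & !ptv] <- config$optWOar
  w[ptv] <- 1
  ## Lipschitz estimate of grad = D' W D via power iteration
  nf <- ncol(D)
  v <- rep(1, nf)
  for (i in 1:12) {
    v <- as.vector(Matrix::crossprod(D, w * as.vector(D %*% v)))
    nv <- sqrt(sum(v^2))
    if (nv == 0) break
    v <- v / nv
  }
  L <- max(nv, 1e-12)
  step <- config$optStepScale / L
  f <- numeric(nf)
  obj <- numeric(config$optIterations)
  prev <- Inf; bad <- 0L
  for (it in seq_len(config$optIterations)) {
    r <- as.vector(D %*% f) - tgt
    obj[it] <- 0.5 * sum(w * r^2)
    if (obj[it] > prev + 1e-9) {
      bad <- bad + 1L
      if (bad > 5L) stop("reference-fluence optimization diverged; ",
                         "reduce optStepScale")
    } else bad <- 0L
    prev <- obj[it]
    g <- as.vector(Matrix::crossprod(D, w * r))
    f <- pmax(0, f - step * g)
  }
  nbml <- beams@planeRows * beams@planeCols
  fl <- array(f, dim = c(beams@planeRows, beams@planeCols, nb))
  list(fluence = fl, objective = obj, transfer = transfer)
}

#' Generate one complete phantom case
#'
#' Anatomy, reference fluence (optimizer) and planned dose (forward engine
#' with smoothing), assembled into a validated \code{PatientCase}.
#' Deterministic given the seed.
#'
#' @param seed integer seed.
#' @param config a \code{\link{phantomConfig}}.
#' @param ops optional precomputed full-volume operators (rebuilt if NULL).
#' @return A \code{\link{PatientCase-class}}.
#' @export
#' @examples
#' case <- generateCase(1, phantomConfig("micro"))
generateCase <- function(seed, config = phantomConfig(), ops = NULL) {
  case <- generateAnatomy(seed, config)
  if (is.null(ops)) ops <- buildPlanOperators(case@grid, case@beams)
  opt <- optimizeReferenceFluence(case, ops, config)
  dose <- forwardDose(opt$fluence, case@ct, ops, muEff = config$muEff,
                      smoothSigmaMm = config$smoothSigmaMm,
                      gain = config$engineGain, transfer = opt$transfer)
  case@fluence <- opt$fluence
  case@dose <- dose
  methods::validObject(case)
  case
}

#' Generate a cohort of phantom cases with a split manifest
#'
#' @param seeds integer vector of case seeds.
#' @param split character vector (train/val/test) aligned with seeds.
#' @param config a \code{\link{phantomConfig}}.
#' @return list with \code{cases} (list of PatientCase) and
#'   \code{manifest} (data.frame of seed, split, prescriptions).
#' @export
generateCohort <- function(seeds, split = rep("train", length(seeds)),
                           config = phantomConfig()) {
  stopifnot(length(split) == length(seeds))
  grid <- phantomGrid(config); beams <- phantomBeams(config)
  ops <- buildPlanOperators(grid, beams)
  cases <- lapply(seeds, generateCase, config = config, ops = ops)
  manifest <- data.frame(
    seed = as.integer(seeds), split = split,
    t(vapply(cases, function(cs) cs@prescriptions, numeric(5))),
    check.names = FALSE)
  list(cases = cases, manifest = manifest)
}
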