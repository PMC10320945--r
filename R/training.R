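## Dataset assembly, normalization, augmentation, the masked dual loss and
## the optimization loop.

#' Training configuration
#'
#' All training hyperparameters. Reference-scale values: 32-slice patches,
#' batch 2, Adam at initial learning rate 3e-4, reduce-on-plateau (factor
#' 0.7, i.e. a 30% cut, patience 4 epochs, relative improvement threshold
#' 1e-4), 150 epochs of 400 iterations, left-right flip probability 0.6,
#' rotation probability 0.4 over the eight 40-degree multiples,
#' normalization constants 7000 cGy (dose and PTV prescription mask),
#' 2000 MU (fluence) and 2000 HU (CT, after trimming to [-1024, 2000]),
#' and a fluence loss restricted to the middle patch rows (3 trimmed per
#' edge: 26 of 32 rows at reference scale). The desk-scale profiles keep
#' every normalization/augmentation constant and shrink only the patch,
#' epoch and iteration sizes.
#'
#' @param profile "default", "tiny" or "micro" (patch 32/32/16 slices).
#' @param ... named overrides.
#' @return named list.
#' @export
trainConfig <- function(profile = c("default", "tiny", "micro"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    patch_slices = if (profile == "micro") 16L else 32L,
    batch = 2L,
    initial_lr = 3e-4,
    plateau_factor = 0.7,
    plateau_patience = 4L,
    plateau_threshold = 1e-4,
    epochs = if (profile == "default") 150L else 10L,
    iterations_per_epoch = if (profile == "default") 400L else 50L,
    flip_prob = 0.6,
    rotation_prob = 0.4,
    rotation_angles = seq(40, 320, by = 40),
    dose_norm = 7000,
    fluence_norm = 2000,
    hu_window = c(-1024, 2000),
    hu_norm = 2000,
    edge_trim_rows = 3L,
    bev_margin_mm = 5,
    seed = 1L)
  ov <- list(...)
  for (nm in names(ov)) {
    if (!nm %in% names(cfg)) stop("unknown training config field: ", nm)
    cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Normalize raw physical values for the network
#'
#' Dose and the prescription-filled PTV mask are divided by 7000 cGy,
#' fluence by 2000 MU, and CT values are trimmed to [-1024, 2000] HU then
#' divided by 2000 HU. \code{denormalize} inverts the scaling (the HU clip
#' is lossy by construction).
#'
#' @param x numeric values.
#' @param what one of "dose", "ptv", "fluence", "hu".
#' @param config a \code{\link{trainConfig}}.
#' @return normalized values, same shape.
#' @export
#' @examples
#' normalizeValues(7000, "dose")        # 1
#' normalizeValues(3000, "hu")          # clipped to 2000 -> 1
#' normalizeValues(-1024, "hu")         # -0.512
normalizeValues <- function(x, what = c("dose", "ptv", "fluence", "hu"),
                            config = trainConfig()) {
  what <- match.arg(what)
  switch(what,
    dose = , ptv = x / config$dose_norm,
    fluence = x / config$fluence_norm,
    hu = pmin(pmax(x, config$hu_window[1]), config$hu_window[2]) /
      config$hu_norm)
}

#' @rdname normalizeValues
#' @export
denormalizeValues <- function(x, what = c("dose", "ptv", "fluence", "hu"),
                              config = trainConfig()) {
  what <- match.arg(what)
  switch(what,
    dose = , ptv = x * config$dose_norm,
    fluence = x * config$fluence_norm,
    hu = x * config$hu_norm)
}

#' Assemble the 19-channel normalized input volume of a case
#'
#' Channel 1: prescription-filled PTV mask / 7000 cGy; channels 2-18: the
#' seventeen OAR masks in canonical alphabetical order; channel 19:
#' trimmed, normalized CT.
#'
#' @param case a \code{PatientCase}.
#' @param config a \code{\link{trainConfig}}.
#' @return array (nx, ny, nz, 19).
#' @export
caseInputVolume <- function(case, config = trainConfig()) {
  d <- case@grid@dims
  out <- array(0, c(d, 19L))
  out[, , , 1L] <- normalizeValues(case@ptvDose, "ptv", config)
  for (i in seq_along(oarNames()))
    out[, , , 1L + i] <- case@oarMasks[[oarNames()[i]]]
  out[, , , 19L] <- normalizeValues(case@ct, "hu", config)
  out
}

## precompute everything reused across patch draws for one case
prepareCase <- function(case, ops, config) {
  ptvAny <- case@ptvDose > 0
  ptvSlices <- which(apply(ptvAny, 3, any))
  if (length(ptvSlices) == 0) stop("case rejected: PTV mask is empty")
  bev <- lapply(ops, function(op)
    bevTargetMask(ptvAny, op, config$bev_margin_mm))
  list(case = case,
       inputs = caseInputVolume(case, config),
       doseN = normalizeValues(case@dose, "dose", config),
       fluN = normalizeValues(case@fluence, "fluence", config),
       body = case@oarMasks[["body"]] > 0,
       bev = bev,                       # full-plane masks, one per beam
       ptvSlices = ptvSlices,
       ops = ops,
       rowOffset = planeRowOffset(case@grid, case@beams))
}

## slice the full-plane fluence stack / bev masks to patch rows
fluenceRowsForSlices <- function(stack, z1, z2, rowOffset) {
  stack[(z1 + rowOffset):(z2 + rowOffset), , , drop = FALSE]
}

#' Sample one training patch
#'
#' Uniformly chooses a window of \code{patch_slices} contiguous slices
#' among all starts whose window contains at least one slice with a
#' nonzero PTV mask, and extracts the aligned input stack, dose target,
#' fluence target rows, body-mask patch, per-beam BEV target masks and
#' patch-restricted projection operators. Draws come from the R RNG, so a
#' fixed seed gives a reproducible patch sequence.
#'
#' @param prep output of the internal case preparation (or a
#'   \code{PatientCase}; operators are then built on the fly).
#' @param config a \code{\link{trainConfig}}.
#' @param ops full-volume operators (only if \code{prep} is a case).
#' @return list with \code{x}, \code{dose}, \code{fluence}, \code{body},
#'   \code{bev} (rows x cols x beams logical), \code{ops} (patch
#'   operators), \code{z1}, \code{z2}.
#' @export
samplePatch <- function(prep, config = trainConfig(), ops = NULL) {
  if (methods::is(prep, "PatientCase")) {
    if (is.null(ops)) ops <- buildPlanOperators(prep@grid, prep@beams)
    prep <- prepareCase(prep, ops, config)
  }
  ps <- config$patch_slices
  nz <- dim(prep$inputs)[3]
  if (nz < ps) stop("case has fewer slices than the patch length")
  starts <- validPatchStarts(nz, ps, prep$ptvSlices)
  if (length(starts) == 0) stop("case rejected: no window intersects the PTV")
  z1 <- starts[sample.int(length(starts), 1L)]
  extractPatch(prep, z1, config)
}

## all window starts whose [z1, z1+ps-1] intersects the PTV slices
validPatchStarts <- function(nz, ps, ptvSlices) {
  s <- seq_len(nz - ps + 1L)
  s[vapply(s, function(z1) any(ptvSlices >= z1 & ptvSlices <= z1 + ps - 1L),
           TRUE)]
}

extractPatch <- function(prep, z1, config) {
  ps <- config$patch_slices
  z2 <- z1 + ps - 1L
  ro <- prep$rowOffset
  bev <- array(FALSE, c(ps, ncol(prep$bev[[1]]), length(prep$bev)))
  for (b in seq_along(prep$bev))
    bev[, , b] <- prep$bev[[b]][(z1 + ro):(z2 + ro), ]
  list(x = prep$inputs[, , z1:z2, , drop = FALSE],
       dose = prep$doseN[, , z1:z2],
       fluence = fluenceRowsForSlices(prep$fluN, z1, z2, ro),
       body = prep$body[, , z1:z2],
       bev = bev,
       ops = lapply(prep$ops, patchOperator, z1 = z1, z2 = z2),
       z1 = z1, z2 = z2)
}

#' Geometric training augmentation
#'
#' Left-right flip with probability 0.6 and rotation about the
#' superior-inferior axis by one of the eight multiples of 40 degrees
#' with probability 0.4 (independent draws, so no augmentation happens
#' with probability 0.4 * 0.6 = 0.24). Volumes are flipped/rotated
#' (nearest-neighbor resampling for masks, linear for CT and dose); the
#' nine fluence maps are transformed consistently: a flip maps beam angle
#' g to (360 - g) mod 360 and reverses the column axis, a rotation by
#' k*40 degrees cyclically shifts the beam channels by k.
#'
#' @param patch a \code{\link{samplePatch}} result.
#' @param config a \code{\link{trainConfig}}.
#' @param flip,rotK optional forced draws (logical / integer 0-8) for
#'   testing; NULL draws from the RNG via \code{\link{augmentDraw}}.
#' @return the transformed patch (operators are unchanged: they refer to
#'   the machine, not the patient).
#' @export
augmentPatch <- function(patch, config = trainConfig(), flip = NULL,
                         rotK = NULL) {
  if (is.null(flip) || is.null(rotK)) {
    d <- augmentDraw(config)
    if (is.null(flip)) flip <- d$flip
    if (is.null(rotK)) rotK <- d$rotK
  }
  nb <- dim(patch$bev)[3]
  if (flip) {
    patch$x <- patch$x[dim(patch$x)[1]:1, , , , drop = FALSE]
    patch$dose <- patch$dose[dim(patch$dose)[1]:1, , , drop = FALSE]
    patch$body <- patch$body[dim(patch$body)[1]:1, , , drop = FALSE]
    perm <- flipBeamPermutation(nb)
    patch$fluence <- patch$fluence[, dim(patch$fluence)[2]:1, perm,
                                   drop = FALSE]
    patch$bev <- patch$bev[, dim(patch$bev)[2]:1, perm, drop = FALSE]
  }
  if (rotK > 0L) {
    ang <- config$rotation_angles[rotK]
    k <- as.integer(round(ang / 40))
    patch$x <- rotateChannels(patch$x, ang,
                              nearest = c(FALSE, rep(TRUE, 17L), FALSE),
                              fill = c(0, rep(0, 17L), -0.512))
    patch$dose <- cpp_rotate_z(patch$dose, ang, FALSE, 0)
    patch$body <- cpp_rotate_z((patch$body) * 1, ang, TRUE, 0) > 0
    perm <- rotateBeamPermutation(nb, k)
    patch$fluence <- patch$fluence[, , perm, drop = FALSE]
    patch$bev <- patch$bev[, , perm, drop = FALSE]
  }
  patch
}

#' Draw one augmentation decision
#'
#' Independent draws: flip with probability \code{flip_prob} (0.6) and a
#' rotation (uniform over the eight 40-degree multiples) with probability
#' \code{rotation_prob} (0.4); with the reference probabilities a sample
#' is left unaugmented with probability 0.4 * 0.6 = 0.24.
#'
#' @param config a \code{\link{trainConfig}}.
#' @return list(flip = logical, rotK = 0 for none or the rotation index).
#' @export
augmentDraw <- function(config = trainConfig()) {
  flip <- stats::runif(1) < config$flip_prob
  rotK <- if (stats::runif(1) < config$rotation_prob)
    sample.int(length(config$rotation_angles), 1L) else 0L
  list(flip = flip, rotK = rotK)
}

## beam index permutation under a left-right flip: angle g -> (360 - g)
flipBeamPermutation <- function(nb) {
  ang <- seq(0, 360 - 360 / nb, by = 360 / nb)
  match((360 - ang) %% 360, ang)
}

## beam permutation under a patient rotation by +k steps: the map now at
## channel b was delivered at channel b - k before rotation
rotateBeamPermutation <- function(nb, k) ((seq_len(nb) - 1L - k) %% nb) + 1L

rotateChannels <- function(x, ang, nearest, fill) {
  for (c in seq_len(dim(x)[4])) {
    r <- cpp_rotate_z(x[, , , c], ang, nearest[c], fill[c])
    if (nearest[c]) r <- round(r)
    x[, , , c] <- r
  }
  x
}

#' Masked dual loss (dose + fluence mean absolute error)
#'
#' Sum of (i) the mean absolute dose error over body voxels and (ii) the
#' mean absolute fluence error over the per-beam BEV PTV+margin masks
#' restricted to the middle patch rows (the trimmed edge rows are not
#' fully covered by the patch volume because of beam divergence), both on
#' normalized scales. Also returns the loss gradients w.r.t. both
#' predictions. An empty mask skips its term with a warning.
#'
#' @param predDose,predFluence network outputs (normalized).
#' @param patch a \code{\link{samplePatch}} result (targets and masks).
#' @param config a \code{\link{trainConfig}}.
#' @return list(loss, doseTerm, fluenceTerm, dDose, dFluence).
#' @export
dualLoss <- function(predDose, predFluence, patch, config = trainConfig()) {
  dDose <- array(0, dim(predDose))
  doseTerm <- 0
  nb <- sum(patch$body)
  if (nb == 0) warning("empty body mask: dose loss term skipped")
  else {
    diff <- predDose - patch$dose
    doseTerm <- sum(abs(diff[patch$body])) / nb
    dDose[patch$body] <- sign(diff[patch$body]) / nb
  }
  fmask <- patch$bev
  tr <- config$edge_trim_rows
  nr <- dim(fmask)[1]
  if (tr > 0) fmask[c(seq_len(tr), nr + 1L - seq_len(tr)), , ] <- FALSE
  dFlu <- array(0, dim(predFluence))
  fluTerm <- 0
  nf <- sum(fmask)
  if (nf == 0) warning("empty fluence mask: fluence loss term skipped")
  else {
    diff <- predFluence - patch$fluence
    fluTerm <- sum(abs(diff[fmask])) / nf
    dFlu[fmask] <- sign(diff[fmask]) / nf
  }
  list(loss = doseTerm + fluTerm, doseTerm = doseTerm, fluenceTerm = fluTerm,
       dDose = dDose, dFluence = dFlu)
}

## Adam optimizer state and step
adamInit <- function(params)
  list(m = lapply(params, function(x) { x[] <- 0; x }),
       v = lapply(params, function(x) { x[] <- 0; x }),
       t = 0L, beta1 = 0.9, beta2 = 0.999, eps = 1e-8)

adamStep <- function(params, grads, st, lr) {
  st$t <- st$t + 1L
  b1t <- 1 - st$beta1^st$t
  b2t <- 1 - st$beta2^st$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st$m[[nm]] <- st$beta1 * st$m[[nm]] + (1 - st$beta1) * g
    st$v[[nm]] <- st$beta2 * st$v[[nm]] + (1 - st$beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / b1t) / (sqrt(st$v[[nm]] / b2t) + st$eps)
  }
  list(params = params, state = st)
}

#' Reduce-on-plateau learning-rate scheduler step
#'
#' Tracks the best validation loss; when it has not improved by the
#' relative threshold for more than \code{plateau_patience} consecutive
#' epochs, multiplies the learning rate by \code{plateau_factor} (0.7: a
#' 30% reduction) and resets the counter. Two plateau events therefore
#' leave the rate at \code{initial_lr * 0.7^2}.
#'
#' @param state list(lr, best, sinceBest) or NULL to initialize.
#' @param vloss current validation loss.
#' @param config a \code{\link{trainConfig}}.
#' @return updated state; \code{state$improved} says whether this epoch
#'   set a new best.
#' @export
plateauUpdate <- function(state, vloss, config = trainConfig()) {
  if (is.null(state))
    state <- list(lr = config$initial_lr, best = Inf, sinceBest = 0L)
  if (is.finite(vloss) &&
      vloss < state$best * (1 - config$plateau_threshold)) {
    state$best <- vloss
    state$sinceBest <- 0L
    state$improved <- TRUE
  } else {
    state$sinceBest <- state$sinceBest + 1L
    state$improved <- FALSE
    if (state$sinceBest > config$plateau_patience) {
      state$lr <- state$lr * config$plateau_factor
      state$sinceBest <- 0L
    }
  }
  state
}

## deterministic validation loss of one case: sliding windows, loss masks
## restricted to PTV-containing slices, no augmentation
validationLoss <- function(model, prep, config) {
  nz <- dim(prep$inputs)[3]
  ps <- config$patch_slices
  wins <- planWindows(nz, ps, max(1L, ps - 8L))
  keep <- vapply(wins, function(w)
    any(prep$ptvSlices > w[1] & prep$ptvSlices <= w[2]), TRUE)
  wins <- wins[keep]
  tot <- 0
  for (w in wins) {
    patch <- extractPatch(prep, w[1] + 1L, config)
    zz <- (w[1] + 1L):w[2]
    keepSlice <- zz %in% prep$ptvSlices
    patch$body <- patch$body & rep(keepSlice, each = prod(dim(patch$body)[1:2]))
    patch$bev <- patch$bev & array(rep(keepSlice,
                                       times = prod(dim(patch$bev)[2:3])),
                                   dim(patch$bev))
    fw <- modelForward(model, patch$x, patch$ops, train = FALSE)
    tot <- tot + suppressWarnings(
      dualLoss(fw$dose, fw$fluence, patch, config)$loss)
  }
  tot / max(length(wins), 1L)
}

#' Train the shared-encoder network
#'
#' Adam (batch 2, initial learning rate 3e-4) over
#' \code{epochs x iterations_per_epoch} sampled, augmented patches; after
#' every epoch the validation loss is computed (no augmentation, loss
#' masks restricted to PTV-containing slices, matching the model-selection
#' rule of keeping the checkpoint that best predicts the high-dose
#' region); reduce-on-plateau cuts the learning rate by 30% when the
#' validation loss has not improved for more than \code{plateau_patience}
#' epochs. The best-validation parameter set is retained.
#'
#' @param trainCases,valCases lists of \code{PatientCase} (disjoint).
#' @param config a \code{\link{trainConfig}}.
#' @param mconfig a \code{\link{modelConfig}}.
#' @param ops optional precomputed full-volume operators (shared grid).
#' @param verbose print per-epoch progress.
#' @return list with \code{model} (best checkpoint),
#'   \code{finalModel}, \code{history} (data.frame epoch/trainLoss/
#'   valLoss/lr), \code{config}, \code{mconfig}.
#' @export
trainModel <- function(trainCases, valCases, config = trainConfig("tiny"),
                       mconfig = modelConfig(base_channels = 8L),
                       ops = NULL, verbose = interactive()) {
  stopifnot(length(trainCases) >= 1L, length(valCases) >= 1L)
  grid <- trainCases[[1]]@grid; beams <- trainCases[[1]]@beams
  if (is.null(ops)) ops <- buildPlanOperators(grid, beams)
  withSeed(config$seed, {
    prepTrain <- lapply(trainCases, prepareCase, ops = ops, config = config)
    prepVal <- lapply(valCases, prepareCase, ops = ops, config = config)
    model <- buildModel(mconfig, seed = config$seed)
    adam <- adamInit(model@params)
    sched <- NULL
    lr <- config$initial_lr
    bestParams <- model@params
    hist <- data.frame()
    for (ep in seq_len(config$epochs)) {
      epLoss <- 0
      for (it in seq_len(config$iterations_per_epoch)) {
        grads <- NULL; bloss <- 0
        for (bi in seq_len(config$batch)) {
          prep <- prepTrain[[sample.int(length(prepTrain), 1L)]]
          patch <- augmentPatch(samplePatch(prep, config), config)
          fw <- modelForward(model, patch$x, patch$ops, train = TRUE)
          ls <- dualLoss(fw$dose, fw$fluence, patch, config)
          if (!is.finite(ls$loss))
            stop(sprintf(
              "non-finite loss at epoch %d iteration %d (dose %g, fluence %g)",
              ep, it, ls$doseTerm, ls$fluenceTerm))
          g <- modelBackward(model, fw, ls$dDose, ls$dFluence, patch$ops)
          grads <- if (is.null(grads)) g else
            mapply(`+`, grads, g, SIMPLIFY = FALSE)
          bloss <- bloss + ls$loss
        }
        grads <- lapply(grads, `/`, config$batch)
        upd <- adamStep(model@params, grads, adam, lr)
        model@params <- upd$params; adam <- upd$state
        epLoss <- epLoss + bloss / config$batch
      }
      epLoss <- epLoss / config$iterations_per_epoch
      vloss <- mean(vapply(prepVal, function(pv)
        validationLoss(model, pv, config), 0))
      sched <- plateauUpdate(sched, vloss, config)
      if (sched$improved) bestParams <- model@params
      lr <- sched$lr
      hist <- rbind(hist, data.frame(epoch = ep, trainLoss = epLoss,
                                     valLoss = vloss, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e",
                        ep, epLoss, vloss, lr))
    }
    bestModel <- model; bestModel@params <- bestParams
    list(model = bestModel, finalModel = model, history = hist,
         config = config, mconfig = mconfig)
  })
}
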