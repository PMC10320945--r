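## The shared-encoder network: one encoding path with five resolution
## levels; two decoding paths (dose, fluence) with four levels each, using
## trilinear upsampling + convolutions and skip concatenations; the
## fluence decoder additionally concatenates the dose decoder's feature
## map at every resolution level and ends in the geometric projection
## head f = t(P) %*% v.

#' Network configuration
#'
#' Defaults mirror the reference architecture: 19 input channels (PTV
#' prescription mask, 17 OARs in canonical alphabetical order, CT last),
#' base width 32 doubling per encoder level (32 to 512 at the deepest
#' level while the spatial size contracts 16-fold per transverse axis and
#' the slice axis), and a 9-channel pre-projection feature volume, one
#' channel per beam. Instance normalization uses learned affine terms.
#'
#' @param in_channels input channels (19).
#' @param base_channels first-level width (32; smaller for test profiles).
#' @param fluence_channels pre-projection channels, one per beam (9).
#' @return named list.
#' @export
#' @examples
#' modelConfig(base_channels = 8L)
modelConfig <- function(in_channels = 19L, base_channels = 32L,
                        fluence_channels = 9L) {
  list(in_channels = as.integer(in_channels),
       base_channels = as.integer(base_channels),
       fluence_channels = as.integer(fluence_channels),
       levels = 5L, affine = TRUE, eps = nnEps)
}

## layer table: name, kernel, cin, cout, stride, kind
modelLayers <- function(config) {
  C <- config$base_channels
  inC <- config$in_channels
  fc <- config$fluence_channels
  L <- list(
    list("enc1a", 3L, inC, C, 1L, "block"),
    list("enc1b", 3L, C, C, 1L, "block"),
    list("enc2d", 3L, C, 2L * C, 2L, "block"),
    list("enc2b", 3L, 2L * C, 2L * C, 1L, "block"),
    list("enc3d", 3L, 2L * C, 4L * C, 2L, "block"),
    list("enc3b", 3L, 4L * C, 4L * C, 1L, "block"),
    list("enc4d", 3L, 4L * C, 8L * C, 2L, "block"),
    list("enc4b", 3L, 8L * C, 8L * C, 1L, "block"),
    list("enc5d", 3L, 8L * C, 16L * C, 2L, "block"),
    list("enc5b", 3L, 16L * C, 16L * C, 1L, "block"),
    list("dd4a", 3L, 24L * C, 8L * C, 1L, "block"),
    list("dd4b", 3L, 8L * C, 8L * C, 1L, "block"),
    list("dd3a", 3L, 12L * C, 4L * C, 1L, "block"),
    list("dd3b", 3L, 4L * C, 4L * C, 1L, "block"),
    list("dd2a", 3L, 6L * C, 2L * C, 1L, "block"),
    list("dd2b", 3L, 2L * C, 2L * C, 1L, "block"),
    list("dd1a", 3L, 3L * C, C, 1L, "block"),
    list("dd1out", 1L, C, 1L, 1L, "lin"),
    list("fd4a", 3L, 32L * C, 8L * C, 1L, "block"),
    list("fd4b", 3L, 8L * C, 8L * C, 1L, "block"),
    list("fd3a", 3L, 16L * C, 4L * C, 1L, "block"),
    list("fd3b", 3L, 4L * C, 4L * C, 1L, "block"),
    list("fd2a", 3L, 8L * C, 2L * C, 1L, "block"),
    list("fd2b", 3L, 2L * C, 2L * C, 1L, "block"),
    list("fd1a", 3L, 4L * C, C, 1L, "block"),
    list("fd1out", 1L, C, fc, 1L, "lin"))
  names(L) <- vapply(L, `[[`, "", 1L)
  L
}

#' Build the shared-encoder model
#'
#' Initializes all convolution weights (He-normal, seeded) and instance
#' norm affine terms. Encoder level 1 is two stride-1 3x3x3 convolutions;
#' levels 2-5 are one stride-2 3x3x3 convolution (halving each axis,
#' doubling the channels) plus one stride-1 3x3x3 convolution; every
#' 3x3x3 convolution is followed by instance normalization and ReLU.
#' Each decoder level upsamples trilinearly, concatenates the matching
#' encoder feature map (the fluence decoder also the dose decoder's), and
#' applies two 3x3x3 convolutions -- except the finest level, which has
#' one 3x3x3 convolution and one linear 1x1x1 output convolution.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed RNG seed for initialization.
#' @return A \code{\link{SharedEncoderModel-class}}.
#' @export
#' @examples
#' model <- buildModel(modelConfig(base_channels = 4L), seed = 1)
buildModel <- function(config = modelConfig(), seed = 1) {
  layers <- modelLayers(config)
  params <- withSeed(seed, {
    p <- list()
    for (ly in layers) {
      if (ly[[6]] == "block")
        p <- nnInitBlock(p, ly[[1]], ly[[2]], ly[[3]], ly[[4]])
      else {
        p[[paste0(ly[[1]], ".w")]] <- nnInitConv(ly[[2]], ly[[3]], ly[[4]])
        p[[paste0(ly[[1]], ".b")]] <- numeric(ly[[4]])
      }
    }
    p
  })
  new("SharedEncoderModel", config = config, params = params)
}

#' Number of learnable parameters
#'
#' A pure function of the configuration.
#'
#' @param model a \code{SharedEncoderModel} or a \code{modelConfig} list.
#' @return integer parameter count.
#' @export
parameterCount <- function(model) {
  if (methods::is(model, "SharedEncoderModel"))
    return(as.integer(sum(vapply(model@params, length, 0))))
  layers <- modelLayers(model)
  tot <- 0
  for (ly in layers) {
    tot <- tot + ly[[2]]^3 * ly[[3]] * ly[[4]] + ly[[4]]
    if (ly[[6]] == "block") tot <- tot + 2 * ly[[4]]
  }
  as.integer(tot)
}

#' Project the pre-projection feature volume to per-beam fluence patches
#'
#' Channel b of the output is t(P_b) %*% v_b reshaped to
#' (covered rows x plane columns). The operators must be patch-restricted
#' to the feature volume's slices; the first and last rows of the result
#' are only partially covered by the patch volume (beam divergence), which
#' is why training losses trim edge rows.
#'
#' @param v array (nx, ny, n_slices, n_beams).
#' @param ops list of patch-restricted \code{ProjectionOperator}s, one per
#'   beam channel.
#' @return array (n_slices, planeCols, n_beams), i.e. one fluence-plane
#'   patch per beam.
#' @export
projectFeatures <- function(v, ops) {
  nb <- dim(v)[4]
  if (length(ops) != nb)
    stop("need one patch operator per feature channel (", nb, ")")
  nr <- ops[[1]]@rowRange[2] - ops[[1]]@rowRange[1] + 1L
  nc <- ops[[1]]@beam@planeCols
  out <- array(0, c(nr, nc, nb))
  for (b in seq_len(nb)) out[, , b] <- projectVolume(ops[[b]], v[, , , b])
  out
}

## adjoint of projectFeatures
backprojectFeatures <- function(df, ops) {
  nb <- dim(df)[3]
  dd <- opVolumeDims(ops[[1]])
  out <- array(0, c(dd, nb))
  for (b in seq_len(nb)) out[, , , b] <- backprojectPlane(ops[[b]], df[, , b])
  out
}

#' Forward pass of the shared-encoder network
#'
#' Runs one normalized 19-channel input patch through the encoder and both
#' decoders. Spatial extents must be divisible by 16 (four halvings); the
#' architecture is fully convolutional along the slice axis. In evaluation
#' mode two passes on the same input are bit-identical (the network is
#' deterministic).
#'
#' @param model a \code{SharedEncoderModel}.
#' @param x input array (nx, ny, n_slices, in_channels), normalized.
#' @param ops list of patch-restricted projection operators (one per
#'   beam); NULL returns the pre-projection volume only.
#' @param train logical; TRUE retains the activation cache for
#'   \code{\link{modelBackward}}.
#' @return list with \code{dose} (nx, ny, n_slices), \code{v}
#'   (nx, ny, n_slices, 9), \code{fluence} (n_slices, planeCols, 9; NULL
#'   when \code{ops} is NULL), \code{bottleneck} (dim of the deepest
#'   encoder feature map), and \code{cache} when training.
#' @export
modelForward <- function(model, x, ops = NULL, train = FALSE) {
  p <- model@params
  d <- dim(x)
  if (length(d) != 4L || d[4] != model@config$in_channels)
    stop("input must be (nx, ny, nz, ", model@config$in_channels, ")")
  if (any(d[1:3] %% 16L != 0L))
    stop("spatial extents must be divisible by 16")
  if (!is.null(ops)) {
    od <- opVolumeDims(ops[[1]])
    if (!all(od == d[1:3]))
      stop("patch operators do not match the input patch slices")
  }
  cc <- if (train) list() else NULL
  blk <- function(name, xs, stride = 1L) {
    r <- convBlockForward(p, name, xs, stride, train)
    if (train) cc[[name]] <<- r$cache
    r$out
  }
  lin <- function(name, x) {
    r <- convLinForward(p, name, x, train)
    if (train) cc[[name]] <<- r$cache
    r$out
  }
  e1 <- blk("enc1b", blk("enc1a", x))
  if (!train) rm(x)
  e2 <- blk("enc2b", blk("enc2d", e1, 2L))
  e3 <- blk("enc3b", blk("enc3d", e2, 2L))
  e4 <- blk("enc4b", blk("enc4d", e3, 2L))
  e5 <- blk("enc5b", blk("enc5d", e4, 2L))
  bottleneck <- dim(e5)

  d4 <- blk("dd4b", blk("dd4a", list(upFw(e5), e4)))
  d3 <- blk("dd3b", blk("dd3a", list(upFw(d4), e3)))
  d2 <- blk("dd2b", blk("dd2a", list(upFw(d3), e2)))
  d1 <- blk("dd1a", list(upFw(d2), e1))
  dose <- lin("dd1out", d1)

  f4 <- blk("fd4b", blk("fd4a", list(upFw(e5), e4, d4)))
  if (!train) rm(e5, e4, d4)
  f3 <- blk("fd3b", blk("fd3a", list(upFw(f4), e3, d3)))
  if (!train) rm(f4, e3, d3)
  f2 <- blk("fd2b", blk("fd2a", list(upFw(f3), e2, d2)))
  if (!train) rm(f3, e2, d2)
  f1 <- blk("fd1a", list(upFw(f2), e1, d1))
  if (!train) rm(f2, e1, d1)
  v <- lin("fd1out", f1)
  if (!train) rm(f1)

  fl <- if (is.null(ops)) NULL else projectFeatures(v, ops)
  dim(dose) <- d[1:3]
  list(dose = dose, v = v, fluence = fl, bottleneck = bottleneck,
       cache = cc)
}

#' Backward pass of the shared-encoder network
#'
#' Propagates loss gradients w.r.t. the dose output and the projected
#' fluence patch back through both decoders (gradients flow through the
#' projection via its exact adjoint), the cross-decoder and skip
#' concatenations, and the encoder, accumulating parameter gradients.
#'
#' @param model a \code{SharedEncoderModel}.
#' @param fwd result of \code{modelForward(..., train = TRUE)}.
#' @param dDose gradient array (nx, ny, nz).
#' @param dFluence gradient array (nz, planeCols, 9), or NULL.
#' @param ops the patch operators used in the forward pass.
#' @return named list of parameter gradients (same names as the params).
#' @export
modelBackward <- function(model, fwd, dDose, dFluence, ops = NULL) {
  p <- model@params
  cc <- fwd$cache
  if (is.null(cc)) stop("forward pass was not run with train = TRUE")
  grads <- lapply(p, function(x) { g <- x; g[] <- 0; g })
  blkB <- function(name, dOut, needDx = TRUE) {
    r <- convBlockBackward(p, name, dOut, cc[[name]], grads, needDx)
    grads <<- r$grads
    r$dxs
  }
  linB <- function(name, dOut) {
    r <- convLinBackward(p, name, dOut, cc[[name]], grads)
    grads <<- r$grads
    r$dx
  }
  ## fluence head and decoder (consumes d4..d1, e1..e4, upsampled e5)
  dv <- if (is.null(dFluence)) {
    z <- fwd$v; z[] <- 0; z
  } else backprojectFeatures(dFluence, ops)
  s <- blkB("fd1a", linB("fd1out", dv))       # parts: up(f2), e1, d1
  dUf <- s[[1]]; dE1 <- s[[2]]; dD1 <- s[[3]]
  s <- blkB("fd2a", blkB("fd2b", upBw(dUf))[[1]])
  dUf <- s[[1]]; dE2 <- s[[2]]; dD2 <- s[[3]]
  s <- blkB("fd3a", blkB("fd3b", upBw(dUf))[[1]])
  dUf <- s[[1]]; dE3 <- s[[2]]; dD3 <- s[[3]]
  s <- blkB("fd4a", blkB("fd4b", upBw(dUf))[[1]])
  dE5 <- upBw(s[[1]]); dE4 <- s[[2]]; dD4 <- s[[3]]

  ## dose head and decoder (adds its own gradient to the shared maps)
  dd <- dDose; dim(dd) <- c(dim(dDose), 1L)
  dD1 <- dD1 + linB("dd1out", dd)
  s <- blkB("dd1a", dD1)                       # parts: up(d2), e1
  dE1 <- dE1 + s[[2]]
  dD2 <- dD2 + upBw(s[[1]])
  s <- blkB("dd2a", blkB("dd2b", dD2)[[1]])
  dE2 <- dE2 + s[[2]]
  dD3 <- dD3 + upBw(s[[1]])
  s <- blkB("dd3a", blkB("dd3b", dD3)[[1]])
  dE3 <- dE3 + s[[2]]
  dD4 <- dD4 + upBw(s[[1]])
  s <- blkB("dd4a", blkB("dd4b", dD4)[[1]])
  dE4 <- dE4 + s[[2]]
  dE5 <- dE5 + upBw(s[[1]])

  ## encoder
  dE4 <- dE4 + blkB("enc5d", blkB("enc5b", dE5)[[1]])[[1]]
  dE3 <- dE3 + blkB("enc4d", blkB("enc4b", dE4)[[1]])[[1]]
  dE2 <- dE2 + blkB("enc3d", blkB("enc3b", dE3)[[1]])[[1]]
  dE1 <- dE1 + blkB("enc2d", blkB("enc2b", dE2)[[1]])[[1]]
  blkB("enc1a", blkB("enc1b", dE1)[[1]], needDx = FALSE)
    grads
}
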