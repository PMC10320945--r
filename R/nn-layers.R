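## Building blocks of the prediction network: 3x3x3 / 1x1x1 convolutions
## (im2col + GEMM kernels in src/), instance normalization and ReLU, with
## hand-written backward passes. Feature tensors are channels-last arrays
## dim (nx, ny, nz, C).
##
## Skip/cross concatenations are never materialized: a conv block accepts
## a LIST of input tensors and slices its weight tensor along the input-
## channel axis, summing the partial convolutions -- algebraically
## identical to convolving the channel concatenation, but without the
## large temporary (whole-volume inference at reference scale must stay
## within a few GB of memory).

nnEps <- 1e-5

## He-normal conv weight init
nnInitConv <- function(k, cin, cout) {
  fan <- k^3 * cin
  array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fan)),
        dim = c(k, k, k, cin, cout))
}

## parameters of one conv(+IN) block, flat-named into a list
nnInitBlock <- function(params, name, k, cin, cout, affine = TRUE) {
  params[[paste0(name, ".w")]] <- nnInitConv(k, cin, cout)
  params[[paste0(name, ".b")]] <- numeric(cout)
  if (affine) {
    params[[paste0(name, ".g")]] <- rep(1, cout)
    params[[paste0(name, ".be")]] <- numeric(cout)
  }
  params
}

## channel ranges of the input parts within the block's weight tensor
partOffsets <- function(xs) {
  sizes <- vapply(xs, function(x) dim(x)[4], 0L)
  cumsum(c(0L, sizes))[seq_along(sizes)]
}

## sum of partial convolutions over the input parts
convParts <- function(w, b, xs, stride) {
  y0 <- NULL
  off <- 0L
  for (x in xs) {
    ck <- dim(x)[4]
    wk <- w[, , , off + seq_len(ck), , drop = FALSE]
    yk <- cpp_conv3d_fw(x, wk, if (is.null(y0)) b else numeric(dim(w)[5]),
                        stride)
    y0 <- if (is.null(y0)) yk else y0 + yk
    off <- off + ck
  }
  y0
}

## conv 3x3x3 (stride 1 or 2) -> instance norm -> ReLU
convBlockForward <- function(params, name, xs, stride, train = FALSE) {
  if (!is.list(xs)) xs <- list(xs)
  g <- params[[paste0(name, ".g")]]
  be <- params[[paste0(name, ".be")]]
  y0 <- convParts(params[[paste0(name, ".w")]], params[[paste0(name, ".b")]],
                  xs, stride)
  if (!train) {
    cpp_in_relu(y0, g, be, nnEps)   # in place
    return(list(out = y0, cache = NULL))
  }
  d <- dim(y0); nvox <- prod(d[1:3]); C <- d[4]
  m <- matrix(y0, nvox, C)
  mu <- .colMeans(m, nvox, C)
  cen <- sweep(m, 2L, mu, `-`)
  sd_ <- sqrt(.colMeans(cen * cen, nvox, C) + nnEps)
  xhat <- sweep(cen, 2L, sd_, `/`)
  y <- sweep(sweep(xhat, 2L, g, `*`), 2L, be, `+`)
  y[y < 0] <- 0
  dim(y) <- d
  list(out = y,
       cache = list(xs = xs, xhat = xhat, sd = sd_, out = y, stride = stride))
}

## backward through ReLU, instance norm and the partial convolutions;
## returns one input-gradient per input part
convBlockBackward <- function(params, name, dOut, cache, grads,
                              needDx = TRUE) {
  d <- dim(cache$out); nvox <- prod(d[1:3]); C <- d[4]
  dY <- matrix(dOut, nvox, C)
  dY[matrix(cache$out, nvox, C) <= 0] <- 0          # ReLU gate
  g <- params[[paste0(name, ".g")]]
  grads[[paste0(name, ".g")]] <- grads[[paste0(name, ".g")]] +
    .colSums(dY * cache$xhat, nvox, C)
  grads[[paste0(name, ".be")]] <- grads[[paste0(name, ".be")]] +
    .colSums(dY, nvox, C)
  dxh <- sweep(dY, 2L, g, `*`)
  m1 <- .colMeans(dxh, nvox, C)
  m2 <- .colMeans(dxh * cache$xhat, nvox, C)
  dy0 <- sweep(dxh - sweep(cache$xhat, 2L, m2, `*`), 2L, m1, `-`)
  dy0 <- sweep(dy0, 2L, cache$sd, `/`)
  dim(dy0) <- d
  w <- params[[paste0(name, ".w")]]
  dwFull <- array(0, dim(w))
  dxs <- vector("list", length(cache$xs))
  off <- 0L
  for (k in seq_along(cache$xs)) {
    x <- cache$xs[[k]]
    ck <- dim(x)[4]
    wk <- w[, , , off + seq_len(ck), , drop = FALSE]
    bw <- cpp_conv3d_bw(x, wk, dy0, cache$stride, needDx)
    dwFull[, , , off + seq_len(ck), ] <- bw$dw
    if (k == 1L)
      grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + bw$db
    if (needDx) dxs[[k]] <- bw$dx
    off <- off + ck
  }
  grads[[paste0(name, ".w")]] <- grads[[paste0(name, ".w")]] + dwFull
  list(dxs = dxs, grads = grads)
}

## plain linear convolution (used for the 1x1x1 output heads)
convLinForward <- function(params, name, x, train = FALSE) {
  y <- cpp_conv3d_fw(x, params[[paste0(name, ".w")]],
                     params[[paste0(name, ".b")]], 1L)
  list(out = y, cache = if (train) list(x = x) else NULL)
}

convLinBackward <- function(params, name, dOut, cache, grads) {
  bw <- cpp_conv3d_bw(cache$x, params[[paste0(name, ".w")]], dOut, 1L, TRUE)
  grads[[paste0(name, ".w")]] <- grads[[paste0(name, ".w")]] + bw$dw
  grads[[paste0(name, ".b")]] <- grads[[paste0(name, ".b")]] + bw$db
  list(dx = bw$dx, grads = grads)
}

upFw <- function(x) cpp_upsample2_fw(x)
upBw <- function(dy) {
  d <- dim(dy)
  cpp_upsample2_bw(dy, d[1] %/% 2L, d[2] %/% 2L, d[3] %/% 2L)
}
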