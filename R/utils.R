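## small internal helpers

## evaluate expr under a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## voxel-center coordinate vectors (mm) of a grid, one per axis
gridAxes <- function(grid) {
  lapply(1:3, function(a)
    grid@origin[a] + (seq_len(grid@dims[a]) - 1L) * grid@spacing[a])
}

## full 3D coordinate arrays are avoided; masks are built from axis vectors
## with outer-style recycling: X varies fastest, then Y, then Z
expandX <- function(ax, dims) rep(ax, times = dims[2] * dims[3])
expandY <- function(ay, dims) rep(rep(ay, each = dims[1]), times = dims[3])
expandZ <- function(az, dims) rep(az, each = dims[1] * dims[2])

zeroVolume <- function(grid) array(0, dim = grid@dims)
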