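# Shared small fixtures, memoized so expensive objects are built once per
# test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

microConfig <- function() phantomConfig("micro")

microGrid <- function() gridSpec(48, 48, 16)

microBeams <- function() beamGeometry(planeRows = 32L, planeCols = 32L)

microOps <- function() memo("microOps",
  buildPlanOperators(microGrid(), microBeams()))

microPatchOps <- function() memo("microPatchOps",
  lapply(microOps(), patchOperator, z1 = 1L, z2 = 16L))

## one fully generated micro case (anatomy + optimized plan + dose)
microCase <- function() memo("microCase", generateCase(1, microConfig()))

## anatomy-only micro case (cheap)
microAnatomy <- function(seed = 5) memo(paste0("microAnat", seed),
  generateAnatomy(seed, microConfig()))

microTrainConfig <- function(...) trainConfig("micro", ...)

## small model on the micro grid
microModel <- function(base = 4L) memo(paste0("microModel", base),
  buildModel(modelConfig(base_channels = base), seed = 1))

## independent brute-force projection of one voxel grid through one beam:
## per-voxel ray-plane intersection with nearest-pixel splatting
bruteProjection <- function(grid, beam, beamIndex) {
  src <- gantrySourcePosition(beam@gantryAngles[beamIndex], beam@sad)
  th <- beam@gantryAngles[beamIndex] * pi / 180
  eu <- c(cos(th), sin(th), 0)
  d0 <- -src / beam@sad
  d <- grid@dims
  entries <- list()
  for (iz in seq_len(d[3])) for (iy in seq_len(d[2])) for (ix in seq_len(d[1])) {
    p <- grid@origin + (c(ix, iy, iz) - 1) * grid@spacing
    vv <- p - src
    tpar <- beam@sad / sum(vv * d0)
    q <- src + tpar * vv
    u <- sum(q * eu)
    col <- ceiling(u / beam@planePitch + (beam@planeCols + 1) / 2 - 0.5)
    row <- ceiling(q[3] / beam@planePitch + (beam@planeRows + 1) / 2 - 0.5)
    if (col < 1 || col > beam@planeCols || row < 1 || row > beam@planeRows)
      next
    w <- beam@sad^2 / sum(vv^2)
    i <- ix + d[1] * (iy - 1) + d[1] * d[2] * (iz - 1)
    j <- (col - 1) * beam@planeRows + row
    entries[[length(entries) + 1L]] <- c(i, j, w)
  }
  do.call(rbind, entries)
}

# independent exhaustive fine-grid gamma oracle (plain per-pixel loops)
bruteGamma <- function(ref, ev, spacing, dd = 3, dta = 3, thr = 0,
                       fine = 0.1) {
  mx <- max(ref); ddA <- dd / 100 * mx
  nr <- nrow(ref); nc <- ncol(ref)
  xs <- seq(1, nr, by = fine); ys <- seq(1, nc, by = fine)
  G <- expand.grid(x = xs, y = ys)
  x0 <- pmin(floor(G$x), nr - 1); y0 <- pmin(floor(G$y), nc - 1)
  fx <- G$x - x0; fy <- G$y - y0
  Ev <- ev[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    ev[cbind(x0 + 1, y0)] * fx * (1 - fy) +
    ev[cbind(x0, y0 + 1)] * (1 - fx) * fy +
    ev[cbind(x0 + 1, y0 + 1)] * fx * fy
  pass <- 0; tot <- 0
  for (i in 1:nr) for (j in 1:nc) {
    if (ref[i, j] <= thr / 100 * mx) next
    tot <- tot + 1
    d2 <- ((G$x - i)^2 + (G$y - j)^2) * spacing^2
    sel <- d2 <= (3 * dta)^2
    if (min((Ev[sel] - ref[i, j])^2 / ddA^2 + d2[sel] / dta^2) <= 1)
      pass <- pass + 1
  }
  100 * pass / tot
}
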