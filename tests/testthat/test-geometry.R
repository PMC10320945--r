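test_that("source positions follow the fixed frame convention", {
  expect_equal(gantrySourcePosition(0, 1000), c(0, -1000, 0))
  expect_equal(gantrySourcePosition(180, 1000), c(0, 1000, 0))
  # rotation-matrix oracle for an oblique angle
  th <- 40 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  expect_equal(gantrySourcePosition(40, 1000), as.vector(R %*% c(0, -1000, 0)))
  expect_equal(sqrt(sum(gantrySourcePosition(40, 1000)^2)), 1000)
  # angles taken mod 360
  expect_equal(gantrySourcePosition(400, 500), gantrySourcePosition(40, 500))
})

test_that("projection operator matches the brute-force ray-trace oracle", {
  grid <- gridSpec(4, 4, 4)
  beam <- beamGeometry(planeRows = 8L, planeCols = 8L)
  for (b in c(1L, 2L, 5L)) {
    op <- buildProjectionOperator(grid, beam, b)
    oracle <- bruteProjection(grid, beam, b)
    trip <- Matrix::summary(op@P)
    got <- as.matrix(trip[order(trip$i), ])
    want <- oracle[order(oracle[, 1]), ]
    dimnames(got) <- dimnames(want) <- NULL
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("every stored weight is the inverse-square factor", {
  op <- microOps()[[3]]
  grid <- op@grid
  src <- gantrySourcePosition(op@gantryAngle, op@beam@sad)
  trip <- Matrix::summary(op@P)
  d <- grid@dims
  iz <- (trip$i - 1) %/% (d[1] * d[2])
  rem <- (trip$i - 1) %% (d[1] * d[2])
  iy <- rem %/% d[1]; ix <- rem %% d[1]
  p <- cbind(grid@origin[1] + ix * grid@spacing[1],
             grid@origin[2] + iy * grid@spacing[2],
             grid@origin[3] + iz * grid@spacing[3])
  d2 <- rowSums(sweep(p, 2, src)^2)
  expect_equal(trip$x, op@beam@sad^2 / d2, tolerance = 1e-9)
})

test_that("a voxel at the isocenter projects to the central pixel with weight 1", {
  grid <- gridSpec(1, 1, 1)        # single voxel exactly at the isocenter
  beam <- beamGeometry(planeRows = 9L, planeCols = 9L)
  op <- buildProjectionOperator(grid, beam, 1L)
  trip <- Matrix::summary(op@P)
  expect_equal(nrow(trip), 1L)
  expect_equal(trip$x, 1)
  row <- (trip$j - 1) %% 9 + 1; col <- (trip$j - 1) %/% 9 + 1
  expect_equal(c(row, col), c(5, 5))
})

test_that("weight follows the inverse-square law along a ray", {
  # voxel at the isocenter vs a voxel at twice the source distance on the
  # same ray (source anterior at y = -sad): weight drops to exactly 1/4
  beam <- beamGeometry(planeRows = 9L, planeCols = 9L, sad = 100)
  g <- gridSpec(1, 201, 1, spacing = 1)   # column of voxels along y
  P <- buildProjectionOperator(g, beam, 1L)@P
  wIso <- P[101, which(P[101, ] != 0)]    # voxel at the isocenter
  wFar <- P[201, which(P[201, ] != 0)]    # voxel at twice the source distance
  expect_equal(wIso, 1)
  expect_equal(wFar, wIso / 4)
})

test_that("projection is linear and matches the dense oracle; adjoint holds", {
  op <- patchOperator(microOps()[[4]], 3L, 10L)
  dd <- c(48, 48, 8)
  set.seed(11)
  v1 <- array(rnorm(prod(dd)), dd)
  v2 <- array(rnorm(prod(dd)), dd)
  expect_equal(projectVolume(op, v1 * 0), projectVolume(op, v1) * 0)
  expect_equal(projectVolume(op, 2.5 * v1 + v2),
               2.5 * projectVolume(op, v1) + projectVolume(op, v2),
               tolerance = 1e-12)
  dense <- as.matrix(op@P)
  f <- matrix(as.vector(crossprod(dense, as.vector(v1))), 8, 32)
  expect_equal(projectVolume(op, v1), f, tolerance = 1e-12)
  # adjoint identity <P v, f> = <v, P^T f>
  fr <- matrix(rnorm(8 * 32), 8, 32)
  a <- sum(projectVolume(op, v1) * fr)
  b <- sum(v1 * backprojectPlane(op, fr))
  expect_lt(abs(a - b) / max(abs(a), abs(b)), 1e-6)
})

test_that("a voxel column parallel to the central axis lands in one beamlet", {
  grid <- gridSpec(1, 9, 1, spacing = c(2.5, 2.5, 2.5))  # column along y
  beam <- beamGeometry(planeRows = 15L, planeCols = 15L)
  op <- buildProjectionOperator(grid, beam, 1L)  # beam 0: axis along +y
  trip <- Matrix::summary(op@P)
  expect_equal(length(unique(trip$j)), 1L)
})

test_that("beam's-eye-view target masks dilate correctly and are monotone", {
  op <- microPatchOps()[[1]]
  ptv <- array(0, c(48, 48, 16))
  expect_warning(m0 <- bevTargetMask(ptv, op), "empty")
  expect_false(any(m0))
  # single voxel at the isocenter -> central pixel + 2-pixel Euclidean disc
  g <- gridSpec(1, 1, 1)
  beam <- beamGeometry(planeRows = 11L, planeCols = 11L)
  op1 <- buildProjectionOperator(g, beam, 1L)
  m5 <- bevTargetMask(array(1, c(1, 1, 1)), op1, marginMm = 5)
  want <- matrix(FALSE, 11, 11)
  for (r in 1:11) for (cc in 1:11)
    want[r, cc] <- (r - 6)^2 + (cc - 6)^2 <= 4
  expect_equal(m5, want)
  m0 <- bevTargetMask(array(1, c(1, 1, 1)), op1, marginMm = 0)
  expect_equal(sum(m0), 1)
  expect_equal(which(m0), which(matrix(seq_len(121), 11) == 61))
  # monotone in the margin
  ptv <- ptvDoseMask(microAnatomy()) > 0
  a <- bevTargetMask(ptv, op, 0)
  b <- bevTargetMask(ptv, op, 2.5)
  c3 <- bevTargetMask(ptv, op, 7.5)
  expect_true(all(b[a]))
  expect_true(all(c3[b]))
})

test_that("patch operators are slices of the full operator", {
  full <- microOps()[[2]]
  p <- patchOperator(full, 5L, 12L)
  expect_equal(p@sliceRange, c(5L, 12L))
  expect_equal(p@rowRange, c(5L + 8L, 12L + 8L))  # 32-row plane, 16 slices
  set.seed(3)
  v <- array(rnorm(48 * 48 * 16), c(48, 48, 16))
  fFull <- projectVolume(full, v)
  fPatch <- projectVolume(p, v[, , 5:12])
  # interior rows can differ (out-of-patch voxels are missing); the patch
  # projection must equal the full projection of the zero-padded volume
  vz <- v; vz[, , -(5:12)] <- 0
  expect_equal(fPatch, projectVolume(full, vz)[13:20, ], tolerance = 1e-12)
})

test_that("operators serialize to triplets and round-trip bit-exactly", {
  op <- patchOperator(microOps()[[7]], 2L, 9L)
  dir <- withr::local_tempdir()
  saveProjection(op, dir)
  op2 <- loadProjection(dir)
  expect_identical(as.matrix(Matrix::summary(op@P)),
                   as.matrix(Matrix::summary(op2@P)))
  expect_identical(op@sliceRange, op2@sliceRange)
  expect_identical(op@rowRange, op2@rowRange)
  expect_equal(op@grid@origin, op2@grid@origin)
  expect_equal(op@beam@gantryAngles, op2@beam@gantryAngles)
})
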