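# Fluence reconstruction from MLC control-point sequences.

smallBeam <- function() beamGeometry(planeRows = 16L, planeCols = 16L)
smallModel <- function(transmission = 0.015, dlg = 1.4, jawT = 0)
  mlcModel(transmission, dlg, leafBoundaries = seq(-20, 20, by = 5),
           jawTransmission = jawT)

# independent per-pixel point-in-region oracle
apertureOracle <- function(u, v, left, right, jaws, model) {
  if (u < jaws[1] || u > jaws[2] || v < jaws[3] || v > jaws[4])
    return(model@jawTransmission)
  p <- findInterval(v, model@leafBoundaries, rightmost.closed = TRUE)
  half <- model@dlg / 2
  if (u > left[p] - half && u < right[p] + half) 1 else model@transmission
}

test_that("aperture masks cover the limiting cases", {
  beam <- smallBeam()
  mod <- smallModel()
  np <- length(mod@leafBoundaries) - 1L
  wide <- c(-100, 100, -100, 100)
  # fully retracted leaves, jaws covering the plane -> all ones
  m <- apertureTransmissionMask(rep(-100, np), rep(100, np), wide, mod, beam)
  expect_true(all(m == 1))
  # fully closed leaves (left = right, dlg = 0) -> uniform transmission
  # inside the jaws, jaw transmission outside
  mod0 <- smallModel(dlg = 0, jawT = 0.001)
  jaws <- c(-10, 10, -10, 10)
  m <- apertureTransmissionMask(rep(0, np), rep(0, np), jaws, mod0, beam)
  pc <- DoseFluence:::planePixelCenters(beam)
  inJaw <- outer(pc$v >= -10 & pc$v <= 10, pc$u >= -10 & pc$u <= 10, `&`)
  expect_true(all(m[inJaw] == mod0@transmission))
  expect_true(all(m[!inJaw] == mod0@jawTransmission))
})

test_that("a 10 mm opening with 2 mm DLG gives a 12 mm strip, per-pixel", {
  beam <- smallBeam()
  mod <- smallModel(dlg = 2)
  np <- length(mod@leafBoundaries) - 1L
  left <- rep(0, np); right <- rep(0, np)
  left[4] <- -5; right[4] <- 5      # one pair open 10 mm
  jaws <- c(-15, 15, -15, 15)
  m <- apertureTransmissionMask(left, right, jaws, mod, beam)
  pc <- DoseFluence:::planePixelCenters(beam)
  for (r in seq_along(pc$v)) for (cc in seq_along(pc$u))
    expect_equal(m[r, cc],
                 apertureOracle(pc$u[cc], pc$v[r], left, right, jaws, mod))
})

test_that("static fields and segment re-partitioning behave linearly", {
  beam <- smallBeam(); mod <- smallModel()
  np <- length(mod@leafBoundaries) - 1L
  left <- rep(-6, np); right <- rep(4, np)
  jaws <- c(-12, 12, -14, 14)
  mk <- function(w) controlPointSequence(
    weights = w,
    mlcLeft = matrix(left, length(w), np, byrow = TRUE),
    mlcRight = matrix(right, length(w), np, byrow = TRUE),
    jaws = matrix(jaws, length(w), 4, byrow = TRUE), mu = 137)
  fStatic <- fluenceFromControlPoints(mk(c(0, 1)), mod, beam)
  expect_equal(fStatic,
               137 * apertureTransmissionMask(left, right, jaws, mod, beam))
  # splitting one static segment leaves the fluence unchanged
  expect_equal(fluenceFromControlPoints(mk(c(0, 0.5, 1)), mod, beam), fStatic)
  expect_equal(fluenceFromControlPoints(mk(c(0, 0.2, 0.7, 1)), mod, beam),
               fStatic)
})

test_that("sliding-window sequences match a per-pixel accumulation oracle", {
  beam <- smallBeam(); mod <- smallModel()
  np <- length(mod@leafBoundaries) - 1L
  set.seed(21)
  K <- 6L
  starts <- seq(-12, 4, length.out = K)
  left <- starts + matrix(runif(K * np, -1, 1), K, np)
  right <- left + 6 + matrix(runif(K * np, 0, 2), K, np)
  jaws <- matrix(c(-15, 15, -12, 12), K, 4, byrow = TRUE)
  cps <- controlPointSequence(seq(0, 1, length.out = K), left, right, jaws,
                              mu = 200)
  got <- fluenceFromControlPoints(cps, mod, beam)
  # oracle: explicit per-pixel loop over segments at midpoint positions
  pc <- DoseFluence:::planePixelCenters(beam)
  want <- matrix(0, 16, 16)
  for (k in seq_len(K - 1)) {
    dw <- cps@weights[k + 1] - cps@weights[k]
    ml <- (left[k, ] + left[k + 1, ]) / 2
    mr <- (right[k, ] + right[k + 1, ]) / 2
    for (r in 1:16) for (cc in 1:16)
      want[r, cc] <- want[r, cc] +
        dw * apertureOracle(pc$u[cc], pc$v[r], ml, mr, jaws[1, ], mod)
  }
  expect_equal(got, 200 * want, tolerance = 1e-12)
  # invariants: non-negative, bounded by the field meterset
  expect_true(all(got >= 0))
  expect_true(all(got <= 200 + 1e-9))
})

test_that("fluence is monotone in the aperture", {
  beam <- smallBeam(); mod <- smallModel()
  np <- length(mod@leafBoundaries) - 1L
  jaws <- c(-12, 12, -12, 12)
  narrow <- apertureTransmissionMask(rep(-2, np), rep(2, np), jaws, mod, beam)
  wideJ <- c(-14, 14, -14, 14)
  wide <- apertureTransmissionMask(rep(-5, np), rep(6, np), wideJ, mod, beam)
  expect_true(all(wide >= narrow - 1e-12))
})

test_that("plan stacks are beam-ordered with exact round trips", {
  beam <- beamGeometry()
  zero <- matrix(0, 160, 160)
  maps <- replicate(9, zero, simplify = FALSE)
  st <- stackPlanFluence(maps, beam@gantryAngles, beam)
  expect_equal(dim(st), c(160L, 160L, 9L))
  expect_true(all(st == 0))
  # a map supplied at angle 80 lands at beam index 3 (angles 0, 40, 80)
  marked <- maps
  marked[[5]] <- matrix(7, 160, 160)
  angles <- c(80, 0, 40, 120, 160, 200, 240, 280, 320)
  angles <- c(angles[2:3], 80, angles[4:9])      # supply out of order
  shuffled <- list(marked[[5]], zero, zero, zero, zero, zero, zero, zero,
                   zero)
  st2 <- stackPlanFluence(shuffled, c(80, 0, 40, 120, 160, 200, 240, 280,
                                      320), beam)
  expect_true(all(st2[, , 3] == 7))
  expect_true(all(st2[, , -3] == 0))
  # stack then unstack: bit-exact
  set.seed(4)
  maps <- lapply(1:9, function(i) matrix(rnorm(160 * 160), 160, 160))
  st3 <- stackPlanFluence(maps, beam@gantryAngles, beam)
  for (b in 1:9) expect_identical(st3[, , b], maps[[b]])
  expect_error(stackPlanFluence(maps[1:8], beam@gantryAngles[1:8], beam),
               "exactly 9")
})

test_that("uncovered plane rows are a configuration error", {
  beam <- smallBeam()
  mod <- mlcModel(leafBoundaries = seq(-5, 5, by = 5))  # covers 2 rows only
  expect_error(
    apertureTransmissionMask(c(-5, -5), c(5, 5), c(-10, 10, -10, 10), mod,
                             beam),
    "not covered")
})
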