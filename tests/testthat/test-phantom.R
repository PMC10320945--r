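# Synthetic phantom generator, forward dose engine and reference-plan
# optimizer.

test_that("anatomy generation is deterministic and respects nesting", {
  cfg <- microConfig()
  a <- generateAnatomy(11, cfg)
  b <- generateAnatomy(11, cfg)
  expect_identical(a@ct, b@ct)
  expect_identical(a@ptvDose, b@ptvDose)
  expect_identical(a@oarMasks, b@oarMasks)
  expect_identical(a@prescriptions, b@prescriptions)
  # nesting: every PTV-GTV voxel is also PTV-1 and PTV-2
  expect_true(all(a@ptvMasks[["PTV-1"]][a@ptvMasks[["PTV-GTV"]] > 0] > 0))
  expect_true(all(a@ptvMasks[["PTV-2"]][a@ptvMasks[["PTV-1"]] > 0] > 0))
  # body is a superset of every structure
  body <- a@oarMasks[["body"]]
  for (m in c(a@ptvMasks, a@oarMasks)) expect_true(all(body[m > 0] > 0))
})

test_that("sampled prescriptions only come from the printed sets", {
  cfg <- microConfig()
  combos <- list(c(7000, 6400, 5800), c(7000, 6000, 5400))
  nodal <- seq(6000, 7000, by = 200)
  seen <- integer(2)
  for (seed in 1:50) {
    p <- generateAnatomy(seed, cfg)@prescriptions
    main <- unname(p[c("PTV-GTV", "PTV-1", "PTV-2")])
    match1 <- isTRUE(all.equal(main, combos[[1]]))
    match2 <- isTRUE(all.equal(main, combos[[2]]))
    expect_true(match1 || match2)
    seen[if (match1) 1 else 2] <- seen[if (match1) 1 else 2] + 1L
    expect_true(all(p[c("PTV-LN-L", "PTV-LN-R")] %in% nodal))
  }
  expect_true(all(seen > 0))   # both combinations occur
})

test_that("the forward engine is linear, non-negative and zero-preserving", {
  case <- microAnatomy()
  ops <- microOps()
  zero <- array(0, dim(case@fluence))
  expect_true(all(forwardDose(zero, case@ct, ops) == 0))
  set.seed(8)
  f <- array(runif(length(zero), 0, 100), dim(zero))
  d1 <- forwardDose(f, case@ct, ops, smoothSigmaMm = 0)
  d2 <- forwardDose(2 * f, case@ct, ops, smoothSigmaMm = 0)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  ds1 <- forwardDose(f, case@ct, ops, smoothSigmaMm = 2)
  ds2 <- forwardDose(2 * f, case@ct, ops, smoothSigmaMm = 2)
  expect_equal(ds2, 2 * ds1, tolerance = 1e-12)
  expect_true(all(d1 >= 0))
})

test_that("central-axis dose follows the inverse-square x attenuation form", {
  # uniform water phantom (0 HU everywhere), single anterior beam with
  # uniform fluence, no smoothing: along the central axis
  # dose ratio (d/d0) = (sad/dist)^2/(sad/dist0)^2 * exp(-mu (y - y0))
  grid <- gridSpec(9, 64, 9)
  beam <- beamGeometry(gantryAngles = 0, planeRows = 31L, planeCols = 31L)
  op <- buildProjectionOperator(grid, beam, 1L)
  ct <- array(0, grid@dims)
  flu <- array(1, c(31, 31, 1))
  mu <- 0.004
  dose <- forwardDose(flu, ct, list(op), muEff = mu, smoothSigmaMm = 0)
  ys <- grid@origin[2] + (seq_len(64) - 1) * grid@spacing[2]
  axis <- dose[5, , 5]
  j0 <- 14
  for (j in c(20, 26, 32, 38, 44)) {
    want <- ((1000 + ys[j0]) / (1000 + ys[j]))^2 * exp(-mu * (ys[j] - ys[j0]))
    expect_equal(axis[j] / axis[j0], want, tolerance = 0.01)
  }
})

test_that("the dose transfer map is adjoint-consistent with the optimizer", {
  case <- microAnatomy()
  ops <- microOps()
  tr <- DoseFluence:::doseTransferMatrices(case@ct, case@grid, case@beams,
                                           ops, 0.004, 2)
  D <- do.call(cbind, tr)
  set.seed(9)
  f <- runif(ncol(D)); r <- rnorm(nrow(D))
  a <- sum(as.vector(D %*% f) * r)
  b <- sum(f * as.vector(Matrix::crossprod(D, r)))
  expect_lt(abs(a - b) / abs(a), 1e-10)
  # finite-difference gradient of the least-squares objective
  tgt <- as.vector(case@ptvDose)
  w <- as.vector(case@oarMasks[["body"]]) * 0.01 + (tgt > 0)
  obj <- function(f) 0.5 * sum(w * (as.vector(D %*% f) - tgt)^2)
  g <- as.vector(Matrix::crossprod(D, w * (as.vector(D %*% f) - tgt)))
  eps <- 1   # central differences are exact for a quadratic objective
  for (i in sample(length(f), 5)) {
    fp <- f; fp[i] <- f[i] + eps
    fm <- f; fm[i] <- f[i] - eps
    fd <- (obj(fp) - obj(fm)) / (2 * eps)
    expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-9), 1e-3)
  }
})

test_that("the optimizer decreases its objective and fixes zero at zero", {
  case <- microAnatomy()
  ops <- microOps()
  cfg <- microConfig()
  cfg$optIterations <- 40L
  opt <- optimizeReferenceFluence(case, ops, cfg)
  expect_true(all(diff(opt$objective) <= 1e-9))
  expect_true(all(opt$fluence >= 0))
  # all-zero prescription: zero fluence is a fixed point
  case0 <- case
  case0@ptvDose <- DoseFluence:::zeroVolume(case@grid)
  cfg$optIterations <- 5L
  opt0 <- optimizeReferenceFluence(case0, ops, cfg)
  expect_true(all(opt0$fluence == 0))
})

test_that("a water cylinder with one spherical target reaches prescription", {
  cfg <- microConfig()
  case <- generateAnatomy(3, cfg)
  gtv <- case@ptvMasks[["PTV-GTV"]]
  case@ct[case@oarMasks[["body"]] > 0] <- 0   # water body
  for (nm in ptvNames()) case@ptvMasks[[nm]] <- gtv
  case@prescriptions <- stats::setNames(c(7000, 6400, 5800, 7000, 7000),
                                        ptvNames())
  case@ptvDose <- gtv * 7000
  ops <- microOps()
  cfg$optIterations <- 400L
  opt <- optimizeReferenceFluence(case, ops, cfg)
  dose <- forwardDose(opt$fluence, case@ct, ops, muEff = cfg$muEff,
                      smoothSigmaMm = 0, gain = cfg$engineGain,
                      transfer = opt$transfer)
  expect_lt(abs(mean(dose[gtv > 0]) - 7000) / 7000, 0.05)
})

test_that("generated cases meet the optimization quality gate", {
  case <- microCase()
  gtv <- ptvMask(case, "PTV-GTV") > 0
  expect_lt(abs(mean(doseVolume(case)[gtv]) - 7000) / 7000, 0.10)
  nb <- length(case@beams@gantryAngles)
  expect_equal(dim(fluenceStack(case)),
               c(case@beams@planeRows, case@beams@planeCols, nb))
  # regeneration from the stored seed is bit-identical
  again <- generateCase(case@seed, microConfig(), ops = microOps())
  expect_identical(doseVolume(again), doseVolume(case))
  expect_identical(fluenceStack(again), fluenceStack(case))
  expect_identical(again@ct, case@ct)
})

test_that("the HU-to-density ramp hits its anchor points", {
  expect_equal(hounsfieldToDensity(c(-2000, -1000, -500, 0, 1500)),
               c(0, 0, 0.5, 1, 2))
})
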