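# Fluence/dose quality metrics, DVH and clinical indices, paired tests
# and the cohort report.

test_that("masked MAE% follows its formula and scale invariance", {
  gt <- matrix(0, 8, 8); gt[3, 3] <- 10
  pred <- gt; mask <- matrix(TRUE, 8, 8)
  expect_equal(maskedMaePercent(pred, gt, mask), 0)
  pred2 <- gt + 0.5
  expect_equal(maskedMaePercent(pred2, gt, mask), 5)  # 0.5 / 10 * 100
  # random instance against an independent elementwise oracle
  set.seed(31)
  gt <- matrix(runif(64, 0, 20), 8, 8)
  pred <- gt + rnorm(64)
  mask <- matrix(runif(64) > 0.4, 8, 8)
  oracle <- 0
  for (i in 1:8) for (j in 1:8)
    if (mask[i, j]) oracle <- oracle + abs(pred[i, j] - gt[i, j])
  oracle <- 100 * oracle / sum(mask) / max(gt)
  expect_equal(maskedMaePercent(pred, gt, mask), oracle, tolerance = 1e-12)
  # invariance under a joint rescaling of both maps
  expect_equal(maskedMaePercent(3 * pred, 3 * gt, mask),
               maskedMaePercent(pred, gt, mask), tolerance = 1e-12)
  expect_error(maskedMaePercent(pred, gt, mask & FALSE), "empty")
  expect_error(maskedMaePercent(pred, gt * 0, mask), "zero")
})

test_that("SSIM matches the reference implementation and closed forms", {
  set.seed(101)
  frozen <- c(0.997833860302, 0.992205483187, 0.917078316259)
  for (k in 1:3) {
    g <- matrix(runif(256, 0, 10), 16, 16)
    p <- g + matrix(rnorm(256, 0, c(0.2, 0.5, 1.0)[k]), 16, 16)
    expect_equal(ssimMap(p, g), frozen[k], tolerance = 1e-6)
  }
  # identity
  g <- matrix(runif(400, 0, 50), 20, 20)
  expect_equal(ssimMap(g, g), 1)
  # constant shift of a constant image: variances vanish, so SSIM reduces
  # to the closed-form luminance term (2 u1 u2 + C1)/(u1^2 + u2^2 + C1)
  gc <- matrix(5, 20, 20)
  shift <- 6
  C1 <- (0.01 * 5)^2
  want <- (2 * 5 * 11 + C1) / (25 + 121 + C1)
  expect_equal(ssimMap(gc + shift, gc), want, tolerance = 1e-9)
  expect_lt(ssimMap(gc + shift, gc), 1)
  expect_error(ssimMap(gc, gc * 0), "constant zero")
})

test_that("gamma pass rates agree with the exhaustive oracle", {
  expect_equal(gammaPassRate(matrix(1:16, 4), matrix(1:16, 4), 2.5), 100)
  set.seed(5)
  for (rep in 1:3) {
    ref <- matrix(runif(256, 10, 100), 16, 16)
    ev <- ref * (1 + rnorm(256, 0, 0.04))
    expect_lt(abs(gammaPassRate(ref, ev, 2.5) - bruteGamma(ref, ev, 2.5)),
              1)
  }
})

test_that("the gamma threshold excludes low-dose pixels and is asymmetric", {
  # hand-constructed 4x4 case: max 100; the whole low-dose region is
  # uniformly off by more than the dose criterion (3% of max = 3), so no
  # spatial search can rescue it; only the (1,1) pixel agrees
  ref <- matrix(5, 4, 4)
  ref[1, 1] <- 100                       # the only pixel above 10% of max
  ev <- ref + 4
  ev[1, 1] <- 100
  # threshold 0: 15 of 16 evaluated pixels fail by hand count
  expect_equal(gammaPassRate(ref, ev, 2.5, thresholdPercent = 0),
               100 * 1 / 16)
  # threshold 10%: only the (1,1) pixel is evaluated and it agrees
  expect_equal(gammaPassRate(ref, ev, 2.5, thresholdPercent = 10), 100)
  # asymmetry: swapping ref and eval changes the outcome on a case where
  # the eval map has an extra hot spot far from any reference dose
  a <- matrix(10, 8, 8); a[2, 2] <- 100
  b <- a; b[7, 7] <- 100
  expect_false(isTRUE(all.equal(gammaPassRate(a, b, 2.5),
                                gammaPassRate(b, a, 2.5))))
})

test_that("DVH curves are correct for uniform and ramp doses", {
  mask <- array(1, c(5, 5, 4))
  uni <- array(7000, c(5, 5, 4))
  d <- dvh(uni, mask)
  expect_equal(d$volumeFraction[d$doseCGy <= 7000], rep(1, 701))
  expect_equal(d$volumeFraction[d$doseCGy > 7000], 0)
  # linear ramp: V(d) matches the analytic line within one bin
  ramp <- array(seq(0, 1000, length.out = 100), c(5, 5, 4))
  dr <- dvh(ramp, mask, binCGy = 10)
  analytic <- pmax(0, pmin(1, 1 - dr$doseCGy / 1000))
  expect_true(all(abs(dr$volumeFraction - analytic) <= 1 / 99 + 1e-9))
  # monotone non-increasing, V(0) = 1 on random inputs
  set.seed(12)
  rd <- array(rexp(500, 1 / 3000), c(5, 10, 10))
  dd <- dvh(rd, array(1, dim(rd)))
  expect_true(all(diff(dd$volumeFraction) <= 0))
  expect_equal(dd$volumeFraction[1], 1)
})

test_that("clinical indices use the stated percentile convention", {
  mask <- array(1, c(10, 10, 1))
  uni <- array(4200, c(10, 10, 1))
  expect_equal(clinicalIndices(uni, mask),
               c(D95 = 42, Dmean = 42, Dmax = 42))
  doses <- array(seq(100, 10000, by = 100), c(10, 10, 1))  # 1..100 Gy
  idx <- clinicalIndices(doses, mask)
  expect_equal(idx[["D95"]], 5)       # voxel 5th percentile, lower interp
  expect_equal(idx[["Dmean"]], 50.5)
  expect_equal(idx[["Dmax"]], 100)
  # ordering property on random inputs
  set.seed(3)
  for (i in 1:5) {
    d <- array(runif(1000, 0, 8000), c(10, 10, 10))
    ix <- clinicalIndices(d, array(1, c(10, 10, 10)))
    expect_true(ix[["D95"]] <= ix[["Dmean"]] && ix[["Dmean"]] <= ix[["Dmax"]])
  }
  expect_error(clinicalIndices(uni, mask * 0), "empty")
})

test_that("the paired signed-rank test matches the exact distribution", {
  a <- c(3.1, 4.5, 2.2, 6.7, 5.5, 4.4, 3.3, 2.8, 5.1, 4.9)
  shifts <- seq(0.5, 1.4, by = 0.1)   # distinct, so ranks are untied
  r <- pairedWilcoxon(a, a + shifts)
  # all 10 differences share one sign: the two-sided exact p-value is the
  # extreme-rank-sum probability 2/2^10
  expect_equal(r$p, 2 / 2^10)
  expect_true(r$significant)
  expect_false(r$undefined)
  # symmetric differences constructed to be far from significance
  b <- a + c(1, -1, 1, -1, 1, -1, 1, -1, 1, -1) * 0.5
  r2 <- pairedWilcoxon(a, b)
  expect_gt(r2$p, 0.05)
  expect_false(r2$significant)
  # identical vectors: undefined
  r3 <- pairedWilcoxon(a, a)
  expect_true(r3$undefined)
  expect_true(is.na(r3$p))
  expect_error(pairedWilcoxon(a[1:4], a[1:4] + 1), "at least 6")
})

test_that("a perfect prediction yields a perfect cohort report", {
  case <- microCase()
  pred <- list(dose = doseVolume(case), fluence = fluenceStack(case))
  rep_ <- evaluateCohort(list(case), list(pred),
                         fluenceDoses = list(doseVolume(case)),
                         config = microTrainConfig(), ops = microOps())
  expect_true(all(rep_@fluence$maePercent == 0))
  expect_true(all(rep_@fluence$ssim == 1))
  expect_true(all(rep_@fluence$gamma0 == 100))
  expect_true(all(rep_@fluence$gamma10 == 100))
  idx <- rep_@doseIndices
  wide <- split(idx, idx$structure)
  for (s in names(wide)) {
    g <- wide[[s]][wide[[s]]$source == "groundTruth", c("D95", "Dmean", "Dmax")]
    p <- wide[[s]][wide[[s]]$source == "predicted", c("D95", "Dmean", "Dmax")]
    expect_equal(unlist(g), unlist(p))
  }
  # schema: 5 PTVs + 17 OARs x 3 sources, three indices in Gy
  expect_setequal(unique(idx$structure), c(ptvNames(), oarNames()))
  expect_setequal(unique(idx$source),
                  c("groundTruth", "predicted", "fluenceGenerated"))
  expect_true(all(c("D95", "Dmean", "Dmax") %in% names(idx)))
  expect_true(all(idx$Dmax < 100))   # Gy scale, not cGy
  # cohort summary recomputed by an independent aggregation oracle
  sm <- rep_@summary
  row <- sm[sm$structure == "PTV-GTV" & sm$index == "Dmean", ]
  sub <- idx[idx$structure == "PTV-GTV" & idx$source == "groundTruth", ]
  expect_equal(row$groundTruthMean, mean(sub$Dmean))
  # single case: no paired tests possible
  expect_true(all(is.na(sm$p1)))
})

test_that("reports serialize to CSV and JSON", {
  case <- microCase()
  pred <- list(dose = doseVolume(case), fluence = fluenceStack(case))
  rep_ <- evaluateCohort(list(case), list(pred),
                         config = microTrainConfig(), ops = microOps())
  dir <- withr::local_tempdir()
  paths <- writeEvalReport(rep_, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["fluence"]])
  expect_equal(nrow(back), nrow(rep_@fluence))
})
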