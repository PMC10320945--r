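## Fluence and dose quality metrics, DVH/clinical indices and cohort
## statistics. All dose indices are reported in Gy; volumes are stored in
## cGy and converted at exactly one point (clinicalIndices).

#' Masked mean absolute error in percent
#'
#' 100 * mean over the mask of |pred - gt|, normalized by the maximum of
#' the ground-truth map over the whole map (per map, i.e. per beam).
#'
#' @param pred,gt numeric maps of identical shape.
#' @param mask logical/binary mask (non-empty).
#' @return percent value >= 0.
#' @export
maskedMaePercent <- function(pred, gt, mask) {
  m <- mask > 0
  if (!any(m)) stop("empty evaluation mask")
  mx <- max(gt)
  if (mx <= 0) stop("ground-truth maximum is zero")
  100 * mean(abs(pred[m] - gt[m])) / mx
}

## separable Gaussian filtering of a matrix, sigma in pixels, radius
## floor(truncate * sigma + 0.5), edge-replicating reflection
gaussFilter2d <- function(x, sigma, truncate = 3.5) {
  r <- as.integer(truncate * sigma + 0.5)
  k <- exp(-0.5 * ((-r):r)^2 / sigma^2)
  k <- k / sum(k)
  pad <- function(n) c(rev(seq_len(r)), seq_len(n), n + 1 - seq_len(r))
  conv1 <- function(m) {   # filter along rows (dim 1)
    mp <- m[pad(nrow(m)), , drop = FALSE]
    out <- m * 0
    for (j in seq_along(k))
      out <- out + k[j] * mp[(j - 1) + seq_len(nrow(m)), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x))))
}

#' Structural similarity index of two maps
#'
#' Standard SSIM with Gaussian weighting (sigma 1.5, 11 x 11 window),
#' K1 = 0.01, K2 = 0.03, and the data range set to the ground-truth
#' maximum; the local-statistics maps are cropped by the window radius
#' before averaging.
#'
#' @param pred,gt numeric matrices of identical shape.
#' @return SSIM value in [-1, 1].
#' @export
ssimMap <- function(pred, gt) {
  stopifnot(all(dim(pred) == dim(gt)))
  L <- max(gt)
  if (L <= 0) stop("ground-truth map is constant zero: data range undefined")
  sigma <- 1.5; truncate <- 3.5
  r <- as.integer(truncate * sigma + 0.5)
  C1 <- (0.01 * L)^2; C2 <- (0.03 * L)^2
  ux <- gaussFilter2d(pred, sigma); uy <- gaussFilter2d(gt, sigma)
  uxx <- gaussFilter2d(pred * pred, sigma)
  uyy <- gaussFilter2d(gt * gt, sigma)
  uxy <- gaussFilter2d(pred * gt, sigma)
  vx <- uxx - ux * ux; vy <- uyy - uy * uy; vxy <- uxy - ux * uy
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux * ux + uy * uy + C1) * (vx + vy + C2))
  ri <- (r + 1):(nrow(S) - r); ci <- (r + 1):(ncol(S) - r)
  mean(S[ri, ci])
}

#' Global gamma pass rate of two maps
#'
#' Global-normalization gamma: the dose-difference denominator is
#' \code{ddPercent}% of the reference maximum; every reference pixel above
#' \code{thresholdPercent}% of the reference maximum is evaluated by
#' searching evaluation-map positions within 3 x \code{dtaMm} of it on a
#' 0.1-pixel bilinear-interpolated subgrid for
#' min sqrt((dose diff / dd)^2 + (distance / dta)^2); the pixel passes if
#' that minimum is <= 1. Note gamma is not symmetric in (ref, eval).
#'
#' @param ref reference map (the ground truth).
#' @param eval_ evaluation map, same shape and pixel grid.
#' @param spacing pixel pitch in mm.
#' @param ddPercent dose-difference criterion in percent (3).
#' @param dtaMm distance-to-agreement criterion in mm (3).
#' @param thresholdPercent low-dose exclusion threshold in percent of the
#'   reference maximum (0 or 10).
#' @param subStep search-grid refinement in pixels (0.1).
#' @return pass rate in percent.
#' @export
gammaPassRate <- function(ref, eval_, spacing = 2.5, ddPercent = 3,
                          dtaMm = 3, thresholdPercent = 0, subStep = 0.1) {
  stopifnot(all(dim(ref) == dim(eval_)))
  mx <- max(ref)
  if (mx <= 0) stop("reference maximum is zero")
  ddAbs <- ddPercent / 100 * mx
  keep <- ref > thresholdPercent / 100 * mx
  if (!any(keep)) stop("no reference pixels above the threshold")
  radiusMm <- 3 * dtaMm
  stepPx <- subStep
  maxPx <- radiusMm / spacing
  offs <- seq(-ceiling(maxPx / stepPx), ceiling(maxPx / stepPx)) * stepPx
  g2 <- array(Inf, dim(ref))
  nr <- nrow(ref); nc <- ncol(ref)
  for (da in offs) for (db in offs) {
    distMm2 <- (da^2 + db^2) * spacing^2
    if (distMm2 > radiusMm^2 + 1e-9) next
    sh <- bilinearShift(eval_, da, db)
    gg <- (sh - ref)^2 / ddAbs^2 + distMm2 / dtaMm^2
    gg[is.na(gg)] <- Inf
    g2 <- pmin(g2, gg)
  }
  100 * mean(g2[keep] <= 1 + 1e-12)
}

## map shifted by (da, db) pixels via bilinear interpolation; NA outside
bilinearShift <- function(m, da, db) {
  a0 <- floor(da); b0 <- floor(db)
  fa <- da - a0; fb <- db - b0
  out <- 0
  for (ia in 0:1) for (ib in 0:1) {
    w <- (if (ia) fa else 1 - fa) * (if (ib) fb else 1 - fb)
    if (w == 0) next
    out <- out + w * integerShift(m, a0 + ia, b0 + ib)
  }
  out
}

integerShift <- function(m, a, b) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + a; cs <- seq_len(nc) + b
  rok <- rs >= 1 & rs <= nr; cok <- cs >= 1 & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

#' Cumulative dose-volume histogram
#'
#' V(d): the fraction of structure voxels receiving at least dose d, on a
#' binned dose grid. Monotone non-increasing with V(0) = 1.
#'
#' @param dose dose volume (cGy).
#' @param mask binary structure mask (non-empty).
#' @param binCGy bin width (cGy, default 10).
#' @return data.frame with \code{doseCGy} and \code{volumeFraction}.
#' @export
dvh <- function(dose, mask, binCGy = 10) {
  m <- mask > 0
  if (!any(m)) stop("empty structure mask")
  dv <- dose[m]
  grid <- seq(0, max(dv) + binCGy, by = binCGy)
  data.frame(doseCGy = grid,
             volumeFraction = vapply(grid, function(d) mean(dv >= d), 0))
}

#' Clinical dose indices of a structure
#'
#' D95% (dose covering 95% of the volume; the voxel 5th percentile with
#' lower interpolation), Dmean and Dmax, converted from cGy to Gy here
#' and nowhere else.
#'
#' @param dose dose volume (cGy).
#' @param mask binary structure mask (non-empty).
#' @return named numeric: D95, Dmean, Dmax (Gy).
#' @export
clinicalIndices <- function(dose, mask) {
  m <- mask > 0
  if (!any(m)) stop("empty structure mask")
  dv <- dose[m]
  c(D95 = unname(stats::quantile(dv, 0.05, type = 1)),
    Dmean = mean(dv), Dmax = max(dv)) / 100
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired values; zero differences are
#' dropped first. The exact null distribution is used for n <= 25 and the
#' normal approximation (with tie correction) above; if ties force an
#' approximation at small n this is flagged. All differences zero makes
#' the test undefined (flagged, p = NA).
#'
#' @param a,b paired numeric vectors of equal length.
#' @param alpha significance level (0.05).
#' @return list(p, significant, undefined, n).
#' @export
pairedWilcoxon <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  d <- b - a
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(list(p = NA_real_, significant = NA, undefined = TRUE, n = 0L))
  if (n < 6L) stop("need at least 6 nonzero paired differences")
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = n <= 25, alternative = "two.sided"))
  list(p = wt$p.value, significant = wt$p.value < alpha, undefined = FALSE,
       n = as.integer(n))
}

## per-case fluence metrics within the BEV PTV+margin masks
caseFluenceMetrics <- function(gtStack, predStack, bevMasks, spacing) {
  nb <- dim(gtStack)[3]
  do.call(rbind, lapply(seq_len(nb), function(b) {
    gt <- gtStack[, , b]; pr <- predStack[, , b]
    data.frame(
      beam = b,
      maePercent = maskedMaePercent(pr, gt, bevMasks[[b]]),
      ssim = ssimMap(pr, gt),
      gamma0 = gammaPassRate(gt, pr, spacing, thresholdPercent = 0),
      gamma10 = gammaPassRate(gt, pr, spacing, thresholdPercent = 10))
  }))
}

#' Evaluate a cohort of predictions
#'
#' Computes, per case: per-beam fluence MAE% / SSIM / gamma pass rates
#' (3%/3mm, thresholds 0% and 10%) within the projected PTV + 5 mm BEV
#' masks, and per-structure clinical indices (5 PTVs and 17 OARs) for the
#' ground-truth dose, the predicted dose, and optionally the
#' predicted-fluence-generated dose. Cohort rows carry mean +/- SD and,
#' with at least 6 cases, two paired signed-rank p-values per index
#' (ground truth vs predicted, p1; ground truth vs fluence-generated,
#' p2). A case whose metrics fail is skipped with a message.
#'
#' @param cases list of \code{PatientCase}.
#' @param predictions list of \code{\link{predictCase}} results (or lists
#'   with \code{dose} and \code{fluence}).
#' @param fluenceDoses optional list of dose volumes (cGy) recomputed from
#'   the predicted fluence with the phantom forward engine.
#' @param config a \code{\link{trainConfig}} (BEV margin).
#' @param ops full-volume operators for the shared case grid (rebuilt if
#'   NULL).
#' @return An \code{\link{EvalReport-class}}.
#' @export
evaluateCohort <- function(cases, predictions, fluenceDoses = NULL,
                           config = trainConfig("tiny"), ops = NULL) {
  stopifnot(length(cases) == length(predictions))
  if (is.null(ops))
    ops <- buildPlanOperators(cases[[1]]@grid, cases[[1]]@beams)
  fluRows <- list(); idxRows <- list()
  for (ci in seq_along(cases)) {
    res <- tryCatch({
      case <- cases[[ci]]; pred <- predictions[[ci]]
      bev <- lapply(ops, function(op)
        bevTargetMask(case@ptvDose > 0, op, config$bev_margin_mm))
      fm <- caseFluenceMetrics(case@fluence, pred$fluence, bev,
                               case@beams@planePitch)
      fm$case <- ci
      structures <- c(ptvNames(), oarNames())
      rows <- list()
      for (s in structures) {
        mask <- if (s %in% ptvNames()) case@ptvMasks[[s]] else
          case@oarMasks[[s]]
        if (!any(mask > 0)) next
        srcs <- list(groundTruth = case@dose, predicted = pred$dose)
        if (!is.null(fluenceDoses))
          srcs$fluenceGenerated <- fluenceDoses[[ci]]
        for (src in names(srcs)) {
          idx <- clinicalIndices(srcs[[src]], mask)
          rows[[length(rows) + 1L]] <- data.frame(
            case = ci, structure = s, source = src,
            D95 = idx["D95"], Dmean = idx["Dmean"], Dmax = idx["Dmax"],
            row.names = NULL)
        }
      }
      list(flu = fm, idx = do.call(rbind, rows))
    }, error = function(e) {
      message("case ", ci, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      fluRows[[length(fluRows) + 1L]] <- res$flu
      idxRows[[length(idxRows) + 1L]] <- res$idx
    }
  }
  flu <- do.call(rbind, fluRows)
  idx <- do.call(rbind, idxRows)
  summary <- cohortIndexSummary(idx)
  fluSummary <- data.frame(
    metric = c("maePercent", "ssim", "gamma0", "gamma10"),
    mean = vapply(c("maePercent", "ssim", "gamma0", "gamma10"),
                  function(m) mean(flu[[m]]), 0),
    sd = vapply(c("maePercent", "ssim", "gamma0", "gamma10"),
                function(m) stats::sd(flu[[m]]), 0),
    row.names = NULL)
  new("EvalReport", fluence = flu, doseIndices = idx, summary = summary,
      fluenceSummary = fluSummary)
}

cohortIndexSummary <- function(idx) {
  rows <- list()
  hasFlu <- "fluenceGenerated" %in% idx$source
  for (s in unique(idx$structure)) for (ix in c("D95", "Dmean", "Dmax")) {
    sub <- idx[idx$structure == s, c("case", "source", ix)]
    wide <- stats::reshape(sub, idvar = "case", timevar = "source",
                           direction = "wide")
    gt <- wide[[paste0(ix, ".groundTruth")]]
    pr <- wide[[paste0(ix, ".predicted")]]
    fl <- if (hasFlu) wide[[paste0(ix, ".fluenceGenerated")]] else NULL
    p1 <- p2 <- NA_real_
    ok <- stats::complete.cases(gt, pr)
    if (sum(gt[ok] != pr[ok]) >= 6)
      p1 <- pairedWilcoxon(gt[ok], pr[ok])$p
    if (!is.null(fl)) {
      ok2 <- stats::complete.cases(gt, fl)
      if (sum(gt[ok2] != fl[ok2]) >= 6)
        p2 <- pairedWilcoxon(gt[ok2], fl[ok2])$p
    }
    row <- data.frame(
      structure = s, index = ix,
      groundTruthMean = mean(gt, na.rm = TRUE),
      groundTruthSd = stats::sd(gt),
      predictedMean = mean(pr, na.rm = TRUE), predictedSd = stats::sd(pr),
      p1 = p1, p2 = p2, row.names = NULL)
    if (hasFlu) {
      row$fluenceGeneratedMean <- mean(fl, na.rm = TRUE)
      row$fluenceGeneratedSd <- stats::sd(fl)
    }
    rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

#' Write an evaluation report to disk
#'
#' Per-case long-format CSVs plus a JSON cohort summary.
#'
#' @param report an \code{EvalReport}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    fluence = file.path(dir, "fluence_metrics.csv"),
    doseIndices = file.path(dir, "dose_indices.csv"),
    summary = file.path(dir, "cohort_summary.csv"),
    json = file.path(dir, "cohort_summary.json"))
  utils::write.csv(report@fluence, paths["fluence"], row.names = FALSE)
  utils::write.csv(report@doseIndices, paths["doseIndices"], row.names = FALSE)
  utils::write.csv(report@summary, paths["summary"], row.names = FALSE)
  jsonlite::write_json(
    list(doseIndices = report@summary, fluence = report@fluenceSummary),
    paths["json"], dataframe = "rows", digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
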