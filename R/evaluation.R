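#' Construct a marker set
#'
#' @param points N x 2 matrix of (x = lateral, y = axial) positions in mm
#'   with unique rownames.
#' @param source "detected" or "supplied".
#' @return A \linkS4class{MarkerSet}.
#' @export
markerSet <- function(points, source = "supplied") {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L)
  new("MarkerSet", points = points, source = source)
}

## Otsu threshold of a value vector in [0, 1], via EBImage's histogram Otsu.
.otsuVec <- function(vals) {
  EBImage::otsu(EBImage::Image(matrix(vals, nrow = 1L)), range = c(0, 1))
}

#' Detect bright sphere markers in a B-mode image
#'
#' Median-smooths the image, thresholds it, labels connected components,
#' discards components smaller than \code{minAreaMM2}, and returns the
#' centroids of the \code{expectedCount} largest components in mm.  The
#' threshold is an iterative Otsu: starting from the full image, the Otsu
#' level is recomputed over the above-threshold pixels until the foreground
#' covers less than \code{foregroundFrac} of the image (or the level stops
#' increasing).  Log-compressed B-mode histograms are dominated by the
#' anechoic background and the broad speckle mode, so a single Otsu level
#' separates background from tissue rather than tissue from the echogenic
#' targets; the iteration walks the level up past the speckle mode.
#' Centroids are intensity-weighted (weight = intensity above threshold).
#' Markers are named m1..mk in order of increasing x (ties by y), giving a
#' stable pairing between two images of the same scene.
#'
#' @param img A \linkS4class{BModeImage} or \linkS4class{GrayImage} with
#'   values in [0, 255].
#' @param expectedCount Number of markers to return (>= 1).
#' @param minAreaMM2 Minimum component area, mm^2 (default 2).
#' @param medianWindow Smoothing window before thresholding (default 5).
#' @param foregroundFrac Stop the threshold iteration once the foreground
#'   fraction drops below this (default 0.05).
#' @return A \linkS4class{MarkerSet} with \code{source = "detected"}.
#' @export
detectSphereMarkers <- function(img, expectedCount, minAreaMM2 = 2,
                                medianWindow = 5L, foregroundFrac = 0.05) {
  stopifnot(is(img, "GrayImage"))
  .assertParam(expectedCount >= 1, "expectedCount must be >= 1")
  sm <- medianFilterImage(img, medianWindow)
  v <- pmin(pmax(sm@values / 255, 0), 1)
  thr <- 0
  for (it in 1:6) {
    sel <- v[v > thr]
    if (length(sel) < 50) break
    t2 <- .otsuVec(sel)
    if (t2 <= thr) break
    thr <- t2
    if (mean(v > thr) < foregroundFrac) break
  }
  bin <- v > thr
  if (!any(bin))
    .eusStop("eus_detection_error",
             "no components above threshold (expected %d)", expectedCount)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bin * 1)))))
  pxArea <- prod(img@pixelSpacing)
  counts <- tabulate(lab[lab > 0])
  keep <- which(counts * pxArea >= minAreaMM2)
  if (length(keep) < expectedCount)
    .eusStop("eus_detection_error",
             "found %d component(s) >= %.1f mm^2, expected %d",
             length(keep), minAreaMM2, expectedCount)
  keep <- keep[order(-counts[keep])][seq_len(expectedCount)]
  pts <- t(vapply(keep, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    wt <- v[w] - thr
    c(img@origin[1] + (sum(w[, 2] * wt) / sum(wt) - 1) * img@pixelSpacing[1],
      img@origin[2] + (sum(w[, 1] * wt) / sum(wt) - 1) * img@pixelSpacing[2])
  }, numeric(2)))
  ord <- order(pts[, 1], pts[, 2])
  pts <- pts[ord, , drop = FALSE]
  rownames(pts) <- paste0("m", seq_len(nrow(pts)))
  colnames(pts) <- c("x", "y")
  markerSet(pts, source = "detected")
}

#' Per-marker localization errors between two marker sets
#'
#' Errors are matched minus target, per shared marker name, with x =
#' lateral and y = axial (mm).
#'
#' @param target,matched \linkS4class{MarkerSet}s sharing >= 1 marker name.
#' @return A \linkS4class{MarkerErrorReport}.
#' @export
markerErrors <- function(target, matched) {
  stopifnot(is(target, "MarkerSet"), is(matched, "MarkerSet"))
  shared <- intersect(rownames(target@points), rownames(matched@points))
  .assertParam(length(shared) >= 1, "marker sets share no names")
  d <- matched@points[shared, , drop = FALSE] -
    target@points[shared, , drop = FALSE]
  pm <- data.frame(name = shared, dx = d[, 1], dy = d[, 2],
                   row.names = NULL)
  new("MarkerErrorReport", perMarker = pm,
      maxAbsError = max(abs(c(pm$dx, pm$dy))),
      meanAbsError = mean(abs(c(pm$dx, pm$dy))))
}

#' Add seeded Gaussian pixel noise to an image
#'
#' @param img A \linkS4class{GrayImage} (values in [0, 255]).
#' @param sigmaFrac Noise sigma as a fraction of the 255 intensity range.
#' @param seed Integer seed.
#' @return The noisy image, clipped back to [0, 255].
#' @export
addPixelNoise <- function(img, sigmaFrac = 0.05, seed = 1L) {
  stopifnot(is(img, "GrayImage"))
  set.seed(seed)
  v <- img@values + stats::rnorm(length(img@values), 0, sigmaFrac * 255)
  initialize(img, values = matrix(pmin(pmax(v, 0), 255), nrow(img@values)))
}

#' Assemble the default phantom study
#'
#' Bundles the pieces of the phantom experiment: the training-phantom
#' geometry, its sampled scatterer field, the per-target candidate pose grid
#' (offsets at 5-mm spacing, rotations 0 and +/-15 degrees), the linear
#' endoscopic probe preset and the default PSF.
#'
#' @param seed Seed for the phantom geometry and scatterer field.
#' @param density Scatterers per mm^3.
#' @param nOffsets,offsetStep,rotations Pose-grid parameters.
#' @param extent Imaging-plane extent (u, v), mm.
#' @param matchSize Image/matching resolution (rows, cols).
#' @return List with elements spec, field, grid, probe, psf, density, seed.
#' @export
phantomStudy <- function(seed = 1L, density = 5, nOffsets = 10L,
                         offsetStep = 5, rotations = c(0, 15, -15),
                         extent = c(80, 80), matchSize = c(128L, 128L)) {
  spec <- eusTrainingPhantomSpec(seed)
  field <- sampleGeometricScatterers(spec, density = density, seed = seed)
  grid <- buildPhantomPoseGrid(
    as.matrix(spec@spheres[, c("x", "y", "z")]), nOffsets = nOffsets,
    offsetStep = offsetStep, rotations = rotations,
    channelAxis = spec@channelAxis, extent = extent,
    pixelSpacing = extent / matchSize[c(2, 1)])
  list(spec = spec, field = field, grid = grid,
       probe = makeProbePreset("endoscopic_linear"), psf = psfModel(),
       density = density, seed = seed)
}

## Index of the central (offset 0, rotation 0) pose of a target.
.centralPoseIndex <- function(grid, targetId) {
  hit <- which(vapply(grid@poses, function(p)
    p@targetId == targetId && p@offset == 0 && p@rotation == 0, TRUE))
  .assertParam(length(hit) == 1L,
               "no unique central pose for target '%s'", targetId)
  hit
}

#' Marker-based phantom localization evaluation
#'
#' Re-simulates the central (offset 0, rotation 0) pose of each requested
#' target from an independently seeded scatterer field, adds Gaussian pixel
#' noise, matches the resulting off-dictionary target image against the
#' dictionary, and measures the sphere-centroid marker error between the
#' target image and the matched dictionary image.  This stands in for the
#' real acquired EUS frame of the physical experiment, which is not
#' available.
#'
#' @param study A \code{\link{phantomStudy}} list.
#' @param dict The \linkS4class{FeatureDictionary} built from
#'   \code{study$field} over \code{study$grid} (with images kept).
#' @param basis The \linkS4class{HaarBasisSet} used for the dictionary.
#' @param targetSeed Seed of the independent target scatterer field.
#' @param noiseSigmaFrac Pixel-noise sigma as a fraction of the range.
#' @param noiseSeed Seed for the pixel noise.
#' @param whichTargets Target ids (default: all spheres).
#' @param dynamicRange,medianWindow Imaging/preprocessing parameters
#'   (must match the dictionary build).
#' @return List with \code{report} (\linkS4class{MarkerErrorReport}, one
#'   marker per target), \code{matches} (data.frame with the true and
#'   estimated dictionary index, score and correctness per target) and
#'   \code{targetImages}.
#' @export
evaluatePhantomLocalization <- function(study, dict, basis,
                                        targetSeed = study$seed + 500L,
                                        noiseSigmaFrac = 0.05,
                                        noiseSeed = study$seed + 900L,
                                        whichTargets = NULL,
                                        dynamicRange = 60,
                                        medianWindow = 5L) {
  .assertParam(length(dict@images) > 0,
               "dictionary must be built with keepImages = TRUE")
  ids <- rownames(study$spec@spheres)
  if (!is.null(whichTargets)) ids <- intersect(ids, whichTargets)
  targetField <- sampleGeometricScatterers(study$spec, study$density,
                                           seed = targetSeed)
  tgtPts <- matrix(NA_real_, length(ids), 2,
                   dimnames = list(ids, c("x", "y")))
  matPts <- tgtPts
  rows <- vector("list", length(ids))
  targetImages <- stats::setNames(vector("list", length(ids)), ids)
  for (k in seq_along(ids)) {
    id <- ids[k]
    trueIdx <- .centralPoseIndex(study$grid, id)
    pose <- study$grid@poses[[trueIdx]]
    img <- simulateBMode(targetField, study$probe, study$psf, pose@plane,
                         basis@matchSize, dynamicRange)
    img <- addPixelNoise(img, noiseSigmaFrac, noiseSeed + k)
    targetImages[[id]] <- img
    res <- findBestMatch(dict, img, basis, medianWindow)
    mt <- detectSphereMarkers(img, 1L)
    mm <- detectSphereMarkers(dictionaryImage(dict, res@bestIndex), 1L)
    tgtPts[id, ] <- mt@points[1, ]
    matPts[id, ] <- mm@points[1, ]
    rows[[k]] <- data.frame(targetId = id, trueIndex = trueIdx,
                            bestIndex = res@bestIndex,
                            correct = res@bestIndex == trueIdx,
                            score = res@score)
  }
  report <- markerErrors(markerSet(tgtPts), markerSet(matPts))
  list(report = report, matches = do.call(rbind, rows),
       targetImages = targetImages)
}

## Feature extraction over pre-rendered pose images (shared by the sweep so
## per-config dictionaries reuse one simulation pass).
.dictionaryFromImages <- function(images, grid, basis, medianWindow = 5L) {
  plan <- .featurePlan(basis, basis@matchSize)
  vectors <- matrix(NA_real_, length(images), plan$nFeatures)
  valid <- logical(length(images))
  for (i in seq_along(images)) {
    if (is.null(images[[i]])) next
    filt <- medianFilterImage(images[[i]], medianWindow)
    vectors[i, ] <- extractFeatureVector(filt, basis)@values
    valid[i] <- TRUE
  }
  new("FeatureDictionary", poses = grid@poses, vectors = vectors,
      scaleBlocks = plan$scaleBlocks, indexMap = plan$index,
      images = images, valid = valid, fingerprint = plan$fingerprint)
}

#' Sweep matching accuracy over scale sets and basis sizes
#'
#' Re-runs the phantom matching experiment for every combination of a scale
#' set and a template count: dictionaries share one simulation pass (the
#' images do not depend on the basis), and for every configuration and seed
#' an off-dictionary target (independent scatterer seed plus pixel noise) is
#' matched and the sphere-marker error recorded.  When marker detection on
#' the matched image fails (e.g. the matched pose shows no sphere), the
#' error is recorded as half the image diagonal -- a gross-mismatch
#' sentinel.
#'
#' @param study A \code{\link{phantomStudy}} list.
#' @param scalesList List of integer scale-set vectors.
#' @param basisCounts Integer vector of template counts (the first k of the
#'   8 base templates are used).
#' @param seeds Integer vector of trial seeds.
#' @param images Optional pre-rendered pose images (from a dictionary built
#'   with \code{keepImages = TRUE}); rendered if missing.
#' @param baseSupport,matchSize,dynamicRange,medianWindow Shared basis /
#'   imaging parameters.
#' @param noiseSigmaFrac Target pixel-noise sigma fraction.
#' @return data.frame with one row per (config, seed): scales, nTemplates,
#'   seed, targetId, correct, markerError (mm), and the per-config label.
#' @export
sweepMatchingConfig <- function(study, scalesList, basisCounts, seeds,
                                images = NULL, baseSupport = 12L,
                                matchSize = c(128L, 128L),
                                dynamicRange = 60, medianWindow = 5L,
                                noiseSigmaFrac = 0.05) {
  .assertParam(length(scalesList) > 0 && length(basisCounts) > 0 &&
               length(seeds) > 0, "sweep lists must be non-empty")
  if (is.null(images)) {
    images <- lapply(study$grid@poses, function(pose)
      simulateBMode(study$field, study$probe, study$psf, pose@plane,
                    matchSize, dynamicRange))
  }
  ids <- rownames(study$spec@spheres)
  halfDiag <- sqrt(sum((dim(images[[1]]) *
                          images[[1]]@pixelSpacing[c(2, 1)])^2)) / 2
  rows <- list()
  for (sc in scalesList) {
    for (nb in basisCounts) {
      basis <- haarBasisSet(templates = seq_len(nb), scales = sc,
                            baseSupport = baseSupport, matchSize = matchSize)
      dict <- .dictionaryFromImages(images, study$grid, basis, medianWindow)
      for (sd in seeds) {
        id <- ids[(sd %% length(ids)) + 1L]
        trueIdx <- .centralPoseIndex(study$grid, id)
        pose <- study$grid@poses[[trueIdx]]
        tf <- sampleGeometricScatterers(study$spec, study$density,
                                        seed = study$seed + 1000L + sd)
        img <- simulateBMode(tf, study$probe, study$psf, pose@plane,
                             matchSize, dynamicRange)
        img <- addPixelNoise(img, noiseSigmaFrac, sd)
        res <- findBestMatch(dict, img, basis, medianWindow)
        err <- tryCatch({
          mt <- detectSphereMarkers(img, 1L)
          mm <- detectSphereMarkers(dictionaryImage(dict, res@bestIndex), 1L)
          markerErrors(mt, mm)@meanAbsError
        }, eus_detection_error = function(e) halfDiag)
        rows[[length(rows) + 1L]] <- data.frame(
          config = sprintf("s{%s}_n%d", paste(sc, collapse = ","), nb),
          scales = paste(sc, collapse = ","), nTemplates = nb, seed = sd,
          targetId = id, correct = res@bestIndex == trueIdx,
          markerError = err)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-configuration summary of a sweep table
#'
#' @param sweep Output of \code{\link{sweepMatchingConfig}}.
#' @return data.frame with per-config mean marker error and accuracy.
#' @export
summarizeSweep <- function(sweep) {
  agg <- stats::aggregate(cbind(markerError, correct) ~ config + scales +
                            nTemplates, data = sweep, FUN = mean)
  names(agg)[names(agg) == "markerError"] <- "meanMarkerError"
  names(agg)[names(agg) == "correct"] <- "accuracy"
  agg[order(agg$scales, agg$nTemplates), ]
}
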