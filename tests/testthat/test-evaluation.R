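test_that("sphere markers are detected at disk centroids", {
  one <- diskImage(matrix(c(10, 20), 1, 2), radiusMM = 3)
  m <- detectSphereMarkers(one, 1L)
  expect_lt(abs(markerPoints(m)[1, "x"] - 10), 0.5)
  expect_lt(abs(markerPoints(m)[1, "y"] - 20), 0.5)
  ## blank image: detection error
  blank <- new("BModeImage", values = matrix(0, 64, 64),
               pixelSpacing = c(0.5, 0.5), origin = c(0, 0),
               dynamicRange = 60, plane = axialPlane(c(32, 32)))
  expect_error(detectSphereMarkers(blank, 1L), class = "eus_detection_error")
  ## four disks give four markers, one per disk, ordered by x
  ctrs <- rbind(c(8, 10), c(18, 30), c(30, 12), c(40, 35))
  four <- diskImage(ctrs, radiusMM = 3)
  m4 <- detectSphereMarkers(four, 4L)
  expect_equal(nrow(markerPoints(m4)), 4L)
  for (k in 1:4) {
    expect_lt(abs(markerPoints(m4)[k, "x"] - ctrs[k, 1]), 0.5)
    expect_lt(abs(markerPoints(m4)[k, "y"] - ctrs[k, 2]), 0.5)
  }
  ## asking for more markers than exist is a detection error
  expect_error(detectSphereMarkers(one, 3L), class = "eus_detection_error")
})

test_that("marker error reports are exact differences, matched minus target", {
  pts <- matrix(c(1, 2, 10, 4), 2, 2,
                dimnames = list(c("a", "b"), c("x", "y")))
  t0 <- markerSet(pts)
  expect_equal(markerErrors(t0, t0)@maxAbsError, 0)
  shifted <- markerSet(sweep(pts, 2, c(0.5, -0.2), "+"))
  rep1 <- markerErrors(t0, shifted)
  expect_equal(rep1@perMarker$dx, rep(0.5, 2), tolerance = 1e-12)
  expect_equal(rep1@perMarker$dy, rep(-0.2, 2), tolerance = 1e-12)
  expect_equal(rep1@maxAbsError, 0.5, tolerance = 1e-12)
  ## random perturbations match direct subtraction; antisymmetry
  set.seed(44)
  d <- matrix(rnorm(4, 0, 1), 2, 2)
  pert <- markerSet(pts + d, source = "supplied")
  fwd <- markerErrors(t0, pert)
  expect_equal(unname(cbind(fwd@perMarker$dx, fwd@perMarker$dy)), unname(d),
               tolerance = 1e-12)
  bwd <- markerErrors(pert, t0)
  expect_equal(bwd@perMarker$dx, -fwd@perMarker$dx)
  expect_equal(bwd@perMarker$dy, -fwd@perMarker$dy)
  ## disjoint names
  other <- markerSet(matrix(1:4, 2, 2, dimnames = list(c("p", "q"), NULL)))
  expect_error(markerErrors(t0, other), class = "eus_parameter_error")
})

test_that("phantom localization evaluation matches and measures per target", {
  st <- smallStudy()
  dict <- smallDictionary()
  ev <- evaluatePhantomLocalization(st, dict, smallBasis(),
                                    whichTargets = c("target_1", "target_2"))
  expect_equal(nrow(ev$matches), 2L)
  expect_equal(nrow(ev$report@perMarker), 2L)
  expect_true(all(is.finite(ev$report@perMarker$dx)))
  ## correct matches at this scale recover the central pose
  expect_true(all(ev$matches$correct))
})

test_that("sweep rows reproduce a direct pipeline run and are reproducible", {
  st <- smallStudy()
  dict <- smallDictionary()
  sw1 <- sweepMatchingConfig(st, scalesList = list(0:2), basisCounts = 8L,
                             seeds = 3L, images = dict@images,
                             matchSize = c(64L, 64L))
  expect_equal(nrow(sw1), 1L)
  ## consistency with a direct run of the same trial
  id <- rownames(st$spec@spheres)[(3L %% 4L) + 1L]
  trueIdx <- eusTracker:::.centralPoseIndex(st$grid, id)
  tf <- sampleGeometricScatterers(st$spec, st$density, seed = st$seed + 1003L)
  img <- addPixelNoise(simulateBMode(tf, st$probe, st$psf,
                                     poses(st$grid)[[trueIdx]]@plane,
                                     c(64L, 64L)), 0.05, 3L)
  res <- findBestMatch(dict, img, smallBasis())
  expect_equal(sw1$correct, res@bestIndex == trueIdx)
  sw2 <- sweepMatchingConfig(st, scalesList = list(0:2), basisCounts = 8L,
                             seeds = 3L, images = dict@images,
                             matchSize = c(64L, 64L))
  expect_identical(sw1, sw2)
  ## config x seed row counts and finite errors for different basis sizes
  sw3 <- sweepMatchingConfig(st, scalesList = list(0:2),
                             basisCounts = c(4L, 8L), seeds = c(1L, 2L),
                             images = dict@images, matchSize = c(64L, 64L))
  expect_equal(nrow(sw3), 4L)
  expect_true(all(is.finite(sw3$markerError)))
  sm <- summarizeSweep(sw3)
  expect_equal(nrow(sm), 2L)
})
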