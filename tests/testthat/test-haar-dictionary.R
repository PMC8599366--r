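test_that("integral images reproduce brute-force rectangle sums", {
  expect_equal(integralImage(matrix(1, 3, 3))[3, 3], 9)
  expect_true(all(integralImage(matrix(0, 4, 5)) == 0))
  set.seed(2)
  m <- matrix(runif(32 * 32, 0, 10), 32, 32)
  ii <- integralImage(m)
  for (k in 1:100) {
    r0 <- sample(0:30, 1); c0 <- sample(0:30, 1)
    h <- sample(seq_len(32 - r0), 1); w <- sample(seq_len(32 - c0), 1)
    fast <- ii[r0 + h, c0 + w] -
      (if (r0 > 0) ii[r0, c0 + w] else 0) -
      (if (c0 > 0) ii[r0 + h, c0] else 0) +
      (if (r0 > 0 && c0 > 0) ii[r0, c0] else 0)
    slow <- bruteRectSum(m, r0, c0, h, w)
    expect_lt(abs(fast - slow) / max(abs(slow), 1), 1e-9)
  }
})

test_that("Haar features match rendered-mask dot products", {
  basis <- haarBasisSet(scales = 0:1, matchSize = c(48L, 48L))
  set.seed(4)
  img <- matrix(runif(48 * 48, 0, 255), 48, 48)
  ii <- integralImage(img)
  idx <- enumerateFeatures(basis, c(48L, 48L))
  fv <- extractFeatureVector(GrayImage(img), basis)
  for (k in seq_len(nrow(idx))) {
    oracle <- renderedMaskResponse(img, idx[k, ], basis)
    expect_lt(abs(evalHaarFeature(ii, idx[k, ], basis) - oracle) /
                max(abs(oracle), 1), 1e-9)
    expect_lt(abs(featureValues(fv)[k] - oracle) / max(abs(oracle), 1), 1e-9)
  }
})

test_that("all templates except the average vanish on constant images", {
  basis <- haarBasisSet(matchSize = c(128L, 128L))
  fv <- extractFeatureVector(GrayImage(matrix(5, 128, 128)), basis)
  avg <- fv@indexMap$template == 8L
  expect_true(all(abs(featureValues(fv)[!avg]) < 1e-9))
  expect_true(all(featureValues(fv)[avg] > 0))
})

test_that("an edge feature spanning a step reads the half-support area", {
  ## left half 0, right half 1; template 1 at split 0.5 centred on the step
  S <- 24L
  img <- cbind(matrix(0, S, S / 2), matrix(1, S, S / 2))
  basis <- haarBasisSet(templates = 1L, edgeSplits = 0.5, scales = 1L,
                        baseSupport = 12L, matchSize = c(S, S))
  ii <- integralImage(img)
  idx <- data.frame(template = 1L, variant = 1L, scale = 1L, tx = 0L, ty = 0L)
  val <- evalHaarFeature(ii, idx, basis)
  expect_equal(abs(val), S * S / 2)
})

test_that("feature enumeration is combinatorial and deterministic", {
  ## one template, one variant, support 8, stride 8 on a 16 x 16 image
  b1 <- haarBasisSet(templates = 5L, scales = 0L, baseSupport = 8L,
                     matchSize = c(16L, 16L))
  idx <- enumerateFeatures(b1, c(16L, 16L))
  expect_equal(nrow(idx), 4L)
  ## two scales group into exactly two scale blocks
  b2 <- haarBasisSet(templates = c(1L, 5L), scales = c(0L, 1L),
                     matchSize = c(64L, 64L))
  fv <- extractFeatureVector(randomImage(64, 64), b2)
  expect_equal(nrow(scaleBlocks(fv)), 2L)
  ## identical inputs give identical orderings
  expect_identical(enumerateFeatures(b1, c(16L, 16L)),
                   enumerateFeatures(b1, c(16L, 16L)))
  expect_error(enumerateFeatures(b1, c(6L, 6L)), class = "eus_parameter_error")
})

test_that("feature extraction is linear and size-stable", {
  basis <- smallBasis()
  img <- randomImage(64, 64, seed = 12)
  f1 <- extractFeatureVector(img, basis)
  f2 <- extractFeatureVector(initialize(img, values = 2 * img@values), basis)
  expect_equal(featureValues(f2), 2 * featureValues(f1), tolerance = 1e-12)
  ## equal-size images yield equal-length, fingerprint-compatible vectors
  g <- extractFeatureVector(randomImage(64, 64, seed = 13), basis)
  expect_length(featureValues(g), length(featureValues(f1)))
  expect_identical(basisFingerprint(g), basisFingerprint(f1))
  ## a different basis yields a different fingerprint
  h <- extractFeatureVector(img, haarBasisSet(scales = 0:1,
                                              matchSize = c(64L, 64L)))
  expect_false(identical(basisFingerprint(h), basisFingerprint(f1)))
})

test_that("dictionaries are built in grid order, reproducibly", {
  st <- smallStudy()
  dict <- smallDictionary()
  expect_length(dict, length(st$grid))
  expect_identical(vapply(poses(dict), function(p) p@label, ""),
                   vapply(poses(st$grid), function(p) p@label, ""))
  expect_true(all(dict@valid))
  ## bitwise reproducible rebuild
  dict2 <- buildDictionary(st$field, st$grid, st$probe, st$psf, smallBasis(),
                           keepImages = FALSE)
  expect_identical(dict2@vectors, dict@vectors)
  emptyGrid <- new("PoseGrid", poses = list(), perTargetCounts = integer())
  expect_error(buildDictionary(st$field, emptyGrid, st$probe, st$psf,
                               smallBasis()),
               class = "eus_parameter_error")
})

test_that("poses whose plane misses the data are flagged invalid", {
  st <- smallStudy()
  far <- probePose("far_away", "t9",
                   axialPlane(extent = c(20, 20), center = c(900, 900, 900)))
  grid <- eusTracker:::.poseGrid(c(poses(st$grid)[1], list(far)))
  expect_warning(
    dict <- buildDictionary(st$field, grid, st$probe, st$psf, smallBasis()),
    "far_away")
  expect_identical(dict@valid, c(TRUE, FALSE))
  res <- findBestMatch(dict, dictionaryImage(dict, 1), smallBasis())
  expect_equal(res@bestIndex, 1L)
  expect_false(2L %in% res@ranking)
})

test_that("dictionaries round-trip through their on-disk layout", {
  dict <- smallDictionary()
  dir <- tempfile()
  saveDictionary(dict, dir)
  back <- loadDictionary(dir)
  expect_identical(back@fingerprint, dict@fingerprint)
  expect_equal(back@vectors, dict@vectors, tolerance = 1e-12)
  expect_identical(vapply(poses(back), function(p) p@label, ""),
                   vapply(poses(dict), function(p) p@label, ""))
  ## a different-fingerprint dictionary refuses to overwrite
  st <- smallStudy()
  other <- buildDictionary(st$field, st$grid, st$probe, st$psf,
                           haarBasisSet(scales = 0:1,
                                        matchSize = c(64L, 64L)),
                           keepImages = FALSE)
  expect_error(saveDictionary(other, dir), class = "eus_contract_error")
  expect_silent(saveDictionary(other, dir, overwrite = TRUE))
})

test_that("volume-backed dictionaries build through the bitmap route", {
  toy <- generateToyVolume("eus_training_phantom", seed = 7)
  ctr <- as.matrix(toy$spec@spheres[1, c("x", "y", "z")])
  grid <- buildPhantomPoseGrid(ctr, nOffsets = 2L, offsetStep = 5,
                               rotations = 0,
                               pixelSpacing = c(80, 80) / 64)
  basis <- smallBasis()
  dict <- buildDictionary(toy$volume, grid, makeProbePreset("endoscopic_linear"),
                          psfModel(), basis, seed = 3L,
                          scatterersPerImage = 30000L)
  expect_true(all(dict@valid))
  res <- findBestMatch(dict, dictionaryImage(dict, 1), basis)
  expect_equal(res@bestIndex, 1L)
  expect_equal(res@score, 1, tolerance = 1e-12)
})
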