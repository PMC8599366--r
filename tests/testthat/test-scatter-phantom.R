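test_that("geometric scatterer sampling is seeded, counted and regioned", {
  spec <- geometricPhantomSpec(
    box = c(10, 10, 10),
    spheres = data.frame(x = 0, y = 0, z = 0, radius = 3, amplitude = 1),
    channelRadius = 0.5, backgroundAmplitude = 0)
  ## expected count = density * volume
  f1 <- sampleGeometricScatterers(spec, density = 0.001, seed = 4)
  expect_equal(nScatterers(f1), 1L)
  f2 <- sampleGeometricScatterers(spec, density = 0.001, seed = 4)
  expect_identical(positions(f1), positions(f2))
  expect_identical(amplitudes(f1), amplitudes(f2))
  ## background factor 0: every nonzero amplitude lies inside the sphere
  f3 <- sampleGeometricScatterers(spec, density = 5, seed = 11)
  nz <- amplitudes(f3) != 0
  r <- sqrt(rowSums(positions(f3)[nz, , drop = FALSE]^2))
  expect_true(all(r <= 3 + 1e-9))
  ## channel has priority over the sphere: amplitudes exactly 0 inside it
  axial <- sqrt(rowSums(positions(f3)[, 1:2, drop = FALSE]^2))
  expect_true(all(amplitudes(f3)[axial <= 0.5] == 0))
})

test_that("scatterer count scales linearly with density", {
  spec <- eusTrainingPhantomSpec(seed = 2)
  n1 <- nScatterers(sampleGeometricScatterers(spec, density = 0.05, seed = 1))
  n4 <- nScatterers(sampleGeometricScatterers(spec, density = 0.20, seed = 1))
  expect_gt(n1, 1e4)
  expect_lt(abs(n4 / n1 - 4), 0.05 * 4)
})

test_that("amplitudes in a constant-factor region are Gaussian(0, factor^2)", {
  spec <- geometricPhantomSpec(
    box = c(30, 30, 30), spheres = data.frame(
      x = numeric(), y = numeric(), z = numeric(), radius = numeric(),
      amplitude = numeric()),
    channelRadius = 1e-6, backgroundAmplitude = 2)
  f <- sampleGeometricScatterers(spec, density = 0.4, seed = 8)
  keep <- sqrt(rowSums(positions(f)[, 1:2]^2)) > 1e-6
  a <- amplitudes(f)[keep]
  expect_gt(length(a), 1e4)
  ks <- ks.test(a, "pnorm", mean = 0, sd = 2)
  expect_gt(ks$p.value, 0.01)
})

test_that("bitmap scatterers follow the intensity-to-factor map", {
  zero <- GrayImage(matrix(0, 16, 16))
  fz <- sampleBitmapScatterers(zero, n = 500, seed = 1)
  expect_true(all(amplitudes(fz) == 0))
  ## two-level bitmap: zero variance in the dark half, positive in the bright
  two <- GrayImage(cbind(matrix(0, 32, 16), matrix(200, 32, 16)))
  ft <- sampleBitmapScatterers(two, n = 1e5, seed = 2)
  ## u spans [-0.5, 31.5] with unit pixels; bright half is columns 17-32
  u <- positions(ft)[, 1]
  expect_equal(stats::var(amplitudes(ft)[u < 15.5]), 0)
  expect_gt(stats::var(amplitudes(ft)[u > 16.5]), 0.5)
  ## determinism
  fa <- sampleBitmapScatterers(two, n = 1000, seed = 9)
  fb <- sampleBitmapScatterers(two, n = 1000, seed = 9)
  expect_identical(positions(fa), positions(fb))
  expect_identical(amplitudes(fa), amplitudes(fb))
})

test_that("toy volume generator meets its structural contracts", {
  toy <- generateToyVolume("eus_training_phantom", seed = 3)
  sphereMasks <- Filter(function(m) m@name != "channel", toy$masks)
  expect_length(sphereMasks, 4L)
  ctr <- as.matrix(toy$spec@spheres[, c("x", "y", "z")])
  dists <- as.matrix(dist(ctr))
  expect_gt(min(dists[upper.tri(dists)]), 10)
  ## determinism
  toy2 <- generateToyVolume("eus_training_phantom", seed = 3)
  expect_identical(intensities(toy2$volume), intensities(toy$volume))
  ## abdomen-like variant with 3 hydrogel blobs
  abd <- generateToyVolume("abdomen_like", seed = 5, nHydrogel = 3)
  nms <- vapply(abd$masks, function(m) m@name, "")
  expect_equal(sum(grepl("^hydrogel_", nms)), 3L)
  expect_true(all(c("tumor", "marker") %in% nms))
  expect_identical(dim(abd$masks[[1]]@values), dim(abd$volume))
})

test_that("scatterer fields round-trip through columnar CSV", {
  spec <- eusTrainingPhantomSpec(seed = 1)
  f <- sampleGeometricScatterers(spec, density = 0.001, seed = 2)
  path <- tempfile(fileext = ".csv")
  writeScattererField(f, path)
  back <- readScattererField(path)
  expect_equal(positions(back), positions(f), tolerance = 1e-12)
  expect_equal(amplitudes(back), amplitudes(f), tolerance = 1e-12)
})
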