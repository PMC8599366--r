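test_that("probe presets carry the published hardware parameters", {
  lin <- makeProbePreset("endoscopic_linear")
  expect_equal(lin@nElements, 128L)
  expect_equal(lin@centerFrequency, 7.5e6)
  expect_equal(lin@elementWidth, 0.29)
  expect_equal(lin@elementHeight, 0.41)
  cur <- makeProbePreset("endoscopic_curvilinear")
  expect_equal(cur@nElements, 159L)
  expect_equal(cur@arrayRadius, 91.1)
  expect_equal(cur@nScanlines, 128L)
  expect_error(makeProbePreset("sector_phased"), class = "eus_parameter_error")
})

test_that("an empty scatterer field renders a uniform minimum image", {
  empty <- new("ScattererField", positions = matrix(numeric(), 0, 3),
               amplitudes = numeric(), bounds = rbind(rep(-1, 3), rep(1, 3)))
  img <- simulateBMode(empty, makeProbePreset("endoscopic_linear"),
                       psfModel(), axialPlane())
  expect_true(all(intensities(img) == 0))
})

test_that("a point target peaks at its true depth and scanline", {
  probe <- makeProbePreset("endoscopic_linear")
  psf <- psfModel()
  lam <- probe@speedOfSound / probe@centerFrequency
  plane <- axialPlane()
  f <- pointField(c(0, -40 + 30, 0))       # depth 30 mm on the axis
  be <- simulateBMode(f, probe, psf, plane, output = "envelope")
  pk <- which(be$envelope == max(be$envelope), arr.ind = TRUE)[1, ]
  expect_lt(abs(be$depth[pk[1]] - 30), lam / 2)
  sig <- eusTracker:::.lateralSigma(30, probe, psf)
  expect_lt(abs(be$lateral[pk[2]]), sig + be$lateral[2] - be$lateral[1])
})

test_that("B-mode output is deterministic and amplitude-scale invariant", {
  st <- smallStudy()
  plane <- poses(st$grid)[[1]]@plane
  a <- simulateBMode(st$field, st$probe, st$psf, plane, c(64L, 64L))
  b <- simulateBMode(st$field, st$probe, st$psf, plane, c(64L, 64L))
  expect_identical(intensities(a), intensities(b))
  scaled <- new("ScattererField", positions = positions(st$field),
                amplitudes = 2 * amplitudes(st$field),
                bounds = st$field@bounds)
  c2 <- simulateBMode(scaled, st$probe, st$psf, plane, c(64L, 64L))
  expect_equal(intensities(c2), intensities(a), tolerance = 1e-9)
})

test_that("a centred sphere target appears with its physical radius", {
  ## dense scatterers, echogenic 5-mm sphere at the plane centre
  spec <- geometricPhantomSpec(
    box = c(60, 60, 20),
    spheres = data.frame(x = 0, y = 0, z = 0, radius = 5, amplitude = 3),
    channelRadius = 1e-9, backgroundAmplitude = 1)
  f <- sampleGeometricScatterers(spec, density = 8, seed = 3)
  plane <- obliqueSliceSpec(c(0, 0, 0), c(0, 0, 1), c(0, 1, 0), c(50, 50))
  img <- simulateBMode(f, makeProbePreset("endoscopic_linear"), psfModel(),
                       plane)
  m <- detectSphereMarkers(img, 1L)
  ## sphere centre maps to lateral 0, depth 25
  expect_lt(abs(markerPoints(m)[1, "x"]), 1.5)
  expect_lt(abs(markerPoints(m)[1, "y"] - 25), 1.5)
})

test_that("scan conversion maps the fan geometry correctly", {
  probe <- makeProbePreset("endoscopic_curvilinear")
  ## constant polar image: constant inside the fan, 0 outside
  const <- matrix(100, 81, 64)
  bm <- scanConvert(const, probe, pixelSpacing = 0.5, depthSpacing = 0.5)
  v <- intensities(bm)
  ## fan axis column, mid depth is interior
  midc <- ncol(v) %/% 2L
  expect_equal(v[40, midc], 100, tolerance = 1e-6)
  expect_equal(v[1, 1], 0)  # outside the fan corner
  ## single bright sample at known (angle, depth)
  polar <- matrix(0, 81, 64)
  polar[41, 30] <- 200
  span <- probe@angularSpan * pi / 180
  th <- ((30 - 0.5) / 64 - 0.5) * span
  R <- probe@arrayRadius
  xExp <- sin(th) * (R + 20); yExp <- cos(th) * (R + 20) - R
  bm2 <- scanConvert(polar, probe, pixelSpacing = 0.5, depthSpacing = 0.5)
  w <- which(intensities(bm2) == max(intensities(bm2)), arr.ind = TRUE)[1, ]
  x <- imgOrigin(bm2)[1] + (w[2] - 1) * spacing(bm2)[1]
  y <- imgOrigin(bm2)[2] + (w[1] - 1) * spacing(bm2)[2]
  expect_lt(abs(x - xExp), 0.5 + 1e-9)
  expect_lt(abs(y - yExp), 0.5 + 1e-9)
  expect_error(scanConvert(polar, makeProbePreset("endoscopic_linear")),
               class = "eus_parameter_error")
})

test_that("a narrow fan approaches linear column-to-scanline geometry", {
  probe <- makeProbePreset("endoscopic_curvilinear")
  probe@angularSpan <- 2          # nearly straight beams
  polar <- matrix(0, 81, 64)
  polar[31, 48] <- 200                      # depth 15 mm, angle index 48
  ## pixels smaller than one beam's Cartesian footprint at this depth
  bm <- scanConvert(polar, probe, pixelSpacing = 0.05, depthSpacing = 0.5)
  span <- 2 * pi / 180
  th <- ((48 - 0.5) / 64 - 0.5) * span
  xExp <- sin(th) * (probe@arrayRadius + 15)
  w <- which(intensities(bm) == max(intensities(bm)), arr.ind = TRUE)[1, ]
  x <- imgOrigin(bm)[1] + (w[2] - 1) * spacing(bm)[1]
  y <- imgOrigin(bm)[2] + (w[1] - 1) * spacing(bm)[2]
  expect_lt(abs(x - xExp), 0.05 + 1e-9)   # within 1 px of the straight-beam x
  expect_lt(abs(y - 15), 0.5 + 1e-9)
})

test_that("curvilinear simulation localizes a point target in the fan", {
  probe <- makeProbePreset("endoscopic_curvilinear")
  psf <- psfModel()
  plane <- axialPlane()
  f <- pointField(c(0, -40 + 30, 0))
  be <- simulateBMode(f, probe, psf, plane, output = "envelope")
  pk <- which(be$envelope == max(be$envelope), arr.ind = TRUE)[1, ]
  expect_lt(abs(be$depth[pk[1]] - 30), 0.11)
  expect_lt(abs(be$lateral[pk[2]]), 2 * (be$lateral[2] - be$lateral[1]))
})
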