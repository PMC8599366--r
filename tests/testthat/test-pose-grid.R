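test_that("phantom pose grid enumerates target x rotation x offset", {
  ctr <- matrix(c(35, 0, 0), 1, 3, dimnames = list("t1", NULL))
  g1 <- buildPhantomPoseGrid(ctr, nOffsets = 10L, offsetStep = 5,
                             rotations = c(0, 15, -15))
  expect_length(g1, 30L)                         # 10 offsets x 3 rotations
  ctr4 <- rbind(c(35, 0, 0), c(0, 35, 0), c(-35, 0, 0), c(0, -35, 0))
  g4 <- buildPhantomPoseGrid(ctr4, nOffsets = 10L, offsetStep = 5,
                             rotations = c(0, 15, -15))
  expect_length(g4, 120L)
  expect_true(all(g4@perTargetCounts == 30L))
  ## single-pose grid sits exactly at the target centre
  g0 <- buildPhantomPoseGrid(ctr, nOffsets = 1L, rotations = 0)
  expect_length(g0, 1L)
  expect_equal(poses(g0)[[1]]@plane@center, c(35, 0, 0))
  expect_equal(poses(g0)[[1]]@offset, 0)
  expect_error(buildPhantomPoseGrid(ctr, rotations = numeric()),
               class = "eus_parameter_error")
  ## fixed ordering: target, then rotation, then offset
  labs <- vapply(poses(g1), function(p) p@label, "")
  expect_equal(labs[1:3], c("t1_rot+0_off-25", "t1_rot+0_off-20",
                            "t1_rot+0_off-15"))
  expect_equal(poses(g1)[[11]]@rotation, 15)
})

test_that("stored planes reproduce their (offset, rotation) parameters", {
  ctr <- matrix(c(25, 18, 4), 1, 3)
  g <- buildPhantomPoseGrid(ctr, nOffsets = 4L, offsetStep = 5,
                            rotations = c(0, 15, -15))
  for (p in poses(g)) {
    par <- poseParameters(p, ctr[1, ])
    expect_equal(unname(par["offset"]), p@offset, tolerance = 1e-9)
    expect_equal(unname(par["rotation"]), p@rotation, tolerance = 1e-9)
  }
})

test_that("rotating a plane by +theta then -theta returns the reference", {
  v <- eusTracker:::.unit(c(1, 2, 0.5))
  ax <- eusTracker:::.unit(c(0.2, -1, 3))
  back <- eusTracker:::.rotateAbout(eusTracker:::.rotateAbout(v, ax, 15),
                                    ax, -15)
  expect_equal(back, v, tolerance = 1e-12)
})

test_that("MRI pose sets hold exactly 7 planes per injection point", {
  expect_length(buildMriPoseSet(mriPoints(1)), 7L)
  g6 <- buildMriPoseSet(mriPoints(6))
  expect_length(g6, 42L)
  expect_true(all(g6@perTargetCounts == 7L))
  expect_length(buildMriPoseSet(list()), 0L)
  bad <- list(list(center = c(0, 0, 0), rl = c(1, 0, 0), pa = c(1, 0.1, 0),
                   si = c(0, 0, 1)))
  expect_error(buildMriPoseSet(bad), class = "eus_parameter_error")
})

test_that("pose grids round-trip through JSON", {
  g <- buildPhantomPoseGrid(matrix(c(35, 5, -2), 1, 3), nOffsets = 3L,
                            offsetStep = 5, rotations = c(0, 15))
  path <- tempfile(fileext = ".json")
  writePoseGrid(g, path)
  back <- readPoseGrid(path)
  expect_length(back, length(g))
  for (i in seq_along(poses(g))) {
    a <- poses(g)[[i]]; b <- poses(back)[[i]]
    expect_identical(a@label, b@label)
    expect_equal(a@plane@center, b@plane@center, tolerance = 1e-12)
    expect_equal(a@plane@vAxis, b@plane@vAxis, tolerance = 1e-12)
    expect_equal(a@rotation, b@rotation)
  }
})
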