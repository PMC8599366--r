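## Shared fixtures, memoised so expensive builds happen once per test run.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

## Small phantom study for unit tests: light scatterer density, 2 offsets x
## 2 rotations per target (16 poses), 64 px matching resolution.
smallStudy <- function() {
  memoFixture("smallStudy", function() {
    phantomStudy(seed = 7L, density = 0.8, nOffsets = 2L, offsetStep = 5,
                 rotations = c(0, 15), extent = c(80, 80),
                 matchSize = c(64L, 64L))
  })
}

smallBasis <- function() {
  haarBasisSet(scales = 0:2, matchSize = c(64L, 64L))
}

smallDictionary <- function() {
  memoFixture("smallDictionary", function() {
    st <- smallStudy()
    buildDictionary(st$field, st$grid, st$probe, st$psf, smallBasis())
  })
}

## A seeded random GrayImage.
randomImage <- function(nr, nc, seed = 1L, spacing = c(1, 1)) {
  set.seed(seed)
  GrayImage(matrix(runif(nr * nc, 0, 255), nr, nc), pixelSpacing = spacing)
}

## Synthetic B-mode-like image holding bright disks on a dim noisy floor.
diskImage <- function(centersMM, radiusMM = 3, size = c(96L, 96L),
                      spacing = c(0.5, 0.5), seed = 1L) {
  set.seed(seed)
  v <- matrix(pmax(rnorm(prod(size), 30, 8), 0), size[1], size[2])
  x <- (seq_len(size[2]) - 1) * spacing[1]
  y <- (seq_len(size[1]) - 1) * spacing[2]
  for (k in seq_len(nrow(centersMM))) {
    d2 <- outer(
      (y - centersMM[k, 2])^2, (x - centersMM[k, 1])^2, "+")
    v[d2 <= radiusMM^2] <- 220
  }
  new("BModeImage", values = pmin(v, 255), pixelSpacing = spacing,
      origin = c(0, 0), dynamicRange = 60,
      plane = obliqueSliceSpec(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                               extent = size * spacing))
}

## Single point scatterer field.
pointField <- function(p, amplitude = 1) {
  new("ScattererField", positions = matrix(p, 1), amplitudes = amplitude,
      bounds = rbind(p - 1, p + 1))
}

## Centred axial test plane spanned by world x (lateral) and y (depth).
axialPlane <- function(extent = c(80, 80), center = c(0, 0, 0)) {
  obliqueSliceSpec(center, c(1, 0, 0), c(0, 1, 0), extent)
}

## Orthonormal-axis injection points for the MRI pose scheme.
mriPoints <- function(n) {
  lapply(seq_len(n), function(i)
    list(center = c(10 * i, 0, 0), rl = c(1, 0, 0), pa = c(0, 1, 0),
         si = c(0, 0, 1)))
}
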