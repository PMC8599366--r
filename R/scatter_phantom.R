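#' Construct a geometric phantom specification
#'
#' @param box Numeric(3) box edge lengths, mm (centred on the origin).
#' @param spheres data.frame with columns x, y, z, radius, amplitude.
#' @param channelAxis Numeric(3) scan-channel axis direction.
#' @param channelRadius Channel radius, mm.
#' @param backgroundAmplitude Background amplitude factor.
#' @return A \linkS4class{GeometricPhantomSpec}.
#' @export
geometricPhantomSpec <- function(box, spheres, channelAxis = c(0, 0, 1),
                                 channelRadius = 25,
                                 backgroundAmplitude = 1) {
  new("GeometricPhantomSpec", box = as.numeric(box),
      spheres = as.data.frame(spheres), channelAxis = .unit(channelAxis),
      channelRadius = channelRadius,
      backgroundAmplitude = backgroundAmplitude)
}

#' The EUS training-phantom geometry
#'
#' Emulates an endoscopic-ultrasound training phantom: four echogenic
#' spheres of 5-mm radius randomly placed around a central 25-mm-radius scan
#' channel in homogeneous tissue-mimicking background.  Sphere azimuths are
#' drawn with a guaranteed angular separation (so pairwise centre distances
#' exceed 10 mm), radial distances in [32, 38] mm from the channel axis and
#' small axial jitter, all seeded.
#'
#' @param seed Integer seed for the sphere placement.
#' @param sphereAmplitude Echogenicity factor of the spheres relative to
#'   background 1 (default 3, a clearly echogenic target).
#' @return A \linkS4class{GeometricPhantomSpec} with 4 spheres; target ids
#'   \code{target_1..target_4} are the sphere rownames.
#' @export
eusTrainingPhantomSpec <- function(seed = 1L, sphereAmplitude = 3) {
  set.seed(seed)
  az <- (c(0, 90, 180, 270) + stats::runif(4, -25, 25)) * pi / 180
  rad <- stats::runif(4, 32, 38)
  zz <- stats::runif(4, -3, 3)
  spheres <- data.frame(
    x = rad * cos(az), y = rad * sin(az), z = zz,
    radius = 5, amplitude = sphereAmplitude,
    row.names = paste0("target_", 1:4)
  )
  geometricPhantomSpec(box = c(100, 100, 90), spheres = spheres)
}

## Region lookup with priority channel > sphere > background.
.phantomRegionFactor <- function(spec, pts) {
  fac <- rep(spec@backgroundAmplitude, nrow(pts))
  for (i in seq_len(nrow(spec@spheres))) {
    s <- spec@spheres[i, ]
    d2 <- (pts[, 1] - s$x)^2 + (pts[, 2] - s$y)^2 + (pts[, 3] - s$z)^2
    fac[d2 <= s$radius^2] <- s$amplitude
  }
  ax <- spec@channelAxis
  proj <- pts %*% ax
  perp2 <- rowSums(pts^2) - proj^2
  fac[perp2 <= spec@channelRadius^2] <- 0
  fac
}

#' Sample a point-scatterer field from a geometric phantom
#'
#' Scatterer positions are uniform over the phantom box; each amplitude is a
#' standard-normal draw multiplied by the amplitude factor of the region the
#' scatterer falls in (0 inside the scan channel, the sphere factor inside a
#' sphere, the background factor elsewhere; priority channel > sphere >
#' background).  Coherent summation of these scatterers in the simulator
#' produces fully developed speckle.
#'
#' @param spec A \linkS4class{GeometricPhantomSpec}.
#' @param density Scatterers per mm^3 (default 5, a desk-scale density; the
#'   expected count is \code{density * prod(box)}).
#' @param seed Integer seed; fields are bit-reproducible for a fixed seed.
#' @return A \linkS4class{ScattererField}.
#' @export
sampleGeometricScatterers <- function(spec, density = 5, seed = 1L) {
  stopifnot(is(spec, "GeometricPhantomSpec"))
  .assertParam(density > 0, "density must be > 0")
  set.seed(seed)
  n <- max(0L, round(density * prod(spec@box)))
  pts <- cbind(stats::runif(n, -spec@box[1] / 2, spec@box[1] / 2),
               stats::runif(n, -spec@box[2] / 2, spec@box[2] / 2),
               stats::runif(n, -spec@box[3] / 2, spec@box[3] / 2))
  amp <- stats::rnorm(n) * .phantomRegionFactor(spec, pts)
  new("ScattererField", positions = pts, amplitudes = amp,
      bounds = rbind(-spec@box / 2, spec@box / 2))
}

#' Sample scatterers from a slice bitmap
#'
#' Builds a thin-slab scatterer phantom from a 2D image: positions are
#' uniform over the image extent times an elevation slab, and each amplitude
#' is a standard-normal draw multiplied by the bitmap value at the
#' scatterer's in-plane position, linearly rescaled to [0, 1] (so zero
#' intensity contributes nothing and the brightest pixel has factor 1).
#' This is the route from an interpolated CT/MRI slice to a simulated EUS
#' image.
#'
#' @param img A \linkS4class{GrayImage} (the pre-processed slice bitmap).
#' @param n Number of scatterers (> 0).
#' @param seed Integer seed.
#' @param slabThickness Elevation slab thickness, mm (default 5).
#' @param plane Optional \linkS4class{ObliqueSliceSpec}; when supplied, the
#'   scatterers are placed in world coordinates on that plane (elevation
#'   along the plane normal), so the field can be simulated with the same
#'   plane.  Otherwise positions are in the image's own (u, v, elevation)
#'   frame.
#' @return A \linkS4class{ScattererField}.
#' @export
sampleBitmapScatterers <- function(img, n, seed = 1L, slabThickness = 5,
                                   plane = NULL) {
  stopifnot(is(img, "GrayImage"))
  .assertParam(n > 0, "n must be > 0")
  .assertParam(slabThickness > 0, "slabThickness must be > 0")
  d <- dim(img@values)
  .assertParam(all(d >= 1), "img must be non-empty")
  set.seed(seed)
  ext <- d * img@pixelSpacing[c(2, 1)]            # (v, u) extents
  u0 <- img@origin[1] - img@pixelSpacing[1] / 2
  v0 <- img@origin[2] - img@pixelSpacing[2] / 2
  u <- stats::runif(n, u0, u0 + ext[2])
  v <- stats::runif(n, v0, v0 + ext[1])
  e <- stats::runif(n, -slabThickness / 2, slabThickness / 2)
  ci <- pmin(pmax(ceiling((u - u0) / img@pixelSpacing[1]), 1L), d[2])
  ri <- pmin(pmax(ceiling((v - v0) / img@pixelSpacing[2]), 1L), d[1])
  mx <- max(img@values)
  fac <- if (mx > 0) img@values[cbind(ri, ci)] / mx else numeric(n)
  amp <- stats::rnorm(n) * fac
  if (is.null(plane)) {
    pos <- cbind(u, v, e)
    bounds <- rbind(c(u0, v0, -slabThickness / 2),
                    c(u0 + ext[2], v0 + ext[1], slabThickness / 2))
  } else {
    stopifnot(is(plane, "ObliqueSliceSpec"))
    nrm <- .unit(c(
      plane@uAxis[2] * plane@vAxis[3] - plane@uAxis[3] * plane@vAxis[2],
      plane@uAxis[3] * plane@vAxis[1] - plane@uAxis[1] * plane@vAxis[3],
      plane@uAxis[1] * plane@vAxis[2] - plane@uAxis[2] * plane@vAxis[1]))
    ## image (u, v) frame is centred on the plane centre
    pos <- outer(u, plane@uAxis) + outer(v, plane@vAxis) + outer(e, nrm) +
      matrix(plane@center, n, 3L, byrow = TRUE)
    bounds <- rbind(apply(pos, 2L, min), apply(pos, 2L, max))
  }
  new("ScattererField", positions = pos, amplitudes = amp, bounds = bounds)
}

#' Generate a synthetic study volume with structure masks
#'
#' Fixture generator standing in for real CT/MRI data.
#' \code{"eus_training_phantom"} voxelizes \code{\link{eusTrainingPhantomSpec}}
#' at 1-mm spacing: homogeneous background (100) with mild seeded texture,
#' four high-intensity (200) spheres, and the near-zero scan channel;
#' returned masks cover each sphere and the channel.
#' \code{"abdomen_like"} builds a smooth abdominal-appearance slab with one
#' low-intensity "tumor" ellipsoid, a small bright "marker" dot inside it,
#' and \code{nHydrogel} bright "hydrogel" blobs; masks are returned for each
#' structure.
#'
#' @param kind "eus_training_phantom" or "abdomen_like".
#' @param seed Integer seed; identical seeds give identical volumes.
#' @param nHydrogel Number of hydrogel blobs (abdomen_like only).
#' @return A list with elements \code{volume} (\linkS4class{Volume3D}),
#'   \code{masks} (list of \linkS4class{StructureMask}) and, for the
#'   training phantom, \code{spec} (the generating
#'   \linkS4class{GeometricPhantomSpec}).
#' @export
generateToyVolume <- function(kind = c("eus_training_phantom", "abdomen_like"),
                              seed = 1L, nHydrogel = 3L) {
  kind <- match.arg(kind)
  if (kind == "eus_training_phantom") .toyPhantomVolume(seed)
  else .toyAbdomenVolume(seed, nHydrogel)
}

.smoothNoise1d <- function(n, k = 9L) {
  x <- stats::rnorm(n + 2L * k)
  stats::filter(x, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)[(k + 1):(k + n)]
}

.toyPhantomVolume <- function(seed) {
  spec <- eusTrainingPhantomSpec(seed)
  sp <- c(1, 1, 1)
  d <- as.integer(spec@box / sp)
  origin <- -spec@box / 2 + sp / 2
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(d[k]) - 1) * sp[k])
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  fac <- .phantomRegionFactor(spec, pts)
  set.seed(seed + 1000L)
  tex <- stats::rnorm(length(fac), 0, 3)
  vals <- ifelse(fac == 0, 2, 100 + (fac - 1) * 50) + tex
  vals <- pmax(vals, 0)
  vol <- Volume3D(array(vals, d), spacing = sp, origin = origin)
  masks <- lapply(rownames(spec@spheres), function(id) {
    s <- spec@spheres[id, ]
    inside <- (pts[, 1] - s$x)^2 + (pts[, 2] - s$y)^2 + (pts[, 3] - s$z)^2 <=
      s$radius^2
    structureMask(id, array(inside, d))
  })
  proj <- pts %*% spec@channelAxis
  chan <- rowSums(pts^2) - proj^2 <= spec@channelRadius^2
  masks <- c(masks, list(structureMask("channel", array(chan, d))))
  list(volume = vol, masks = masks, spec = spec)
}

.toyAbdomenVolume <- function(seed, nHydrogel) {
  set.seed(seed)
  d <- c(96L, 96L, 40L)
  sp <- c(1.25, 1.25, 1.5)
  origin <- -(d - 1L) * sp / 2
  ax <- lapply(1:3, function(k) origin[k] + (seq_len(d[k]) - 1) * sp[k])
  bg <- 120 +
    20 * outer(outer(.smoothNoise1d(d[1]) * 3, .smoothNoise1d(d[2]) * 3),
               rep(1, d[3])) +
    array(stats::rnorm(prod(d), 0, 4), d)
  pts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  ## tumor: low-intensity ellipsoid off-centre
  tc <- c(stats::runif(2, -12, 12), stats::runif(1, -6, 6))
  tr <- c(stats::runif(2, 12, 18), stats::runif(1, 8, 12))
  tum <- ((pts[, 1] - tc[1]) / tr[1])^2 + ((pts[, 2] - tc[2]) / tr[2])^2 +
    ((pts[, 3] - tc[3]) / tr[3])^2 <= 1
  bg[tum] <- bg[tum] * 0.25
  ## fiducial marker: bright 1.5-mm dot inside the tumor
  mc <- tc + c(stats::runif(2, -4, 4), 0)
  mrk <- (pts[, 1] - mc[1])^2 + (pts[, 2] - mc[2])^2 +
    (pts[, 3] - mc[3])^2 <= 1.5^2
  bg[mrk] <- 400
  masks <- list(structureMask("tumor", array(tum, d)),
                structureMask("marker", array(mrk, d)))
  ## hydrogel blobs: bright spheres near the tumor boundary
  if (nHydrogel > 0) {
    for (i in seq_len(nHydrogel)) {
      th <- stats::runif(1, 0, 2 * pi)
      hc <- tc + c((tr[1] + 5) * cos(th), (tr[2] + 5) * sin(th),
                   stats::runif(1, -4, 4))
      hr <- stats::runif(1, 3, 5)
      hyd <- (pts[, 1] - hc[1])^2 + (pts[, 2] - hc[2])^2 +
        (pts[, 3] - hc[3])^2 <= hr^2
      bg[hyd] <- 320
      masks <- c(masks, list(structureMask(paste0("hydrogel_", i),
                                           array(hyd, d))))
    }
  }
  bg <- pmax(bg, 0)
  list(volume = Volume3D(array(bg, d), spacing = sp, origin = origin),
       masks = masks)
}

## ---- serialization --------------------------------------------------------

#' Write / read a scatterer field as columnar CSV
#'
#' Columns x, y, z, amplitude (mm, unitless).
#'
#' @param field A \linkS4class{ScattererField}.
#' @param path Output path.
#' @return \code{path} (write) or the \linkS4class{ScattererField} (read).
#' @export
writeScattererField <- function(field, path) {
  stopifnot(is(field, "ScattererField"))
  df <- data.frame(x = field@positions[, 1], y = field@positions[, 2],
                   z = field@positions[, 3], amplitude = field@amplitudes)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScattererField
#' @export
readScattererField <- function(path) {
  if (!file.exists(path)) .eusStop("eus_input_error", "no such file: %s", path)
  df <- utils::read.csv(path)
  pos <- as.matrix(df[, c("x", "y", "z")])
  dimnames(pos) <- NULL
  bounds <- if (nrow(pos)) rbind(apply(pos, 2, min), apply(pos, 2, max))
            else rbind(rep(0, 3), rep(0, 3))
  new("ScattererField", positions = pos, amplitudes = df$amplitude,
      bounds = bounds)
}
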