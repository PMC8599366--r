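#' Endoscopic probe presets
#'
#' \code{"endoscopic_linear"}: the linear endoscopic array used for phantom
#' imaging -- 128 elements, 7.5 MHz centre frequency, element width 0.29 mm
#' and height 0.41 mm.  \code{"endoscopic_curvilinear"}: the curvilinear
#' array used for patient imaging -- 159 elements on a 91.1 mm radius, 128
#' scanlines.  Quantities the hardware leaves open (speed of sound, pitch,
#' bandwidth, fan span) carry documented defaults.
#'
#' @param name Preset name.
#' @return A \linkS4class{ProbeSpec}.
#' @examples
#' makeProbePreset("endoscopic_linear")
#' @export
makeProbePreset <- function(name = c("endoscopic_linear",
                                     "endoscopic_curvilinear")) {
  if (length(name) == 1L && !name %in% c("endoscopic_linear",
                                         "endoscopic_curvilinear"))
    .eusStop("eus_parameter_error", "unknown probe preset '%s'", name)
  name <- match.arg(name)
  if (name == "endoscopic_linear")
    new("ProbeSpec", geometry = "linear", nElements = 128L,
        centerFrequency = 7.5e6, elementWidth = 0.29, elementHeight = 0.41,
        pitch = 0.30, arrayRadius = NA_real_, angularSpan = NA_real_,
        nScanlines = 128L, speedOfSound = 1.54e6, fractionalBandwidth = 0.6)
  else
    new("ProbeSpec", geometry = "curvilinear", nElements = 159L,
        centerFrequency = 7.5e6, elementWidth = 0.5, elementHeight = 0.5,
        pitch = NA_real_, arrayRadius = 91.1, angularSpan = 60,
        nScanlines = 128L, speedOfSound = 1.54e6, fractionalBandwidth = 0.6)
}

#' Construct a separable PSF model
#'
#' @param lateralSigmaRange Clip range (mm) for the depth-dependent lateral
#'   beam sigma \code{depth * wavelength / aperture}.
#' @param elevationSlab Elevation slab thickness, mm.
#' @param rfOversample RF sampling rate as a multiple of the centre
#'   frequency (axial sample spacing = wavelength / rfOversample).
#' @return A \linkS4class{PSFModel}.
#' @export
psfModel <- function(lateralSigmaRange = c(0.3, 2.0), elevationSlab = 5,
                     rfOversample = 4) {
  new("PSFModel", lateralSigmaRange = as.numeric(lateralSigmaRange),
      elevationSlab = elevationSlab, rfOversample = rfOversample)
}

.wavelength <- function(probe) probe@speedOfSound / probe@centerFrequency

.aperture <- function(probe) {
  if (probe@geometry == "linear") probe@nElements * probe@pitch
  else probe@arrayRadius * probe@angularSpan * pi / 180
}

## Gaussian-modulated sinusoid pulse sampled at dz; -6 dB fractional
## bandwidth sets the Gaussian envelope width.
.axialPulse <- function(probe, dz) {
  lam <- .wavelength(probe)
  sigZ <- 2.3548 * lam / (2 * pi * probe@fractionalBandwidth)
  half <- ceiling(4 * sigZ / dz)
  z <- (-half:half) * dz
  exp(-z^2 / (2 * sigZ^2)) * cos(2 * pi * z / lam)
}

.lateralSigma <- function(depth, probe, psf) {
  s <- depth * .wavelength(probe) / .aperture(probe)
  pmin(pmax(s, psf@lateralSigmaRange[1]), psf@lateralSigmaRange[2])
}

.planeNormal <- function(plane) {
  .unit(c(plane@uAxis[2] * plane@vAxis[3] - plane@uAxis[3] * plane@vAxis[2],
          plane@uAxis[3] * plane@vAxis[1] - plane@uAxis[1] * plane@vAxis[3],
          plane@uAxis[1] * plane@vAxis[2] - plane@uAxis[2] * plane@vAxis[1]))
}

## AABB overlap test between the plane rectangle (thickened by the slab)
## and the field bounds.
.planeIntersectsBounds <- function(plane, bounds, slab) {
  eu <- plane@extent[1] / 2; ev <- plane@extent[2] / 2
  corners <- rbind(c(-eu, -ev), c(eu, -ev), c(-eu, ev), c(eu, ev))
  pts <- corners[, 1] %o% plane@uAxis + corners[, 2] %o% plane@vAxis +
    matrix(plane@center, 4L, 3L, byrow = TRUE)
  n <- .planeNormal(plane)
  lo <- apply(rbind(pts + matrix(n * slab / 2, 4, 3, byrow = TRUE),
                    pts - matrix(n * slab / 2, 4, 3, byrow = TRUE)), 2, min)
  hi <- apply(rbind(pts + matrix(n * slab / 2, 4, 3, byrow = TRUE),
                    pts - matrix(n * slab / 2, 4, 3, byrow = TRUE)), 2, max)
  all(lo <= bounds[2, ] + 1e-9) && all(hi >= bounds[1, ] - 1e-9)
}

## Beam-space envelope formation shared by both geometries. Returns the
## envelope matrix (depth sample x scanline), depth coordinates (mm from the
## probe face) and scanline coordinates (mm lateral for linear, radians for
## curvilinear).
.beamEnvelope <- function(field, probe, psf, plane) {
  lam <- .wavelength(probe)
  dz <- lam / psf@rfOversample
  maxD <- plane@extent[2]
  nSamp <- ceiling(maxD / dz) + 1L
  nl <- probe@nScanlines
  pulse <- .axialPulse(probe, dz)
  guard <- (length(pulse) %/% 2) * dz
  pos <- field@positions
  D <- matrix(0, nSamp, nl)
  if (probe@geometry == "linear") {
    lat <- ((seq_len(nl) - 0.5) / nl - 0.5) * plane@extent[1]
  } else {
    span <- probe@angularSpan * pi / 180
    lat <- ((seq_len(nl) - 0.5) / nl - 0.5) * span
  }
  if (nrow(pos) > 0) {
    rel <- sweep(pos, 2L, plane@center, "-")
    x <- drop(rel %*% plane@uAxis)
    y <- drop(rel %*% plane@vAxis) + plane@extent[2] / 2   # depth from face
    e <- drop(rel %*% .planeNormal(plane))
    keep <- abs(e) <= psf@elevationSlab / 2
    if (probe@geometry == "curvilinear") {
      R <- probe@arrayRadius
      th <- atan2(x, y + R)
      rr <- sqrt(x^2 + (y + R)^2) - R
      keep <- keep & rr >= -guard & rr <= maxD + guard
      beamPos <- th; depth <- rr
    } else {
      keep <- keep & y >= -guard & y <= maxD + guard
      beamPos <- x; depth <- y
    }
    if (any(keep)) {
      beamPos <- beamPos[keep]; depth <- depth[keep]
      sigE <- psf@elevationSlab / 4
      w0 <- field@amplitudes[keep] * exp(-e[keep]^2 / (2 * sigE^2))
      sig <- .lateralSigma(pmax(depth, 0), probe, psf)
      bins <- as.integer(round(depth / dz)) + 1L
      ord <- order(beamPos)
      bp <- beamPos[ord]; w0 <- w0[ord]; sig <- sig[ord]
      bins <- bins[ord]; depth <- depth[ord]
      if (probe@geometry == "curvilinear") {
        arm <- probe@arrayRadius + pmax(depth, 0)
        sigBeam <- sig / arm          # lateral sigma expressed in radians
      } else {
        sigBeam <- sig
      }
      win <- 3 * max(sigBeam)
      lo <- findInterval(lat - win, bp) + 1L
      hi <- findInterval(lat + win, bp)
      for (l in seq_len(nl)) {
        if (hi[l] < lo[l]) next
        idx <- lo[l]:hi[l]
        w <- w0[idx] * exp(-(bp[idx] - lat[l])^2 / (2 * sigBeam[idx]^2))
        D[, l] <- D[, l] + .binSum(bins[idx], w, nSamp)
      }
    }
  }
  rf <- .convColumnsSame(D, pulse)
  env <- .envelopeColumns(rf)
  list(envelope = env, depth = (seq_len(nSamp) - 1L) * dz, lateral = lat,
       geometry = probe@geometry, dz = dz)
}

#' Simulate a B-mode EUS image of a scatterer field
#'
#' Convolution-model B-mode simulation: scatterers within the elevation slab
#' are projected into the imaging plane with Gaussian elevation weighting;
#' per scanline an RF line is formed by summing scatterer amplitudes
#' (laterally weighted by a depth-dependent Gaussian beam profile about the
#' scanline) convolved with a Gaussian-modulated sinusoid axial pulse; the
#' envelope is the magnitude of the analytic signal; envelopes are
#' normalized to the image maximum, log-compressed over
#' \code{dynamicRange} dB and mapped to [0, 255].  Curvilinear geometries
#' are scan-converted from (beam angle, depth) to Cartesian.  The output is
#' therefore invariant under global scatterer-amplitude scaling, and an
#' empty field yields a uniform minimum-intensity image.
#'
#' @param field A \linkS4class{ScattererField}.
#' @param probe A \linkS4class{ProbeSpec}.
#' @param psf A \linkS4class{PSFModel}.
#' @param plane The imaging plane (\linkS4class{ObliqueSliceSpec}); the
#'   probe face lies along the plane's top edge (v = -extent/2) with beams
#'   along +v.
#' @param imageSize Integer(2) output size (rows, cols).
#' @param dynamicRange Display dynamic range, dB.
#' @param output "image" for the \linkS4class{BModeImage}, "envelope" for
#'   the beam-space envelope (a list with the envelope matrix, depth in mm
#'   from the probe face, and scanline coordinates), used for
#'   point-spread-function verification.
#' @return A \linkS4class{BModeImage}, or the envelope list.
#' @export
simulateBMode <- function(field, probe, psf, plane,
                          imageSize = c(128L, 128L), dynamicRange = 60,
                          output = c("image", "envelope")) {
  stopifnot(is(field, "ScattererField"), is(probe, "ProbeSpec"),
            is(psf, "PSFModel"), is(plane, "ObliqueSliceSpec"))
  output <- match.arg(output)
  .assertParam(dynamicRange > 0, "dynamicRange must be > 0")
  if (nrow(field@positions) > 0 &&
      !.planeIntersectsBounds(plane, field@bounds, psf@elevationSlab))
    .eusStop("eus_input_error", "imaging plane does not intersect the field bounds")
  be <- .beamEnvelope(field, probe, psf, plane)
  if (output == "envelope") return(be)
  .envelopeToImage(be, probe, plane, imageSize, dynamicRange)
}

.logCompress <- function(env, dynamicRange) {
  mx <- max(env)
  if (mx <= 0) return(array(0, dim(env)))
  db <- 20 * log10(env / mx)
  pmax(pmin(255 * (db + dynamicRange) / dynamicRange, 255), 0)
}

.envelopeToImage <- function(be, probe, plane, imageSize, dynamicRange) {
  imageSize <- as.integer(imageSize)
  disp <- .logCompress(be$envelope, dynamicRange)
  px <- plane@extent / imageSize[c(2, 1)]
  xs <- (seq_len(imageSize[2]) - 0.5) * px[1] - plane@extent[1] / 2
  ys <- (seq_len(imageSize[1]) - 0.5) * px[2]
  X <- matrix(xs, imageSize[1], imageSize[2], byrow = TRUE)
  Y <- matrix(ys, imageSize[1], imageSize[2])
  if (probe@geometry == "linear") {
    ri <- Y / be$dz + 1
    dlat <- be$lateral[2] - be$lateral[1]
    ci <- (X - be$lateral[1]) / dlat + 1
  } else {
    R <- probe@arrayRadius
    th <- atan2(X, Y + R)
    rr <- sqrt(X^2 + (Y + R)^2) - R
    ri <- rr / be$dz + 1
    dlat <- be$lateral[2] - be$lateral[1]
    ci <- (th - be$lateral[1]) / dlat + 1
  }
  vals <- matrix(.interpMatrix(disp, as.vector(ri), as.vector(ci)),
                 imageSize[1], imageSize[2])
  new("BModeImage", values = vals, pixelSpacing = px,
      origin = c(xs[1], ys[1]), dynamicRange = dynamicRange, plane = plane)
}

#' Scan-convert a fan of scanlines to Cartesian
#'
#' Resamples a polar image (rows = depth from the array face along each
#' beam, columns = beam angle uniformly spanning the probe's angular span)
#' to a Cartesian grid by bilinear interpolation.  The fan apex sits
#' \code{arrayRadius} behind the array face on the central axis; pixels
#' outside the fan are 0.
#'
#' @param polar Numeric matrix over (depth, angle).
#' @param probe A curvilinear \linkS4class{ProbeSpec}.
#' @param pixelSpacing Output pixel size, mm (scalar or length 2).
#' @param depthSpacing Depth sample spacing of \code{polar}, mm.
#' @return A \linkS4class{BModeImage} covering the fan.
#' @export
scanConvert <- function(polar, probe, pixelSpacing = 0.5, depthSpacing = 0.5) {
  stopifnot(is.matrix(polar), is(probe, "ProbeSpec"))
  if (probe@geometry != "curvilinear")
    .eusStop("eus_parameter_error", "scanConvert requires a curvilinear probe")
  .assertParam(all(pixelSpacing > 0) && depthSpacing > 0,
               "spacings must be > 0")
  if (length(pixelSpacing) == 1L) pixelSpacing <- rep(pixelSpacing, 2L)
  span <- probe@angularSpan * pi / 180
  R <- probe@arrayRadius
  maxD <- (nrow(polar) - 1L) * depthSpacing
  halfW <- (R + maxD) * sin(span / 2)
  nx <- max(2L, ceiling(2 * halfW / pixelSpacing[1]))
  ny <- max(2L, ceiling(maxD / pixelSpacing[2]))
  xs <- (seq_len(nx) - 0.5) * pixelSpacing[1] - halfW
  ys <- (seq_len(ny) - 0.5) * pixelSpacing[2]
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  th <- atan2(X, Y + R)
  rr <- sqrt(X^2 + (Y + R)^2) - R
  nAng <- ncol(polar)
  dth <- span / nAng
  th0 <- -span / 2 + dth / 2
  ri <- rr / depthSpacing + 1
  ci <- (th - th0) / dth + 1
  vals <- matrix(.interpMatrix(polar, as.vector(ri), as.vector(ci)), ny, nx)
  vals[abs(th) > span / 2 | rr < 0 | rr > maxD] <- 0
  vals <- pmax(pmin(vals, 255), 0)
  plane <- obliqueSliceSpec(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
                            extent = c(2 * halfW, maxD),
                            pixelSpacing = pixelSpacing)
  new("BModeImage", values = vals, pixelSpacing = pixelSpacing,
      origin = c(xs[1], ys[1]), dynamicRange = 60, plane = plane)
}
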