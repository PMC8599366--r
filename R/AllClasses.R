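#' @import methods
NULL

## ---- errors ---------------------------------------------------------------

## Structured conditions so callers (and the command-line driver) can map
## failure modes to exit codes.  Classes:
##   eus_input_error     - unreadable / missing user input
##   eus_format_error    - input parsed but violates the format contract
##   eus_parameter_error - invalid argument value
##   eus_contract_error  - objects not comparable (e.g. fingerprint mismatch)
##   eus_match_error     - matching could not produce a result
##   eus_detection_error - marker detection failed
.eusStop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "eus_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

.assertParam <- function(ok, fmt, ...) {
  if (!isTRUE(ok)) .eusStop("eus_parameter_error", fmt, ...)
  invisible(TRUE)
}

## ---- io_volumes types -----------------------------------------------------

#' Volume3D: an axis-aligned 3D scalar grid with millimetre geometry
#'
#' The in-memory stand-in for a diagnostic CT or MRI volume.  Voxel
#' \code{[i, j, k]} (1-based) has its centre at
#' \code{origin + (c(i, j, k) - 1) * spacing} in a right-handed millimetre
#' world frame with x = left to right, y = posterior to anterior and
#' z = inferior to superior.
#'
#' @slot values 3D numeric array of intensities (arbitrary units).
#' @slot spacing Numeric(3), voxel spacing in mm per axis; all > 0.
#' @slot origin Numeric(3), world position (mm) of the first voxel centre.
#' @exportClass Volume3D
setClass("Volume3D", representation(
  values = "array", spacing = "numeric", origin = "numeric"
))

setValidity("Volume3D", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3D array")
  if (any(d < 2L)) return("grid needs >= 2 samples per axis")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  if (any(!is.finite(object@values))) return("all values must be finite")
  TRUE
})

#' ObliqueSliceSpec: an arbitrarily oriented image plane through a volume
#'
#' Defines the interpolated CT/MRI plane paired with each probe pose.  The
#' plane is spanned by the orthonormal in-plane axes \code{uAxis} (image
#' columns, lateral) and \code{vAxis} (image rows, axial/depth), centred at
#' \code{center}.  Pixel \code{(r, c)} of the extracted image is sampled at
#' \code{center + ((c - 0.5) * pixelSpacing[1] - extent[1]/2) * uAxis +
#' ((r - 0.5) * pixelSpacing[2] - extent[2]/2) * vAxis}.
#'
#' @slot center Numeric(3) plane centre, mm.
#' @slot uAxis,vAxis Numeric(3) orthonormal unit vectors spanning the plane.
#' @slot extent Numeric(2) physical size (u, v) in mm.
#' @slot pixelSpacing Numeric(2) sample spacing (u, v) in mm.
#' @exportClass ObliqueSliceSpec
setClass("ObliqueSliceSpec", representation(
  center = "numeric", uAxis = "numeric", vAxis = "numeric",
  extent = "numeric", pixelSpacing = "numeric"
))

setValidity("ObliqueSliceSpec", function(object) {
  for (s in c("center", "uAxis", "vAxis"))
    if (length(slot(object, s)) != 3L || any(!is.finite(slot(object, s))))
      return(sprintf("%s must be 3 finite values", s))
  if (abs(sqrt(sum(object@uAxis^2)) - 1) > 1e-9) return("|uAxis| must be 1")
  if (abs(sqrt(sum(object@vAxis^2)) - 1) > 1e-9) return("|vAxis| must be 1")
  if (abs(sum(object@uAxis * object@vAxis)) > 1e-9)
    return("uAxis and vAxis must be orthogonal")
  if (length(object@extent) != 2L || any(object@extent <= 0))
    return("extent must be 2 positive values")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be 2 positive values")
  TRUE
})

#' GrayImage: a 2D scalar image with millimetre pixel geometry
#'
#' Rows run along the plane's v axis (axial/depth), columns along u
#' (lateral).  Pixel \code{(r, c)} has plane-frame position
#' \code{(origin[1] + (c - 1) * pixelSpacing[1],
#'        origin[2] + (r - 1) * pixelSpacing[2])}, i.e. origin is the (u, v)
#' position of the first pixel centre.
#'
#' @slot values Numeric matrix of intensities.
#' @slot pixelSpacing Numeric(2), mm per pixel as (u/column, v/row).
#' @slot origin Numeric(2), plane-frame (u, v) of pixel (1, 1), mm.
#' @exportClass GrayImage
setClass("GrayImage", representation(
  values = "matrix", pixelSpacing = "numeric", origin = "numeric"
))

setValidity("GrayImage", function(object) {
  if (any(!is.finite(object@values))) return("values must be finite")
  if (length(object@pixelSpacing) != 2L || any(object@pixelSpacing <= 0))
    return("pixelSpacing must be 2 positive values")
  if (length(object@origin) != 2L || any(!is.finite(object@origin)))
    return("origin must be 2 finite values")
  TRUE
})

#' StructureMask: a named boolean mask congruent with its parent grid
#'
#' Holds contoured structures (tumor, hydrogel, marker, sphere target) as a
#' logical array whose shape equals the parent \linkS4class{Volume3D} or
#' \linkS4class{GrayImage} grid.
#'
#' @slot name Single label string.
#' @slot values Logical array (2D or 3D).
#' @exportClass StructureMask
setClass("StructureMask", representation(name = "character", values = "array"))

setValidity("StructureMask", function(object) {
  if (length(object@name) != 1L || is.na(object@name)) return("name must be a single string")
  if (!is.logical(object@values)) return("values must be logical")
  if (anyNA(object@values)) return("mask values must not be NA")
  TRUE
})

## ---- scatter_phantom types ------------------------------------------------

#' GeometricPhantomSpec: geometry of the EUS training phantom
#'
#' Describes a box of tissue-mimicking background containing echogenic
#' spheres and a cylindrical scan channel (an anechoic void holding the
#' probe).  The box is centred on the world origin; the channel runs through
#' the origin along \code{channelAxis}.  Region priority when assigning
#' scatterer amplitude factors is channel > sphere > background.
#'
#' @slot box Numeric(3) box edge lengths, mm (box spans +/- box/2).
#' @slot spheres data.frame with columns x, y, z (centre, mm), radius (mm)
#'   and amplitude (echogenicity factor relative to background 1).
#' @slot channelAxis Numeric(3) unit vector of the scan-channel axis.
#' @slot channelRadius Channel radius, mm.
#' @slot backgroundAmplitude Background amplitude factor (>= 0).
#' @exportClass GeometricPhantomSpec
setClass("GeometricPhantomSpec", representation(
  box = "numeric", spheres = "data.frame", channelAxis = "numeric",
  channelRadius = "numeric", backgroundAmplitude = "numeric"
))

setValidity("GeometricPhantomSpec", function(object) {
  if (length(object@box) != 3L || any(object@box <= 0))
    return("box must be 3 positive extents")
  need <- c("x", "y", "z", "radius", "amplitude")
  if (!all(need %in% names(object@spheres)))
    return("spheres needs columns x, y, z, radius, amplitude")
  if (nrow(object@spheres) > 0) {
    if (any(object@spheres$radius <= 0)) return("sphere radii must be > 0")
    if (any(object@spheres$amplitude < 0)) return("amplitude factors must be >= 0")
    ctr <- as.matrix(object@spheres[, c("x", "y", "z")])
    half <- matrix(object@box / 2, nrow(ctr), 3, byrow = TRUE)
    if (any(abs(ctr) + object@spheres$radius > half + 1e-9))
      return("spheres must lie inside the box")
  }
  if (abs(sqrt(sum(object@channelAxis^2)) - 1) > 1e-9)
    return("channelAxis must be a unit vector")
  if (object@channelRadius <= 0) return("channelRadius must be > 0")
  if (object@backgroundAmplitude < 0) return("backgroundAmplitude must be >= 0")
  TRUE
})

#' ScattererField: point scatterers feeding the B-mode simulator
#'
#' @slot positions N x 3 numeric matrix of scatterer positions, mm.
#' @slot amplitudes Numeric(N) unitless scattering amplitudes.
#' @slot bounds 2 x 3 matrix (rows min, max) of the bounding box, mm.
#' @exportClass ScattererField
setClass("ScattererField", representation(
  positions = "matrix", amplitudes = "numeric", bounds = "matrix"
))

setValidity("ScattererField", function(object) {
  if (ncol(object@positions) != 3L) return("positions must be N x 3")
  if (nrow(object@positions) != length(object@amplitudes))
    return("positions and amplitudes disagree in length")
  if (any(!is.finite(object@amplitudes))) return("amplitudes must be finite")
  if (!all(dim(object@bounds) == c(2L, 3L))) return("bounds must be 2 x 3")
  if (nrow(object@positions) > 0) {
    lo <- matrix(object@bounds[1, ], nrow(object@positions), 3, byrow = TRUE)
    hi <- matrix(object@bounds[2, ], nrow(object@positions), 3, byrow = TRUE)
    if (any(object@positions < lo - 1e-9) || any(object@positions > hi + 1e-9))
      return("all positions must lie within bounds")
  }
  TRUE
})

## ---- us_simulator types ---------------------------------------------------

#' ProbeSpec: transducer geometry and pulse parameters
#'
#' @slot geometry "linear" or "curvilinear".
#' @slot nElements Element count (>= 2).
#' @slot centerFrequency Hz.
#' @slot elementWidth,elementHeight mm.
#' @slot pitch Element pitch, mm (linear arrays).
#' @slot arrayRadius Array radius, mm (curvilinear arrays).
#' @slot angularSpan Fan opening angle, degrees (curvilinear arrays).
#' @slot nScanlines Beam count per frame (>= 2).
#' @slot speedOfSound mm/s.
#' @slot fractionalBandwidth Pulse -6 dB fractional bandwidth, in (0, 2].
#' @exportClass ProbeSpec
setClass("ProbeSpec", representation(
  geometry = "character", nElements = "integer", centerFrequency = "numeric",
  elementWidth = "numeric", elementHeight = "numeric", pitch = "numeric",
  arrayRadius = "numeric", angularSpan = "numeric", nScanlines = "integer",
  speedOfSound = "numeric", fractionalBandwidth = "numeric"
))

setValidity("ProbeSpec", function(object) {
  if (!object@geometry %in% c("linear", "curvilinear"))
    return("geometry must be 'linear' or 'curvilinear'")
  if (object@centerFrequency <= 0) return("centerFrequency must be > 0")
  if (object@nElements < 2L) return("nElements must be >= 2")
  if (object@nScanlines < 2L) return("nScanlines must be >= 2")
  if (object@fractionalBandwidth <= 0 || object@fractionalBandwidth > 2)
    return("fractionalBandwidth must be in (0, 2]")
  if (object@speedOfSound <= 0) return("speedOfSound must be > 0")
  if (object@geometry == "curvilinear" &&
      (object@arrayRadius <= 0 || object@angularSpan <= 0))
    return("curvilinear arrays need positive arrayRadius and angularSpan")
  TRUE
})

#' PSFModel: separable point-spread-function model for B-mode simulation
#'
#' Axially the pulse is a Gaussian-modulated sinusoid at the probe's centre
#' frequency with the probe's fractional bandwidth; laterally and in
#' elevation the beam is Gaussian.  The lateral sigma grows linearly with
#' depth as \code{depth * wavelength / aperture}, clipped to
#' \code{lateralSigmaRange}.
#'
#' @slot lateralSigmaRange Numeric(2) clip range for the lateral sigma, mm.
#' @slot elevationSlab Full elevation slab thickness, mm; scatterers beyond
#'   +/- elevationSlab/2 from the plane are ignored, closer ones weighted by
#'   a Gaussian with sigma = elevationSlab/4.
#' @slot rfOversample RF sampling frequency as a multiple of the centre
#'   frequency.
#' @exportClass PSFModel
setClass("PSFModel", representation(
  lateralSigmaRange = "numeric", elevationSlab = "numeric",
  rfOversample = "numeric"
))

setValidity("PSFModel", function(object) {
  if (length(object@lateralSigmaRange) != 2L ||
      any(object@lateralSigmaRange <= 0) ||
      diff(object@lateralSigmaRange) < 0)
    return("lateralSigmaRange must be increasing and positive")
  if (object@elevationSlab <= 0) return("elevationSlab must be > 0")
  if (object@rfOversample < 2) return("rfOversample must be >= 2")
  TRUE
})

#' BModeImage: a simulated (or loaded) B-mode ultrasound image
#'
#' Extends \linkS4class{GrayImage}: values are log-compressed envelope
#' amplitudes mapped to [0, 255] over \code{dynamicRange} dB.  Row
#' coordinate (origin/pixelSpacing v component) is depth from the probe
#' face; column coordinate is lateral position about the beam axis.
#'
#' @slot dynamicRange Display dynamic range, dB.
#' @slot plane The \linkS4class{ObliqueSliceSpec} the image depicts.
#' @exportClass BModeImage
setClass("BModeImage", contains = "GrayImage", representation(
  dynamicRange = "numeric", plane = "ObliqueSliceSpec"
))

setValidity("BModeImage", function(object) {
  if (object@dynamicRange <= 0) return("dynamicRange must be > 0")
  v <- object@values
  if (length(v) && (min(v) < -1e-9 || max(v) > 255 + 1e-9))
    return("values must lie in [0, 255]")
  TRUE
})

## ---- pose_grid types ------------------------------------------------------

#' ProbePose: one candidate probe pose and its imaging plane
#'
#' @slot label Unique pose label.
#' @slot targetId Identifier of the target (sphere or injection point) the
#'   pose belongs to.
#' @slot plane The imaging plane as an \linkS4class{ObliqueSliceSpec}.
#' @slot offset Plane-centre shift along the target axis, mm.
#' @slot rotation Rotation about \code{rotationAxis}, degrees in [-180, 180].
#' @slot rotationAxis Numeric(3) unit rotation axis.
#' @exportClass ProbePose
setClass("ProbePose", representation(
  label = "character", targetId = "character", plane = "ObliqueSliceSpec",
  offset = "numeric", rotation = "numeric", rotationAxis = "numeric"
))

setValidity("ProbePose", function(object) {
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  if (abs(object@rotation) > 180) return("rotation must be in [-180, 180]")
  if (abs(sqrt(sum(object@rotationAxis^2)) - 1) > 1e-9)
    return("rotationAxis must be a unit vector")
  TRUE
})

#' PoseGrid: an ordered set of candidate probe poses
#'
#' @slot poses List of \linkS4class{ProbePose}, order fixed (dictionary
#'   indices refer to this order).
#' @slot perTargetCounts Named integer vector, poses per target.
#' @exportClass PoseGrid
setClass("PoseGrid", representation(poses = "list", perTargetCounts = "integer"))

setValidity("PoseGrid", function(object) {
  if (!all(vapply(object@poses, is, TRUE, "ProbePose")))
    return("poses must all be ProbePose")
  labs <- vapply(object@poses, function(p) p@label, "")
  if (anyDuplicated(labs)) return("pose labels must be unique")
  tids <- vapply(object@poses, function(p) p@targetId, "")
  tab <- table(tids)
  if (length(object@poses)) {
    if (!setequal(names(tab), names(object@perTargetCounts)))
      return("perTargetCounts names disagree with pose target ids")
    if (!all(object@perTargetCounts[names(tab)] == as.integer(tab)))
      return("perTargetCounts disagree with the pose list")
  }
  TRUE
})

## ---- haar_dictionary types ------------------------------------------------

#' HaarBasisSet: the multi-scale Haar-like feature basis
#'
#' Eight base templates (vertical/horizontal two-rectangle edges,
#' vertical/horizontal three-rectangle lines, four-rectangle checkerboard,
#' center-surround, two-rectangle diagonal pair, full-support average), each
#' a set of non-overlapping axis-aligned rectangles with integer weights
#' over a unit support.  Edge templates additionally carry black/white
#' proportion variants.  Feature supports are dyadic:
#' \code{baseSupport * 2^s} pixels for scale levels \code{s} in
#' \code{scales}; translations step by \code{strideFactor * support} pixels.
#'
#' @slot templates Integer vector of template ids used (subset of 1:8).
#' @slot edgeSplits Numeric split fractions for edge-template variants.
#' @slot scales Strictly increasing integer scale levels.
#' @slot baseSupport Support size at scale 0, pixels (multiple of 12 keeps
#'   all rectangle edges on pixel boundaries).
#' @slot strideFactor Translation stride as a fraction of the support.
#' @slot matchSize Numeric(2) image size (rows, cols) that images are
#'   brought to before feature extraction.
#' @exportClass HaarBasisSet
setClass("HaarBasisSet", representation(
  templates = "integer", edgeSplits = "numeric", scales = "integer",
  baseSupport = "integer", strideFactor = "numeric", matchSize = "integer"
))

setValidity("HaarBasisSet", function(object) {
  if (!length(object@templates) || !all(object@templates %in% 1:8))
    return("templates must be a non-empty subset of 1:8")
  if (anyDuplicated(object@templates)) return("duplicate template ids")
  if (any(object@edgeSplits <= 0) || any(object@edgeSplits >= 1))
    return("edgeSplits must lie in (0, 1)")
  if (!length(object@scales) || any(diff(object@scales) <= 0))
    return("scales must be strictly increasing")
  if (object@baseSupport < 2L) return("baseSupport must be >= 2")
  if (object@strideFactor <= 0) return("strideFactor must be > 0")
  if (length(object@matchSize) != 2L || any(object@matchSize < 2L))
    return("matchSize must be 2 values >= 2")
  sup <- object@baseSupport * 2^max(object@scales)
  if (sup > min(object@matchSize))
    return("largest scaled support exceeds matchSize")
  TRUE
})

#' HaarFeatureVector: ordered Haar responses of one image, in scale blocks
#'
#' @slot values Numeric feature responses, ordered scale (ascending), then
#'   template, variant, translation (row-major).
#' @slot indexMap data.frame with one row per feature: scale, template,
#'   variant, tx, ty (pixel translation, 0-based).
#' @slot scaleBlocks data.frame with columns scale, start, end: contiguous
#'   index ranges sharing a scale level (1-based, inclusive).
#' @slot fingerprint Hash of the generating basis + image size; vectors are
#'   comparable iff fingerprints agree.
#' @exportClass HaarFeatureVector
setClass("HaarFeatureVector", representation(
  values = "numeric", indexMap = "data.frame", scaleBlocks = "data.frame",
  fingerprint = "character"
))

setValidity("HaarFeatureVector", function(object) {
  if (length(object@values) != nrow(object@indexMap))
    return("values and indexMap disagree in length")
  sb <- object@scaleBlocks
  if (!all(c("scale", "start", "end") %in% names(sb)))
    return("scaleBlocks needs columns scale, start, end")
  if (nrow(sb)) {
    if (sb$start[1] != 1L || sb$end[nrow(sb)] != length(object@values) ||
        (nrow(sb) > 1 && any(sb$start[-1] != sb$end[-nrow(sb)] + 1L)))
      return("scaleBlocks must partition the index range")
  }
  TRUE
})

#' FeatureDictionary: pose-tagged Haar feature vectors of simulated images
#'
#' @slot poses List of \linkS4class{ProbePose}, one per entry, in pose-grid
#'   order.
#' @slot vectors Numeric matrix, one row per entry (equal-length vectors).
#' @slot scaleBlocks Shared scale-block table (see
#'   \linkS4class{HaarFeatureVector}).
#' @slot indexMap Shared feature index table.
#' @slot images List of the simulated \linkS4class{BModeImage}s (possibly
#'   empty when built with \code{keepImages = FALSE}).
#' @slot valid Logical per entry; poses whose plane missed the data are
#'   flagged invalid and excluded from matching.
#' @slot fingerprint Basis + image-size hash shared by all vectors.
#' @exportClass FeatureDictionary
setClass("FeatureDictionary", representation(
  poses = "list", vectors = "matrix", scaleBlocks = "data.frame",
  indexMap = "data.frame", images = "list", valid = "logical",
  fingerprint = "character"
))

setValidity("FeatureDictionary", function(object) {
  n <- length(object@poses)
  if (nrow(object@vectors) != n) return("one vector row per pose required")
  if (length(object@valid) != n) return("one valid flag per pose required")
  if (length(object@images) && length(object@images) != n)
    return("images, when kept, must have one entry per pose")
  if (length(object@fingerprint) != 1L) return("single fingerprint required")
  TRUE
})

## ---- matcher / evaluation types -------------------------------------------

#' MatchResult: outcome of matching a target image against a dictionary
#'
#' @slot bestIndex Dictionary position of the best-matched entry.
#' @slot bestPose The matched \linkS4class{ProbePose}.
#' @slot score Mean per-scale NCC of the best entry, in [-1, 1].
#' @slot perScaleNcc NCC per scale block for the best entry.
#' @slot ranking Valid entry indices sorted by descending score (ties by
#'   ascending index).
#' @slot scores Scores of all entries (NA for invalid entries).
#' @exportClass MatchResult
setClass("MatchResult", representation(
  bestIndex = "integer", bestPose = "ProbePose", score = "numeric",
  perScaleNcc = "numeric", ranking = "integer", scores = "numeric"
))

setValidity("MatchResult", function(object) {
  if (abs(object@score) > 1 + 1e-9) return("score must lie in [-1, 1]")
  if (length(object@perScaleNcc) &&
      (any(abs(object@perScaleNcc) > 1 + 1e-9)))
    return("per-scale NCCs must lie in [-1, 1]")
  if (length(object@perScaleNcc) &&
      abs(object@score - mean(object@perScaleNcc)) > 1e-12)
    return("score must equal mean(perScaleNcc)")
  if (anyDuplicated(object@ranking)) return("ranking must be a permutation")
  TRUE
})

#' MarkerSet: named marker positions in the image plane frame
#'
#' @slot points N x 2 numeric matrix of (x = lateral, y = axial) positions,
#'   mm, with unique rownames.
#' @slot source "detected" or "supplied".
#' @exportClass MarkerSet
setClass("MarkerSet", representation(points = "matrix", source = "character"))

setValidity("MarkerSet", function(object) {
  if (ncol(object@points) != 2L) return("points must be N x 2")
  if (is.null(rownames(object@points)) || anyDuplicated(rownames(object@points)))
    return("points need unique rownames")
  if (!object@source %in% c("detected", "supplied"))
    return("source must be 'detected' or 'supplied'")
  TRUE
})

#' MarkerErrorReport: per-marker localization errors, matched minus target
#'
#' @slot perMarker data.frame with columns name, dx, dy (mm).
#' @slot maxAbsError Max over all |dx| and |dy|, mm.
#' @slot meanAbsError Mean over all |dx| and |dy|, mm.
#' @exportClass MarkerErrorReport
setClass("MarkerErrorReport", representation(
  perMarker = "data.frame", maxAbsError = "numeric", meanAbsError = "numeric"
))

setValidity("MarkerErrorReport", function(object) {
  pm <- object@perMarker
  if (!all(c("name", "dx", "dy") %in% names(pm)))
    return("perMarker needs columns name, dx, dy")
  if (nrow(pm)) {
    m <- max(abs(c(pm$dx, pm$dy)))
    if (abs(m - object@maxAbsError) > 1e-9)
      return("maxAbsError inconsistent with perMarker")
  }
  TRUE
})
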