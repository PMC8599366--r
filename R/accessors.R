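#' @rdname accessors
setMethod("intensities", "Volume3D", function(x) x@values)

#' @rdname accessors
setMethod("intensities", "GrayImage", function(x) x@values)

#' @rdname accessors
setMethod("spacing", "Volume3D", function(x) x@spacing)

#' @rdname accessors
setMethod("spacing", "GrayImage", function(x) x@pixelSpacing)

#' @rdname accessors
setMethod("imgOrigin", "Volume3D", function(x) x@origin)

#' @rdname accessors
setMethod("imgOrigin", "GrayImage", function(x) x@origin)

#' @rdname accessors
setMethod("nScatterers", "ScattererField", function(x) nrow(x@positions))

#' @rdname accessors
setMethod("positions", "ScattererField", function(x) x@positions)

#' @rdname accessors
setMethod("amplitudes", "ScattererField", function(x) x@amplitudes)

#' @rdname accessors
setMethod("poses", "PoseGrid", function(x) x@poses)

#' @rdname accessors
setMethod("poses", "FeatureDictionary", function(x) x@poses)

#' @rdname accessors
setMethod("featureValues", "HaarFeatureVector", function(x) x@values)

#' @rdname accessors
setMethod("scaleBlocks", "HaarFeatureVector", function(x) x@scaleBlocks)

#' @rdname accessors
setMethod("scaleBlocks", "FeatureDictionary", function(x) x@scaleBlocks)

#' @rdname accessors
setMethod("basisFingerprint", "HaarFeatureVector", function(x) x@fingerprint)

#' @rdname accessors
setMethod("basisFingerprint", "FeatureDictionary", function(x) x@fingerprint)

#' @rdname accessors
setMethod("markerPoints", "MarkerSet", function(x) x@points)

#' @rdname accessors
#' @param i Entry index.
#' @export
dictionaryEntry <- function(x, i) {
  stopifnot(is(x, "FeatureDictionary"))
  .assertParam(i >= 1 && i <= length(x@poses), "entry index out of range")
  new("HaarFeatureVector", values = x@vectors[i, ], indexMap = x@indexMap,
      scaleBlocks = x@scaleBlocks, fingerprint = x@fingerprint)
}

#' @rdname accessors
#' @export
dictionaryImage <- function(x, i) {
  stopifnot(is(x, "FeatureDictionary"))
  .assertParam(length(x@images) > 0, "dictionary was built with keepImages = FALSE")
  .assertParam(i >= 1 && i <= length(x@images), "entry index out of range")
  x@images[[i]]
}

setMethod("length", "PoseGrid", function(x) length(x@poses))
setMethod("length", "FeatureDictionary", function(x) length(x@poses))

setMethod("dim", "Volume3D", function(x) dim(x@values))
setMethod("dim", "GrayImage", function(x) dim(x@values))

setMethod("show", "Volume3D", function(object) {
  d <- dim(object@values)
  cat(sprintf("Volume3D: %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  origin (%g, %g, %g) mm, intensity range [%g, %g]\n",
              object@origin[1], object@origin[2], object@origin[3],
              min(object@values), max(object@values)))
})

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d px, spacing (%g, %g) mm, range [%g, %g]\n",
              class(object), d[1], d[2], object@pixelSpacing[1],
              object@pixelSpacing[2], min(object@values), max(object@values)))
})

setMethod("show", "ScattererField", function(object) {
  cat(sprintf("ScattererField: %d scatterers in [%g, %g] x [%g, %g] x [%g, %g] mm\n",
              nrow(object@positions), object@bounds[1, 1], object@bounds[2, 1],
              object@bounds[1, 2], object@bounds[2, 2], object@bounds[1, 3],
              object@bounds[2, 3]))
})

setMethod("show", "ProbeSpec", function(object) {
  cat(sprintf("ProbeSpec: %s array, %d elements, %.3g MHz, %d scanlines\n",
              object@geometry, object@nElements,
              object@centerFrequency / 1e6, object@nScanlines))
  if (object@geometry == "curvilinear")
    cat(sprintf("  radius %g mm, span %g deg\n", object@arrayRadius,
                object@angularSpan))
})

setMethod("show", "PoseGrid", function(object) {
  cat(sprintf("PoseGrid: %d poses over %d targets\n", length(object@poses),
              length(object@perTargetCounts)))
  if (length(object@perTargetCounts))
    print(object@perTargetCounts)
})

setMethod("show", "HaarBasisSet", function(object) {
  cat(sprintf(
    "HaarBasisSet: %d templates, scales {%s}, base support %d px, match size %d x %d\n",
    length(object@templates), paste(object@scales, collapse = ", "),
    object@baseSupport, object@matchSize[1], object@matchSize[2]))
})

setMethod("show", "HaarFeatureVector", function(object) {
  cat(sprintf("HaarFeatureVector: %d features in %d scale blocks\n",
              length(object@values), nrow(object@scaleBlocks)))
})

setMethod("show", "FeatureDictionary", function(object) {
  cat(sprintf("FeatureDictionary: %d entries (%d valid), %d features each\n",
              length(object@poses), sum(object@valid), ncol(object@vectors)))
  cat(sprintf("  fingerprint %s\n", object@fingerprint))
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf("MatchResult: best entry %d ('%s'), score %.6f\n",
              object@bestIndex, object@bestPose@label, object@score))
  cat("  per-scale NCC:", sprintf("%.4f", object@perScaleNcc), "\n")
})

setMethod("show", "MarkerSet", function(object) {
  cat(sprintf("MarkerSet (%s): %d markers\n", object@source,
              nrow(object@points)))
  print(round(object@points, 3))
})

setMethod("show", "MarkerErrorReport", function(object) {
  cat(sprintf("MarkerErrorReport: max |error| %.3f mm, mean |error| %.3f mm\n",
              object@maxAbsError, object@meanAbsError))
  print(object@perMarker, digits = 3)
})
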