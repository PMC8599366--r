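#' Accessor generics
#'
#' Small accessor family used across the package's classes: `intensities()`
#' returns the raw scalar grid of a volume or image, `spacing()` its
#' grid spacing in mm, `imgOrigin()` the first-sample position, and
#' `nScatterers()` / `positions()` / `amplitudes()` the scatterer-field
#' contents.
#'
#' @param x The object.
#' @return The slot contents (see the class documentation).
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("imgOrigin", function(x) standardGeneric("imgOrigin"))

#' @rdname accessors
#' @export
setGeneric("nScatterers", function(x) standardGeneric("nScatterers"))

#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname accessors
#' @export
setGeneric("amplitudes", function(x) standardGeneric("amplitudes"))

#' @rdname accessors
#' @export
setGeneric("poses", function(x) standardGeneric("poses"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("scaleBlocks", function(x) standardGeneric("scaleBlocks"))

#' @rdname accessors
#' @export
setGeneric("basisFingerprint", function(x) standardGeneric("basisFingerprint"))

#' @rdname accessors
#' @export
setGeneric("markerPoints", function(x) standardGeneric("markerPoints"))
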