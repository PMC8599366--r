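#' Integral image (summed-area table)
#'
#' Entry (i, j) holds the sum of the image over rows <= i and columns <= j,
#' so any axis-aligned rectangle sum is retrievable from four lookups.
#'
#' @param img A \linkS4class{GrayImage} or numeric matrix.
#' @return Numeric matrix of the same size.
#' @examples
#' integralImage(matrix(1, 3, 3))[3, 3]  # 9
#' @export
integralImage <- function(img) {
  v <- if (is(img, "GrayImage")) img@values else img
  .assertParam(is.matrix(v) && length(v) > 0, "img must be a non-empty matrix")
  t(apply(apply(v, 2L, cumsum), 1L, cumsum))
}

## Rectangle sum over rows (r0+1)..(r0+h), cols (c0+1)..(c0+w) (r0, c0
## 0-based) from an unpadded integral image.
.rectSum <- function(ii, r0, c0, h, w) {
  at <- function(r, c) if (r < 1 || c < 1) 0 else ii[r, c]
  at(r0 + h, c0 + w) - at(r0, c0 + w) - at(r0 + h, c0) + at(r0, c0)
}

#' Evaluate one Haar-like feature from an integral image
#'
#' Computes the inner product of the image with the scaled, translated
#' template -- the sum over the template's rectangles of (weight x rectangle
#' sum) -- using only integral-image lookups.
#'
#' @param ii Integral image from \code{\link{integralImage}}.
#' @param idx A single-row data.frame (or list) with elements
#'   \code{template}, \code{variant}, \code{scale}, \code{tx}, \code{ty}
#'   as produced by \code{\link{enumerateFeatures}}.
#' @param basis The \linkS4class{HaarBasisSet}.
#' @return The scalar feature response.
#' @export
evalHaarFeature <- function(ii, idx, basis) {
  stopifnot(is(basis, "HaarBasisSet"))
  support <- basis@baseSupport * 2L^idx$scale
  if (idx$tx < 0 || idx$ty < 0 || idx$ty + support > nrow(ii) ||
      idx$tx + support > ncol(ii))
    .eusStop("eus_parameter_error",
             "feature support (%d px at t = (%d, %d)) exceeds the image",
             support, idx$tx, idx$ty)
  rects <- .featureRectsPx(basis, idx$template, idx$variant, support,
                           idx$tx, idx$ty)
  s <- 0
  for (k in seq_len(nrow(rects)))
    s <- s + rects$weight[k] *
      .rectSum(ii, rects$r0[k], rects$c0[k], rects$h[k], rects$w[k])
  s
}

#' Extract the Haar feature vector of an image
#'
#' Resizes the image to the basis matching resolution if necessary
#' (bilinear), computes one integral image, and evaluates the full feature
#' enumeration through vectorized integral-image lookups.  The result is
#' linear in image intensity, and two images of equal size always yield
#' index-aligned vectors with identical fingerprints.
#'
#' @param img A \linkS4class{GrayImage}.
#' @param basis A \linkS4class{HaarBasisSet}.
#' @return A \linkS4class{HaarFeatureVector}.
#' @export
extractFeatureVector <- function(img, basis) {
  stopifnot(is(img, "GrayImage"), is(basis, "HaarBasisSet"))
  if (!all(dim(img@values) == basis@matchSize))
    img <- resizeImage(img, basis@matchSize)
  plan <- .featurePlan(basis, dim(img@values))
  v <- img@values
  ii <- rbind(0, cbind(0, t(apply(apply(v, 2L, cumsum), 1L, cumsum))))
  contrib <- plan$weight * (ii[plan$a] - ii[plan$b] - ii[plan$c] + ii[plan$d])
  vals <- as.numeric(rowsum(contrib, plan$fid, reorder = FALSE))
  new("HaarFeatureVector", values = vals, indexMap = plan$index,
      scaleBlocks = plan$scaleBlocks, fingerprint = plan$fingerprint)
}
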