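#' Construct a multi-scale Haar-like basis
#'
#' The eight base templates (see \linkS4class{HaarBasisSet}) are indexed
#' 1. vertical two-rectangle edge, 2. horizontal two-rectangle edge,
#' 3. vertical three-rectangle line, 4. horizontal three-rectangle line,
#' 5. four-rectangle checkerboard, 6. center-surround square,
#' 7. two-rectangle diagonal pair, 8. full-support average.  Rectangle
#' weights are small integers chosen so that every template except the
#' average has exactly zero response on constant images, including the
#' unequal-area proportion variants of the edge templates.
#'
#' @param templates Subset of 1:8 (default all eight).
#' @param edgeSplits Black/white proportion splits for the edge templates
#'   (default 1/4, 1/2, 3/4).
#' @param scales Integer scale levels; the support at level s is
#'   \code{baseSupport * 2^s} pixels, so larger s means a coarser pattern.
#' @param baseSupport Support at scale 0, pixels.  The default 12 is the
#'   smallest size divisible by 2, 3 and 4, keeping every rectangle edge of
#'   every template and variant on an exact pixel boundary.
#' @param strideFactor Translation stride as a fraction of the support
#'   (default 1: non-overlapping tiling).
#' @param matchSize Image size (rows, cols) images are brought to before
#'   feature extraction (default 128 x 128).
#' @return A \linkS4class{HaarBasisSet}.
#' @examples
#' basis <- haarBasisSet()
#' nrow(enumerateFeatures(basis, c(128, 128)))
#' @export
haarBasisSet <- function(templates = 1:8, edgeSplits = c(0.25, 0.5, 0.75),
                         scales = 0:3, baseSupport = 12L, strideFactor = 1,
                         matchSize = c(128L, 128L)) {
  new("HaarBasisSet", templates = as.integer(templates),
      edgeSplits = as.numeric(edgeSplits), scales = as.integer(scales),
      baseSupport = as.integer(baseSupport), strideFactor = strideFactor,
      matchSize = as.integer(matchSize))
}

## Integer weight pair for a two-rectangle split at fraction p that cancels
## on constant input: weights proportional to (-p(right area), +(left
## area)) reduced by their gcd over a denominator-4 lattice.
.edgeWeights <- function(p) {
  wl <- -round(4 * (1 - p)); wr <- round(4 * p)
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(abs(wl), abs(wr))
  c(wl, wr) / max(d, 1)
}

## Rectangle description (x0, y0, w, h, weight) of one template variant over
## the unit support. x runs along columns, y along rows.
.templateRects <- function(templateId, split = 0.5) {
  p <- split
  switch(templateId,
    { w <- .edgeWeights(p)                                   # 1 vertical edge
      data.frame(x0 = c(0, p), y0 = 0, w = c(p, 1 - p), h = 1,
                 weight = w) },
    { w <- .edgeWeights(p)                                   # 2 horizontal edge
      data.frame(x0 = 0, y0 = c(0, p), w = 1, h = c(p, 1 - p),
                 weight = w) },
    data.frame(x0 = c(0, 0.25, 0.75), y0 = 0,                # 3 vertical line
               w = c(0.25, 0.5, 0.25), h = 1, weight = c(-1, 1, -1)),
    data.frame(x0 = 0, y0 = c(0, 0.25, 0.75), w = 1,         # 4 horizontal line
               h = c(0.25, 0.5, 0.25), weight = c(-1, 1, -1)),
    data.frame(x0 = c(0, 0.5, 0, 0.5), y0 = c(0, 0, 0.5, 0.5),  # 5 checkerboard
               w = 0.5, h = 0.5, weight = c(1, -1, -1, 1)),
    data.frame(x0 = c(0.25, 0, 0, 0, 0.75),                  # 6 center-surround
               y0 = c(0.25, 0, 0.75, 0.25, 0.25),
               w = c(0.5, 1, 1, 0.25, 0.25),
               h = c(0.5, 0.25, 0.25, 0.5, 0.5),
               weight = c(3, -1, -1, -1, -1)),
    data.frame(x0 = c(0, 0.5), y0 = c(0, 0.5), w = 0.5, h = 0.5,  # 7 diagonal
               weight = c(1, -1)),
    data.frame(x0 = 0, y0 = 0, w = 1, h = 1, weight = 1)     # 8 average
  )
}

.nVariants <- function(basis, templateId)
  if (templateId %in% c(1L, 2L)) length(basis@edgeSplits) else 1L

.variantSplit <- function(basis, templateId, variant)
  if (templateId %in% c(1L, 2L)) basis@edgeSplits[variant] else 0.5

## Pixel rectangles (0-based c0, r0, w, h, weight) of one feature instance.
.featureRectsPx <- function(basis, templateId, variant, support, tx, ty) {
  r <- .templateRects(templateId, .variantSplit(basis, templateId, variant))
  c0 <- tx + round(r$x0 * support)
  r0 <- ty + round(r$y0 * support)
  w <- tx + round((r$x0 + r$w) * support) - c0
  h <- ty + round((r$y0 + r$h) * support) - r0
  data.frame(c0 = c0, r0 = r0, w = w, h = h, weight = r$weight)
}

#' Enumerate the feature indices of a basis over an image size
#'
#' Deterministic ordering: scale (ascending), then template, variant and
#' translation (row-major); translations step by the basis stride at each
#' scale and every support fits inside the image.
#'
#' @param basis A \linkS4class{HaarBasisSet}.
#' @param imageSize Integer(2) image size (rows, cols).
#' @return data.frame with columns scale, template, variant, tx, ty
#'   (translations 0-based) and support (pixels).
#' @export
enumerateFeatures <- function(basis, imageSize) {
  stopifnot(is(basis, "HaarBasisSet"))
  imageSize <- as.integer(imageSize)
  supports <- basis@baseSupport * 2L^basis@scales
  if (min(imageSize) < min(supports))
    .eusStop("eus_parameter_error",
             "image (%d x %d) smaller than the smallest feature support (%d)",
             imageSize[1], imageSize[2], min(supports))
  if (min(imageSize) < max(supports))
    .eusStop("eus_parameter_error",
             "largest scaled support (%d) exceeds the image (%d x %d)",
             max(supports), imageSize[1], imageSize[2])
  out <- vector("list", length(basis@scales))
  for (si in seq_along(basis@scales)) {
    S <- supports[si]
    stride <- max(1L, as.integer(round(S * basis@strideFactor)))
    txs <- seq.int(0L, imageSize[2] - S, by = stride)
    tys <- seq.int(0L, imageSize[1] - S, by = stride)
    rows <- list()
    for (tmpl in basis@templates) {
      for (vv in seq_len(.nVariants(basis, tmpl))) {
        rows[[length(rows) + 1L]] <- data.frame(
          scale = basis@scales[si], template = tmpl, variant = vv,
          tx = rep(txs, times = length(tys)),
          ty = rep(tys, each = length(txs)), support = S)
      }
    }
    out[[si]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.basisFingerprint <- function(basis, imageSize) {
  .hashText(.canonicalText(list(
    templates = basis@templates, edgeSplits = basis@edgeSplits,
    scales = basis@scales, baseSupport = basis@baseSupport,
    strideFactor = basis@strideFactor, imageSize = as.integer(imageSize))))
}

## ---- evaluation plan (vectorized integral-image lookups) ------------------

.planCache <- new.env(parent = emptyenv())

## Builds (and caches) the flattened rectangle lookup table for a basis at a
## fixed image size: per rectangle the 4 corner indices into the zero-padded
## integral image, its weight, and owning feature id.
.featurePlan <- function(basis, imageSize) {
  fp <- .basisFingerprint(basis, imageSize)
  cached <- .planCache[[fp]]
  if (!is.null(cached)) return(cached)
  idx <- enumerateFeatures(basis, imageSize)
  nr1 <- imageSize[1] + 1L
  parts <- vector("list", 64L); np <- 0L
  offset <- 0L
  key <- paste(idx$scale, idx$template, idx$variant, sep = "/")
  for (k in unique(key)) {
    sel <- which(key == k)
    first <- idx[sel[1], ]
    base <- .featureRectsPx(basis, first$template, first$variant,
                            first$support, 0L, 0L)
    nrect <- nrow(base)
    tx <- rep(idx$tx[sel], each = nrect)
    ty <- rep(idx$ty[sel], each = nrect)
    c0 <- rep(base$c0, times = length(sel)) + tx
    r0 <- rep(base$r0, times = length(sel)) + ty
    w <- rep(base$w, times = length(sel))
    h <- rep(base$h, times = length(sel))
    lin <- function(r, c) c * nr1 + r + 1L      # (r, c) 0-based into padded ii
    parts[[np <- np + 1L]] <- data.frame(
      a = lin(r0 + h, c0 + w), b = lin(r0, c0 + w),
      c = lin(r0 + h, c0), d = lin(r0, c0),
      weight = rep(base$weight, times = length(sel)),
      fid = rep(sel, each = nrect))
  }
  tab <- do.call(rbind, parts[seq_len(np)])
  tab <- tab[order(tab$fid), ]
  sb <- .scaleBlockTable(idx)
  plan <- list(index = idx, a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               weight = tab$weight, fid = tab$fid, nFeatures = nrow(idx),
               scaleBlocks = sb, fingerprint = fp, imageSize = imageSize)
  .planCache[[fp]] <- plan
  plan
}

.scaleBlockTable <- function(idx) {
  sc <- unique(idx$scale)
  data.frame(scale = sc,
             start = vapply(sc, function(s) min(which(idx$scale == s)), 0L),
             end = vapply(sc, function(s) max(which(idx$scale == s)), 0L))
}
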