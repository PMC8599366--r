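## Independent oracles, written against the documented behaviour rather than
## the implementation's code paths.

## Brute-force rectangle sum over rows r0+1..r0+h, cols c0+1..c0+w (0-based
## corner), by direct summation of the image.
bruteRectSum <- function(img, r0, c0, h, w) {
  sum(img[(r0 + 1):(r0 + h), (c0 + 1):(c0 + w)])
}

## Brute-force per-pixel median filter with clamped (edge-replicated)
## neighbourhood indices.
bruteMedianFilter <- function(m, window) {
  h <- window %/% 2
  out <- m
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      ri <- pmin(pmax((i - h):(i + h), 1L), nrow(m))
      cj <- pmin(pmax((j - h):(j + h), 1L), ncol(m))
      out[i, j] <- median(m[ri, cj])
    }
  }
  out
}

## Independently painted pixel masks of the eight Haar templates, from their
## documented geometry (x along columns, y along rows; weights as documented:
## edge-split weights -4(1-p)/gcd and 4p/gcd, lines -1/+1/-1 on
## quarter/half/quarter, center-surround +3 centre / -1 surround).
paintTemplateMask <- function(template, support, split = 0.5) {
  S <- support
  m <- matrix(0, S, S)
  px <- function(frac) round(frac * S)
  fill <- function(m, x0, x1, y0, y1, w) {
    m[(px(y0) + 1):px(y1), (px(x0) + 1):px(x1)] <-
      m[(px(y0) + 1):px(y1), (px(x0) + 1):px(x1)] + w
    m
  }
  edgeW <- function(p) if (p == 0.5) c(-1, 1) else c(-4 * (1 - p), 4 * p)
  if (template == 1L) {
    w <- edgeW(split)
    m <- fill(m, 0, split, 0, 1, w[1])
    m <- fill(m, split, 1, 0, 1, w[2])
  } else if (template == 2L) {
    w <- edgeW(split)
    m <- fill(m, 0, 1, 0, split, w[1])
    m <- fill(m, 0, 1, split, 1, w[2])
  } else if (template == 3L) {
    m <- fill(m, 0, 0.25, 0, 1, -1)
    m <- fill(m, 0.25, 0.75, 0, 1, 1)
    m <- fill(m, 0.75, 1, 0, 1, -1)
  } else if (template == 4L) {
    m <- fill(m, 0, 1, 0, 0.25, -1)
    m <- fill(m, 0, 1, 0.25, 0.75, 1)
    m <- fill(m, 0, 1, 0.75, 1, -1)
  } else if (template == 5L) {
    m <- fill(m, 0, 0.5, 0, 0.5, 1)
    m <- fill(m, 0.5, 1, 0, 0.5, -1)
    m <- fill(m, 0, 0.5, 0.5, 1, -1)
    m <- fill(m, 0.5, 1, 0.5, 1, 1)
  } else if (template == 6L) {
    m <- fill(m, 0, 1, 0, 1, -1)
    m <- fill(m, 0.25, 0.75, 0.25, 0.75, 4)  # -1 surround, +3 centre
  } else if (template == 7L) {
    m <- fill(m, 0, 0.5, 0, 0.5, 1)
    m <- fill(m, 0.5, 1, 0.5, 1, -1)
  } else {
    m <- fill(m, 0, 1, 0, 1, 1)
  }
  m
}

## Rendered-mask evaluation of one enumerated feature on a full image.
renderedMaskResponse <- function(imgValues, row, basis) {
  support <- basis@baseSupport * 2L^row$scale
  split <- if (row$template %in% c(1L, 2L))
    basis@edgeSplits[row$variant] else 0.5
  mask <- paintTemplateMask(row$template, support, split)
  sub <- imgValues[(row$ty + 1):(row$ty + support),
                   (row$tx + 1):(row$tx + support)]
  sum(sub * mask)
}

## Direct zero-mean NCC formula.
nccOracle <- function(u, v) {
  du <- u - mean(u); dv <- v - mean(v)
  den <- sqrt(sum(du^2) * sum(dv^2))
  if (den == 0) 0 else sum(du * dv) / den
}
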