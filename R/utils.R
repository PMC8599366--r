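## Internal numerical helpers shared across modules.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  .assertParam(n > 1e-12, "cannot normalize a near-zero vector")
  v / n
}

## Rodrigues rotation of vector(s) v (3 or n x 3) about unit axis by degrees.
.rotateAbout <- function(v, axis, degrees) {
  axis <- .unit(axis)
  th <- degrees * pi / 180
  if (is.null(dim(v))) v <- matrix(v, 1L, 3L)
  k <- matrix(axis, nrow(v), 3L, byrow = TRUE)
  kxv <- cbind(k[, 2] * v[, 3] - k[, 3] * v[, 2],
               k[, 3] * v[, 1] - k[, 1] * v[, 3],
               k[, 1] * v[, 2] - k[, 2] * v[, 1])
  kdv <- rowSums(k * v)
  out <- v * cos(th) + kxv * sin(th) + k * kdv * (1 - cos(th))
  if (nrow(out) == 1L) drop(out) else out
}

## Canonical text rendering of a (possibly nested) list of atomic values,
## used for reproducible fingerprints/hashes without a digest dependency.
.canonicalText <- function(x) {
  render <- function(v) {
    if (is.list(v)) {
      inner <- vapply(seq_along(v), function(i) {
        nm <- names(v)[i]
        paste0(if (!is.null(nm) && nzchar(nm)) paste0(nm, "=") else "",
               render(v[[i]]))
      }, "")
      paste0("(", paste(inner, collapse = ";"), ")")
    } else if (is.numeric(v)) {
      paste(sprintf("%.17g", v), collapse = ",")
    } else {
      paste(as.character(v), collapse = ",")
    }
  }
  render(x)
}

.hashText <- function(txt) {
  f <- tempfile()
  on.exit(unlink(f))
  writeChar(txt, f, eos = NULL)
  unname(tools::md5sum(f))
}

## Vectorized trilinear sampling of a Volume3D at world points (n x 3, mm).
## Points outside the voxel-centre lattice return `outside` (default 0).
.sampleVolume <- function(vol, pts, outside = 0) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L)
  d <- dim(vol@values)
  idx <- sweep(sweep(pts, 2L, vol@origin, "-"), 2L, vol@spacing, "/") + 1
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] &
        idx[, 2] >= 1 & idx[, 2] <= d[2] &
        idx[, 3] >= 1 & idx[, 3] <= d[3]
  out <- rep(outside, nrow(pts))
  if (!any(ok)) return(out)
  ix <- idx[ok, , drop = FALSE]
  i0 <- pmin(floor(ix), matrix(d - 1L, nrow(ix), 3L, byrow = TRUE))
  i0 <- pmax(i0, 1)
  f <- ix - i0
  v <- vol@values
  lin <- function(a, b, c) v[cbind(a, b, c)]
  x0 <- i0[, 1]; y0 <- i0[, 2]; z0 <- i0[, 3]
  x1 <- x0 + 1L; y1 <- y0 + 1L; z1 <- z0 + 1L
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- lin(x0, y0, z0) * (1 - fx) + lin(x1, y0, z0) * fx
  c10 <- lin(x0, y1, z0) * (1 - fx) + lin(x1, y1, z0) * fx
  c01 <- lin(x0, y0, z1) * (1 - fx) + lin(x1, y0, z1) * fx
  c11 <- lin(x0, y1, z1) * (1 - fx) + lin(x1, y1, z1) * fx
  out[ok] <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
             (c01 * (1 - fy) + c11 * fy) * fz
  out
}

## Bilinear interpolation of matrix `m` (grid coordinates = matrix indices)
## at fractional (row, col) positions; outside the grid returns `outside`.
.interpMatrix <- function(m, r, c, outside = 0) {
  nr <- nrow(m); nc <- ncol(m)
  ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
  out <- rep(outside, length(r))
  if (!any(ok)) return(out)
  rr <- r[ok]; cc <- c[ok]
  r0 <- pmax(pmin(floor(rr), nr - 1L), 1L)
  c0 <- pmax(pmin(floor(cc), nc - 1L), 1L)
  fr <- rr - r0; fc <- cc - c0
  out[ok] <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
             m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
             m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
             m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
  out
}

## Envelope of real-valued columns via the analytic signal (FFT Hilbert).
.envelopeColumns <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  sp <- stats::mvfft(m) * h
  Mod(stats::mvfft(sp, inverse = TRUE) / n)
}

## Same-length convolution of each column of `m` with centred kernel `k`
## (odd length), zero-padded, via FFT.
.convColumnsSame <- function(m, k) {
  n <- nrow(m); lk <- length(k)
  nf <- stats::nextn(n + lk - 1L, c(2, 3, 5))
  kp <- c(k, numeric(nf - lk))
  mp <- rbind(m, matrix(0, nf - n, ncol(m)))
  res <- Re(stats::mvfft(stats::mvfft(mp) * c(stats::fft(kp))
                         , inverse = TRUE) / nf)
  half <- (lk - 1L) / 2L
  res[(half + 1L):(half + n), , drop = FALSE]
}

## Weighted bincount: sums w by integer bin in [1, n].
.binSum <- function(bins, w, n) {
  out <- numeric(n)
  keep <- bins >= 1L & bins <= n
  if (!any(keep)) return(out)
  rs <- rowsum(w[keep], bins[keep])
  out[as.integer(rownames(rs))] <- rs
  out
}
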