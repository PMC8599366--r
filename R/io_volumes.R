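#' Construct a Volume3D
#'
#' @param values 3D numeric array of intensities.
#' @param spacing Numeric(3) voxel spacing, mm.
#' @param origin Numeric(3) world position of the first voxel centre, mm.
#' @return A \linkS4class{Volume3D}.
#' @examples
#' vol <- Volume3D(array(0, c(4, 4, 4)), spacing = c(1, 1, 3))
#' spacing(vol)
#' @export
Volume3D <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume3D", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a GrayImage
#'
#' @param values Numeric matrix (rows = v/axial, cols = u/lateral).
#' @param pixelSpacing Numeric(2) mm per pixel, (u/column, v/row).
#' @param origin Numeric(2) plane-frame (u, v) of pixel (1, 1), mm.
#' @return A \linkS4class{GrayImage}.
#' @export
GrayImage <- function(values, pixelSpacing = c(1, 1), origin = c(0, 0)) {
  new("GrayImage", values = values, pixelSpacing = as.numeric(pixelSpacing),
      origin = as.numeric(origin))
}

#' Construct an oblique slice specification
#'
#' @param center Numeric(3) plane centre, mm.
#' @param uAxis,vAxis Numeric(3) orthogonal in-plane directions (normalized
#'   internally; orthogonality is required to 1e-9 after normalization).
#' @param extent Numeric(2) plane size (u, v), mm.
#' @param pixelSpacing Numeric(2) sample spacing (u, v), mm; defaults to
#'   extent/128.
#' @return An \linkS4class{ObliqueSliceSpec}.
#' @export
obliqueSliceSpec <- function(center, uAxis, vAxis, extent,
                             pixelSpacing = extent / 128) {
  new("ObliqueSliceSpec", center = as.numeric(center), uAxis = .unit(uAxis),
      vAxis = .unit(vAxis), extent = as.numeric(extent),
      pixelSpacing = as.numeric(pixelSpacing))
}

#' Construct a structure mask
#'
#' @param name Label of the structure.
#' @param values Logical array congruent with the parent grid.
#' @return A \linkS4class{StructureMask}.
#' @export
structureMask <- function(name, values) {
  storage.mode(values) <- "logical"
  if (is.matrix(values)) dim(values) <- dim(values)
  new("StructureMask", name = name, values = as.array(values))
}

## ---- volume IO ------------------------------------------------------------

#' Read a 3D volume from NIfTI or a DICOM series directory
#'
#' Voxel order follows the package convention (x = left to right,
#' y = posterior to anterior, z = inferior to superior); NIfTI data are
#' assumed already RAS-aligned (no reorientation is applied), and DICOM
#' series must be axial, uncompressed, explicit-VR little-endian with
#' uniform slice spacing (checked to 1%).
#'
#' @param path File path (NIfTI) or directory (DICOM series).
#' @param format "nifti" or "dicom_dir".
#' @return A \linkS4class{Volume3D} whose spacing and origin reflect the
#'   file metadata.
#' @export
loadVolume <- function(path, format = c("nifti", "dicom_dir")) {
  format <- match.arg(format)
  if (format == "nifti") {
    if (!file.exists(path))
      .eusStop("eus_input_error", "no such file: %s", path)
    img <- tryCatch(RNifti::readNifti(path), error = function(e)
      .eusStop("eus_input_error", "unreadable NIfTI '%s': %s", path,
               conditionMessage(e)))
    if (length(dim(img)) != 3L)
      .eusStop("eus_format_error", "'%s' is not a 3D volume", path)
    arr <- array(as.numeric(img), dim(img))
    xf <- RNifti::xform(img)
    Volume3D(arr, spacing = RNifti::pixdim(img)[1:3],
             origin = as.numeric(xf[1:3, 4]))
  } else {
    .readDicomSeries(path)
  }
}

#' Write a volume to NIfTI
#'
#' @param vol A \linkS4class{Volume3D}.
#' @param path Output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(vol, path) {
  stopifnot(is(vol, "Volume3D"))
  img <- RNifti::asNifti(vol@values)
  RNifti::pixdim(img) <- vol@spacing
  m <- diag(c(vol@spacing, 1))
  m[1:3, 4] <- vol@origin
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a mask stack alongside a volume
#'
#' Stores a list of 3D \linkS4class{StructureMask}s as a single NIfTI label
#' volume (labels 1..n in list order; later masks overwrite earlier ones
#' where they overlap) plus a JSON sidecar mapping labels to names.
#'
#' @param masks List of \linkS4class{StructureMask}.
#' @param vol The parent \linkS4class{Volume3D} (for geometry).
#' @param path Output NIfTI path.
#' @return \code{path}, invisibly.
#' @export
writeMaskStack <- function(masks, vol, path) {
  lab <- array(0L, dim(vol@values))
  for (i in seq_along(masks)) lab[masks[[i]]@values] <- i
  writeVolume(Volume3D(lab, vol@spacing, vol@origin), path)
  names <- vapply(masks, function(m) m@name, "")
  jsonlite::write_json(as.list(stats::setNames(seq_along(masks), names)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Resample a volume to isotropic spacing
#'
#' Trilinear interpolation onto an isotropic grid starting at the original
#' origin; the physical bounding box is preserved to within one voxel.
#'
#' @param vol A \linkS4class{Volume3D}.
#' @param targetSpacing Isotropic target spacing, mm (default 1, the
#'   interpolated-CT convention).
#' @return The resampled \linkS4class{Volume3D}.
#' @export
resampleIsotropic <- function(vol, targetSpacing = 1) {
  stopifnot(is(vol, "Volume3D"))
  .assertParam(is.numeric(targetSpacing) && length(targetSpacing) == 1L &&
               targetSpacing > 0, "targetSpacing must be a positive scalar")
  d <- dim(vol@values)
  ext <- (d - 1L) * vol@spacing
  nNew <- pmax(floor(ext / targetSpacing + 1e-9) + 1L, 2L)
  ax <- lapply(1:3, function(k) vol@origin[k] + (seq_len(nNew[k]) - 1) * targetSpacing)
  pts <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  vals <- .sampleVolume(vol, pts)
  Volume3D(array(vals, nNew), spacing = rep(targetSpacing, 3),
           origin = vol@origin)
}

#' Extract an arbitrarily oriented interpolated slice
#'
#' Samples the volume on the plane's pixel grid by trilinear interpolation;
#' samples outside the volume are 0 (air/black), so planes running off the
#' volume edge still render.  A plane that misses the volume entirely is an
#' error.
#'
#' @param vol A \linkS4class{Volume3D}.
#' @param spec An \linkS4class{ObliqueSliceSpec}.
#' @return A \linkS4class{GrayImage} with plane-frame origin centred on the
#'   plane centre.
#' @export
extractObliqueSlice <- function(vol, spec) {
  stopifnot(is(vol, "Volume3D"), is(spec, "ObliqueSliceSpec"))
  g <- .planePixelGrid(spec)
  pts <- .planePointsWorld(spec, g$u, g$v)
  d <- dim(vol@values)
  idx <- sweep(sweep(pts, 2L, vol@origin, "-"), 2L, vol@spacing, "/") + 1
  inside <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 &
            idx[, 2] <= d[2] & idx[, 3] >= 1 & idx[, 3] <= d[3]
  if (!any(inside))
    .eusStop("eus_input_error", "slice plane lies entirely outside the volume")
  vals <- .sampleVolume(vol, pts)
  GrayImage(matrix(vals, g$nrow, g$ncol), pixelSpacing = spec@pixelSpacing,
            origin = c(g$u[1], g$v[1]))
}

## Pixel-centre coordinates of a slice plane in its own (u, v) frame.
.planePixelGrid <- function(spec) {
  ncol <- max(2L, round(spec@extent[1] / spec@pixelSpacing[1]))
  nrow <- max(2L, round(spec@extent[2] / spec@pixelSpacing[2]))
  u <- (seq_len(ncol) - 0.5) * spec@pixelSpacing[1] - spec@extent[1] / 2
  v <- (seq_len(nrow) - 0.5) * spec@pixelSpacing[2] - spec@extent[2] / 2
  list(u = u, v = v, nrow = nrow, ncol = ncol)
}

## World coordinates of the full (row-major over v then u) pixel grid.
.planePointsWorld <- function(spec, u, v) {
  uu <- rep(u, each = length(v))
  vv <- rep(v, times = length(u))
  outer(uu, spec@uAxis) + outer(vv, spec@vAxis) +
    matrix(spec@center, length(uu), 3L, byrow = TRUE)
}

#' Black out masked pixels
#'
#' Sets image pixels inside the mask to 0, the pre-processing applied to
#' tumor regions so they render hypoechoic in simulated ultrasound.
#'
#' @param img A \linkS4class{GrayImage}.
#' @param mask A \linkS4class{StructureMask} congruent with \code{img}.
#' @return The masked \linkS4class{GrayImage}; unmasked pixels are unchanged
#'   bit-for-bit.
#' @export
maskToBlack <- function(img, mask) {
  stopifnot(is(img, "GrayImage"), is(mask, "StructureMask"))
  .assertParam(identical(dim(img@values), dim(mask@values)),
               "mask shape (%s) does not match image shape (%s)",
               paste(dim(mask@values), collapse = "x"),
               paste(dim(img@values), collapse = "x"))
  v <- img@values
  v[mask@values] <- 0
  initialize(img, values = v)
}

#' Median-filter an image
#'
#' Square-window median smoothing (default 5 x 5, the pre-processing applied
#' to every simulated EUS image before feature extraction, removing isolated
#' scatter noise).  Borders are handled by edge replication: window pixels
#' beyond the image take the nearest edge pixel's value.
#'
#' @param img A \linkS4class{GrayImage} (or \linkS4class{BModeImage}).
#' @param window Odd window size in pixels, >= 1.
#' @return The filtered image, same class and geometry.
#' @export
medianFilterImage <- function(img, window = 5L) {
  stopifnot(is(img, "GrayImage"))
  .assertParam(length(window) == 1L && window >= 1 && window %% 2 == 1,
               "window must be odd and >= 1, got %s", format(window))
  if (window == 1L) return(img)
  initialize(img, values = median_filter_replicate(img@values, as.integer(window)))
}

#' Resize an image by bilinear interpolation
#'
#' Used to bring targets and dictionary images to the common matching
#' resolution.  Pixel centres of the output grid are placed uniformly over
#' the same physical extent; spacing and origin are updated accordingly.
#'
#' @param img A \linkS4class{GrayImage}.
#' @param size Integer(2) output size (rows, cols).
#' @return The resized \linkS4class{GrayImage}.
#' @export
resizeImage <- function(img, size) {
  stopifnot(is(img, "GrayImage"))
  size <- as.integer(size)
  .assertParam(length(size) == 2L && all(size >= 2L),
               "size must be two integers >= 2")
  d <- dim(img@values)
  if (all(d == size)) return(img)
  out <- EBImage::resize(EBImage::Image(t(img@values)), w = size[2],
                         h = size[1])
  vals <- t(EBImage::imageData(out))
  sc <- d / size
  newSpacing <- c(img@pixelSpacing[1] * sc[2], img@pixelSpacing[2] * sc[1])
  newOrigin <- c(img@origin[1] - img@pixelSpacing[1] / 2 + newSpacing[1] / 2,
                 img@origin[2] - img@pixelSpacing[2] / 2 + newSpacing[2] / 2)
  GrayImage(vals, pixelSpacing = newSpacing, origin = newOrigin)
}

## ---- 2D image IO ----------------------------------------------------------

#' Write a gray image as 8-bit PNG or 16-bit TIFF
#'
#' Values are mapped linearly from \code{range} (default [0, 255], the
#' B-mode display range) to the full bit depth; the format follows the file
#' extension (.png: 8-bit, .tif/.tiff: 16-bit).
#'
#' @param img A \linkS4class{GrayImage}.
#' @param path Output path (.png, .tif or .tiff).
#' @param range Numeric(2) intensity range mapped onto the bit depth.
#' @return \code{path}, invisibly.
#' @export
writeGrayImage <- function(img, path, range = c(0, 255)) {
  stopifnot(is(img, "GrayImage"))
  v <- (img@values - range[1]) / diff(range)
  v <- pmin(pmax(v, 0), 1)
  tif <- grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (tif) tiff::writeTIFF(v, path, bits.per.sample = 16L)
  else png::writePNG(v, path, dpi = NULL)
  side <- list(pixel_spacing_mm = img@pixelSpacing, origin_mm = img@origin,
               value_range = range, bits = if (tif) 16L else 8L)
  if (is(img, "BModeImage")) {
    side$dynamic_range_db <- img@dynamicRange
    side$plane <- .sliceSpecToList(img@plane)
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a gray image from PNG or TIFF
#'
#' If a JSON sidecar written by \code{\link{writeGrayImage}} exists it
#' supplies the geometry; otherwise \code{pixelSpacing} must be given and
#' intensities are returned scaled to [0, 255].
#'
#' @param path PNG or TIFF path.
#' @param pixelSpacing Numeric(2) mm per pixel, used when no sidecar exists.
#' @return A \linkS4class{GrayImage}.
#' @export
readGrayImage <- function(path, pixelSpacing = NULL) {
  if (!file.exists(path)) .eusStop("eus_input_error", "no such file: %s", path)
  v <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path)
  else png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    vals <- v * diff(meta$value_range) + meta$value_range[1]
    GrayImage(vals, pixelSpacing = meta$pixel_spacing_mm,
              origin = meta$origin_mm)
  } else {
    .assertParam(!is.null(pixelSpacing),
                 "pixelSpacing required when '%s' has no sidecar", path)
    GrayImage(v * 255, pixelSpacing = pixelSpacing)
  }
}

.sliceSpecToList <- function(spec) {
  list(center = spec@center, u_axis = spec@uAxis, v_axis = spec@vAxis,
       extent = spec@extent, pixel_spacing = spec@pixelSpacing)
}

.sliceSpecFromList <- function(x) {
  obliqueSliceSpec(unlist(x$center), unlist(x$u_axis), unlist(x$v_axis),
                   unlist(x$extent), unlist(x$pixel_spacing))
}
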