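#' Build the pose-tagged Haar feature dictionary
#'
#' For every pose in the grid, renders the simulated EUS image, smooths it
#' with a 5 x 5 median filter, and extracts its Haar feature vector.  The
#' scatterer input is either a \linkS4class{ScattererField} (geometric
#' phantom route: one shared field, sliced by each pose plane) or a
#' \linkS4class{Volume3D} (bitmap route: each pose plane is sliced from the
#' volume and converted to a thin-slab scatterer phantom whose scattering
#' factors follow the slice intensities).  A pose whose plane misses the
#' data entirely is flagged invalid, excluded from matching, and reported
#' with a warning.
#'
#' @param input A \linkS4class{ScattererField} or \linkS4class{Volume3D}.
#' @param grid A non-empty \linkS4class{PoseGrid}.
#' @param probe A \linkS4class{ProbeSpec}.
#' @param psf A \linkS4class{PSFModel}.
#' @param basis A \linkS4class{HaarBasisSet}; images are simulated directly
#'   at the basis matching resolution.
#' @param dynamicRange Log-compression range, dB.
#' @param medianWindow Median pre-filter window (default 5).
#' @param keepImages Keep the simulated images in the dictionary (needed for
#'   marker-based evaluation).
#' @param seed Base seed for the bitmap route (pose i uses seed + i).
#' @param scatterersPerImage Scatterer count per bitmap-route image.
#' @return A \linkS4class{FeatureDictionary} with entries in grid order.
#' @export
buildDictionary <- function(input, grid, probe, psf, basis,
                            dynamicRange = 60, medianWindow = 5L,
                            keepImages = TRUE, seed = 1L,
                            scatterersPerImage = 150000L) {
  stopifnot(is(grid, "PoseGrid"), is(probe, "ProbeSpec"),
            is(psf, "PSFModel"), is(basis, "HaarBasisSet"))
  .assertParam(length(grid) > 0, "pose grid is empty")
  n <- length(grid)
  plan <- .featurePlan(basis, basis@matchSize)
  vectors <- matrix(NA_real_, n, plan$nFeatures)
  images <- if (keepImages) vector("list", n) else list()
  valid <- logical(n)
  for (i in seq_len(n)) {
    pose <- grid@poses[[i]]
    img <- tryCatch(
      .renderPoseImage(input, pose, probe, psf, basis@matchSize,
                       dynamicRange, seed + i, scatterersPerImage),
      eus_error = function(e) {
        warning(sprintf("pose '%s' skipped: %s", pose@label,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (is.null(img)) next
    filt <- medianFilterImage(img, medianWindow)
    vectors[i, ] <- extractFeatureVector(filt, basis)@values
    if (keepImages) images[[i]] <- img
    valid[i] <- TRUE
  }
  new("FeatureDictionary", poses = grid@poses, vectors = vectors,
      scaleBlocks = plan$scaleBlocks, indexMap = plan$index,
      images = images, valid = valid, fingerprint = plan$fingerprint)
}

.renderPoseImage <- function(input, pose, probe, psf, imageSize,
                             dynamicRange, seed, scatterersPerImage) {
  if (is(input, "ScattererField")) {
    simulateBMode(input, probe, psf, pose@plane, imageSize, dynamicRange)
  } else if (is(input, "Volume3D")) {
    slice <- extractObliqueSlice(input, pose@plane)
    field <- sampleBitmapScatterers(slice, n = scatterersPerImage,
                                    seed = seed,
                                    slabThickness = psf@elevationSlab,
                                    plane = pose@plane)
    simulateBMode(field, probe, psf, pose@plane, imageSize, dynamicRange)
  } else {
    .eusStop("eus_parameter_error",
             "input must be a ScattererField or Volume3D, got %s",
             class(input)[1])
  }
}

## ---- persistence ----------------------------------------------------------

#' Save / load a feature dictionary
#'
#' Persists a dictionary as a directory: \code{manifest.json} (poses,
#' fingerprint, validity, scale blocks), \code{vectors.tsv} (one row per
#' entry) and, when images were kept, \code{images/entry_####.png} with
#' geometry sidecars.  \code{saveDictionary} refuses to overwrite a
#' directory holding a different fingerprint unless \code{overwrite = TRUE}.
#'
#' @param dict A \linkS4class{FeatureDictionary}.
#' @param dir Directory path.
#' @param overwrite Allow replacing a dictionary with a different
#'   fingerprint.
#' @return \code{dir} (save) or the \linkS4class{FeatureDictionary} (load).
#' @export
saveDictionary <- function(dict, dir, overwrite = FALSE) {
  stopifnot(is(dict, "FeatureDictionary"))
  manifestPath <- file.path(dir, "manifest.json")
  if (file.exists(manifestPath) && !overwrite) {
    old <- jsonlite::read_json(manifestPath)
    if (!identical(old$fingerprint, dict@fingerprint))
      .eusStop("eus_contract_error",
               "'%s' holds a dictionary with a different fingerprint; use overwrite = TRUE",
               dir)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(dict@poses, function(p) list(
    label = p@label, target_id = p@targetId, offset = p@offset,
    rotation = p@rotation, rotation_axis = p@rotationAxis,
    plane = .sliceSpecToList(p@plane)))
  jsonlite::write_json(
    list(fingerprint = dict@fingerprint, valid = dict@valid,
         scale_blocks = dict@scaleBlocks, poses = entries,
         has_images = length(dict@images) > 0),
    manifestPath, auto_unbox = TRUE, digits = NA)
  utils::write.table(dict@vectors, file.path(dir, "vectors.tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  utils::write.table(dict@indexMap, file.path(dir, "index_map.tsv"),
                     row.names = FALSE, sep = "\t")
  if (length(dict@images)) {
    imgDir <- file.path(dir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    for (i in seq_along(dict@images))
      if (!is.null(dict@images[[i]]))
        writeGrayImage(dict@images[[i]],
                       file.path(imgDir, sprintf("entry_%04d.png", i)))
  }
  invisible(dir)
}

#' @rdname saveDictionary
#' @export
loadDictionary <- function(dir) {
  manifestPath <- file.path(dir, "manifest.json")
  if (!file.exists(manifestPath))
    .eusStop("eus_input_error", "no dictionary manifest under '%s'", dir)
  man <- jsonlite::read_json(manifestPath, simplifyVector = FALSE)
  posesList <- lapply(man$poses, function(e) probePose(
    e$label, e$target_id, .sliceSpecFromList(e$plane), e$offset, e$rotation,
    unlist(e$rotation_axis)))
  vectors <- as.matrix(utils::read.table(file.path(dir, "vectors.tsv"),
                                         sep = "\t"))
  dimnames(vectors) <- NULL
  indexMap <- utils::read.table(file.path(dir, "index_map.tsv"), sep = "\t",
                                header = TRUE)
  sb <- do.call(rbind, lapply(man$scale_blocks, as.data.frame))
  images <- list()
  if (isTRUE(man$has_images)) {
    paths <- file.path(dir, "images",
                       sprintf("entry_%04d.png", seq_along(posesList)))
    images <- lapply(paths, function(p)
      if (file.exists(p)) readGrayImage(p) else NULL)
  }
  new("FeatureDictionary", poses = posesList, vectors = vectors,
      scaleBlocks = sb, indexMap = indexMap, images = images,
      valid = vapply(man$valid, isTRUE, TRUE),
      fingerprint = man$fingerprint)
}
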