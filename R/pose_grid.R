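#' Construct a probe pose
#'
#' @param label Unique label.
#' @param targetId Target identifier.
#' @param plane \linkS4class{ObliqueSliceSpec}.
#' @param offset mm along the target axis.
#' @param rotation Degrees about \code{rotationAxis}.
#' @param rotationAxis Numeric(3) unit axis.
#' @return A \linkS4class{ProbePose}.
#' @export
probePose <- function(label, targetId, plane, offset = 0, rotation = 0,
                      rotationAxis = c(0, 0, 1)) {
  new("ProbePose", label = label, targetId = targetId, plane = plane,
      offset = offset, rotation = rotation, rotationAxis = .unit(rotationAxis))
}

#' Build the phantom candidate-pose grid
#'
#' For every target the reference imaging plane is spanned by the scan
#' channel axis (image u / lateral) and the "target axis" -- the radial unit
#' vector from the channel axis to the target centre (image v / depth), and
#' is centred on the target.  Candidate poses enumerate every rotation in
#' \code{rotations} (about the channel-axis direction through the plane
#' centre, i.e. twisting the endoscopic probe) combined with
#' \code{nOffsets} plane positions spaced \code{offsetStep} mm along the
#' (rotated) target axis, symmetric about the target centre (indices
#' \code{-floor(n/2) .. n - floor(n/2) - 1}).  Pose order is fixed:
#' target, then rotation, then offset, so dictionary indices are
#' reproducible.
#'
#' @param targetCenters Numeric k x 3 matrix of target centres, mm; rownames
#'   become target ids (default \code{target_1..k}).
#' @param nOffsets Offsets per rotation (default 10, giving the canonical
#'   10 x 3 = 30 poses per target).
#' @param offsetStep Offset spacing, mm (default 5).
#' @param rotations Rotations in degrees (default \code{c(0, 15, -15)}).
#' @param channelAxis Scan-channel axis (default z).
#' @param extent,pixelSpacing Plane geometry passed to every pose's
#'   \linkS4class{ObliqueSliceSpec}.
#' @return A \linkS4class{PoseGrid} with \code{k * nOffsets *
#'   length(rotations)} poses.
#' @export
buildPhantomPoseGrid <- function(targetCenters, nOffsets = 10L,
                                 offsetStep = 5, rotations = c(0, 15, -15),
                                 channelAxis = c(0, 0, 1),
                                 extent = c(80, 80),
                                 pixelSpacing = extent / 128) {
  if (is.null(dim(targetCenters)))
    targetCenters <- matrix(targetCenters, ncol = 3L)
  .assertParam(ncol(targetCenters) == 3L, "targetCenters must be k x 3")
  .assertParam(nOffsets >= 1L, "nOffsets must be >= 1")
  .assertParam(offsetStep > 0, "offsetStep must be > 0")
  .assertParam(length(rotations) > 0, "rotations must be non-empty")
  ids <- rownames(targetCenters)
  if (is.null(ids)) ids <- paste0("target_", seq_len(nrow(targetCenters)))
  channelAxis <- .unit(channelAxis)
  offsets <- (seq_len(nOffsets) - 1L - floor(nOffsets / 2)) * offsetStep
  posesList <- list()
  for (k in seq_len(nrow(targetCenters))) {
    ctr <- targetCenters[k, ]
    radial <- ctr - sum(ctr * channelAxis) * channelAxis
    targetAxis <- .unit(radial)
    for (rot in rotations) {
      vAxis <- .rotateAbout(targetAxis, channelAxis, rot)
      for (off in offsets) {
        plane <- obliqueSliceSpec(ctr + off * vAxis, channelAxis, vAxis,
                                  extent, pixelSpacing)
        posesList[[length(posesList) + 1L]] <- probePose(
          label = sprintf("%s_rot%+g_off%+g", ids[k], rot, off),
          targetId = ids[k], plane = plane, offset = off, rotation = rot,
          rotationAxis = channelAxis)
      }
    }
  }
  .poseGrid(posesList)
}

#' Build the patient-MRI 7-slice pose sets
#'
#' For every injection point, exactly 7 candidate planes: the axial plane
#' rotated +/-15 degrees about the patient right-to-left axis (2, radial-
#' scanning-like), the axial plane rotated +/-15 degrees about the
#' posterior-to-anterior axis (2), and a plane perpendicular to the axial
#' plane (the injection plane) plus its +/-15-degree rotations about the
#' axial (superior-inferior) direction (3, linear-scanning-like).  Six
#' points (two injection points with two nearby points each) therefore give
#' the canonical 42-pose set.
#'
#' @param injectionPoints List of lists, each with elements \code{center}
#'   (numeric 3, mm), \code{rl}, \code{pa}, \code{si} (orthonormal
#'   right-left, posterior-anterior and superior-inferior axes) and
#'   optionally \code{id}.
#' @param extent,pixelSpacing Plane geometry for every pose.
#' @return A \linkS4class{PoseGrid} with \code{7 * length(injectionPoints)}
#'   poses.
#' @export
buildMriPoseSet <- function(injectionPoints, extent = c(80, 80),
                            pixelSpacing = extent / 128) {
  posesList <- list()
  for (k in seq_along(injectionPoints)) {
    p <- injectionPoints[[k]]
    id <- if (!is.null(p$id)) p$id else paste0("point_", k)
    rl <- .unit(p$rl); pa <- .unit(p$pa); si <- .unit(p$si)
    g <- rbind(rl, pa, si)
    if (max(abs(g %*% t(g) - diag(3))) > 1e-6)
      .eusStop("eus_parameter_error",
               "axes of injection point '%s' are not orthonormal", id)
    mk <- function(suffix, u, v, rot, axis)
      probePose(sprintf("%s_%s", id, suffix), id,
                obliqueSliceSpec(p$center, u, v, extent, pixelSpacing),
                offset = 0, rotation = rot, rotationAxis = axis)
    posesList <- c(posesList, list(
      ## radial-like: axial plane tilted about R-L
      mk("rl+15", rl, .rotateAbout(pa, rl, 15), 15, rl),
      mk("rl-15", rl, .rotateAbout(pa, rl, -15), -15, rl),
      ## radial-like: axial plane tilted about P-A
      mk("pa+15", .rotateAbout(rl, pa, 15), pa, 15, pa),
      mk("pa-15", .rotateAbout(rl, pa, -15), pa, -15, pa),
      ## linear-like: perpendicular injection plane and +/-15 about S-I
      mk("perp0", si, pa, 0, si),
      mk("perp+15", si, .rotateAbout(pa, si, 15), 15, si),
      mk("perp-15", si, .rotateAbout(pa, si, -15), -15, si)
    ))
  }
  .poseGrid(posesList)
}

.poseGrid <- function(posesList) {
  tids <- vapply(posesList, function(p) p@targetId, "")
  counts <- table(tids)
  new("PoseGrid", poses = posesList,
      perTargetCounts = stats::setNames(as.integer(counts), names(counts)))
}

#' Recover pose parameters from a stored plane
#'
#' Inverse of the phantom pose construction: given a pose and its target
#' centre, recomputes the (offset, rotation) pair from the stored plane.
#' Used to verify that pose construction and the stored geometry stay
#' consistent.
#'
#' @param pose A \linkS4class{ProbePose}.
#' @param targetCenter Numeric(3) target centre, mm.
#' @return Named numeric: offset (mm), rotation (degrees).
#' @export
poseParameters <- function(pose, targetCenter) {
  stopifnot(is(pose, "ProbePose"))
  axis <- pose@rotationAxis
  ctr <- as.numeric(targetCenter)
  radial <- ctr - sum(ctr * axis) * axis
  ref <- .unit(radial)
  v <- pose@plane@vAxis
  cosr <- sum(ref * v)
  crossRef <- c(ref[2] * v[3] - ref[3] * v[2],
                ref[3] * v[1] - ref[1] * v[3],
                ref[1] * v[2] - ref[2] * v[1])
  sinr <- sum(crossRef * axis)
  rotation <- atan2(sinr, cosr) * 180 / pi
  offset <- sum((pose@plane@center - ctr) * v)
  c(offset = offset, rotation = rotation)
}

#' Serialize / deserialize a pose grid as JSON
#'
#' @param grid A \linkS4class{PoseGrid}.
#' @param path Output path.
#' @return \code{path} (write) or the \linkS4class{PoseGrid} (read).
#' @export
writePoseGrid <- function(grid, path) {
  stopifnot(is(grid, "PoseGrid"))
  entries <- lapply(grid@poses, function(p) list(
    label = p@label, target_id = p@targetId, offset = p@offset,
    rotation = p@rotation, rotation_axis = p@rotationAxis,
    plane = .sliceSpecToList(p@plane)))
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePoseGrid
#' @export
readPoseGrid <- function(path) {
  if (!file.exists(path)) .eusStop("eus_input_error", "no such file: %s", path)
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  posesList <- lapply(entries, function(e) probePose(
    e$label, e$target_id, .sliceSpecFromList(e$plane), e$offset, e$rotation,
    unlist(e$rotation_axis)))
  .poseGrid(posesList)
}
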