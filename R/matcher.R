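#' Normalized cross-correlation of two vectors
#'
#' Zero-mean NCC: \code{sum((u - mean(u)) * (v - mean(v))) /
#' sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))}, in [-1, 1].  If
#' either vector is constant the correlation is undefined and 0 is returned
#' (a featureless block carries no evidence).  With \code{centered = FALSE}
#' the means are not subtracted (cosine similarity).
#'
#' @param u,v Numeric vectors of equal length >= 2.
#' @param centered Subtract means (default TRUE).
#' @return Scalar in [-1, 1].
#' @examples
#' ncc(c(1, 2, 3), c(2, 4, 7))
#' @export
ncc <- function(u, v, centered = TRUE) {
  if (length(u) != length(v))
    .eusStop("eus_parameter_error", "vector lengths differ (%d vs %d)",
             length(u), length(v))
  .assertParam(length(u) >= 2L, "vectors must have length >= 2")
  if (centered) {
    u <- u - mean(u)
    v <- v - mean(v)
  }
  su <- sum(u * u); sv <- sum(v * v)
  if (su == 0 || sv == 0) return(0)
  max(-1, min(1, sum(u * v) / sqrt(su * sv)))
}

#' Per-scale-averaged match score between two feature vectors
#'
#' The NCC is computed independently on each scale block of the vectors and
#' the score is the arithmetic mean over blocks, so every scale level
#' contributes equally regardless of how many coefficients it holds.  With
#' \code{perScale = FALSE} a single NCC over the whole vector is used
#' instead.
#'
#' @param entryVector,targetVector \linkS4class{HaarFeatureVector}s with
#'   identical basis fingerprints.
#' @param perScale Average per-scale NCCs (default) or correlate the whole
#'   vector at once.
#' @param centered Passed to \code{\link{ncc}}.
#' @return List with elements \code{score} and \code{perScale} (one NCC per
#'   scale block).
#' @export
matchScore <- function(entryVector, targetVector, perScale = TRUE,
                       centered = TRUE) {
  stopifnot(is(entryVector, "HaarFeatureVector"),
            is(targetVector, "HaarFeatureVector"))
  if (!identical(entryVector@fingerprint, targetVector@fingerprint))
    .eusStop("eus_contract_error",
             "feature vectors come from different bases (fingerprints %s vs %s)",
             entryVector@fingerprint, targetVector@fingerprint)
  .scoreVectors(entryVector@values, targetVector@values,
                entryVector@scaleBlocks, perScale, centered)
}

.scoreVectors <- function(u, v, scaleBlocks, perScale = TRUE,
                          centered = TRUE) {
  if (!perScale) {
    s <- ncc(u, v, centered)
    return(list(score = s, perScale = s))
  }
  per <- vapply(seq_len(nrow(scaleBlocks)), function(b) {
    r <- scaleBlocks$start[b]:scaleBlocks$end[b]
    ncc(u[r], v[r], centered)
  }, 0)
  list(score = mean(per), perScale = per)
}

#' Find the dictionary entry best matching a target image
#'
#' The target is preprocessed exactly like the dictionary images (resize to
#' the matching resolution, 5 x 5 median filter), encoded as a Haar feature
#' vector, and scored against every valid dictionary entry by
#' \code{\link{matchScore}}.  The pose of the maximum-score entry is the
#' estimated probe pose; ties break to the lowest index.
#'
#' @param dict A \linkS4class{FeatureDictionary}.
#' @param target The target EUS image (\linkS4class{GrayImage}).
#' @param basis The \linkS4class{HaarBasisSet} used to build the dictionary
#'   (fingerprints are checked).
#' @param medianWindow Median pre-filter window (must match the dictionary
#'   build; default 5).
#' @param perScale,centered Scoring options, see \code{\link{matchScore}}.
#' @return A \linkS4class{MatchResult}.
#' @export
findBestMatch <- function(dict, target, basis, medianWindow = 5L,
                          perScale = TRUE, centered = TRUE) {
  stopifnot(is(dict, "FeatureDictionary"), is(target, "GrayImage"),
            is(basis, "HaarBasisSet"))
  .assertParam(length(dict) > 0, "dictionary is empty")
  if (!all(dim(target@values) == basis@matchSize))
    target <- resizeImage(target, basis@matchSize)
  tv <- extractFeatureVector(medianFilterImage(target, medianWindow), basis)
  if (!identical(tv@fingerprint, dict@fingerprint))
    .eusStop("eus_contract_error",
             "basis fingerprint %s does not match dictionary fingerprint %s",
             tv@fingerprint, dict@fingerprint)
  n <- length(dict)
  scores <- rep(NA_real_, n)
  perScaleAll <- vector("list", n)
  for (i in which(dict@valid)) {
    ms <- .scoreVectors(dict@vectors[i, ], tv@values, dict@scaleBlocks,
                        perScale, centered)
    scores[i] <- ms$score
    perScaleAll[[i]] <- ms$perScale
  }
  if (!any(!is.na(scores)))
    .eusStop("eus_match_error", "no valid dictionary entries to match against")
  best <- which.max(ifelse(is.na(scores), -Inf, scores))  # lowest index wins ties
  validIdx <- which(!is.na(scores))
  ranking <- validIdx[order(-scores[validIdx], validIdx)]
  new("MatchResult", bestIndex = as.integer(best),
      bestPose = dict@poses[[best]], score = scores[best],
      perScaleNcc = perScaleAll[[best]], ranking = as.integer(ranking),
      scores = scores)
}

#' Write a match result as JSON
#'
#' @param result A \linkS4class{MatchResult}.
#' @param path Output path.
#' @param topK How many ranking entries to include.
#' @return \code{path}, invisibly.
#' @export
writeMatchResult <- function(result, path, topK = 10L) {
  stopifnot(is(result, "MatchResult"))
  p <- result@bestPose
  jsonlite::write_json(list(
    best_index = result@bestIndex,
    best_pose = list(label = p@label, target_id = p@targetId,
                     offset = p@offset, rotation = p@rotation,
                     plane = .sliceSpecToList(p@plane)),
    score = result@score, per_scale_ncc = result@perScaleNcc,
    ranking = utils::head(result@ranking, topK),
    ranking_scores = result@scores[utils::head(result@ranking, topK)]
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
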