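#' Neighbor interpolation of bad channels
#'
#' Replaces every bad channel by the unweighted mean of its `mNeighbors`
#' nearest good channels, nearest in angular (great-circle) distance on
#' the unit sphere. Equivalently each interpolated channel is the product
#' of a weight vector with exactly `mNeighbors` entries equal to
#' `1/mNeighbors` (and zeros elsewhere) with the good-channel data. Good
#' channels are untouched and the bad mask of the result is cleared. Ties
#' in angular distance are broken by channel-label lexicographic order,
#' so the interpolation is deterministic.
#'
#' @param rec an [EEGRecording-class] with a non-empty bad mask.
#' @param montage the [ElectrodeMontage-class] of the recording.
#' @param mNeighbors how many good neighbors to average (default 4).
#'
#' @return The interpolated [EEGRecording-class] (bad mask cleared,
#'   reference unchanged).
#'
#' @export
niInterpolate <- function(rec, montage, mNeighbors = 4) {
  stopifnot(is(rec, "EEGRecording"), is(montage, "ElectrodeMontage"))
  labels <- rownames(rec)
  if (!all(labels %in% montage@labels))
    stop("recording channels missing from the montage: ",
         paste(setdiff(labels, montage@labels), collapse = ", "))
  bad <- badMask(rec)
  goodIdx <- which(!bad)
  if (length(goodIdx) < mNeighbors)
    stop("need at least ", mNeighbors, " good channels, have ",
         length(goodIdx))
  x <- eegData(rec)
  if (any(bad)) {
    pos <- montage@positions[match(labels, montage@labels), , drop = FALSE]
    dist <- acos(.clampCos(tcrossprod(pos)))
    for (i in which(bad)) {
      nb <- .nearestGood(dist, labels, i, goodIdx, mNeighbors)
      x[i, ] <- colMeans(x[nb, , drop = FALSE])
    }
  }
  .remake(rec, data = x, bad = rep(FALSE, nrow(rec)))
}
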