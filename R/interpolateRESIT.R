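# shared equivalent-source reconstruction path: estimate sources from the
# good channels in the recording's own reference, forward-project through
# the full infinity-referenced lead field
.resitCore <- function(rec, leadfield, pinvRtol) {
  labels <- rownames(rec)
  if (!all(labels %in% rownames(leadfield@gains)))
    stop("recording channels missing from the lead field: ",
         paste(setdiff(labels, rownames(leadfield@gains)), collapse = ", "))
  if (leadfield@reference != "infinity")
    stop("resitInterpolate needs the full infinity-referenced lead field")
  bad <- badMask(rec)
  good <- labels[!bad]
  if (!length(good)) stop("all channels are bad; nothing to estimate from")
  if (length(good) < 2L)
    stop("at least 2 good channels are required (k <= N - 2)")
  ref <- eegReference(rec)
  lfRef <- switch(ref,
    infinity = {
      g <- leadfield@gains[good, , drop = FALSE]
      new("LeadField", gains = g, reference = "infinity",
          refChannel = NA_character_, gridConfig = leadfield@gridConfig)
    },
    average = applyLeadFieldReference(leadfield, "average", channels = good),
    point = {
      rc <- referenceChannel(rec)
      if (!rc %in% good)
        stop("the point-reference channel '", rc,
             "' must be a good channel")
      applyLeadFieldReference(leadfield, "point", channels = good,
                              refChannel = rc)
    })
  lfPinv <- .pinv(lfRef@gains, rtol = pinvRtol)
  sHat <- lfPinv %*% eegData(rec)[good, , drop = FALSE]
  vInf <- leadfield@gains[labels, , drop = FALSE] %*% sHat
  list(vInf = vInf, rank = attr(lfPinv, "rank"))
}

#' Equivalent-source interpolation with reference standardization (RESIT)
#'
#' Reconstructs all channels — bad channels included — by estimating the
#' equivalent dipole sources from the good channels and
#' forward-projecting them to every electrode. The good-channel lead
#' field is first expressed in the recording's own reference (average or
#' scalp point), the source amplitudes are estimated through its
#' Moore-Penrose pseudoinverse, and the full infinity-referenced lead
#' field maps them back to all N channels. The output is therefore
#' referenced to infinity: interpolation and reference electrode
#' standardization happen in a single linear step. With no bad channels
#' the operation reduces to plain reference standardization
#' ([restStandardize()]).
#'
#' @param rec an [EEGRecording-class] with a declared reference.
#' @param leadfield the full N-channel infinity-referenced
#'   [LeadField-class] of the montage (see [computeLeadField()]).
#' @param pinvRtol relative singular-value cutoff of the pseudoinverse
#'   (default 1e-8). The effective rank used is stored in the result
#'   metadata as `resitRank`.
#' @param outputReference `"infinity"` (native) or `"average"` to
#'   re-reference the reconstruction to the average, as is customary when
#'   comparing against average-referenced data.
#'
#' @return An [EEGRecording-class] with all channels reconstructed, bad
#'   mask cleared and reference `"infinity"` (or `"average"`).
#'
#' @export
resitInterpolate <- function(rec, leadfield, pinvRtol = 1e-8,
                             outputReference = c("infinity", "average")) {
  outputReference <- match.arg(outputReference)
  stopifnot(is(rec, "EEGRecording"), is(leadfield, "LeadField"))
  core <- .resitCore(rec, leadfield, pinvRtol)
  out <- .remake(rec, data = core$vInf, reference = "infinity",
                 refChannel = NA_character_, bad = rep(FALSE, nrow(rec)))
  md <- S4Vectors::metadata(out)
  md$resitRank <- core$rank
  S4Vectors::metadata(out) <- md
  if (outputReference == "average") out <- rereference(out, "average")
  out
}

#' Reference electrode standardization (REST)
#'
#' Transforms a recording with no bad channels to the infinity reference:
#' equivalent sources are estimated from all channels in the recording's
#' reference and forward-projected back. This is exactly the
#' [resitInterpolate()] path with k = 0 bad channels (same pseudoinverse,
#' same projection).
#'
#' @inheritParams resitInterpolate
#' @return The standardized [EEGRecording-class] (reference
#'   `"infinity"`).
#'
#' @export
restStandardize <- function(rec, leadfield, pinvRtol = 1e-8) {
  if (any(badMask(rec)))
    rec <- .remake(rec, bad = rep(FALSE, nrow(rec)))
  resitInterpolate(rec, leadfield, pinvRtol = pinvRtol)
}
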