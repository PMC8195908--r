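#' Draw a scattered or adjacent bad-channel set
#'
#' Emulates the two bad-channel injection cases of the assessment
#' protocol. `"scattered"`: k channels drawn uniformly without
#' replacement. `"adjacent"`: a uniformly drawn seed channel grown by
#' repeatedly adding the non-member channel with the smallest angular
#' distance to any current member (single-linkage growth), producing a
#' compact contiguous patch. k is `round(fraction * N)`, clamped below to
#' 1; fractions that would leave fewer than 3 good channels are rejected.
#' Randomness comes from the current RNG stream, so results are
#' reproducible under `set.seed()`.
#'
#' @param montage an [ElectrodeMontage-class].
#' @param fraction bad-channel fraction, strictly in (0, 1).
#' @param case `"scattered"` or `"adjacent"`.
#'
#' @return character vector of k bad-channel labels.
#'
#' @export
selectBadChannels <- function(montage, fraction,
                              case = c("scattered", "adjacent")) {
  case <- match.arg(case)
  stopifnot(is(montage, "ElectrodeMontage"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must be strictly in (0, 1)")
  n <- nChannels(montage)
  k <- max(1L, as.integer(round(fraction * n)))
  if (k > n - 3L)
    stop("fraction ", fraction, " leaves fewer than 3 good channels ",
         "(k = ", k, ", N = ", n, ")")
  labels <- montage@labels
  if (case == "scattered") return(labels[sample.int(n, k)])
  dist <- angularDistances(montage)
  members <- sample.int(n, 1L)
  while (length(members) < k) {
    cand <- setdiff(seq_len(n), members)
    d <- apply(dist[members, cand, drop = FALSE], 2, min)
    members <- c(members, cand[order(d, labels[cand])[1L]])
  }
  labels[members]
}

#' Interpolation accuracy metrics
#'
#' Scores a reconstruction against the held-out truth on the bad
#' channels: mean absolute error (microvolts, averaged over bad channels
#' and time), relative absolute error (summed absolute error divided by
#' summed absolute truth — scale-free), and the mean over bad channels of
#' the per-channel Pearson correlation across time. Truth and estimate
#' must share labels, sampling rate and reference convention. A
#' zero-variance true channel has no defined correlation; it is excluded
#' from the mean with a warning.
#'
#' @param truth,estimate [EEGRecording-class] objects on the same
#'   channels and reference.
#' @param badChannels labels of the reconstructed channels to score.
#'
#' @return named numeric vector `c(mae, rae, r)`.
#'
#' @export
interpMetrics <- function(truth, estimate, badChannels) {
  stopifnot(is(truth, "EEGRecording"), is(estimate, "EEGRecording"))
  if (!identical(rownames(truth), rownames(estimate)))
    stop("truth and estimate must have identical channel labels")
  if (!identical(samplingRate(truth), samplingRate(estimate)))
    stop("truth and estimate must share the sampling rate")
  if (!identical(eegReference(truth), eegReference(estimate)))
    stop("truth and estimate must share the reference convention")
  if (!length(badChannels)) stop("badChannels must be non-empty")
  missing <- setdiff(badChannels, rownames(truth))
  if (length(missing))
    stop("unknown channels: ", paste(missing, collapse = ", "))
  vt <- eegData(truth)[badChannels, , drop = FALSE]
  ve <- eegData(estimate)[badChannels, , drop = FALSE]
  absErr <- abs(ve - vt)
  mae <- mean(absErr)
  rae <- sum(absErr) / sum(abs(vt))
  sds <- apply(vt, 1, stats::sd)
  flat <- sds == 0
  if (any(flat)) {
    warning("zero-variance true channel(s) excluded from mean r: ",
            paste(badChannels[flat], collapse = ", "))
  }
  rs <- vapply(which(!flat), function(i) stats::cor(vt[i, ], ve[i, ]),
               numeric(1))
  r <- if (length(rs)) mean(rs) else NA_real_
  c(mae = mae, rae = rae, r = r)
}

#' Run the bad-channel injection assessment protocol
#'
#' For every combination of bad-channel fraction and repeat: draw a bad
#' set (scattered or adjacent), zero out those channels, reconstruct them
#' with each requested method, and score the reconstruction against the
#' held-out truth with [interpMetrics()]. The input recording is the
#' truth: it must be clean (no bad channels) and average-referenced, as
#' in the protocol. RESIT output is re-referenced to the average before
#' scoring so all methods are compared in the same convention. The whole
#' run is reproducible from `seed`; method failures are recorded per cell
#' and surfaced in the result rather than dropped.
#'
#' @param rec clean, average-referenced [EEGRecording-class] (the truth).
#' @param montage the recording's [ElectrodeMontage-class].
#' @param leadfield full infinity-referenced [LeadField-class] (needed
#'   when `"resit"` is among the methods).
#' @param fractions numeric vector of bad-channel fractions in (0, 1).
#' @param case `"scattered"` or `"adjacent"`.
#' @param nRepeats repeats per fraction (default 20).
#' @param methods subset of `c("resit", "ssi", "ni")`.
#' @param seed integer seed for the bad-channel draws.
#' @param mNeighbors neighbors for the NI baseline (default 4).
#' @param pinvRtol pseudoinverse cutoff for RESIT (default 1e-8).
#'
#' @return An [AssessmentResult-class].
#'
#' @export
runAssessment <- function(rec, montage, leadfield = NULL,
                          fractions, case = c("scattered", "adjacent"),
                          nRepeats = 20L,
                          methods = c("resit", "ssi", "ni"),
                          seed = 1L, mNeighbors = 4, pinvRtol = 1e-8) {
  case <- match.arg(case)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is(rec, "EEGRecording"))
  if (any(badMask(rec)))
    stop("the truth recording must be clean (no bad channels)")
  if (eegReference(rec) != "average")
    stop("the truth recording must be average-referenced")
  if ("resit" %in% methods && is.null(leadfield))
    stop("a lead field is required for the resit method")
  set.seed(seed)
  rows <- list()
  fails <- list()
  for (fraction in fractions) {
    for (rep in seq_len(nRepeats)) {
      badSet <- selectBadChannels(montage, fraction, case)
      corrupted <- eegData(rec)
      corrupted[badSet, ] <- 0
      dirty <- .remake(rec, data = corrupted,
                       bad = rownames(rec) %in% badSet)
      for (method in methods) {
        est <- tryCatch(
          switch(method,
            ni = niInterpolate(dirty, montage, mNeighbors = mNeighbors),
            ssi = ssiInterpolate(dirty, ssiBuild(montage, badSet)),
            resit = resitInterpolate(dirty, leadfield,
                                     pinvRtol = pinvRtol,
                                     outputReference = "average")),
          error = function(e) e)
        if (inherits(est, "error")) {
          fails[[length(fails) + 1L]] <- data.frame(
            method = method, case = case, fraction = fraction,
            repeat. = rep, message = conditionMessage(est))
          m <- c(mae = NA_real_, rae = NA_real_, r = NA_real_)
        } else {
          m <- interpMetrics(rec, est, badSet)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, case = case, fraction = fraction,
          repeat. = rep, k = length(badSet),
          mae = m[["mae"]], rae = m[["rae"]], r = m[["r"]])
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  failures <- if (length(fails)) do.call(rbind, fails) else
    data.frame(method = character(), case = character(),
               fraction = numeric(), repeat. = integer(),
               message = character())
  new("AssessmentResult", results = results, failures = failures,
      seed = as.integer(seed))
}

#' @rdname runAssessment
#' @param object,x an `AssessmentResult`.
#' @export
setMethod("show", "AssessmentResult", function(object) {
  r <- object@results
  cat(sprintf(
    "AssessmentResult: %d cells (%s; fractions %s; %d repeats; seed %d)\n",
    nrow(r), paste(unique(r$method), collapse = "/"),
    paste(unique(r$fraction), collapse = ", "),
    max(r$repeat.), object@seed))
  if (nrow(object@failures))
    cat(sprintf("  %d cell(s) failed\n", nrow(object@failures)))
})

#' @rdname runAssessment
#' @export
setMethod("assessmentResults", "AssessmentResult",
          function(x) x@results)

#' @rdname runAssessment
#' @export
setMethod("assessmentFailures", "AssessmentResult",
          function(x) x@failures)

#' Across-repeat summary of an assessment
#'
#' Mean and standard error over repeats of each metric, per method, case
#' and fraction.
#'
#' @param x an [AssessmentResult-class].
#' @return data.frame with columns `method`, `case`, `fraction` and, for
#'   each metric, its across-repeat mean and standard error.
#'
#' @export
assessmentSummary <- function(x) {
  stopifnot(is(x, "AssessmentResult"))
  r <- x@results
  se <- function(v) stats::sd(v) / sqrt(sum(!is.na(v)))
  agg <- function(fun, suffix) {
    out <- stats::aggregate(cbind(mae, rae, r) ~ method + case + fraction,
                            data = r, FUN = fun, na.action = stats::na.omit)
    names(out)[4:6] <- paste0(c("mae", "rae", "r"), suffix)
    out
  }
  merge(agg(mean, "Mean"), agg(se, "Se"),
        by = c("method", "case", "fraction"))
}
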