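#' Build a spherical-spline interpolation system
#'
#' Precomputes the Legendre kernel matrices for spherical-spline
#' interpolation on a fixed montage and bad-channel split. The kernel is
#'
#'   g(x) = (1 / 4 pi) * sum_{n=1}^{nLegendre} (2n+1) / (n (n+1))^orderM * P_n(x)
#'
#' evaluated at the cosine of the angle between electrode pairs; the
#' 1/(4 pi) prefactor is conventional and cancels in the solve.
#'
#' @param montage an [ElectrodeMontage-class].
#' @param badChannels character vector of bad-channel labels.
#' @param orderM spline stiffness order m (default 4).
#' @param nLegendre number of series terms (default 50).
#'
#' @return A [SplineSystem-class].
#'
#' @export
ssiBuild <- function(montage, badChannels, orderM = 4, nLegendre = 50L) {
  stopifnot(is(montage, "ElectrodeMontage"))
  labels <- montage@labels
  missing <- setdiff(badChannels, labels)
  if (length(missing))
    stop("bad channels not in the montage: ",
         paste(missing, collapse = ", "))
  good <- setdiff(labels, badChannels)
  if (length(good) < 3L)
    stop("spherical splines need at least 3 good channels")
  pg <- montage@positions[match(good, labels), , drop = FALSE]
  cosGood <- .clampCos(tcrossprod(pg))
  off <- cosGood[upper.tri(cosGood)]
  if (any(off > 1 - 1e-12))
    stop("coincident electrode positions among the good channels; ",
         "spline angles are undefined for duplicates")
  gGood <- .splineKernel(cosGood, orderM, nLegendre)
  gGood <- (gGood + t(gGood)) / 2
  if (length(badChannels)) {
    pb <- montage@positions[match(badChannels, labels), , drop = FALSE]
    gBad <- .splineKernel(.clampCos(tcrossprod(pb, pg)), orderM, nLegendre)
    gBad <- matrix(gBad, nrow = length(badChannels))
  } else {
    gBad <- matrix(0, 0, length(good))
  }
  new("SplineSystem", gGood = gGood, gBad = gBad, orderM = orderM,
      nLegendre = as.integer(nLegendre), goodLabels = good,
      badLabels = as.character(badChannels))
}

#' @rdname ssiBuild
#' @param object a `SplineSystem`.
#' @export
setMethod("show", "SplineSystem", function(object) {
  cat(sprintf(
    "SplineSystem: %d good / %d bad channels, order m = %g, %d terms\n",
    length(object@goodLabels), length(object@badLabels), object@orderM,
    object@nLegendre))
})

#' Spherical-spline interpolation of bad channels
#'
#' Solves the constrained spline system on the good channels — kernel
#' coefficients C with the zero-sum side condition sum_i C_i = 0 plus a
#' constant offset c0 per time point — through one bordered (augmented)
#' linear solve for all time points simultaneously, then evaluates the
#' spline at the bad-channel sites.
#'
#' @param rec an [EEGRecording-class]; its bad channels must match the
#'   split the system was built on.
#' @param system a [SplineSystem-class] built on the same montage and
#'   bad-channel set.
#'
#' @return The interpolated [EEGRecording-class] (bad mask cleared,
#'   reference unchanged).
#'
#' @export
ssiInterpolate <- function(rec, system) {
  stopifnot(is(rec, "EEGRecording"), is(system, "SplineSystem"))
  labels <- rownames(rec)
  if (!setequal(badChannels(rec), system@badLabels))
    stop("the recording's bad channels do not match the spline system")
  if (!all(system@goodLabels %in% labels))
    stop("good channels of the spline system missing from the recording")
  ng <- length(system@goodLabels)
  vGood <- eegData(rec)[system@goodLabels, , drop = FALSE]
  aug <- rbind(cbind(system@gGood, 1), c(rep(1, ng), 0))
  sol <- tryCatch(
    solve(aug, rbind(vGood, 0)),
    error = function(e) stop(
      "singular spherical-spline system (rank-deficient kernel): ",
      conditionMessage(e), call. = FALSE))
  coefC <- sol[seq_len(ng), , drop = FALSE]
  c0 <- sol[ng + 1L, ]
  x <- eegData(rec)
  if (length(system@badLabels)) {
    vBad <- system@gBad %*% coefC +
      matrix(c0, length(system@badLabels), ncol(x), byrow = TRUE)
    x[system@badLabels, ] <- vBad
  }
  .remake(rec, data = x, bad = rep(FALSE, nrow(rec)))
}
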