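# Legendre-series forward solution for dipoles in the layered sphere.
#
# For a dipole with moment p at position r0 (|r0| = b) and a scalp
# electrode at unit vector e (cos gamma = rhat0 . e), the
# infinity-referenced surface potential is
#
#   V = 1/(4 pi sigmaBrain) * sum_n b^(n-1) g_n *
#         [ n (p . rhat0) P_n(cos gamma)
#           + (p . (e - cos gamma rhat0)) P_n'(cos gamma) ]
#
# with g_n the per-degree transfer coefficients of the shell model
# (.shellGains); in the homogeneous limit g_n = (2n+1)/n and the series
# sums to the classical single-sphere closed form. The tangential term
# uses the associated Legendre function through P_n^1 = sin gamma P_n',
# folded into the coordinate-free projection above.
#
# The series is truncated when the largest term contribution falls below
# seriesRtol of the largest accumulated entry for three consecutive
# degrees (guarding against oscillation zeros), or at nTermsMax with a
# warning.
.dipoleGains <- function(model, electrodes, positions, moments) {
  electrodes <- matrix(as.numeric(electrodes), ncol = 3)
  positions <- matrix(as.numeric(positions), ncol = 3)
  moments <- matrix(as.numeric(moments), ncol = 3)
  b <- sqrt(rowSums(positions^2))
  if (any(b >= model@rBrain))
    stop("dipole(s) at or outside the brain compartment (|pos| >= rBrain): ",
         paste(which(b >= model@rBrain), collapse = ", "))
  rhat <- positions
  inner <- b > 1e-12
  rhat[inner, ] <- positions[inner, , drop = FALSE] / b[inner]
  if (any(!inner)) {
    # central dipole: use the moment direction as the axis (pure n = 1)
    for (i in which(!inner)) {
      m2 <- sqrt(sum(moments[i, ]^2))
      rhat[i, ] <- if (m2 > 0) moments[i, ] / m2 else c(0, 0, 1)
    }
  }
  x <- .clampCos(tcrossprod(electrodes, rhat)) # N x M cos gamma
  pr <- rowSums(moments * rhat)                # M radial moments
  tang <- tcrossprod(electrodes, moments) - sweep(x, 2, pr, "*")
  g <- .shellGains(model, model@nTermsMax)
  nE <- nrow(electrodes)
  nD <- nrow(positions)
  v <- matrix(0, nE, nD)
  pPrev <- matrix(1, nE, nD)
  pCur <- x
  dPrev <- matrix(0, nE, nD)
  dCur <- matrix(1, nE, nD)
  bPow <- rep(1, nD) # b^(n-1)
  belowCount <- 0L
  lastRel <- Inf
  for (n in seq_len(model@nTermsMax)) {
    term <- sweep(pCur, 2, n * pr, "*") + tang * dCur
    term <- sweep(term, 2, g[n] * bPow, "*")
    v <- v + term
    scale <- max(abs(v), .Machine$double.xmin)
    lastRel <- max(abs(term)) / scale
    belowCount <- if (lastRel < model@seriesRtol) belowCount + 1L else 0L
    if (belowCount >= 3L) break
    bPow <- bPow * b
    pNext <- ((2 * n + 1) * x * pCur - n * pPrev) / (n + 1)
    dNext <- dPrev + (2 * n + 1) * pCur
    pPrev <- pCur
    pCur <- pNext
    dPrev <- dCur
    dCur <- dNext
  }
  if (belowCount < 3L && lastRel >= model@seriesRtol)
    warning(sprintf(
      "forward series not converged at nTermsMax = %d (last term %.2g relative); returning the partial sum",
      model@nTermsMax, lastRel))
  v / (4 * pi * model@sigmaBrain)
}

#' Scalp potential of a current dipole in the layered sphere
#'
#' Evaluates the infinity-referenced surface potential generated by a
#' single current dipole inside the brain compartment of a
#' three-concentric-sphere head model, via the per-degree Legendre
#' transfer coefficients of the shell geometry.
#'
#' @param model a [ConcentricSphereHeadModel-class].
#' @param dipolePos numeric length-3 dipole position, strictly inside the
#'   brain compartment.
#' @param dipoleMoment numeric length-3 dipole moment.
#' @param electrodePos unit 3-vector, or an n x 3 matrix of unit vectors,
#'   of scalp electrode positions.
#'
#' @return numeric vector of potentials, one per electrode row.
#'
#' @examples
#' model <- concentricSphereHeadModel()
#' dipolePotential(model, c(0, 0, 0.6), c(0, 0, 1), c(0, 0, 1))
#'
#' @export
dipolePotential <- function(model, dipolePos, dipoleMoment, electrodePos) {
  electrodePos <- matrix(as.numeric(electrodePos), ncol = 3)
  nrm <- sqrt(rowSums(electrodePos^2))
  if (any(abs(nrm - model@rScalp) > 1e-6))
    stop("electrode positions must lie on the scalp sphere")
  drop(.dipoleGains(model, electrodePos, matrix(dipolePos, 1),
                    matrix(dipoleMoment, 1)))
}

#' Compute the lead field of a montage and source grid
#'
#' Entry (i, j) of the result is the scalp potential at electrode i per
#' unit moment of equivalent dipole j, referenced to infinity.
#'
#' @param model a [ConcentricSphereHeadModel-class].
#' @param montage an [ElectrodeMontage-class].
#' @param grid a [SourceGrid-class]; all sources must lie strictly inside
#'   the brain compartment.
#'
#' @return A [LeadField-class] with reference `"infinity"`.
#'
#' @examples
#' model <- concentricSphereHeadModel()
#' mon <- standardMontage(19)
#' lf <- computeLeadField(model, mon, buildSourceGrid(nCap = 50, nPlane = 10))
#' lf
#'
#' @export
computeLeadField <- function(model, montage, grid) {
  gains <- .dipoleGains(model, montage@positions * model@rScalp,
                        grid@positions, grid@orientations)
  rownames(gains) <- montage@labels
  new("LeadField", gains = gains, reference = "infinity",
      refChannel = NA_character_,
      gridConfig = .configKey(grid@nCap, grid@nPlane, grid@capRadius,
                              grid@planeZ, model@rBrain, model@rSkull,
                              model@rScalp, model@sigmaBrain,
                              model@sigmaSkull, model@sigmaScalp))
}

#' Transform a lead field to another reference
#'
#' Restricts an infinity-referenced lead field to a channel subset (for
#' example the good channels of a recording) and re-expresses it in the
#' recording reference: for the average reference every row gets the
#' column mean over the retained channels subtracted, so columns sum to
#' zero; for a point reference the row of the reference electrode is
#' subtracted from every row.
#'
#' @param leadfield a [LeadField-class] with reference `"infinity"`.
#' @param reference `"average"` or `"point"`.
#' @param channels labels of the channels to retain (default: all rows).
#' @param refChannel reference electrode label, required for
#'   `reference = "point"` and must be among `channels`.
#'
#' @return A [LeadField-class] restricted to `channels` in the requested
#'   reference.
#'
#' @export
applyLeadFieldReference <- function(leadfield,
                                    reference = c("average", "point"),
                                    channels = NULL, refChannel = NULL) {
  reference <- match.arg(reference)
  if (leadfield@reference != "infinity")
    stop("the input lead field must be infinity-referenced")
  if (is.null(channels)) channels <- rownames(leadfield@gains)
  if (!length(channels)) stop("the channel subset must not be empty")
  missing <- setdiff(channels, rownames(leadfield@gains))
  if (length(missing))
    stop("channels not in the lead field: ", paste(missing, collapse = ", "))
  g <- leadfield@gains[channels, , drop = FALSE]
  if (reference == "average") {
    g <- sweep(g, 2, colMeans(g))
    refChannel <- NA_character_
  } else {
    if (is.null(refChannel) || !refChannel %in% channels)
      stop("point reference requires refChannel among the retained channels")
    g <- sweep(g, 2, g[refChannel, ])
  }
  new("LeadField", gains = g, reference = reference,
      refChannel = if (is.null(refChannel)) NA_character_ else refChannel,
      gridConfig = leadfield@gridConfig)
}

#' @rdname computeLeadField
#' @param object,x a `LeadField`.
#' @export
setMethod("show", "LeadField", function(object) {
  cat(sprintf("LeadField: %d channels x %d sources, reference = %s%s\n",
              nrow(object@gains), ncol(object@gains), object@reference,
              if (!is.na(object@refChannel))
                paste0("(", object@refChannel, ")") else ""))
})

#' @rdname computeLeadField
#' @export
setMethod("leadFieldGains", "LeadField", function(x) x@gains)

#' @rdname computeLeadField
#' @export
setMethod("channelLabels", "LeadField", function(x) rownames(x@gains))

#' Persist a lead field for reuse across runs
#'
#' Binary container (RDS) holding the gain matrix together with its
#' reference convention, channel labels and the grid/model configuration
#' key, so a cached lead field can be validated before reuse.
#'
#' @param leadfield a [LeadField-class].
#' @param file path of the container file.
#' @return `readLeadField` returns the [LeadField-class];
#'   `writeLeadField` returns `file` invisibly.
#'
#' @export
writeLeadField <- function(leadfield, file) {
  saveRDS(leadfield, file)
  invisible(file)
}

#' @rdname writeLeadField
#' @export
readLeadField <- function(file) {
  obj <- readRDS(file)
  if (!is(obj, "LeadField")) stop("'", file, "' is not a LeadField container")
  validObject(obj)
  obj
}
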