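#' @import methods
#' @importFrom stats rnorm runif sd aggregate cor
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
NULL

#' Three-concentric-sphere volume conductor
#'
#' Piecewise-homogeneous spherical head model: an inner brain sphere, a
#' skull shell and a scalp shell. Radii are dimensionless, normalized by
#' the scalp (head) radius; conductivities are relative to brain tissue.
#' The model owns the per-degree Legendre transfer coefficients used by
#' the forward solution.
#'
#' @slot rBrain inner radius of the skull (outer radius of the brain
#'   compartment), default 0.87.
#' @slot rSkull outer radius of the skull, default 0.92.
#' @slot rScalp radius of the head, default 1.
#' @slot sigmaBrain,sigmaSkull,sigmaScalp relative conductivities
#'   (defaults 1, 0.0125, 1).
#' @slot nTermsMax truncation bound of the Legendre series.
#' @slot seriesRtol relative tolerance at which the series is declared
#'   converged.
#'
#' @seealso [concentricSphereHeadModel()]
#' @export
setClass("ConcentricSphereHeadModel",
  representation(
    rBrain = "numeric", rSkull = "numeric", rScalp = "numeric",
    sigmaBrain = "numeric", sigmaSkull = "numeric", sigmaScalp = "numeric",
    nTermsMax = "integer", seriesRtol = "numeric"
  )
)

setValidity("ConcentricSphereHeadModel", function(object) {
  msg <- character()
  if (!(object@rBrain > 0 && object@rBrain < object@rSkull &&
        object@rSkull < object@rScalp))
    msg <- c(msg, "radii must satisfy 0 < rBrain < rSkull < rScalp")
  if (any(c(object@sigmaBrain, object@sigmaSkull, object@sigmaScalp) <= 0))
    msg <- c(msg, "all conductivities must be positive")
  if (object@nTermsMax < 1L)
    msg <- c(msg, "nTermsMax must be at least 1")
  if (object@seriesRtol <= 0)
    msg <- c(msg, "seriesRtol must be positive")
  if (length(msg)) msg else TRUE
})

#' Labeled electrode positions on the unit sphere
#'
#' Head-centered electrode coordinates (+z toward the vertex, +x toward
#' the nasion), each projected to unit length so that all sensors lie on
#' the scalp sphere of the head model.
#'
#' @slot labels unique channel labels.
#' @slot positions numeric matrix, one unit-norm row per electrode.
#'
#' @seealso [electrodeMontage()], [standardMontage()], [readMontage()]
#' @export
setClass("ElectrodeMontage",
  representation(labels = "character", positions = "matrix")
)

setValidity("ElectrodeMontage", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (n < 2L) msg <- c(msg, "a montage needs at least 2 electrodes")
  if (anyDuplicated(object@labels))
    msg <- c(msg, "channel labels must be unique")
  if (!is.numeric(object@positions) || ncol(object@positions) != 3L ||
      nrow(object@positions) != n)
    msg <- c(msg, "positions must be a numeric n x 3 matrix matching labels")
  else {
    nrm <- sqrt(rowSums(object@positions^2))
    if (any(abs(nrm - 1) > 1e-9))
      msg <- c(msg, "all electrode positions must have unit norm (1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Equivalent-source dipole layer
#'
#' Positions and orientations of the M equivalent dipoles enclosing the
#' brain sources: radially oriented dipoles on a spherical cap plus
#' +z-oriented dipoles on a transverse plane that closes the cap from
#' below.
#'
#' @slot positions M x 3 dipole positions (dimensionless, inside the
#'   brain compartment).
#' @slot orientations M x 3 unit dipole orientations.
#' @slot nCap,nPlane dipole counts on the cap and the plane.
#' @slot capRadius radius of the cap sphere (default 0.869).
#' @slot planeZ height of the closing plane (default -0.076).
#'
#' @seealso [buildSourceGrid()]
#' @export
setClass("SourceGrid",
  representation(
    positions = "matrix", orientations = "matrix",
    nCap = "integer", nPlane = "integer",
    capRadius = "numeric", planeZ = "numeric"
  )
)

setValidity("SourceGrid", function(object) {
  msg <- character()
  m <- object@nCap + object@nPlane
  if (nrow(object@positions) != m || nrow(object@orientations) != m)
    msg <- c(msg, "positions/orientations must have nCap + nPlane rows")
  if (object@nCap > 0L) {
    cap <- object@positions[seq_len(object@nCap), , drop = FALSE]
    if (any(abs(sqrt(rowSums(cap^2)) - object@capRadius) > 1e-9))
      msg <- c(msg, "cap dipoles must lie on the cap sphere")
    if (any(cap[, 3] < object@planeZ - 1e-9))
      msg <- c(msg, "cap dipoles must lie above the closing plane")
    ori <- object@orientations[seq_len(object@nCap), , drop = FALSE]
    if (max(abs(ori - cap / sqrt(rowSums(cap^2)))) > 1e-9)
      msg <- c(msg, "cap orientations must be radial")
  }
  if (object@nPlane > 0L) {
    pl <- object@positions[object@nCap + seq_len(object@nPlane), , drop = FALSE]
    if (any(abs(pl[, 3] - object@planeZ) > 1e-9))
      msg <- c(msg, "plane dipoles must lie on the closing plane")
    rmax <- sqrt(object@capRadius^2 - object@planeZ^2)
    if (any(sqrt(rowSums(pl[, 1:2, drop = FALSE]^2)) > rmax + 1e-9))
      msg <- c(msg, "plane dipoles must lie inside the cap rim")
    ori <- object@orientations[object@nCap + seq_len(object@nPlane), ,
                               drop = FALSE]
    if (max(abs(sweep(ori, 2, c(0, 0, 1)))) > 1e-9)
      msg <- c(msg, "plane orientations must be +z")
  }
  if (length(msg)) msg else TRUE
})

#' Lead-field (gain) matrix with a declared reference
#'
#' N x M matrix of scalp potentials per unit dipole moment, together with
#' the reference convention the rows are expressed in: `"infinity"` (the
#' ideal neutral reference), `"average"` (columns sum to zero over the
#' retained channels) or `"point"` (potentials relative to one named
#' scalp electrode, whose own row is zero).
#'
#' @slot gains N x M numeric matrix, rownames are channel labels.
#' @slot reference one of `"infinity"`, `"average"`, `"point"`.
#' @slot refChannel reference channel label (`NA` unless point-referenced).
#' @slot gridConfig character key describing the source grid the columns
#'   belong to.
#'
#' @seealso [computeLeadField()], [applyLeadFieldReference()]
#' @export
setClass("LeadField",
  representation(
    gains = "matrix", reference = "character",
    refChannel = "character", gridConfig = "character"
  )
)

setValidity("LeadField", function(object) {
  msg <- character()
  if (!all(is.finite(object@gains)))
    msg <- c(msg, "lead-field entries must be finite")
  if (!object@reference %in% c("infinity", "average", "point"))
    msg <- c(msg, "reference must be infinity, average or point")
  if (is.null(rownames(object@gains)))
    msg <- c(msg, "gains must carry channel labels as rownames")
  if (object@reference == "average" && nrow(object@gains) > 0L) {
    cs <- colSums(object@gains)
    nrm <- sqrt(colSums(object@gains^2))
    if (any(abs(cs) > 1e-9 * pmax(nrm, .Machine$double.eps)))
      msg <- c(msg, "average-referenced columns must sum to zero (1e-9)")
  }
  if (object@reference == "point") {
    if (is.na(object@refChannel) ||
        !object@refChannel %in% rownames(object@gains))
      msg <- c(msg, "point reference requires refChannel among the rows")
    else if (any(object@gains[object@refChannel, ] != 0))
      msg <- c(msg, "the reference channel row must be identically zero")
  }
  if (length(msg)) msg else TRUE
})

#' Multichannel EEG recording
#'
#' A channels x time matrix of scalp potentials (microvolts) with channel
#' labels, sampling rate, a declared reference convention and a
#' bad-channel mask, stored as a [SummarizedExperiment::SummarizedExperiment]
#' (assay `"eeg"`, logical `rowData` column `bad`, metadata entries
#' `sfreq`, `reference`, `refChannel`).
#'
#' @seealso [eegRecording()], [rereference()], [badChannels()]
#' @export
setClass("EEGRecording", contains = "SummarizedExperiment")

setValidity("EEGRecording", function(object) {
  msg <- character()
  md <- S4Vectors::metadata(object)
  if (!"eeg" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'eeg' is required")
  else if (!all(is.finite(SummarizedExperiment::assay(object, "eeg"))))
    msg <- c(msg, "EEG samples must be finite")
  if (is.null(md$sfreq) || !is.numeric(md$sfreq) || md$sfreq <= 0)
    msg <- c(msg, "metadata 'sfreq' must be a positive sampling rate in Hz")
  if (is.null(md$reference) ||
      !md$reference %in% c("infinity", "average", "point"))
    msg <- c(msg, "metadata 'reference' must be infinity, average or point")
  if (!"bad" %in% names(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'bad' is required")
  else {
    bad <- SummarizedExperiment::rowData(object)$bad
    if (!is.logical(bad) || anyNA(bad))
      msg <- c(msg, "'bad' must be logical without NA")
    else if (sum(bad) >= nrow(object) && nrow(object) > 0L)
      msg <- c(msg, "at least one channel must be good")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Spherical-spline interpolation system
#'
#' Precomputed Legendre-kernel matrices for spherical-spline
#' interpolation of a fixed montage / bad-channel split: `gGood` holds
#' g(cos angle) between all pairs of good electrodes, `gBad` between each
#' bad and each good electrode.
#'
#' @slot gGood symmetric (N-k) x (N-k) kernel matrix.
#' @slot gBad k x (N-k) kernel matrix.
#' @slot orderM spline stiffness order (default 4).
#' @slot nLegendre number of Legendre terms in the kernel (default 50).
#' @slot goodLabels,badLabels channel labels of the split.
#'
#' @seealso [ssiBuild()], [ssiInterpolate()]
#' @export
setClass("SplineSystem",
  representation(
    gGood = "matrix", gBad = "matrix",
    orderM = "numeric", nLegendre = "integer",
    goodLabels = "character", badLabels = "character"
  )
)

setValidity("SplineSystem", function(object) {
  msg <- character()
  ng <- length(object@goodLabels)
  if (nrow(object@gGood) != ng || ncol(object@gGood) != ng)
    msg <- c(msg, "gGood must be square over the good channels")
  else {
    if (max(abs(object@gGood - t(object@gGood))) > 1e-12)
      msg <- c(msg, "gGood must be symmetric")
    g1 <- .splineKernel(1, object@orderM, object@nLegendre)
    if (any(abs(diag(object@gGood) - g1) > 1e-12))
      msg <- c(msg, "gGood diagonal must equal g(1)")
  }
  if (ncol(object@gBad) != ng)
    msg <- c(msg, "gBad must have one column per good channel")
  if (!all(is.finite(object@gGood)) || !all(is.finite(object@gBad)))
    msg <- c(msg, "kernel matrices must be finite")
  if (length(msg)) msg else TRUE
})

#' Bad-channel interpolation assessment result
#'
#' Per-cell metrics of the bad-channel injection protocol: for every
#' combination of method, case, bad-channel fraction and repeat, the mean
#' absolute error (microvolts), relative absolute error and mean Pearson
#' correlation of the reconstructed bad channels against the held-out
#' truth.
#'
#' @slot results data.frame with columns `method`, `case`, `fraction`,
#'   `repeat.`, `k`, `mae`, `rae`, `r`.
#' @slot failures data.frame describing any per-cell method failures.
#' @slot seed integer seed the protocol was run with.
#'
#' @seealso [runAssessment()], [assessmentSummary()]
#' @export
setClass("AssessmentResult",
  representation(
    results = "data.frame", failures = "data.frame", seed = "integer"
  )
)
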