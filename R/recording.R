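#' Construct an EEG recording
#'
#' Wraps a channels x time matrix of scalp potentials (microvolts) with
#' labels, sampling rate, declared reference and bad-channel mask. When
#' `reference = "average"` the channel mean must already be zero at every
#' time point (within 1e-6 of the data RMS); use [rereference()] to
#' center data that is not.
#'
#' @param data numeric channels x time matrix.
#' @param labels channel labels (default: rownames of `data`).
#' @param sfreq sampling rate in Hz.
#' @param reference `"infinity"`, `"average"` or `"point"`.
#' @param refChannel reference channel label when `reference = "point"`.
#' @param bad logical mask (or character vector of labels) of bad
#'   channels.
#'
#' @return An [EEGRecording-class].
#'
#' @examples
#' x <- matrix(rnorm(4 * 100), 4, dimnames = list(c("Fz", "Cz", "Pz", "Oz")))
#' rec <- eegRecording(sweep(x, 2, colMeans(x)), sfreq = 500,
#'                     reference = "average")
#' rec
#'
#' @export
eegRecording <- function(data, labels = rownames(data), sfreq,
                         reference = c("infinity", "average", "point"),
                         refChannel = NA_character_, bad = NULL) {
  reference <- match.arg(reference)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(labels))
    stop("channel labels are required (rownames of data or 'labels')")
  rownames(data) <- labels
  if (is.null(bad)) bad <- rep(FALSE, nrow(data))
  if (is.character(bad)) {
    missing <- setdiff(bad, labels)
    if (length(missing))
      stop("bad channels not in the montage: ",
           paste(missing, collapse = ", "))
    bad <- labels %in% bad
  }
  if (reference == "point") {
    if (is.na(refChannel) || !refChannel %in% labels)
      stop("point reference requires refChannel among the channel labels")
  } else {
    refChannel <- NA_character_
  }
  if (reference == "average") {
    rms <- sqrt(mean(data^2))
    if (max(abs(colMeans(data))) > 1e-6 * max(rms, .Machine$double.eps))
      stop("data declared average-referenced but channel means are not ",
           "zero; rereference() it first")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(eeg = data),
    rowData = S4Vectors::DataFrame(bad = bad, row.names = labels),
    metadata = list(sfreq = sfreq, reference = reference,
                    refChannel = refChannel)
  )
  new("EEGRecording", se)
}

# rebuild a recording around new data / metadata without re-checking
# average centering (used by interpolators, whose outputs carry the
# declared convention of their inputs while replaced channels are
# approximations)
.remake <- function(rec, data = NULL, reference = NULL,
                    refChannel = NULL, bad = NULL) {
  if (!is.null(data)) {
    rownames(data) <- rownames(rec)
    SummarizedExperiment::assay(rec, "eeg", withDimnames = FALSE) <- data
  }
  md <- S4Vectors::metadata(rec)
  if (!is.null(reference)) md$reference <- reference
  if (!is.null(refChannel)) md$refChannel <- refChannel
  S4Vectors::metadata(rec) <- md
  if (!is.null(bad)) SummarizedExperiment::rowData(rec)$bad <- bad
  rec
}

#' @rdname eegRecording
#' @param x,object an `EEGRecording`.
#' @export
setMethod("eegData", "EEGRecording",
          function(x) SummarizedExperiment::assay(x, "eeg"))

#' @rdname eegRecording
#' @export
setMethod("channelLabels", "EEGRecording", function(x) rownames(x))

#' @rdname eegRecording
#' @export
setMethod("samplingRate", "EEGRecording",
          function(x) S4Vectors::metadata(x)$sfreq)

#' @rdname eegRecording
#' @export
setMethod("eegReference", "EEGRecording",
          function(x) S4Vectors::metadata(x)$reference)

#' @rdname eegRecording
#' @export
setMethod("referenceChannel", "EEGRecording",
          function(x) S4Vectors::metadata(x)$refChannel)

#' @rdname eegRecording
#' @export
setMethod("badChannels", "EEGRecording",
          function(x) rownames(x)[SummarizedExperiment::rowData(x)$bad])

#' @rdname eegRecording
#' @param value character vector of bad-channel labels (or logical mask).
#' @export
setReplaceMethod("badChannels", "EEGRecording", function(x, value) {
  if (is.character(value)) {
    missing <- setdiff(value, rownames(x))
    if (length(missing))
      stop("unknown channels: ", paste(missing, collapse = ", "))
    value <- rownames(x) %in% value
  }
  SummarizedExperiment::rowData(x)$bad <- value
  validObject(x)
  x
})

#' @rdname eegRecording
#' @export
setMethod("badMask", "EEGRecording",
          function(x) SummarizedExperiment::rowData(x)$bad)

#' @rdname eegRecording
#' @export
setMethod("show", "EEGRecording", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf(
    "EEGRecording: %d channels x %d samples @ %g Hz, reference = %s%s\n",
    nrow(object), ncol(object), md$sfreq, md$reference,
    if (!is.na(md$refChannel)) paste0("(", md$refChannel, ")") else ""))
  nb <- sum(SummarizedExperiment::rowData(object)$bad)
  if (nb) cat(sprintf("  bad channels (%d): %s\n", nb,
                      paste(badChannels(object), collapse = " ")))
})

#' Re-reference an EEG recording
#'
#' `"average"` subtracts the mean over channels at every time point
#' (a projection: applying it twice equals applying it once); `"point"`
#' subtracts the time course of the named electrode, whose own channel
#' becomes zero.
#'
#' @param rec an [EEGRecording-class].
#' @param target `"average"` or `"point"`.
#' @param refChannel reference electrode label for `target = "point"`;
#'   must exist and not be marked bad.
#'
#' @return The re-referenced [EEGRecording-class].
#'
#' @export
rereference <- function(rec, target = c("average", "point"),
                        refChannel = NULL) {
  target <- match.arg(target)
  x <- eegData(rec)
  if (target == "average") {
    x <- sweep(x, 2, colMeans(x))
    .remake(rec, data = x, reference = "average",
            refChannel = NA_character_)
  } else {
    if (is.null(refChannel) || !refChannel %in% rownames(rec))
      stop("point rereferencing requires an existing refChannel")
    if (refChannel %in% badChannels(rec))
      stop("refChannel '", refChannel, "' is marked bad")
    x <- sweep(x, 2, x[refChannel, ])
    .remake(rec, data = x, reference = "point", refChannel = refChannel)
  }
}

#' Read / write EEG data matrices
#'
#' Two interchange forms. The delimited text form is a tab-separated
#' table, one column per channel with a header row of channel labels and
#' one row per time point; sampling rate and reference are supplied by
#' the caller on read. The binary container (RDS) serializes the full
#' [EEGRecording-class] losslessly, metadata included.
#'
#' @param rec an [EEGRecording-class].
#' @param file path to write to / read from.
#' @return readers return an [EEGRecording-class]; writers return `file`
#'   invisibly.
#'
#' @export
writeEEGText <- function(rec, file) {
  x <- t(eegData(rec))
  utils::write.table(x, file, sep = "\t", row.names = FALSE,
                     col.names = colnames(x), quote = FALSE)
  invisible(file)
}

#' @rdname writeEEGText
#' @inheritParams eegRecording
#' @export
readEEGText <- function(file, sfreq,
                        reference = c("infinity", "average", "point"),
                        refChannel = NA_character_, bad = NULL) {
  x <- utils::read.table(file, header = TRUE, sep = "\t",
                         check.names = FALSE)
  eegRecording(t(as.matrix(x)), labels = colnames(x), sfreq = sfreq,
               reference = match.arg(reference), refChannel = refChannel,
               bad = bad)
}

#' @rdname writeEEGText
#' @export
writeEEGRecording <- function(rec, file) {
  saveRDS(rec, file)
  invisible(file)
}

#' @rdname writeEEGText
#' @export
readEEGRecording <- function(file) {
  obj <- readRDS(file)
  if (!is(obj, "EEGRecording"))
    stop("'", file, "' is not an EEGRecording container")
  validObject(obj)
  obj
}
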