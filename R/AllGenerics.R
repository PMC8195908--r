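# generics for the package's accessors (methods live next to their classes)

#' @rdname electrodeMontage
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname electrodeMontage
#' @export
setGeneric("electrodePositions",
           function(x) standardGeneric("electrodePositions"))

#' @rdname electrodeMontage
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname buildSourceGrid
#' @export
setGeneric("nSources", function(x) standardGeneric("nSources"))

#' @rdname buildSourceGrid
#' @export
setGeneric("sourcePositions", function(x) standardGeneric("sourcePositions"))

#' @rdname buildSourceGrid
#' @export
setGeneric("sourceOrientations",
           function(x) standardGeneric("sourceOrientations"))

#' @rdname computeLeadField
#' @export
setGeneric("leadFieldGains", function(x) standardGeneric("leadFieldGains"))

#' @rdname eegRecording
#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @rdname eegRecording
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname eegRecording
#' @export
setGeneric("eegReference", function(x) standardGeneric("eegReference"))

#' @rdname eegRecording
#' @export
setGeneric("referenceChannel",
           function(x) standardGeneric("referenceChannel"))

#' @rdname eegRecording
#' @export
setGeneric("badChannels", function(x) standardGeneric("badChannels"))

#' @rdname eegRecording
#' @export
setGeneric("badChannels<-",
           function(x, value) standardGeneric("badChannels<-"))

#' @rdname eegRecording
#' @export
setGeneric("badMask", function(x) standardGeneric("badMask"))

#' @rdname runAssessment
#' @export
setGeneric("assessmentResults",
           function(x) standardGeneric("assessmentResults"))

#' @rdname runAssessment
#' @export
setGeneric("assessmentFailures",
           function(x) standardGeneric("assessmentFailures"))
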