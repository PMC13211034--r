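# Generics for the accessor layer. Slot access from user code is never
# needed; these are the supported surface.

#' @export
setGeneric("markerTable", function(x) standardGeneric("markerTable"))
#' @export
setGeneric("nMarkers", function(x) standardGeneric("nMarkers"))
#' @export
setGeneric("chromosomes", function(x) standardGeneric("chromosomes"))
#' @export
setGeneric("genoCalls", function(x) standardGeneric("genoCalls"))
#' @export
setGeneric("trueCalls", function(x) standardGeneric("trueCalls"))
#' @export
setGeneric("lineNames", function(x) standardGeneric("lineNames"))
#' @export
setGeneric("plotData", function(x) standardGeneric("plotData"))
#' @export
setGeneric("headData", function(x) standardGeneric("headData"))
#' @export
setGeneric("spikePixels", function(x) standardGeneric("spikePixels"))
#' @export
setGeneric("imageTruth", function(x) standardGeneric("imageTruth"))
#' @export
setGeneric("probArray", function(x) standardGeneric("probArray"))
#' @export
setGeneric("kinshipValues", function(x) standardGeneric("kinshipValues"))
#' @export
setGeneric("lodTable", function(x) standardGeneric("lodTable"))
#' @export
setGeneric("scanPeak", function(x) standardGeneric("scanPeak"))
#' @export
setGeneric("scanThreshold", function(x) standardGeneric("scanThreshold"))
#' @export
setGeneric("pcScores", function(x) standardGeneric("pcScores"))
#' @export
setGeneric("varExplained", function(x) standardGeneric("varExplained"))
#' @export
setGeneric("finalMask", function(x) standardGeneric("finalMask"))
#' @export
setGeneric("composite", function(x) standardGeneric("composite"))
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))
#' @export
setGeneric("componentShares", function(x) standardGeneric("componentShares"))
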