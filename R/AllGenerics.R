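#' @rdname ToyGenome-class
#' @param x A hetcal object.
#' @export
setGeneric("species", function(x) standardGeneric("species"))

#' @rdname ToyGenome-class
#' @export
setGeneric("genomeSeqs", function(x) standardGeneric("genomeSeqs"))

#' @rdname ToyReference-class
#' @param x A `ToyReference`.
#' @param which `"target"` or `"spike"`.
#' @export
setGeneric("refGenome", function(x, which = "target")
    standardGeneric("refGenome"))

#' @rdname ToyReference-class
#' @export
setGeneric("refFeatures", function(x, which = "target")
    standardGeneric("refFeatures"))

#' @rdname SimTruth-class
#' @param x A `SimTruth`.
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @rdname SimTruth-class
#' @export
setGeneric("mixingRatio", function(x) standardGeneric("mixingRatio"))

#' @rdname SizeFactors-class
#' @param x A `SizeFactors`.
#' @export
setGeneric("factorValues", function(x) standardGeneric("factorValues"))

#' @rdname SizeFactors-class
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname SizeFactors-class
#' @export
setGeneric("rawCounts", function(x) standardGeneric("rawCounts"))

#' @rdname CoverageTrack-class
#' @param x A `CoverageTrack`.
#' @export
setGeneric("trackCov", function(x) standardGeneric("trackCov"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("trackStrand", function(x) standardGeneric("trackStrand"))

#' @rdname CoverageTrack-class
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' @rdname MetageneProfile-class
#' @param x A `MetageneProfile`.
#' @export
setGeneric("profileOffsets", function(x) standardGeneric("profileOffsets"))

#' @rdname MetageneProfile-class
#' @export
setGeneric("profileMean", function(x) standardGeneric("profileMean"))
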