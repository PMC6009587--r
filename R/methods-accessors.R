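## Accessors and show() methods.  Users never touch slots directly.

#' @rdname ToyGenome-class
#' @export
setMethod("species", "ToyGenome", function(x) x@species)

#' @rdname ToyGenome-class
#' @export
setMethod("genomeSeqs", "ToyGenome", function(x) x@seqs)

#' Chromosome lengths of a ToyGenome
#' @param x A `ToyGenome`.
#' @return Named integer vector of chromosome lengths.
#' @export
setMethod("seqlengths", "ToyGenome",
    function(x) setNames(lengths(x@seqs), names(x@seqs)))

setMethod("show", "ToyGenome", function(object) {
    cat(sprintf("ToyGenome [%s]: %d chromosome(s), %s bp total\n",
        object@species, length(object@seqs),
        format(sum(lengths(object@seqs)), big.mark = ",")))
})

#' @rdname ToyReference-class
#' @export
setMethod("refGenome", "ToyReference", function(x, which = "target") {
    which <- match.arg(which, VALID_SPECIES)
    x@genomes[[which]]
})

#' @rdname ToyReference-class
#' @export
setMethod("refFeatures", "ToyReference", function(x, which = "target") {
    which <- match.arg(which, VALID_SPECIES)
    x@annotations[[which]]
})

setMethod("show", "ToyReference", function(object) {
    cat("ToyReference (two-species synthetic reference)\n")
    for (sp in VALID_SPECIES) {
        a <- object@annotations[[sp]]
        cat(sprintf("  %s: %s bp, %d features (%s)\n", sp,
            format(sum(seqlengths(object@genomes[[sp]])), big.mark = ","),
            length(a),
            paste(sprintf("%s=%d", names(table(a$biotype)),
                          table(a$biotype)), collapse = ", ")))
    }
    cat(sprintf("  seed: %d\n", object@seed))
})

#' @rdname SimTruth-class
#' @export
setMethod("truthTable", "SimTruth", function(x) x@table)

#' @rdname SimTruth-class
#' @export
setMethod("mixingRatio", "SimTruth", function(x) x@mixingRatio)

setMethod("show", "SimTruth", function(object) {
    tab <- object@table
    tgt <- tab[tab$species == "target", ]
    cat(sprintf(paste0(
        "SimTruth: %d features (%d target), mixing ratio %g:1\n",
        "  TSA-affected: %d up, %d down; rrp6-stabilized: %d\n"),
        nrow(tab), nrow(tgt), object@mixingRatio,
        sum(tgt$tsa_effect >= 2), sum(tgt$tsa_effect <= 0.5),
        sum(tab$rrp6_effect > 2)))
})

#' @rdname SizeFactors-class
#' @export
setMethod("factorValues", "SizeFactors", function(x) x@factors)

#' @rdname SizeFactors-class
#' @export
setMethod("scheme", "SizeFactors", function(x) x@scheme)

#' @rdname SizeFactors-class
#' @export
setMethod("rawCounts", "SizeFactors", function(x) x@counts)

setMethod("show", "SizeFactors", function(object) {
    cat(sprintf("SizeFactors [%s], %d samples:\n", object@scheme,
        length(object@factors)))
    print(round(object@factors, 4))
})

#' @rdname CoverageTrack-class
#' @export
setMethod("trackCov", "CoverageTrack", function(x) x@cov)

#' @rdname CoverageTrack-class
#' @export
setMethod("trackStrand", "CoverageTrack", function(x) x@strand)

#' @rdname CoverageTrack-class
#' @export
setMethod("isCalibrated", "CoverageTrack", function(x) x@calibrated)

setMethod("show", "CoverageTrack", function(object) {
    tot <- sum(vapply(object@cov, function(r) sum(as.numeric(r), na.rm = TRUE),
                      numeric(1)))
    cat(sprintf(
        "CoverageTrack [%s, strand %s] %d chrom(s), mass %.4g %s%s\n",
        object@sampleId, object@strand, length(object@cov), tot,
        object@units, if (object@calibrated) " (calibrated)" else ""))
})

#' @rdname MetageneProfile-class
#' @export
setMethod("profileOffsets", "MetageneProfile", function(x) x@offsets)

#' @rdname MetageneProfile-class
#' @export
setMethod("profileMean", "MetageneProfile", function(x) x@mean)

setMethod("show", "MetageneProfile", function(object) {
    pk <- object@offsets[which.max(object@mean)]
    cat(sprintf(
        "MetageneProfile: window [%d, %d] around TSS, %d features (%d dropped), peak at %+d bp\n",
        object@window[1], object@window[2], object@n, object@nDropped, pk))
})
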