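## Spike-derived calibration.  All size factors are anchored to geometric
## mean 1 across the comparison group; dividing a sample's raw signal by
## its factor puts every sample on the spike scale.

.geomean <- function(x) exp(mean(log(x)))

#' Count spike-side signal for calibration
#'
#' Counts disambiguated spike fragments, either in total (every unique
#' spike read) or over an annotated subset: the ribosomal-protein-coding
#' genes (the NET-seq normalization set) or the ERCC-like transcripts (the
#' CUT RNA-seq normalization set).  Subset counting is strand-aware
#' interval overlap; unstranded fragments overlap features on either
#' strand.
#'
#' @param spikeFrags GRanges of unique spike fragments (from
#'   [disambiguate()]).
#' @param annotation Spike-side annotation GRanges (`feature_id`,
#'   `biotype`).
#' @param subset `"all"`, `"spike_rp_gene"` or `"ercc"`.
#' @param sampleId Sample label.
#' @return A list of class `SpikeCounts`: `sample_id`, `subset`, `total`
#'   (all unique spike reads), `count` (the scalar used for calibration),
#'   `perFeature` (named per-feature counts for subsets).
#' @export
countSpike <- function(spikeFrags, annotation,
                       subset = c("all", "spike_rp_gene", "ercc"),
                       sampleId = "sample") {
    subset <- match.arg(subset)
    total <- length(spikeFrags)
    if (subset == "all") {
        res <- list(sample_id = sampleId, subset = subset, total = total,
                    count = total, perFeature = NULL)
    } else {
        feats <- annotation[annotation$biotype == subset]
        if (length(feats) == 0L)
            stop("config error: annotation has no '", subset, "' features")
        pf <- countOverlaps(feats, spikeFrags)
        names(pf) <- feats$feature_id
        res <- list(sample_id = sampleId, subset = subset, total = total,
                    count = sum(pf), perFeature = pf)
    }
    class(res) <- "SpikeCounts"
    res
}

#' @export
print.SpikeCounts <- function(x, ...) {
    cat(sprintf("SpikeCounts [%s, subset %s]: %d used / %d unique spike reads\n",
                x$sample_id, x$subset, x$count, x$total))
    invisible(x)
}

.as_count_vector <- function(counts) {
    if (is.list(counts) && all(vapply(counts, inherits, logical(1),
                                      "SpikeCounts")))
        counts <- setNames(vapply(counts, `[[`, numeric(1), "count"),
                           vapply(counts, `[[`, character(1), "sample_id"))
    if (is.null(names(counts)) || anyDuplicated(names(counts)))
        stop("spike counts must be uniquely named by sample")
    counts
}

#' Spike size factors
#'
#' Per-sample calibration scalars from spike signal:
#' `factor_k = count_k / geometric-mean(counts)`, so the factors have
#' geometric mean 1 and dividing each sample's signal by its factor makes
#' the spike signal flat across samples.
#'
#' @param counts Named numeric vector of per-sample spike counts, or a list
#'   of [countSpike()] results.
#' @param scheme `"total_spike"`, `"rp_spike"` or `"ercc"`.
#' @return A [SizeFactors-class] object.
#' @examples
#' spikeSizeFactors(c(a = 100, b = 200), "total_spike")
#' @export
spikeSizeFactors <- function(counts,
                             scheme = c("total_spike", "rp_spike", "ercc")) {
    scheme <- match.arg(scheme)
    counts <- .as_count_vector(counts)
    if (length(counts) < 2L)
        stop("need counts for at least two samples")
    zero <- counts <= 0
    if (any(zero))
        stop("zero spike count in sample(s): ",
             paste(names(counts)[zero], collapse = ", "),
             " -- cannot calibrate")
    f <- counts / .geomean(counts)
    new("SizeFactors", factors = f, scheme = scheme,
        counts = counts, metadata = list())
}

#' Input-corrected ChIP size factors
#'
#' ChIP calibration corrects the IP spike yield for how much spike
#' chromatin entered each IP: `factor_k` is proportional to the
#' IP/input spike-count ratio, anchored to geometric mean 1.  Doubling
#' both a sample's IP and input counts leaves its factor unchanged.
#'
#' @param ipCounts,inputCounts Named numeric vectors (or lists of
#'   [countSpike()] results) for matched IP and input samples.
#' @return A [SizeFactors-class] with scheme `"chip_input_corrected"`.
#' @examples
#' chipSizeFactors(c(a = 100, b = 100), c(a = 50, b = 100))
#' @export
chipSizeFactors <- function(ipCounts, inputCounts) {
    ip <- .as_count_vector(ipCounts)
    inp <- .as_count_vector(inputCounts)
    if (!setequal(names(ip), names(inp)))
        stop("unmatched sample ids between IP and input")
    inp <- inp[names(ip)]
    if (length(ip) < 2L) stop("need at least two matched IP/input pairs")
    if (any(ip <= 0))
        stop("zero IP spike count in sample(s): ",
             paste(names(ip)[ip <= 0], collapse = ", "))
    if (any(inp <= 0))
        stop("zero input spike count in sample(s): ",
             paste(names(inp)[inp <= 0], collapse = ", "))
    r <- ip / inp
    f <- r / .geomean(r)
    new("SizeFactors", factors = f, scheme = "chip_input_corrected",
        counts = ip,
        metadata = list(input_counts = inp,
                        reading = "IP/input spike-count ratio"))
}

#' H3-normalized acetylation track
#'
#' Expresses an H3K14ac coverage track as a per-base ratio to total H3
#' occupancy: `(ac + pseudocount) / (h3 + pseudocount)`.  Positions where
#' H3 falls below a floor (default: the 5th percentile of nonzero H3) are
#' masked as `NA` rather than inflated.  Both inputs must already be
#' spike-calibrated; the ratio is invariant to scaling both tracks by a
#' common constant.
#'
#' @param acTrack,h3Track [CoverageTrack-class] objects on the same
#'   chromosome grid.
#' @param pseudocount Added to numerator and denominator (normalized
#'   units).
#' @param floor H3 level below which positions are masked; `NULL` uses the
#'   5th percentile of nonzero H3 values.
#' @return A `CoverageTrack` of per-base ratios (masked positions `NA`).
#' @export
h3Normalize <- function(acTrack, h3Track, pseudocount = 1, floor = NULL) {
    stopifnot(is(acTrack, "CoverageTrack"), is(h3Track, "CoverageTrack"))
    if (!isCalibrated(acTrack) || !isCalibrated(h3Track))
        stop("both tracks must be spike-calibrated before H3 normalization")
    ac <- trackCov(acTrack); h3 <- trackCov(h3Track)
    if (!identical(names(ac), names(h3)) ||
        !identical(unname(lengths(ac)), unname(lengths(h3))))
        stop("shape error: tracks are not on the same coordinate grid")
    if (is.null(floor)) {
        v <- unlist(lapply(h3, function(r) {
            x <- runValue(r)
            x[!is.na(x) & x > 0]
        }), use.names = FALSE)
        floor <- if (length(v)) unname(quantile(v, 0.05)) else 0
    }
    out <- ac
    for (ch in names(ac)) {
        r <- (ac[[ch]] + pseudocount) / (h3[[ch]] + pseudocount)
        r[h3[[ch]] < floor] <- NA
        out[[ch]] <- r
    }
    new("CoverageTrack", cov = out, strand = trackStrand(acTrack),
        sampleId = acTrack@sampleId, calibrated = TRUE,
        units = "H3K14ac/H3 ratio")
}
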