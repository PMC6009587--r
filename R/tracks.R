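## Coverage tracks, metagene profiles, replicate correlation, bedGraph I/O.

#' Build a normalized coverage track
#'
#' Fragment mode adds `1/sizeFactor` over each fragment interval (RNA
#' density, ChIP); position mode adds `weight/sizeFactor` at single bases
#' (Pol II occupancy from [trimToPol2()]).  Total track mass times the
#' size factor equals the total input fragment-bp (fragment mode) or read
#' count (position mode).
#'
#' @param x GRanges of fragments, or width-1 GRanges with a `weight`
#'   column.
#' @param sizeFactor Positive per-sample size factor (1 = uncalibrated).
#' @param mode `"fragment"` or `"position"`.
#' @param strandFilter `"*"` keeps all records (unstranded track); `"+"` or
#'   `"-"` builds the strand-specific track from matching records.
#' @param sampleId Sample label.
#' @param calibrated Whether the factor came from spike calibration.
#' @param seqlens Optional named chromosome lengths if `x` carries none.
#' @return A [CoverageTrack-class].
#' @examples
#' gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(10, 19),
#'                              strand = "+", seqlengths = c(c1 = 100))
#' makeCoverage(gr, sampleId = "s1")
#' @export
makeCoverage <- function(x, sizeFactor = 1,
                         mode = c("fragment", "position"),
                         strandFilter = c("*", "+", "-"),
                         sampleId = "sample", calibrated = FALSE,
                         seqlens = NULL) {
    mode <- match.arg(mode)
    strandFilter <- match.arg(strandFilter)
    stopifnot(sizeFactor > 0)
    if (!is.null(seqlens)) {
        seqlevels(x) <- names(seqlens)
        seqlengths(x) <- seqlens
    }
    sl <- seqlengths(x)
    if (any(is.na(sl)))
        stop("chromosome lengths are required to build a track")
    if (length(x) && (any(start(x) < 1L) ||
                      any(end(x) > sl[as.character(seqnames(x))])))
        stop("coordinate error: fragment beyond chromosome end")
    if (strandFilter != "*")
        x <- x[strand(x) == strandFilter]
    w <- if (mode == "position") {
        if (is.null(x$weight))
            stop("position mode needs a 'weight' column")
        if (length(x) && any(width(x) != 1L))
            stop("position mode expects width-1 ranges")
        x$weight / sizeFactor
    } else rep(1 / sizeFactor, length(x))
    cov <- coverage(x, weight = w)
    ## fractional weights can leave -1e-12-scale residue in the rolling sum
    for (ch in names(cov)) {
        rv <- runValue(cov[[ch]])
        if (any(rv < 0)) {
            runValue(cov[[ch]]) <- pmax(rv, 0)
        }
    }
    new("CoverageTrack", cov = cov, strand = strandFilter,
        sampleId = sampleId, calibrated = calibrated,
        units = "normalized signal/bp")
}

#' Total mass of a coverage track
#' @param track A [CoverageTrack-class].
#' @return Sum of per-base values (NA-masked positions excluded).
#' @export
trackMass <- function(track)
    sum(vapply(trackCov(track),
               function(r) sum(as.numeric(r), na.rm = TRUE), numeric(1)))

#' TSS-anchored metagene profile
#'
#' Averages track signal over features in a fixed window around the TSS
#' (default 75 bp upstream to 300 bp downstream, the window in which
#' H3K14ac peaks at gene 5' ends).  Minus-strand features are
#' orientation-flipped before averaging; features whose window overruns a
#' chromosome edge are dropped and counted.
#'
#' @param track A [CoverageTrack-class].
#' @param features Stranded GRanges.
#' @param window Length-2 integer `c(-upstream, downstream)` around the
#'   TSS.
#' @return A [MetageneProfile-class].
#' @export
metagene <- function(track, features, window = c(-75L, 300L)) {
    if (length(features) == 0L)
        stop("usage error: empty feature set")
    window <- as.integer(window)
    stopifnot(window[1] <= 0L, window[2] >= 0L)
    cov <- trackCov(track)
    str <- as.character(strand(features))
    if (any(str == "*"))
        stop("features must be stranded (TSS is strand-dependent)")
    chrom <- as.character(seqnames(features))
    if (!all(chrom %in% names(cov)))
        stop("feature chromosome(s) missing from track")
    tss <- ifelse(str == "+", start(features), end(features))
    lo <- ifelse(str == "+", tss + window[1], tss - window[2])
    hi <- ifelse(str == "+", tss + window[2], tss - window[1])
    clen <- vapply(cov, length, numeric(1))[chrom]
    ok <- lo >= 1L & hi <= clen
    nDropped <- sum(!ok)
    if (!any(ok))
        stop("usage error: no feature window fits inside the chromosomes")
    W <- window[2] - window[1] + 1L
    acc <- matrix(0, nrow = sum(ok), ncol = W)
    row <- 1L
    for (ch in unique(chrom[ok])) {
        idx <- which(ok & chrom == ch)
        v <- Views(cov[[ch]], start = lo[idx], end = hi[idx])
        m <- matrix(as.numeric(unlist(v, use.names = FALSE)),
                    nrow = length(idx), ncol = W, byrow = TRUE)
        flip <- str[idx] == "-"
        if (any(flip))
            m[flip, ] <- m[flip, W:1, drop = FALSE]
        acc[row:(row + length(idx) - 1L), ] <- m
        row <- row + length(idx)
    }
    new("MetageneProfile",
        offsets = seq.int(window[1], window[2]),
        mean = colMeans(acc, na.rm = TRUE),
        n = sum(ok), nDropped = as.integer(nDropped), window = window)
}

#' Rank-correlation matrix of binned replicate signal
#'
#' Bins each track and computes the Spearman correlation matrix across
#' samples (ties mid-ranked, the `cor()` default).  A constant (zero
#' variance) sample yields `NA` against the others with a warning, never
#' silent NaN propagation; the diagonal stays 1.
#'
#' @param tracks Named list of [CoverageTrack-class] on the same genome.
#' @param binSize Bin width in bp.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
replicateCorrelation <- function(tracks, binSize = 50L) {
    stopifnot(length(tracks) >= 2L)
    if (is.null(names(tracks)))
        names(tracks) <- vapply(tracks, function(t) t@sampleId,
                                character(1))
    binned <- lapply(tracks, function(t) {
        cov <- trackCov(t)
        unlist(lapply(names(cov), function(ch) {
            v <- as.numeric(cov[[ch]])
            nb <- length(v) %/% binSize
            if (nb == 0L) return(numeric())
            colSums(matrix(v[seq_len(nb * binSize)], nrow = binSize),
                    na.rm = TRUE)
        }), use.names = FALSE)
    })
    nb <- lengths(binned)
    if (length(unique(nb)) != 1L)
        stop("tracks are not on the same genome/bin grid")
    mat <- do.call(cbind, binned)
    const <- apply(mat, 2L, function(x) sd(x) == 0 || !is.finite(sd(x)))
    cm <- suppressWarnings(cor(mat, method = "spearman"))
    if (any(const)) {
        warning("constant sample(s), correlation undefined: ",
                paste(names(tracks)[const], collapse = ", "))
        cm[const, ] <- NA
        cm[, const] <- NA
    }
    diag(cm) <- 1
    cm
}

#' bedGraph output / input
#'
#' Tracks are written as bedGraph (0-based half-open, handled by
#' rtracklayer), with zero and masked runs omitted and adjacent equal
#' values merged into one interval; the strand is encoded in the file name
#' by convention (e.g. `sample.plus.bedGraph`).  Reading restores the
#' full-length track given chromosome lengths; overlapping intervals are a
#' format error.
#'
#' @param track A [CoverageTrack-class].
#' @param path Output path.
#' @return `writeBedGraph`: the path, invisibly.
#' @export
writeBedGraph <- function(track, path) {
    cov <- trackCov(track)
    grl <- lapply(names(cov), function(ch) {
        r <- cov[[ch]]
        ends <- cumsum(runLength(r))
        starts <- ends - runLength(r) + 1L
        val <- runValue(r)
        keep <- !is.na(val) & val != 0
        if (!any(keep)) return(NULL)
        GRanges(factor(ch, levels = names(cov)),
                IRanges(starts[keep], ends[keep]),
                score = as.numeric(val[keep]))
    })
    grl <- grl[!vapply(grl, is.null, logical(1))]
    gr <- if (length(grl)) do.call(c, grl) else GRanges()
    .atomic_write(path, function(tmp) {
        if (length(gr) == 0L)
            writeLines("track type=bedGraph", tmp)
        else
            export(gr, tmp, format = "bedGraph")
    })
}

#' @rdname writeBedGraph
#' @param seqlens Named chromosome lengths for the restored track.
#' @param strand,sampleId,calibrated Metadata for the restored track.
#' @return `readBedGraph`: a [CoverageTrack-class].
#' @export
readBedGraph <- function(path, seqlens, strand = "*", sampleId = "sample",
                         calibrated = FALSE) {
    gr <- import(path, format = "bedGraph")
    if (length(gr) && any(countOverlaps(gr, gr) > 1L))
        stop("format error: overlapping intervals in ", path)
    seqlevels(gr) <- names(seqlens)
    seqlengths(gr) <- seqlens
    new("CoverageTrack", cov = coverage(gr, weight = gr$score),
        strand = strand, sampleId = sampleId, calibrated = calibrated,
        units = "normalized signal/bp")
}
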