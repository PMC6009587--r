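## Read-level simulation.  Expression assays (RNA-seq, NET-seq) place reads
## inside features according to the count model in drawFeatureCounts();
## ChIP assays sample fragments from a piecewise-constant per-bp intensity
## (uniform background, H3K14ac islands at mRNA 5' ends).  Ambiguous reads
## are drawn from the cassette shared between the two genomes and are
## emitted with valid placements in BOTH genomes.

SIM_ASSAYS <- c("rnaseq", "netseq", "chip_h3", "chip_h3k14ac", "chip_input")

## fragment lengths: truncated normal, clamped to [lo, hi] elementwise
.frag_lens <- function(n, mean, sd, lo, hi) {
    fl <- as.integer(round(rnorm(n, mean, sd)))
    pmin(pmax(fl, lo), hi)
}

## Place `counts[i]` reads into feature i.  Returns GRanges with feature_id
## and, for NET-seq, the sampled Pol II position (pol2).
.place_expression_reads <- function(feat, counts, assay, cfg) {
    idx <- rep(seq_along(feat), counts)
    n <- length(idx)
    sl <- seqlengths(feat)
    if (n == 0L)
        return(GRanges(seqlengths = sl))
    fs <- start(feat)[idx]; fe <- end(feat)[idx]
    fw <- fe - fs + 1L
    str <- as.character(strand(feat))[idx]
    rl <- cfg$readLength
    if (assay == "netseq") {
        ## sample the Pol II active-centre nucleotide uniformly inside the
        ## feature; the read is the nascent-RNA 3' portion ending there
        pol2 <- fs + as.integer(floor(runif(n) * fw))
        st <- ifelse(str == "+", pmax(fs, pol2 - rl + 1L), pol2)
        en <- ifelse(str == "+", pol2, pmin(fe, pol2 + rl - 1L))
        gr <- GRanges(seqnames(feat)[idx], IRanges(st, en), strand = str,
                      seqlengths = sl)
        gr$feature_id <- feat$feature_id[idx]
        gr$pol2 <- pol2
    } else {
        fl <- .frag_lens(n, cfg$fragMean, cfg$fragSd, rl, fw)
        st <- fs + as.integer(floor(runif(n) * (fw - fl + 1L)))
        gr <- GRanges(seqnames(feat)[idx], IRanges(st, width = fl),
                      strand = str, seqlengths = sl)
        gr$feature_id <- feat$feature_id[idx]
        gr$pol2 <- NA_integer_
    }
    gr
}

## Piecewise-constant ChIP intensity as a GRanges with weight column.
.chip_intensity <- function(ref, side, assay, condition, truth) {
    g <- refGenome(ref, side)
    sl <- seqlengths(g)
    if (side == "spike")  # chromatin spike: the real spike chroms, no ERCC
        sl <- sl[!grepl("^ERCC-", names(sl))]
    bg <- GRanges(names(sl), IRanges(1L, width = sl), seqlengths = sl)
    bg$weight <- 1
    if (side == "target" && assay == "chip_h3k14ac") {
        cfg <- ref@config
        feat <- refFeatures(ref, "target")
        genes <- feat[feat$biotype == "mRNA"]
        tab <- truth@table
        ac <- tab$acetyl_effect[match(genes$feature_id, tab$feature_id)]
        if (condition != "tsa") ac <- rep(1, length(genes))
        win <- cfg$acetylIslandWindow
        isl <- promoters(genes, upstream = -win[1], downstream = win[2] + 1L)
        isl <- trim(isl)
        isl$weight <- cfg$acetylIslandWeight * ac
        ## carve islands out of the background
        keepbg <- setdiff(bg, isl, ignore.strand = TRUE)
        keepbg$weight <- 1
        mcols(isl) <- mcols(isl)["weight"]
        gr <- sort(c(keepbg, isl), ignore.strand = TRUE)
        return(gr)
    }
    bg
}

.place_chip_reads <- function(intensity, n, cfg, dispersion) {
    sl <- seqlengths(intensity)
    if (n == 0L)
        return(GRanges(seqlengths = sl))
    m <- intensity$weight * width(intensity)
    w <- if (dispersion > 0)
        rgamma(length(m), shape = 1 / dispersion, scale = dispersion * m)
    else m
    w[w <= 0 | !is.finite(w)] <- 1e-12
    cnt <- as.vector(rmultinom(1L, n, w))
    idx <- rep(seq_along(intensity), cnt)
    fs <- start(intensity)[idx]; fw <- width(intensity)[idx]
    mid <- fs + as.integer(floor(runif(n) * fw))
    fl <- .frag_lens(n, cfg$fragMean, cfg$fragSd, cfg$readLength,
                     as.integer(2 * cfg$fragMean))
    st <- mid - fl %/% 2L
    chrom <- as.character(seqnames(intensity))[idx]
    en <- pmin(st + fl - 1L, sl[chrom])
    st <- pmax(st, 1L)
    gr <- GRanges(chrom, IRanges(st, en),
                  strand = sample(c("+", "-"), n, replace = TRUE),
                  seqlengths = sl)
    gr$feature_id <- NA_character_
    gr$pol2 <- NA_integer_
    gr
}

## Ambiguous reads: identical relative offsets inside the cassette copy of
## each genome, so the same read aligns to both.
.place_ambiguous <- function(ref, nAmb, assay, cfg) {
    out <- list(target = NULL, spike = NULL)
    rl <- cfg$readLength
    paired <- assay == "rnaseq"
    flen <- if (paired) min(as.integer(cfg$fragMean),
                            cfg$cassetteLength) else rl
    off <- if (nAmb > 0)
        as.integer(floor(runif(nAmb) * (cfg$cassetteLength - flen + 1L)))
    else integer()
    for (side in c("target", "spike")) {
        cass <- ref@cassette[[side]]
        sl <- seqlengths(refGenome(ref, side))
        if (nAmb == 0L) {
            out[[side]] <- GRanges(seqlengths = sl)
            next
        }
        gr <- GRanges(seqnames(cass), IRanges(start(cass) + off,
                                              width = flen),
                      strand = "+", seqlengths = sl)
        gr$feature_id <- NA_character_
        gr$pol2 <- NA_integer_
        out[[side]] <- gr
    }
    out
}

#' Simulate one sequencing library against both genomes
#'
#' Generates ground-truth read placements for one sample of one assay.
#' Expression assays (`rnaseq`, `netseq`) draw per-feature counts from the
#' calibrated count model ([drawFeatureCounts()]) and place reads within
#' features; NET-seq reads are placed so that their 3' end is the sampled
#' Pol II position.  ChIP assays (`chip_h3`, `chip_h3k14ac`, `chip_input`)
#' sample fragments from a per-bp intensity that is uniform except for
#' H3K14ac islands at mRNA 5' ends.  A configured fraction of reads is drawn
#' from the shared cassette and receives placements in both genomes.
#'
#' @param ref A [ToyReference-class].
#' @param truth A [SimTruth-class].
#' @param assay One of `"rnaseq"`, `"netseq"`, `"chip_h3"`,
#'   `"chip_h3k14ac"`, `"chip_input"`.
#' @param condition One of `"untreated"`, `"tsa"`, `"wt"`, `"rrp6d"`.
#' @param depth Library depth (fragments); defaults to the config value.
#' @param seed Integer seed.
#' @param sampleId Sample name used for read ids and file names.
#' @return A list of class `SimReads`: GRanges `target`, `spike`,
#'   `ambiguousTarget`, `ambiguousSpike` (read ids in `names()`), plus
#'   `assay`, `condition`, `sampleId`, `paired`, `readLength`, `seed`.
#' @examples
#' ref <- buildToyReference(1, simConfig(targetSize = 4e4, spikeSize = 2e4,
#'                                       nMrna = 20, nSpikeMrna = 5))
#' truth <- plantEffects(ref, seed = 2)
#' sim <- simulateAssay(ref, truth, "netseq", "untreated", depth = 2000,
#'                      seed = 3, sampleId = "net_unt_1")
#' length(sim$target)
#' @export
simulateAssay <- function(ref, truth, assay, condition = "untreated",
                          depth = NULL, seed, sampleId = "sample") {
    if (!assay %in% SIM_ASSAYS)
        stop("usage error: unknown assay '", assay, "'")
    if (!condition %in% c("untreated", "tsa", "wt", "rrp6d"))
        stop("usage error: unknown condition '", condition, "'")
    stopifnot(is(ref, "ToyReference"), is(truth, "SimTruth"))
    cfg <- ref@config
    if (is.null(depth))
        depth <- unname(cfg$depth[[if (grepl("^chip", assay)) "chip"
                                   else assay]])
    depth <- as.integer(depth)
    set.seed(as.integer(seed))
    p <- truth@params

    if (grepl("^chip", assay)) {
        nAmb <- if (depth > 0)
            stats::rbinom(1L, depth, p$ambiguousFraction) else 0L
        nRest <- depth - nAmb
        ti <- .chip_intensity(ref, "target", assay, condition, truth)
        si <- .chip_intensity(ref, "spike", assay, condition, truth)
        ## chromatin mixing at the configured ratio: spike mass scaled so
        ## that baseline target mass : spike mass = mixingRatio
        mt <- sum(width(ti) * ti$weight)
        ms <- sum(seqlengths(refGenome(ref, "target"))) / mixingRatio(truth)
        split <- if (nRest > 0)
            as.vector(rmultinom(1L, nRest, c(mt, ms))) else c(0L, 0L)
        tgt <- .place_chip_reads(ti, split[1], cfg, p$dispersion)
        spk <- .place_chip_reads(si, split[2], cfg, p$dispersion)
        ## spike GRanges must carry full spike seqlengths (incl. ERCC tigs)
        full <- seqlengths(refGenome(ref, "spike"))
        seqlevels(spk) <- names(full)
        seqlengths(spk) <- full
    } else {
        dr <- drawFeatureCounts(truth, assay, condition, depth)
        nAmb <- dr$nAmbiguous
        tgt_feat <- refFeatures(ref, "target")
        spk_feat <- refFeatures(ref, "spike")
        if (assay == "netseq")
            spk_feat <- spk_feat[spk_feat$biotype != "ercc"]
        tgt <- .place_expression_reads(
            tgt_feat, dr$counts[tgt_feat$feature_id], assay, cfg)
        spk <- .place_expression_reads(
            spk_feat, dr$counts[spk_feat$feature_id], assay, cfg)
    }
    amb <- .place_ambiguous(ref, nAmb, assay, cfg)

    mk_ids <- function(gr, tag) {
        if (length(gr))
            names(gr) <- sprintf("%s:%s%07d", sampleId, tag, seq_along(gr))
        gr
    }
    out <- list(target = mk_ids(tgt, "t"),
                spike = mk_ids(spk, "s"),
                ambiguousTarget = mk_ids(amb$target, "a"),
                ambiguousSpike = mk_ids(amb$spike, "a"),
                assay = assay, condition = condition, sampleId = sampleId,
                paired = assay == "rnaseq", readLength = cfg$readLength,
                seed = as.integer(seed))
    class(out) <- "SimReads"
    out
}

#' @export
print.SimReads <- function(x, ...) {
    cat(sprintf(
        "SimReads [%s, %s, %s]: %d target + %d spike + %d ambiguous %s\n",
        x$sampleId, x$assay, x$condition, length(x$target),
        length(x$spike), length(x$ambiguousTarget),
        if (x$paired) "fragments (paired)" else "reads"))
    invisible(x)
}
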