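#' Simulation configuration
#'
#' Assemble and validate the configuration for the two-species synthetic
#' experiment generator.  Defaults describe the study conditions the package
#' is built around: an *S. cerevisiae*-style spike lysate mixed at 50:1 with
#' the target lysate, negative-binomial count noise with dispersion 0.05, and
#' planted cryptic unstable transcripts (CUTs) of 250–1500 nt.
#'
#' @param targetSize Total target genome size in bp.
#' @param targetChroms Number of target chromosomes.
#' @param spikeSize Total spike genome size in bp (ERCC contigs are extra).
#' @param spikeChroms Number of spike chromosomes.
#' @param nMrna,nNcrna,nCut Feature counts on the target side (mRNA, ncRNA,
#'   planted CUT intervals).
#' @param nSpikeMrna,nRpSpike Spike-side mRNA and ribosomal-protein-coding
#'   gene counts (the rp subset is the NET-seq normalization set).
#' @param nErcc Number of ERCC-like exogenous transcripts, each on its own
#'   spike-side contig.
#' @param mrnaLenRange,ncrnaLenRange,cutLenRange,rpLenRange,erccLenRange
#'   Length ranges (bp) per biotype.
#' @param readLength Read length in nt.
#' @param fragMean,fragSd Fragment-length distribution (truncated normal),
#'   used for RNA-seq pairs and ChIP fragments.
#' @param mixingRatio Expected target:spike read ratio imposed by the
#'   lysate-mixing protocol (default 50, i.e. 50:1).
#' @param dispersion Negative-binomial dispersion of per-feature counts.
#' @param ambiguousFraction Fraction of reads drawn from a sequence cassette
#'   shared between the two genomes, hence truly ambiguous.
#' @param cassetteLength Length of the shared cassette (bp).
#' @param acetylIslandWindow Length-2 integer: where (relative to each mRNA
#'   TSS) the H3K14ac island is planted.
#' @param acetylIslandWeight Baseline island enrichment over flanking
#'   chromatin in the H3K14ac ChIP.
#' @param depth Named default library depths per assay.
#'
#' @return A validated list of class `SimConfig`.
#' @examples
#' cfg <- simConfig(targetSize = 2e4, spikeSize = 1e4, nMrna = 10)
#' @export
simConfig <- function(targetSize = 200000L, targetChroms = 2L,
                      spikeSize = 60000L, spikeChroms = 1L,
                      nMrna = 120L, nNcrna = 15L, nCut = 12L,
                      nSpikeMrna = 25L, nRpSpike = 20L, nErcc = 12L,
                      mrnaLenRange = c(400L, 1500L),
                      ncrnaLenRange = c(200L, 800L),
                      cutLenRange = c(250L, 1500L),
                      rpLenRange = c(400L, 1200L),
                      erccLenRange = c(400L, 1200L),
                      readLength = 50L,
                      fragMean = 200, fragSd = 40,
                      mixingRatio = 50,
                      dispersion = 0.05,
                      ambiguousFraction = 0.02,
                      cassetteLength = 600L,
                      acetylIslandWindow = c(-50L, 250L),
                      acetylIslandWeight = 3,
                      depth = c(rnaseq = 80000, netseq = 100000,
                                chip = 60000)) {
    cfg <- list(targetSize = as.integer(targetSize),
                targetChroms = as.integer(targetChroms),
                spikeSize = as.integer(spikeSize),
                spikeChroms = as.integer(spikeChroms),
                nMrna = as.integer(nMrna), nNcrna = as.integer(nNcrna),
                nCut = as.integer(nCut),
                nSpikeMrna = as.integer(nSpikeMrna),
                nRpSpike = as.integer(nRpSpike), nErcc = as.integer(nErcc),
                mrnaLenRange = as.integer(mrnaLenRange),
                ncrnaLenRange = as.integer(ncrnaLenRange),
                cutLenRange = as.integer(cutLenRange),
                rpLenRange = as.integer(rpLenRange),
                erccLenRange = as.integer(erccLenRange),
                readLength = as.integer(readLength),
                fragMean = fragMean, fragSd = fragSd,
                mixingRatio = mixingRatio,
                dispersion = dispersion,
                ambiguousFraction = ambiguousFraction,
                cassetteLength = as.integer(cassetteLength),
                acetylIslandWindow = as.integer(acetylIslandWindow),
                acetylIslandWeight = acetylIslandWeight,
                depth = depth)
    class(cfg) <- "SimConfig"
    validateSimConfig(cfg)
    cfg
}

#' @rdname simConfig
#' @param cfg A `SimConfig` list.
#' @return `validateSimConfig` returns `cfg` invisibly or stops.
#' @export
validateSimConfig <- function(cfg) {
    stopifnot(inherits(cfg, "SimConfig"))
    with(cfg, {
        if (any(c(targetSize, spikeSize, targetChroms, spikeChroms,
                  readLength, cassetteLength) <= 0L))
            stop("genome sizes, chromosome counts, read length and cassette ",
                 "length must be positive")
        if (any(c(nMrna, nNcrna, nCut, nSpikeMrna, nRpSpike, nErcc) < 0L))
            stop("feature counts must be >= 0")
        if (nRpSpike < 1L || nErcc < 1L)
            stop("the spike side needs at least one rp gene and one ERCC ",
                 "feature")
        if (mixingRatio <= 0) stop("mixingRatio must be > 0")
        if (dispersion < 0) stop("dispersion must be >= 0")
        if (ambiguousFraction < 0 || ambiguousFraction >= 1)
            stop("ambiguousFraction must be in [0, 1)")
        if (any(depth < 0)) stop("library depths must be >= 0")
        if (fragMean < readLength)
            stop("fragMean must be >= readLength")
    })
    ## sizing feasibility: features + cassette must fit
    tgt_need <- sum(mean(cfg$mrnaLenRange) * cfg$nMrna,
                    mean(cfg$ncrnaLenRange) * cfg$nNcrna,
                    mean(cfg$cutLenRange) * cfg$nCut) + cfg$cassetteLength
    spk_need <- sum(mean(cfg$rpLenRange) * cfg$nRpSpike,
                    mean(cfg$mrnaLenRange) * cfg$nSpikeMrna) +
        cfg$cassetteLength
    if (tgt_need > 0.9 * cfg$targetSize)
        stop("sizing error: requested target features need ~",
             round(tgt_need), " bp but the target genome has only ",
             cfg$targetSize, " bp")
    if (spk_need > 0.9 * cfg$spikeSize)
        stop("sizing error: requested spike features do not fit in ",
             cfg$spikeSize, " bp")
    invisible(cfg)
}
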