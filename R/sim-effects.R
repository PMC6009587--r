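## Ground-truth effect planting.  Effects are multiplicative factors on
## per-feature expression rates; the TSA response can be marked
## RNA-level-only (post-transcriptional), in which case NET-seq (nascent
## transcription) does not see it -- this is what makes the RNA/NET-seq
## concordance on the fixture a known quantity.

#' Plant condition effects onto a toy reference
#'
#' Draws per-feature base expression rates and assigns multiplicative
#' condition effects: a fraction of target mRNAs responds to HDAC inhibition
#' (TSA) up or down, planted CUT intervals are stabilized >2-fold in the
#' exosome mutant (rrp6 deletion), and TSA-up genes gain an H3K14ac island
#' effect.  A configurable fraction of the TSA-responsive genes changes at
#' the RNA level only (post-transcriptional), so nascent-transcription
#' assays do not see it.
#'
#' The spike side is scaled internally so that the expected target:spike
#' read ratio in the baseline condition equals `cfg$mixingRatio`; the
#' ERCC-like transcripts contribute a fixed expected mass (constant across
#' conditions, like a fixed spike-in amount per library).
#'
#' @param ref A [ToyReference-class].
#' @param seed Integer seed (independent of the reference seed).
#' @param tsaDownFrac,tsaUpFrac Fractions of target mRNAs down- or
#'   up-regulated under TSA.  Defaults follow the study conditions the
#'   package models: most of the genome decreases on the calibrated scale.
#' @param tsaDownFold,tsaUpFold Fold changes for the affected genes
#'   (down genes get effect `1/tsaDownFold`).
#' @param tsaRnaOnlyFrac Fraction of TSA-responsive genes whose change is
#'   RNA-level only (invisible to NET-seq).
#' @param rrp6Fold Stabilization factor of planted CUTs in the rrp6
#'   deletion (must be > 2 to be recoverable at the CUT-calling threshold).
#' @param acetylFold H3K14ac island gain on TSA-up genes under TSA.
#' @param globalShift Extra multiplicative factor applied to *all* target
#'   features under TSA (1 = none).
#' @return A [SimTruth-class] object.
#' @examples
#' ref <- buildToyReference(1, simConfig(targetSize = 4e4, spikeSize = 2e4,
#'                                       nMrna = 20, nSpikeMrna = 5))
#' truth <- plantEffects(ref, seed = 2)
#' truth
#' @export
plantEffects <- function(ref, seed,
                         tsaDownFrac = 0.70, tsaUpFrac = 0.06,
                         tsaDownFold = 3, tsaUpFold = 4,
                         tsaRnaOnlyFrac = 0.20,
                         rrp6Fold = 4, acetylFold = 3,
                         globalShift = 1) {
    stopifnot(is(ref, "ToyReference"))
    if (tsaDownFrac + tsaUpFrac > 1)
        stop("config error: affected fractions sum to more than 1")
    if (min(tsaDownFold, tsaUpFold, rrp6Fold, acetylFold, globalShift) <= 0)
        stop("all fold parameters must be positive")
    seed <- as.integer(seed)
    set.seed(seed)

    tgt <- refFeatures(ref, "target")
    spk <- refFeatures(ref, "spike")
    tab <- DataFrame(
        feature_id = c(tgt$feature_id, spk$feature_id),
        species = rep(c("target", "spike"), c(length(tgt), length(spk))),
        biotype = c(tgt$biotype, spk$biotype),
        length = c(width(tgt), width(spk)))

    ## base per-bp rates: broad lognormal for genes, low WT rate for CUTs
    n <- nrow(tab)
    rate <- exp(rnorm(n, 0, 0.8))
    rate[tab$biotype == "ncRNA"] <- 0.4 * exp(rnorm(sum(tab$biotype ==
        "ncRNA"), 0, 0.5))
    rate[tab$biotype == "planted_CUT"] <- 0.08 * exp(rnorm(sum(tab$biotype ==
        "planted_CUT"), 0, 0.3))
    rate[tab$biotype == "ercc"] <- exp(rnorm(sum(tab$biotype == "ercc"),
        0, 1))
    tab$base_rate <- rate

    ## TSA effects on target mRNAs
    tab$tsa_effect <- rep(1, n)
    tab$tsa_rna_only <- rep(FALSE, n)
    mi <- which(tab$species == "target" & tab$biotype == "mRNA")
    nDown <- round(tsaDownFrac * length(mi))
    nUp <- round(tsaUpFrac * length(mi))
    pick <- sample(mi, nDown + nUp)
    down <- pick[seq_len(nDown)]
    up <- if (nUp > 0) pick[nDown + seq_len(nUp)] else integer()
    tab$tsa_effect[down] <- 1 / tsaDownFold
    tab$tsa_effect[up] <- tsaUpFold
    affected <- c(down, up)
    nRnaOnly <- round(tsaRnaOnlyFrac * length(affected))
    if (nRnaOnly > 0)
        tab$tsa_rna_only[sample(affected, nRnaOnly)] <- TRUE

    ## rrp6 deletion stabilizes planted CUTs (RNA level)
    tab$rrp6_effect <- rep(1, n)
    tab$rrp6_effect[tab$biotype == "planted_CUT"] <- rrp6Fold

    ## acetylation islands gain on TSA-up genes
    tab$acetyl_effect <- rep(1, n)
    tab$acetyl_effect[up] <- acetylFold

    ## spike scaling so baseline target:spike mass ratio = mixingRatio
    massT0 <- sum(tab$base_rate[tab$species == "target"] *
                  tab$length[tab$species == "target"])
    sg <- tab$species == "spike" & tab$biotype != "ercc"
    massS0 <- sum(tab$base_rate[sg] * tab$length[sg])
    eg <- tab$biotype == "ercc"
    massE0 <- sum(tab$base_rate[eg] * tab$length[eg])
    cfg <- ref@config
    params <- list(spikeScale = massT0 / (cfg$mixingRatio * massS0),
                   erccScale = 0.02 * massT0 / massE0,
                   dispersion = cfg$dispersion,
                   ambiguousFraction = cfg$ambiguousFraction,
                   globalShift = globalShift,
                   tsaDownFrac = tsaDownFrac, tsaUpFrac = tsaUpFrac,
                   tsaDownFold = tsaDownFold, tsaUpFold = tsaUpFold,
                   tsaRnaOnlyFrac = tsaRnaOnlyFrac,
                   rrp6Fold = rrp6Fold, acetylFold = acetylFold)

    new("SimTruth", table = tab, mixingRatio = cfg$mixingRatio,
        seed = seed, params = params)
}

## Per-feature condition effect for an expression assay.
## rrp6 stabilization and RNA-only TSA effects are RNA-level phenomena:
## NET-seq (nascent transcription) does not see them.
.condition_effect <- function(tab, assay, condition, globalShift = 1) {
    eff <- rep(1, nrow(tab))
    if (condition == "tsa") {
        eff <- tab$tsa_effect
        if (assay == "netseq")
            eff[tab$tsa_rna_only] <- 1
        eff[tab$species == "target"] <-
            eff[tab$species == "target"] * globalShift
    } else if (condition == "rrp6d" && assay == "rnaseq") {
        eff <- tab$rrp6_effect
    } else if (!condition %in% c("untreated", "wt", "rrp6d")) {
        stop("usage error: unknown condition '", condition, "'")
    }
    eff
}

#' Draw per-feature read counts for one simulated library
#'
#' The count model behind [simulateAssay()], exposed directly so that
#' count-level simulations (null calibration of the NB test, the
#' spike-vs-naive normalization contrast) can run without read placement.
#' Sampling is two-stage: the species split (target / spike / ambiguous) is
#' multinomial at the expected mass ratio -- the lysate-mixing ratio is a
#' controlled physical quantity, so species totals carry only read-sampling
#' error -- and within each species reads are allocated by gamma-weighted
#' multinomial, which gives per-feature counts that are negative-binomial
#' with the configured dispersion to a very good approximation.
#'
#' @param truth A [SimTruth-class].
#' @param assay `"rnaseq"` or `"netseq"` (ChIP assays are fragment-level
#'   only; see [simulateAssay()]).
#' @param condition One of `"untreated"`, `"tsa"`, `"wt"`, `"rrp6d"`.
#' @param depth Total library depth (reads / read pairs).
#' @param seed Optional integer seed.
#' @return A list: `counts` (named integer per feature), `species`
#'   (parallel character vector), `nAmbiguous`.
#' @export
drawFeatureCounts <- function(truth, assay = c("rnaseq", "netseq"),
                              condition = "untreated", depth, seed = NULL) {
    assay <- match.arg(assay)
    stopifnot(is(truth, "SimTruth"), depth >= 0)
    if (!is.null(seed)) set.seed(as.integer(seed))
    p <- truth@params
    tab <- truth@table
    ## ERCC transcripts are an RNA spike-in: present in RNA-seq only
    if (assay == "netseq")
        tab <- tab[tab$biotype != "ercc", , drop = FALSE]

    eff <- .condition_effect(tab, assay, condition, p$globalShift)
    mass <- tab$base_rate * tab$length * eff
    sg <- tab$species == "spike" & tab$biotype != "ercc"
    mass[sg] <- mass[sg] * p$spikeScale
    mass[tab$biotype == "ercc"] <- mass[tab$biotype == "ercc"] * p$erccScale

    counts <- setNames(integer(nrow(tab)), tab$feature_id)
    nAmb <- 0L
    if (depth > 0) {
        nAmb <- stats::rbinom(1L, as.integer(depth), p$ambiguousFraction)
        nRest <- as.integer(depth) - nAmb
        isT <- tab$species == "target"
        split <- as.vector(rmultinom(1L, nRest,
                                     c(sum(mass[isT]), sum(mass[!isT]))))
        for (side in c(TRUE, FALSE)) {
            idx <- which(isT == side)
            nSide <- split[if (side) 1L else 2L]
            if (nSide == 0L) next
            m <- mass[idx]
            w <- if (p$dispersion > 0)
                rgamma(length(m), shape = 1 / p$dispersion,
                       scale = p$dispersion * m)
            else m
            w[w <= 0 | !is.finite(w)] <- 1e-12
            counts[idx] <- as.vector(rmultinom(1L, nSide, w))
        }
    }
    list(counts = counts, species = tab$species, nAmbiguous = nAmb)
}
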