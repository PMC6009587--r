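## Central S4 containers.  Sequence data live in Biostrings objects, intervals
## in GRanges, per-base signal in RleList; these classes only add the metadata
## the pipeline needs to keep calibration honest (species tags, size-factor
## schemes, calibration flags).

VALID_BIOTYPES <- c("mRNA", "ncRNA", "planted_CUT", "spike_rp_gene", "ercc")
VALID_SPECIES  <- c("target", "spike")
VALID_SCHEMES  <- c("total_spike", "rp_spike", "ercc", "chip_input_corrected")

#' ToyGenome: one species' synthetic genome
#'
#' A set of named chromosome sequences plus a species tag (`"target"` for the
#' organism under study, `"spike"` for the calibration species whose material
#' is mixed into every library at a fixed ratio).
#'
#' @slot species Either `"target"` or `"spike"`.
#' @slot seqs A [Biostrings::DNAStringSet] of chromosome sequences, uniquely
#'   named.
#' @exportClass ToyGenome
setClass("ToyGenome",
    slots = c(species = "character", seqs = "DNAStringSet"))

setValidity("ToyGenome", function(object) {
    msg <- character()
    if (length(object@species) != 1L || !object@species %in% VALID_SPECIES)
        msg <- c(msg, "species must be one of 'target', 'spike'")
    nm <- names(object@seqs)
    if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
        msg <- c(msg, "chromosome names must be unique and non-empty")
    if (length(object@seqs) == 0L || any(lengths(object@seqs) == 0L))
        msg <- c(msg, "chromosome sequences must be non-empty")
    if (length(msg)) msg else TRUE
})

#' ToyReference: paired target/spike reference with annotations
#'
#' The complete two-species reference a simulated experiment is built on:
#' both genomes, their feature annotations (GRanges with `feature_id` and
#' `biotype` metadata columns), the shared-sequence cassette used to create
#' genuinely ambiguous reads, and the configuration and seed that produced it.
#'
#' @slot genomes Named list with `ToyGenome` elements `target` and `spike`.
#' @slot annotations Named list with [GenomicRanges::GRanges] elements
#'   `target` and `spike`; metadata columns `feature_id`, `biotype`.
#' @slot cassette Named list of GRanges giving the location of the shared
#'   sequence cassette in each genome (used for ambiguous-read simulation).
#' @slot config The [simConfig()] list used to build the reference.
#' @slot seed Integer seed.
#' @exportClass ToyReference
setClass("ToyReference",
    slots = c(genomes = "list", annotations = "list", cassette = "list",
              config = "list", seed = "integer"))

setValidity("ToyReference", function(object) {
    msg <- character()
    if (!identical(sort(names(object@genomes)), sort(VALID_SPECIES)))
        msg <- c(msg, "genomes must be a list with elements 'target','spike'")
    if (!identical(sort(names(object@annotations)), sort(VALID_SPECIES)))
        msg <- c(msg, "annotations must have elements 'target','spike'")
    if (length(msg)) return(msg)
    for (sp in VALID_SPECIES) {
        g <- object@genomes[[sp]]
        a <- object@annotations[[sp]]
        if (!is(g, "ToyGenome") || g@species != sp)
            msg <- c(msg, sprintf("genomes$%s must be a ToyGenome tagged '%s'",
                                  sp, sp))
        if (!is(a, "GRanges") ||
            !all(c("feature_id", "biotype") %in% names(mcols(a)))) {
            msg <- c(msg, sprintf(
                "annotations$%s needs feature_id and biotype columns", sp))
            next
        }
        if (anyDuplicated(a$feature_id))
            msg <- c(msg, sprintf("duplicate feature_id on %s side", sp))
        if (!all(a$biotype %in% VALID_BIOTYPES))
            msg <- c(msg, "unknown biotype")
        sl <- seqlengths(g)
        bad <- end(a) > sl[as.character(seqnames(a))] | start(a) < 1L
        if (any(bad))
            msg <- c(msg, sprintf("features out of bounds on %s side", sp))
    }
    spike_only <- c("spike_rp_gene", "ercc")
    if (any(object@annotations$target$biotype %in% spike_only))
        msg <- c(msg, "spike_rp_gene/ercc biotypes are spike-side only")
    if (length(msg)) msg else TRUE
})

#' SimTruth: planted ground truth for a simulated experiment
#'
#' Per-feature expression rates and planted multiplicative effects (TSA
#' response, rrp6-deletion stabilization, acetylation change), plus the
#' target:spike mixing ratio the lysate-mixing protocol imposes.
#'
#' @slot table A [S4Vectors::DataFrame] with one row per feature (both
#'   species): `feature_id`, `species`, `biotype`, `length`, `base_rate`,
#'   `tsa_effect`, `rrp6_effect`, `acetyl_effect`.
#' @slot mixingRatio Expected target:spike read ratio (e.g. 50 for the 50:1
#'   lysate-mixing protocol).
#' @slot seed Integer seed.
#' @slot params List of the planting parameters used.
#' @exportClass SimTruth
setClass("SimTruth",
    slots = c(table = "DataFrame", mixingRatio = "numeric",
              seed = "integer", params = "list"))

setValidity("SimTruth", function(object) {
    msg <- character()
    need <- c("feature_id", "species", "biotype", "length", "base_rate",
              "tsa_effect", "rrp6_effect", "acetyl_effect")
    if (!all(need %in% colnames(object@table)))
        msg <- c(msg, paste("truth table needs columns:",
                            paste(need, collapse = ", ")))
    else {
        eff <- unlist(as.list(object@table[, c("base_rate", "tsa_effect",
                                               "rrp6_effect",
                                               "acetyl_effect")]))
        if (any(eff <= 0)) msg <- c(msg, "rates and effects must be > 0")
    }
    if (length(object@mixingRatio) != 1L || object@mixingRatio <= 0)
        msg <- c(msg, "mixingRatio must be a single positive number")
    if (length(msg)) msg else TRUE
})

#' SizeFactors: per-sample spike-derived calibration scalars
#'
#' Positive per-sample scalars anchored to geometric mean 1 within a
#' comparison group.  Dividing a sample's raw signal by its factor makes the
#' spike signal flat across samples, so cross-condition comparisons are made
#' on the spike scale rather than the (possibly globally shifted) target
#' scale.
#'
#' @slot factors Named positive numeric, geometric mean 1.
#' @slot scheme One of `"total_spike"`, `"rp_spike"`, `"ercc"`,
#'   `"chip_input_corrected"`.
#' @slot counts The raw per-sample spike quantities the factors derive from.
#' @slot metadata Free-form list (e.g. the IP/input reading used for ChIP).
#' @exportClass SizeFactors
setClass("SizeFactors",
    slots = c(factors = "numeric", scheme = "character",
              counts = "numeric", metadata = "list"))

setValidity("SizeFactors", function(object) {
    msg <- character()
    f <- object@factors
    if (is.null(names(f)) || anyDuplicated(names(f)))
        msg <- c(msg, "factors must be uniquely named by sample")
    if (any(!is.finite(f)) || any(f <= 0))
        msg <- c(msg, "all size factors must be finite and > 0")
    else if (abs(mean(log(f))) > 1e-8)
        msg <- c(msg, "size factors must have geometric mean 1")
    if (length(object@scheme) != 1L || !object@scheme %in% VALID_SCHEMES)
        msg <- c(msg, paste("scheme must be one of:",
                            paste(VALID_SCHEMES, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' CoverageTrack: strand-specific per-base signal
#'
#' Per-base signal over a genome (RNA density, Pol II occupancy, H3 or
#' H3K14ac ChIP) as an [IRanges::RleList], one run-length-encoded vector per
#' chromosome.  Values are non-negative; masked positions (e.g. H3 below the
#' normalization floor) are `NA`.
#'
#' @slot cov An `RleList`, one element per chromosome, full chromosome length.
#' @slot strand `"+"`, `"-"` or `"*"` (unstranded).
#' @slot sampleId Sample identifier.
#' @slot calibrated `TRUE` once the track is on the spike/ERCC scale.
#' @slot units Free-text unit label.
#' @exportClass CoverageTrack
setClass("CoverageTrack",
    slots = c(cov = "RleList", strand = "character", sampleId = "character",
              calibrated = "logical", units = "character"))

setValidity("CoverageTrack", function(object) {
    msg <- character()
    if (!object@strand %in% c("+", "-", "*"))
        msg <- c(msg, "strand must be '+', '-' or '*'")
    v <- suppressWarnings(min(min(object@cov), na.rm = TRUE))
    if (is.finite(v) && v < -1e-9)
        msg <- c(msg, "coverage values must be >= 0 or NA")
    if (length(msg)) msg else TRUE
})

#' MetageneProfile: TSS-anchored average signal
#'
#' Mean signal per offset relative to feature TSSs, orientation-flipped for
#' minus-strand features, over a fixed window (default 75 bp upstream to
#' 300 bp downstream).
#'
#' @slot offsets Integer offsets (negative = upstream of TSS).
#' @slot mean Mean signal per offset across features.
#' @slot n Number of features averaged.
#' @slot nDropped Features dropped because their window overran a chromosome.
#' @slot window Length-2 integer, `c(-upstream, downstream)`.
#' @exportClass MetageneProfile
setClass("MetageneProfile",
    slots = c(offsets = "integer", mean = "numeric", n = "integer",
              nDropped = "integer", window = "integer"))

setValidity("MetageneProfile", function(object) {
    msg <- character()
    if (length(object@offsets) != length(object@mean))
        msg <- c(msg, "offsets and mean must have equal length")
    if (length(object@offsets) !=
        object@window[2] - object@window[1] + 1L)
        msg <- c(msg, "offset count must equal window span + 1")
    if (object@n <= 0L) msg <- c(msg, "n must be positive")
    if (length(msg)) msg else TRUE
})
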