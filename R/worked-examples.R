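## Small, fully executable numeric checks: deletion-interval arithmetic in
## the signed "ATG = 1" coordinate convention, and the mixing-ratio
## recovery harness.

#' Locus intervals in the signed ATG-anchored convention
#'
#' Coordinates are signed bp positions relative to a translation start
#' ("ATG = 1"): position 1 is the A of the ATG, position -1 the base just
#' upstream; there is no position 0.  Interval length is `|end - start|`,
#' which holds on either side of the anchor and across it (the missing
#' zero cancels).
#'
#' @param label Character labels.
#' @param start,end Signed endpoint positions.  The ATG-anchored genome
#'   conversion ([atgToGenome()]) rejects position 0; plain interval
#'   arithmetic does not need to.
#' @return A data.frame of class `LocusIntervals`.
#' @export
locusIntervals <- function(label, start, end) {
    stopifnot(length(label) == length(start), length(start) == length(end))
    structure(data.frame(label = label, start = as.integer(start),
                         end = as.integer(end),
                         stringsAsFactors = FALSE),
              class = c("LocusIntervals", "data.frame"))
}

#' The five phosphate-locus ncRNA promoter-proximal deletions
#'
#' The deletion series tiled across the 5' proximal region of the
#' *prt* lncRNA (upstream of *pho1*, ATG = 1 convention).  A sixth
#' interval (-630 to -441) could not be constructed and is therefore not
#' part of the series.
#'
#' @return A `LocusIntervals` data.frame of the five deletions.
#' @examples
#' intervalLengths(prtDeletions())
#' @export
prtDeletions <- function() {
    locusIntervals(
        label = paste0("prt-", 1:5),
        start = c(-1197L, -1008L, -819L, -441L, -252L),
        end   = c(-1008L,  -819L, -630L, -252L,  -63L))
}

#' Interval lengths and common length
#'
#' @param intervals A [locusIntervals()] data.frame.
#' @return List with `lengths` (named per interval), `common` (the shared
#'   length if all are equal, otherwise `NA`) and `allEqual`.
#' @export
intervalLengths <- function(intervals) {
    stopifnot(inherits(intervals, "LocusIntervals"),
              nrow(intervals) >= 1L)
    len <- abs(intervals$end - intervals$start)
    if (any(len == 0L)) stop("zero-length interval")
    names(len) <- intervals$label
    allEq <- length(unique(len)) == 1L
    list(lengths = len, common = if (allEq) len[[1]] else NA_integer_,
         allEqual = allEq)
}

#' Convert a signed ATG-anchored position to a genome coordinate
#'
#' @param pos Signed positions (no zero).
#' @param atg 1-based genome coordinate of the A of the ATG.
#' @return 1-based genome coordinates.
#' @examples
#' atgToGenome(c(-1, 1), atg = 1000)  # 999, 1000
#' @export
atgToGenome <- function(pos, atg) {
    if (any(pos == 0L)) stop("no position 0 in the ATG = 1 convention")
    ifelse(pos > 0L, atg + pos - 1L, atg + pos)
}

#' Estimate the target:spike mixing ratio from disambiguated reads
#'
#' `ratio = |unique_target| / |unique_spike|`, with a Wilson confidence
#' interval on the spike fraction transformed to the ratio scale.
#'
#' @param disamb Result of [disambiguate()] (or a list with
#'   `unique_target` / `unique_spike`).
#' @param conf Confidence level for the Wilson interval.
#' @return List with `ratio`, `n_target`, `n_spike`, `spike_fraction`,
#'   `conf_int` (ratio scale) and `conf`.
#' @export
mixingRatioEstimate <- function(disamb, conf = 0.99) {
    nt <- length(disamb$unique_target)
    ns <- length(disamb$unique_spike)
    if (ns == 0L) {
        warning("zero spike reads: mixing ratio undefined")
        return(list(ratio = NA_real_, n_target = nt, n_spike = 0L,
                    spike_fraction = 0, conf_int = c(NA_real_, NA_real_),
                    conf = conf))
    }
    n <- nt + ns
    phat <- ns / n
    z <- stats::qnorm(1 - (1 - conf) / 2)
    den <- 1 + z^2 / n
    ctr <- (phat + z^2 / (2 * n)) / den
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / den
    pl <- max(ctr - half, .Machine$double.eps)
    pu <- min(ctr + half, 1)
    list(ratio = nt / ns, n_target = nt, n_spike = ns,
         spike_fraction = phat,
         conf_int = c((1 - pu) / pu, (1 - pl) / pl), conf = conf)
}
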