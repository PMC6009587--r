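## Calibrated differential expression: feature counting, a negative-binomial
## two-group Wald test with *imposed* size factors (the spike factors are
## the whole point -- they are never re-estimated from target counts),
## Benjamini-Hochberg adjustment, two-fold classification, and cross-assay
## concordance.

#' Count fragments per feature
#'
#' A fragment is counted for a feature iff they overlap by at least 1 bp
#' and the strand rule is satisfied (`sense`: same strand, `antisense`:
#' opposite strand, `ignore`: any).  Unstranded fragments match either
#' strand.  A fragment overlapping k features contributes to each (union
#' counting).
#'
#' @param frags GRanges of disambiguated target fragments or Pol II
#'   positions.
#' @param annotation GRanges with a `feature_id` column.
#' @param strandRule `"sense"`, `"antisense"` or `"ignore"`.
#' @return Named integer vector of counts per feature.
#' @export
countFeatures <- function(frags, annotation,
                          strandRule = c("sense", "antisense", "ignore")) {
    strandRule <- match.arg(strandRule)
    sl_f <- seqlevels(frags)
    miss <- setdiff(unique(as.character(seqnames(annotation))), sl_f)
    if (length(miss))
        stop("annotation/genome chromosome mismatch: ",
             paste(miss, collapse = ", "))
    ann <- annotation
    if (strandRule == "antisense")
        strand(ann) <- ifelse(strand(ann) == "+", "-",
                              ifelse(strand(ann) == "-", "+", "*"))
    cnt <- countOverlaps(ann, frags,
                         ignore.strand = strandRule == "ignore")
    setNames(as.integer(cnt), annotation$feature_id)
}

#' Assemble a count matrix across samples
#'
#' @param countsList Named list of [countFeatures()] vectors (identical
#'   feature sets).
#' @param colData Optional data.frame of sample metadata.
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`.
#' @export
buildCountMatrix <- function(countsList, colData = NULL) {
    stopifnot(length(countsList) >= 1L, !is.null(names(countsList)))
    ids <- names(countsList[[1]])
    for (x in countsList)
        if (!identical(names(x), ids))
            stop("count vectors disagree on the feature set")
    mat <- do.call(cbind, countsList)
    se <- SummarizedExperiment(assays = list(counts = mat))
    if (!is.null(colData))
        colData(se) <- S4Vectors::DataFrame(colData,
                                            row.names = colnames(mat))
    se
}

.count_matrix <- function(counts) {
    if (is(counts, "SummarizedExperiment"))
        counts <- assay(counts, "counts")
    stopifnot(is.matrix(counts), !is.null(colnames(counts)))
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be nonnegative integers")
    counts
}

## dispersion trend a0 + a1/mu fitted robustly to the moment estimates
.fit_dispersion_trend <- function(alpha, mu) {
    use <- is.finite(alpha) & is.finite(mu) & mu > 1 & alpha > 1e-8
    if (sum(use) < 10L)
        return(function(m) rep(max(median(alpha[is.finite(alpha)],
                                          na.rm = TRUE), 1e-8),
                               length(m)))
    fit <- tryCatch(
        MASS::rlm(alpha[use] ~ I(1 / mu[use]), maxit = 50),
        error = function(e) NULL)
    if (is.null(fit)) {
        med <- max(median(alpha[use]), 1e-8)
        return(function(m) rep(med, length(m)))
    }
    a0 <- max(coef(fit)[1], 1e-8)
    a1 <- max(coef(fit)[2], 0)
    function(m) pmax(a0 + a1 / pmax(m, 1e-8), 1e-8)
}

#' Negative-binomial two-group test with imposed size factors
#'
#' Normalizes counts by the supplied (spike-derived) size factors,
#' estimates per-feature dispersion by moments, shrinks it toward a fitted
#' mean-dispersion trend, and tests the group log2 fold change with a
#' Wald statistic.  The size factors are taken as given -- calibration is
#' external -- which is what lets a genuinely global expression shift be
#' detected instead of being normalized away.
#'
#' @param counts Integer matrix (features x samples) or a
#'   SummarizedExperiment with a `counts` assay.
#' @param factors A [SizeFactors-class] or named positive numeric vector
#'   covering all samples.
#' @param groups Two-level factor (or character) along samples; the fold
#'   change is `second level / first level` (set the baseline with
#'   `relevel` or the `ref` argument).
#' @param ref Optional reference (baseline) group level.
#' @param dispersion Optional fixed dispersion (scalar or per-feature);
#'   when supplied, groups with a single sample are allowed (Poisson limit
#'   at `dispersion = 0`).
#' @param priorCount Prior count per normalized library added when
#'   computing fold changes, keeping estimates finite at zero counts.
#' @param priorDf Strength of the shrinkage toward the dispersion trend,
#'   in pseudo-degrees-of-freedom.
#' @return A [S4Vectors::DataFrame]: `feature_id`, `baseMeanNorm`,
#'   `log2fc`, `p`, `dispersion`.
#' @export
nbTest <- function(counts, factors, groups, ref = NULL,
                   dispersion = NULL, priorCount = 0.5, priorDf = 10) {
    K <- .count_matrix(counts)
    s <- if (is(factors, "SizeFactors")) factorValues(factors) else factors
    if (!all(colnames(K) %in% names(s)))
        stop("size factors do not cover all samples")
    s <- s[colnames(K)]
    stopifnot(all(s > 0))
    groups <- as.factor(as.character(groups))
    if (nlevels(groups) != 2L)
        stop("groups must have exactly two levels")
    if (!is.null(ref)) groups <- stats::relevel(groups, ref)
    n_g <- table(groups)
    if (is.null(dispersion) && any(n_g < 2L))
        stop("refusing to test: need >= 2 samples per group to estimate ",
             "dispersion (or supply 'dispersion')")

    g1 <- groups == levels(groups)[1]
    g2 <- !g1
    y <- sweep(K, 2L, s, "/")
    mu <- rowMeans(y)

    if (is.null(dispersion)) {
        ## pooled within-group moments, Poisson part removed on the
        ## normalized scale (Var(K/s) = mu/s + alpha mu^2)
        resid2 <- (y[, g1, drop = FALSE] -
                   rowMeans(y[, g1, drop = FALSE]))^2
        resid2 <- cbind(resid2, (y[, g2, drop = FALSE] -
                                 rowMeans(y[, g2, drop = FALSE]))^2)
        df <- ncol(K) - 2L
        v <- rowSums(resid2) / df
        cbar <- mean(1 / s)
        alphaMoM <- (v - mu * cbar) / mu^2
        alphaMoM[!is.finite(alphaMoM)] <- NA
        alphaMoM <- pmin(pmax(alphaMoM, 1e-8), 10)
        trend <- .fit_dispersion_trend(alphaMoM, mu)
        alphaTr <- trend(mu)
        alpha <- (df * alphaMoM + priorDf * alphaTr) / (df + priorDf)
        alpha[is.na(alpha)] <- alphaTr[is.na(alpha)]
    } else {
        alpha <- rep_len(pmax(dispersion, 0), nrow(K))
    }

    groupStats <- function(g) {
        S <- sum(s[g]); n <- sum(g)
        m <- (rowSums(K[, g, drop = FALSE]) + priorCount * n) / S
        ## Var(m) = sum_j (s_j m + alpha s_j^2 m^2) / S^2
        Vlog <- (S * m + alpha * sum(s[g]^2) * m^2) / (S * m)^2
        list(m = m, Vlog = Vlog)
    }
    st1 <- groupStats(g1)
    st2 <- groupStats(g2)
    lfc <- log2(st2$m / st1$m)
    z <- log(st2$m / st1$m) / sqrt(st1$Vlog + st2$Vlog)
    p <- pmin(pmax(2 * pnorm(-abs(z)), .Machine$double.xmin), 1)
    DataFrame(feature_id = rownames(K) %||% as.character(seq_len(nrow(K))),
              baseMeanNorm = unname(mu), log2fc = unname(lfc),
              p = unname(p), dispersion = unname(alpha))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_i = min over j with p_j >= p_i of (m * p_(j) / rank_j)`, capped at 1;
#' monotone in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same order as `p`.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (length(p) == 0L) return(numeric())
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    q <- numeric(m)
    q[o] <- pmin(1, cummin(m * p[o] / seq.int(m, 1)))
    q
}

#' Classify features at a fold-change and significance threshold
#'
#' `up` iff `log2fc >= log2(fcThreshold)` and `q < alpha`; `down` iff
#' `log2fc <= -log2(fcThreshold)` and `q < alpha`; otherwise `no_change`.
#'
#' @param res Result of [nbTest()]; a `q` column is added via [bhAdjust()]
#'   if absent.
#' @param fcThreshold Fold-change threshold (default 2).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `res` with `q` and `class` columns; class counts in
#'   `metadata(res)$classCounts`.
#' @export
classifyDE <- function(res, fcThreshold = 2, alpha = 0.05) {
    if (!"q" %in% colnames(res))
        res$q <- bhAdjust(res$p)
    lt <- log2(fcThreshold)
    cls <- rep("no_change", nrow(res))
    cls[res$log2fc >= lt & res$q < alpha] <- "up"
    cls[res$log2fc <= -lt & res$q < alpha] <- "down"
    res$class <- cls
    metadata(res)$classCounts <- c(up = sum(cls == "up"),
                                   down = sum(cls == "down"),
                                   no_change = sum(cls == "no_change"))
    res
}

#' Cross-assay concordance of fold-change calls
#'
#' Among features called at least two-fold up or down in the first assay
#' (e.g. RNA-seq), the fraction that receives the same-direction call in
#' the second assay (e.g. NET-seq), plus the Venn overlap of the up and
#' down sets.
#'
#' @param callsA,callsB Classified results ([classifyDE()]) sharing a
#'   feature universe.
#' @return List with `fraction`, `nChanged`, `venn_up`, `venn_down`.
#' @export
concordance <- function(callsA, callsB) {
    shared <- intersect(callsA$feature_id, callsB$feature_id)
    if (length(shared) == 0L)
        stop("disjoint feature universes")
    a <- setNames(callsA$class, callsA$feature_id)[shared]
    b <- setNames(callsB$class, callsB$feature_id)[shared]
    changed <- a != "no_change"
    frac <- if (any(changed)) mean(a[changed] == b[changed]) else NA_real_
    venn <- function(cls) {
        A <- shared[a == cls]; B <- shared[b == cls]
        c(only_A = length(setdiff(A, B)), both = length(intersect(A, B)),
          only_B = length(setdiff(B, A)))
    }
    list(fraction = frac, nChanged = sum(changed),
         venn_up = venn("up"), venn_down = venn("down"))
}
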