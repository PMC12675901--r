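## Statistics core: spike-in median-of-ratios size factors, method-of-moments
## negative-binomial dispersion, Wald differential expression, BH adjustment
## and threshold calling.  The normalization is the scientific crux: under an
## acute, genome-wide transcriptional shutdown, library-size (all-features)
## scaling erases the global signal, whereas exogenous spike-ins of constant
## abundance anchor the per-sample scale.

#' Median-of-ratios size factors, optionally from spike-ins only
#'
#' For each eligible reference feature (spike-ins when
#' `useSpikeinsOnly = TRUE`, all features otherwise) with non-zero counts in
#' every sample, the pseudo-reference is the geometric mean of its counts
#' across samples.  The raw factor of sample *j* is the median over
#' reference features of `count[f, j] / reference[f]`; factors are rescaled
#' so that their geometric mean is 1.
#'
#' Because spike-in RNAs are added at constant amounts per sample, factors
#' computed from them are invariant to arbitrary fold changes applied to the
#' biological features, which is what makes a global down-regulation
#' detectable at all.
#'
#' @param x a [DegronExperiment-class] or a counts matrix.
#' @param useSpikeinsOnly restrict the reference to spike-in features
#'   (default `TRUE` when any are flagged).
#' @param isSpikein logical row flags; only needed when `x` is a bare
#'   matrix.
#' @return named numeric vector of per-sample factors (geometric mean 1)
#'   with attribute `"method"` set to `"spikein"` or `"all_features"`.
#' @examples
#' k <- rbind(spike1 = c(10, 20), spike2 = c(20, 40), spike3 = c(40, 80))
#' colnames(k) <- c("A", "B")
#' calcSizeFactors(k, isSpikein = rep(TRUE, 3))  # (1/sqrt(2), sqrt(2))
#' @export
calcSizeFactors <- function(x, useSpikeinsOnly = NULL, isSpikein = NULL) {
    if (is(x, "DegronExperiment")) {
        isSpikein <- isSpikein(x)
        k <- counts(x)
    } else {
        k <- as.matrix(x)
        if (is.null(isSpikein)) isSpikein <- rep(FALSE, nrow(k))
    }
    if (is.null(useSpikeinsOnly)) useSpikeinsOnly <- any(isSpikein)
    rows <- if (useSpikeinsOnly) which(isSpikein) else seq_len(nrow(k))
    if (useSpikeinsOnly && !length(rows))
        stop("no spike-in features flagged; add spike-ins or set ",
             "useSpikeinsOnly = FALSE")
    rows <- rows[rowSums(k[rows, , drop = FALSE] == 0) == 0]
    if (!length(rows))
        stop("no reference feature has non-zero counts in every sample; ",
             "more (or deeper) spike-ins are needed")
    logk <- log(k[rows, , drop = FALSE])
    ref <- exp(rowMeans(logk))
    raw <- apply(k[rows, , drop = FALSE] / ref, 2, median)
    sf <- raw / exp(mean(log(raw)))
    names(sf) <- colnames(k)
    attr(sf, "method") <- if (useSpikeinsOnly) "spikein" else "all_features"
    sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-feature dispersion `alpha` in the NB parameterization
#' `Var = mu + alpha * mu^2`, estimated on size-factor-normalized counts by
#' pooling within-group variances:
#' `alpha = max(eps, (v - m) / m^2)` with the pooled within-group variance
#' `v`, the overall normalized mean `m`, and floor `eps = 1e-8`.  All-zero
#' features get the floor (flagged via attribute `"allZero"`).
#'
#' @param x a [DegronExperiment-class] or counts matrix.
#' @param sizeFactors per-sample factors (default [calcSizeFactors()]).
#' @param groups factor of group labels per sample (default the condition
#'   labels); at least one group needs two replicates.
#' @return numeric vector of dispersions, one per feature.
#' @export
momDispersion <- function(x, sizeFactors = NULL, groups = NULL) {
    k <- if (is(x, "DegronExperiment")) counts(x) else as.matrix(x)
    if (is.null(groups) && is(x, "DegronExperiment"))
        groups <- sampleConditions(x)
    if (is.null(groups)) groups <- rep("all", ncol(k))
    groups <- as.factor(groups)
    if (is.null(sizeFactors))
        sizeFactors <- if (is(x, "DegronExperiment")) calcSizeFactors(x)
                       else rep(1, ncol(k))
    n <- sweep(k, 2, sizeFactors, "/")
    eps <- 1e-8
    ss <- numeric(nrow(k)); df <- 0
    for (g in levels(groups)) {
        idx <- which(groups == g)
        if (length(idx) < 2) next
        m <- rowMeans(n[, idx, drop = FALSE])
        ss <- ss + rowSums((n[, idx, drop = FALSE] - m)^2)
        df <- df + length(idx) - 1
    }
    if (df == 0)
        stop("at least one group needs >= 2 replicates")
    v <- ss / df
    mu <- rowMeans(n)
    alpha <- ifelse(mu > 0, pmax(eps, (v - mu) / mu^2), eps)
    names(alpha) <- rownames(k)
    attr(alpha, "allZero") <- mu == 0
    alpha
}

#' Negative-binomial Wald differential expression
#'
#' For each feature, with normalized group means `mC` (control) and `mT`
#' (treated) and pseudocount `c = 0.5`:
#' `log2fc = log2((mT + c) / (mC + c))`.  The standard error follows the
#' delta method for a log ratio of NB group means (no further adjustment
#' term is applied):
#' `se = (1/ln 2) * sqrt((1/(mT + c) + alpha)/nT + (1/(mC + c) + alpha)/nC)`,
#' where the pseudocount also stabilizes the `1/m` terms for silent
#' features.  `z = log2fc / se` is referred to the standard normal,
#' two-sided; p-values are BH-adjusted across features.  Features with zero
#' counts in all selected samples are reported with `log2fc = 0`,
#' `pvalue = 1`.
#'
#' @param x a [DegronExperiment-class].
#' @param control,treated condition labels of the two groups.
#' @param sizeFactors per-sample factors (default [calcSizeFactors()] on the
#'   full object, spike-in based when spike-ins are flagged).
#' @param dispersions per-feature `alpha` (default [momDispersion()] on the
#'   two selected groups).
#' @param pseudocount fold-change pseudocount (default 0.5).
#' @return A [S4Vectors::DataFrame] with columns `feature_id`, `baseMean`,
#'   `log2fc`, `lfcSE`, `pvalue`, `padj`.
#' @export
waldTest <- function(x, control, treated, sizeFactors = NULL,
                     dispersions = NULL, pseudocount = 0.5) {
    stopifnot(is(x, "DegronExperiment"))
    cond <- sampleConditions(x)
    if (!any(cond == control) || !any(cond == treated))
        stop("both condition labels must be present among the samples")
    if (is.null(sizeFactors)) sizeFactors <- calcSizeFactors(x)
    sel <- cond %in% c(control, treated)
    xs <- x[, sel]
    sfs <- sizeFactors[sel]
    if (is.null(dispersions))
        dispersions <- momDispersion(xs, sfs, sampleConditions(xs))
    n <- sweep(counts(xs), 2, sfs, "/")
    isC <- sampleConditions(xs) == control
    mC <- rowMeans(n[, isC, drop = FALSE])
    mT <- rowMeans(n[, !isC, drop = FALSE])
    nC <- sum(isC); nT <- sum(!isC)
    c0 <- pseudocount
    log2fc <- log2((mT + c0) / (mC + c0))
    se <- sqrt((1 / (mT + c0) + dispersions) / nT +
               (1 / (mC + c0) + dispersions) / nC) / log(2)
    z <- log2fc / se
    pvalue <- 2 * pnorm(-abs(z))
    silent <- mC == 0 & mT == 0
    log2fc[silent] <- 0
    pvalue[silent] <- 1
    DataFrame(feature_id = rownames(xs),
              baseMean = rowMeans(n),
              log2fc = log2fc,
              lfcSE = se,
              pvalue = pvalue,
              padj = bhAdjust(pvalue),
              row.names = rownames(xs))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, capped at 1
#' (delegates to [stats::p.adjust()] after validating the input range).
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
    if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}

#' Call differential features at fold-change and significance thresholds
#'
#' `down` iff `log2fc <= -log2(fcThreshold)` and the significance column
#' (adjusted or raw, per `useAdjusted`) is `< alpha`; `up` symmetric;
#' everything else `ns`.  "Fold change > k" is interpreted two-sidedly as
#' `|log2fc| >= log2(k)`.
#'
#' @param results output of [waldTest()] (or any table with `log2fc`,
#'   `pvalue`, `padj`).
#' @param fcThreshold fold-change threshold (> 1), e.g. 2 for genes, 1.5 for
#'   enhancers and eRNAs.
#' @param alpha significance level.
#' @param useAdjusted use `padj` (`TRUE`, gene-style calls) or raw `pvalue`
#'   (`FALSE`, enhancer/eRNA-style calls).
#' @return `results` with an added `call` factor (`up`/`down`/`ns`).
#' @export
callFeatures <- function(results, fcThreshold = 2, alpha = 0.05,
                         useAdjusted = TRUE) {
    stopifnot(fcThreshold > 1, alpha > 0, alpha < 1)
    sig <- if (useAdjusted) results$padj else results$pvalue
    if (is.null(sig))
        stop("required significance column is missing")
    lt <- log2(fcThreshold)
    call <- rep("ns", nrow(results))
    call[results$log2fc <= -lt & sig < alpha] <- "down"
    call[results$log2fc >= lt & sig < alpha] <- "up"
    results$call <- factor(call, levels = c("up", "down", "ns"))
    results
}

#' @describeIn callFeatures Split feature ids by call.
#' @export
featureSets <- function(results) {
    split(as.character(results$feature_id), results$call)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p-value by enumeration of the permutation distribution
#' when `length(x) + length(y) <= 12` and there are no ties; otherwise the
#' normal approximation with tie and continuity correction.  The statistic
#' `U` counts (x, y) pairs with `x > y`.
#'
#' @param x,y non-empty numeric vectors.
#' @return list with elements `U`, `p.value`, and `exact` (logical).
#' @examples
#' mannWhitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mannWhitney <- function(x, y) {
    if (!length(x) || !length(y))
        stop("both samples must be non-empty")
    ties <- anyDuplicated(c(x, y)) > 0
    exact <- (length(x) + length(y)) <= 12 && !ties
    wt <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = !exact))
    p <- wt$p.value
    if (is.nan(p) || is.na(p)) p <- 1  # degenerate: no rank variance
    list(U = unname(wt$statistic), p.value = min(1, p), exact = exact)
}
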