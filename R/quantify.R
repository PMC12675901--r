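## Interval counting: aligned-read intervals -> feature x sample counts.

.featureIds <- function(features) {
    ids <- mcols(features)$feature_id
    if (is.null(ids)) ids <- names(features)
    if (is.null(ids))
        stop("features need ids (mcols()$feature_id or names())")
    if (anyDuplicated(ids))
        stop("duplicate feature id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ids
}

#' Count reads over features
#'
#' Simple overlap counting: `count[f, s]` is the number of read intervals in
#' sample `s` overlapping feature `f` by at least `minOverlap` bases under
#' the chosen strand mode.  A read overlapping several features increments
#' all of them (no fractional or unique-only assignment); the rule is
#' deterministic and documented, and the simulator keeps features
#' non-overlapping so synthetic fixtures are unaffected.
#'
#' @param reads a named list of `GRanges` (one per sample), a `GRangesList`,
#'   or a single `GRanges` (one sample).
#' @param features `GRanges` with unique ids in `mcols()$feature_id` or
#'   `names()`.
#' @param strandMode `"ignore"` (enhancers, eRNAs) or `"same"` (stranded
#'   gene counting; strand labels must be equal).
#' @param minOverlap minimum overlap in bases (default 1).
#' @param isSpikein,condition,replicate forwarded to [DegronExperiment()].
#' @return A [DegronExperiment-class].
#' @export
countReads <- function(reads, features,
                       strandMode = c("ignore", "same"),
                       minOverlap = 1L,
                       isSpikein = NULL, condition = NULL, replicate = NULL) {
    strandMode <- match.arg(strandMode)
    ids <- .featureIds(features)
    if (is(reads, "GRanges")) reads <- list(sample1 = reads)
    reads <- as.list(reads)
    if (is.null(names(reads)))
        names(reads) <- paste0("sample", seq_along(reads))
    counts <- vapply(reads, function(rd) {
        .checkChromSets(features, rd)
        hits <- findOverlaps(features, rd, minoverlap = minOverlap,
                             ignore.strand = TRUE)
        qi <- queryHits(hits)
        if (strandMode == "same") {
            keep <- as.character(strand(features))[qi] ==
                as.character(strand(rd))[subjectHits(hits)]
            qi <- qi[keep]
        }
        tabulate(qi, nbins = length(features))
    }, numeric(length(features)))
    counts <- matrix(counts, nrow = length(features),
                     dimnames = list(ids, names(reads)))
    DegronExperiment(counts, isSpikein = isSpikein, condition = condition,
                     replicate = replicate)
}

#' Merge count matrices over disjoint sample sets
#'
#' Column-concatenates [DegronExperiment-class] objects sharing an identical
#' feature set.  Features are reordered to match the first part; spike-in
#' flags must agree.
#'
#' @param parts list of `DegronExperiment` objects.
#' @return A merged `DegronExperiment`.
#' @export
mergeCounts <- function(parts) {
    parts <- Filter(function(p) ncol(p) > 0, as.list(parts))
    if (!length(parts)) stop("nothing to merge")
    ref <- rownames(parts[[1]])
    for (p in parts[-1]) {
        extra <- setdiff(rownames(p), ref)
        missing <- setdiff(ref, rownames(p))
        if (length(extra) || length(missing))
            stop("feature sets differ; only in later part: {",
                 paste(extra, collapse = ", "), "}; missing from it: {",
                 paste(missing, collapse = ", "), "}")
    }
    parts <- lapply(parts, function(p) p[ref, ])
    flags <- vapply(parts, function(p) isSpikein(p), logical(length(ref)))
    flags <- matrix(flags, nrow = length(ref))
    if (any(apply(flags, 1, function(x) length(unique(x)) > 1)))
        stop("conflicting is_spikein flags across parts")
    samples <- unlist(lapply(parts, colnames))
    if (anyDuplicated(samples))
        stop("sample sets are not disjoint: ",
             paste(unique(samples[duplicated(samples)]), collapse = ", "))
    DegronExperiment(
        do.call(cbind, lapply(parts, function(p) counts(p))),
        isSpikein = flags[, 1],
        condition = unlist(lapply(parts, sampleConditions)),
        replicate = unlist(lapply(parts, function(p) colData(p)$replicate)))
}
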