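## Central S4 containers.  Counts live in a SummarizedExperiment subclass so
## rowData/colData bookkeeping (spike-in flags, condition labels) travels with
## the matrix; stranded coverage is a pair of run-length GRanges.

#' DegronExperiment: counts with spike-in flags and condition labels
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' integer assay `"counts"` (features x samples), a logical
#' `rowData(x)$is_spikein` flag per feature, and per-sample
#' `colData(x)$condition` / `colData(x)$replicate` labels.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [countReads()], [calcSizeFactors()], [waldTest()]
#' @exportClass DegronExperiment
setClass("DegronExperiment", contains = "SummarizedExperiment")

setValidity("DegronExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        k <- assay(object, "counts")
        if (!is.numeric(k) || anyNA(k))
            msg <- c(msg, "counts must be numeric and free of NA")
        else if (any(k < 0) || any(k != round(k)))
            msg <- c(msg, "counts must be non-negative integers")
        if (is.null(rownames(k)) || anyDuplicated(rownames(k)))
            msg <- c(msg, "feature ids must be present and unique")
        if (is.null(colnames(k)) || anyDuplicated(colnames(k)))
            msg <- c(msg, "sample ids must be present and unique")
    }
    if (!"is_spikein" %in% colnames(rowData(object)) ||
        !is.logical(rowData(object)$is_spikein))
        msg <- c(msg, "rowData(x)$is_spikein (logical) is required")
    if (!"condition" %in% colnames(colData(object)))
        msg <- c(msg, "colData(x)$condition is required")
    if (length(msg)) msg else TRUE
})

#' Construct a DegronExperiment
#'
#' @param counts integer matrix, features x samples, with unique dimnames.
#' @param isSpikein logical vector along rows (default all `FALSE`).
#' @param condition per-sample condition label, e.g. `"0h"`, `"4h"`, `"24h"`
#'   (default: the sample names).
#' @param replicate per-sample replicate index (default: running index within
#'   each condition).
#' @return A [DegronExperiment-class] object.
#' @examples
#' k <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' DegronExperiment(k, condition = c("0h", "0h", "4h"))
#' @export
DegronExperiment <- function(counts, isSpikein = NULL, condition = NULL,
                             replicate = NULL) {
    counts <- as.matrix(counts)
    if (is.null(isSpikein))
        isSpikein <- rep(FALSE, nrow(counts))
    if (is.null(condition))
        condition <- colnames(counts)
    condition <- as.character(condition)
    if (is.null(replicate))
        replicate <- stats::ave(seq_along(condition), condition,
                                FUN = seq_along)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(is_spikein = as.logical(isSpikein),
                            row.names = rownames(counts)),
        colData = DataFrame(condition = condition,
                            replicate = as.integer(replicate),
                            row.names = colnames(counts)))
    new("DegronExperiment", se)
}

#' @describeIn DegronExperiment Spike-in flag per feature.
#' @param x a `DegronExperiment`.
#' @export
isSpikein <- function(x) rowData(x)$is_spikein

#' @describeIn DegronExperiment Condition label per sample.
#' @export
sampleConditions <- function(x) colData(x)$condition

#' @rdname DegronExperiment
#' @param object a `DegronExperiment`.
#' @export
setMethod("counts", "DegronExperiment", function(object)
    assay(object, "counts"))

setMethod("show", "DegronExperiment", function(object) {
    callNextMethod()
    cat(sprintf("spike-ins: %d of %d features; conditions: %s\n",
                sum(isSpikein(object)), nrow(object),
                paste(unique(sampleConditions(object)), collapse = ", ")))
})

#' StrandedCoverage: per-strand depth runs
#'
#' Depth runs from a pair of strand-specific bedGraph tracks.  Each strand is
#' a sorted, disjoint [GenomicRanges::GRanges] with a numeric non-negative
#' `score` column (depth).  Bases absent from the runs have depth 0.
#'
#' @slot plus,minus `GRanges` with a `score` metadata column.
#' @seealso [readBedGraph()], [callTranscriptUnits()]
#' @exportClass StrandedCoverage
setClass("StrandedCoverage",
         representation(plus = "GRanges", minus = "GRanges"))

.validTrack <- function(gr, label) {
    msg <- character()
    if (!"score" %in% colnames(mcols(gr)))
        return(sprintf("%s strand: 'score' column is required", label))
    if (length(gr)) {
        if (anyNA(gr$score) || any(gr$score < 0))
            msg <- c(msg, sprintf("%s strand: depth must be >= 0", label))
        if (!isDisjoint(gr))
            msg <- c(msg, sprintf("%s strand: runs must not overlap", label))
    }
    msg
}

setValidity("StrandedCoverage", function(object) {
    msg <- c(.validTrack(object@plus, "plus"),
             .validTrack(object@minus, "minus"))
    if (length(msg)) msg else TRUE
})

#' Construct a StrandedCoverage object
#'
#' @param plus,minus `GRanges` with a numeric `score` column (depth runs on
#'   the forward and reverse strand).  Runs are sorted and zero-depth runs
#'   dropped.
#' @return A [StrandedCoverage-class] object.
#' @export
StrandedCoverage <- function(plus = GRanges(), minus = GRanges()) {
    clean <- function(gr) {
        if (!"score" %in% colnames(mcols(gr)))
            mcols(gr)$score <- numeric(length(gr))
        gr <- gr[gr$score > 0]
        # strip seqinfo so plus/minus tracks of different extent combine
        out <- GRanges(as.character(seqnames(gr)), ranges(gr))
        mcols(out)$score <- gr$score
        sort(out, ignore.strand = TRUE)
    }
    new("StrandedCoverage", plus = clean(plus), minus = clean(minus))
}

#' @describeIn StrandedCoverage Forward-strand runs.
#' @param x a `StrandedCoverage`.
#' @export
covPlus <- function(x) x@plus

#' @describeIn StrandedCoverage Reverse-strand runs.
#' @export
covMinus <- function(x) x@minus

setMethod("show", "StrandedCoverage", function(object) {
    cat(sprintf("StrandedCoverage: %d (+) and %d (-) depth runs\n",
                length(object@plus), length(object@minus)))
})

#' DirectTargetReport: putative direct-target set intersections
#'
#' Holds the three gene lists of the direct-target analysis and their
#' intersections: list 1, factor-bound genes down-regulated in the acute
#' contrast; list 2, target genes of bound, down-regulated super-enhancers;
#' list 3, the same for typical enhancers.  The putative direct-target set is
#' the union of the two branch overlaps.
#'
#' @slot list1,list2,list3 character vectors of gene ids.
#' @slot overlap12,overlap13,unionGenes character vectors of gene ids.
#' @seealso [directTargets()]
#' @exportClass DirectTargetReport
setClass("DirectTargetReport",
         representation(list1 = "character", list2 = "character",
                        list3 = "character", overlap12 = "character",
                        overlap13 = "character", unionGenes = "character"))

setValidity("DirectTargetReport", function(object) {
    msg <- character()
    if (!all(object@overlap12 %in% object@list1) ||
        !all(object@overlap12 %in% object@list2))
        msg <- c(msg, "overlap12 must be a subset of list1 and list2")
    if (!all(object@overlap13 %in% object@list1) ||
        !all(object@overlap13 %in% object@list3))
        msg <- c(msg, "overlap13 must be a subset of list1 and list3")
    if (!setequal(object@unionGenes,
                  union(object@overlap12, object@overlap13)))
        msg <- c(msg, "unionGenes must equal overlap12 U overlap13")
    if (length(msg)) msg else TRUE
})

#' @describeIn DirectTargetReport All gene sets as a named list.
#' @param x a `DirectTargetReport`.
#' @export
targetSets <- function(x)
    list(list1 = x@list1, list2 = x@list2, list3 = x@list3,
         overlap12 = x@overlap12, overlap13 = x@overlap13,
         union = x@unionGenes)

setMethod("show", "DirectTargetReport", function(object) {
    cat("DirectTargetReport\n")
    cat(sprintf("  list1 (bound, down genes):            %d\n",
                length(object@list1)))
    cat(sprintf("  list2 (targets of bound-down SEs):    %d\n",
                length(object@list2)))
    cat(sprintf("  list3 (targets of bound-down TEs):    %d\n",
                length(object@list3)))
    cat(sprintf("  overlap 1&2: %d   overlap 1&3: %d   union: %d\n",
                length(object@overlap12), length(object@overlap13),
                length(object@unionGenes)))
})

#' IntegrationReport: occupancy, gene classes and direct targets
#'
#' Result container of [integrateReport()]: the enhancer occupancy table, the
#' four-way gene-enhancer classification of down-regulated genes, the
#' percentage bookkeeping table, the [DirectTargetReport-class], the called
#' gene sets and the bound-vs-unbound rank-sum comparisons.
#'
#' @slot occupancy `data.frame` (enhancer_id, klass, bound, down_called,
#'   log2fc).
#' @slot geneClasses `data.frame` (gene_id, class).
#' @slot percentages `data.frame` (label, numerator, denominator, percent).
#' @slot directTargets a `DirectTargetReport`.
#' @slot downGenes,upGenes,boundDownGenes character vectors of gene ids.
#' @slot comparisons list of bound-vs-unbound test results per enhancer class.
#' @exportClass IntegrationReport
setClass("IntegrationReport",
         representation(occupancy = "data.frame", geneClasses = "data.frame",
                        percentages = "data.frame",
                        directTargets = "DirectTargetReport",
                        downGenes = "character", upGenes = "character",
                        boundDownGenes = "character", comparisons = "list"))

#' @describeIn IntegrationReport Enhancer occupancy table.
#' @param x an `IntegrationReport`.
#' @export
occupancyTable <- function(x) x@occupancy

#' @describeIn IntegrationReport Four-way gene classification.
#' @export
geneClasses <- function(x) x@geneClasses

#' @describeIn IntegrationReport Percentage bookkeeping table.
#' @export
percentTable <- function(x) x@percentages

#' @describeIn IntegrationReport The direct-target report.
#' @export
directTargetReport <- function(x) x@directTargets

setMethod("show", "IntegrationReport", function(object) {
    occ <- object@occupancy
    cat("IntegrationReport\n")
    for (kl in c("SE", "TE")) {
        sub <- occ[occ$klass == kl, , drop = FALSE]
        cat(sprintf("  %s: %d total, %d bound, %d down-called\n",
                    kl, nrow(sub), sum(sub$bound), sum(sub$down_called)))
    }
    cat(sprintf("  down genes: %d  up genes: %d  bound-down genes: %d\n",
                length(object@downGenes), length(object@upGenes),
                length(object@boundDownGenes)))
    cat(sprintf("  gene classes: %s\n",
                paste(sprintf("%s=%d", levels(object@geneClasses$class),
                              table(object@geneClasses$class)),
                      collapse = " ")))
    show(object@directTargets)
})
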