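## Occupancy annotation, four-way gene-enhancer classification,
## bound-vs-unbound comparisons, direct-target intersections and the
## percentage bookkeeping table.

#' Annotate enhancer occupancy and down-regulation
#'
#' `bound` is true iff the enhancer overlaps at least one ChIP-seq peak
#' (strand ignored).  When a differential-expression table is supplied,
#' `down_called` applies [callFeatures()] at the enhancer thresholds
#' (default fold change > 1.5 at raw p < 0.05) and `log2fc` is carried
#' through.
#'
#' @param enhancers `GRanges` with `enhancer_id` and `klass` columns.
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param enhDE optional DE table ([waldTest()] output) with `feature_id`
#'   matching the enhancer ids.
#' @param fcThreshold,alpha,useAdjusted thresholds for the down call.
#' @return `data.frame` with `enhancer_id`, `klass`, `bound`, `down_called`,
#'   `log2fc`.
#' @export
annotateOccupancy <- function(enhancers, peaks, enhDE = NULL,
                              fcThreshold = 1.5, alpha = 0.05,
                              useAdjusted = FALSE) {
    .checkChromSets(enhancers, peaks)
    bound <- countOverlaps(enhancers, peaks, ignore.strand = TRUE) > 0
    out <- data.frame(enhancer_id = enhancers$enhancer_id,
                      klass = enhancers$klass,
                      bound = bound,
                      down_called = FALSE,
                      log2fc = NA_real_)
    if (!is.null(enhDE)) {
        called <- callFeatures(enhDE, fcThreshold, alpha, useAdjusted)
        idx <- match(out$enhancer_id, called$feature_id)
        out$down_called <- !is.na(idx) & called$call[idx] == "down"
        out$log2fc <- called$log2fc[idx]
    }
    out
}

#' Classify down-regulated genes by the enhancer classes targeting them
#'
#' Each gene falls in exactly one class: `SE_and_TE` (targeted by at least
#' one super-enhancer and one typical enhancer), `Only_SE`, `Only_TE`, or
#' `Not_assigned`; the classes partition the input set.
#'
#' @param downGenes character vector of gene ids.
#' @param seMap,teMap named character vectors mapping `enhancer_id` to its
#'   target `gene_id` for the SE and TE catalogs.
#' @return `data.frame` with `gene_id` and a `class` factor.
#' @export
classifyGenes <- function(downGenes, seMap, teMap) {
    seG <- unique(unname(seMap))
    teG <- unique(unname(teMap))
    inSE <- downGenes %in% seG
    inTE <- downGenes %in% teG
    cls <- ifelse(inSE & inTE, "SE_and_TE",
           ifelse(inSE, "Only_SE",
           ifelse(inTE, "Only_TE", "Not_assigned")))
    data.frame(gene_id = downGenes,
               class = factor(cls, levels = c("SE_and_TE", "Only_SE",
                                              "Only_TE", "Not_assigned")))
}

#' Compare down-regulation of bound vs unbound enhancers
#'
#' Restricts the occupancy table to down-called enhancers of one class and
#' compares the log2 fold changes of bound vs unbound enhancers with the
#' rank-sum test ([mannWhitney()]); more negative means more strongly
#' down-regulated.
#'
#' @param occupancy `data.frame` from [annotateOccupancy()].
#' @param klass `"SE"` or `"TE"`.
#' @return list with `nBound`, `nUnbound`, `U`, `p.value` (`NA` with a
#'   warning when a group is empty).
#' @export
compareBoundUnbound <- function(occupancy, klass = c("SE", "TE")) {
    klass <- match.arg(klass)
    sub <- occupancy[occupancy$klass == klass & occupancy$down_called, ,
                     drop = FALSE]
    b <- sub$log2fc[sub$bound]
    u <- sub$log2fc[!sub$bound]
    if (!length(b) || !length(u)) {
        warning("empty bound or unbound group for class ", klass,
                "; p undefined", call. = FALSE)
        return(list(nBound = length(b), nUnbound = length(u),
                    U = NA_real_, p.value = NA_real_))
    }
    mw <- mannWhitney(b, u)
    list(nBound = length(b), nUnbound = length(u), U = mw$U,
         p.value = mw$p.value)
}

#' Direct-target intersection analysis
#'
#' List 1 is supplied by the caller (factor-bound genes down-regulated in
#' the acute contrast).  List 2 comprises the target genes of
#' super-enhancers that are both bound and down-called in the occupancy
#' table; list 3 the same for typical enhancers.  The putative direct-target
#' set is the union of the two branch overlaps with list 1.
#'
#' @param downBoundGenes character vector (list 1).
#' @param occupancy `data.frame` from [annotateOccupancy()].
#' @param seMap,teMap named vectors mapping enhancer ids to target gene ids.
#' @return A [DirectTargetReport-class].
#' @export
directTargets <- function(downBoundGenes, occupancy, seMap, teMap) {
    boundDown <- function(kl)
        occupancy$enhancer_id[occupancy$klass == kl & occupancy$bound &
                              occupancy$down_called]
    list2 <- sort(unique(unname(seMap[intersect(names(seMap),
                                                boundDown("SE"))])))
    list3 <- sort(unique(unname(teMap[intersect(names(teMap),
                                                boundDown("TE"))])))
    o12 <- sort(intersect(downBoundGenes, list2))
    o13 <- sort(intersect(downBoundGenes, list3))
    new("DirectTargetReport",
        list1 = sort(unique(downBoundGenes)), list2 = list2, list3 = list3,
        overlap12 = o12, overlap13 = o13,
        unionGenes = sort(union(o12, o13)))
}

#' Percentage bookkeeping table
#'
#' `percent = 100 * numerator / denominator`, rounded half-away-from-zero
#' to one decimal (so e.g. 169/231 prints as 73.2 and 4577/8563 as 53.5).
#'
#' @param labels character labels.
#' @param numerators,denominators integer vectors with
#'   `0 <= numerator <= denominator` and `denominator > 0`.
#' @return `data.frame` with `label`, `numerator`, `denominator`, `percent`.
#' @export
percentageReport <- function(labels, numerators, denominators) {
    if (any(denominators <= 0))
        stop("denominators must be positive")
    if (any(numerators < 0 | numerators > denominators))
        stop("numerators must lie in [0, denominator]")
    data.frame(label = labels,
               numerator = numerators,
               denominator = denominators,
               percent = roundHalfAway(100 * numerators / denominators, 1))
}

#' Round half away from zero
#'
#' Unlike [base::round()] (banker's rounding), exact halves move away from
#' zero, matching how percentages are conventionally printed.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded values.
#' @export
roundHalfAway <- function(x, digits = 1) {
    f <- 10^digits
    sign(x) * floor(abs(x) * f + 0.5) / f
}

#' End-to-end occupancy / classification / direct-target integration
#'
#' Runs the full integration stage: gene calls at the gene thresholds
#' (fold change > `geneFc`, adjusted p < `geneAlpha`), enhancer occupancy
#' and down calls at the enhancer thresholds (raw p), the four-way gene
#' classification of the down set, bound-vs-unbound rank-sum comparisons per
#' enhancer class, the direct-target intersections, and the percentage
#' bookkeeping table.
#'
#' @param geneDE,enhDE DE tables ([waldTest()] output or equivalent) for
#'   genes and enhancers.
#' @param genes `GRanges` with `gene_id` (gene bodies, for peak overlap).
#' @param enhancers `GRanges` with `enhancer_id`, `klass`.
#' @param peaks `GRanges` of ChIP-seq peaks.
#' @param seMap,teMap named vectors mapping enhancer ids to target gene ids.
#' @param geneFc,geneAlpha gene call thresholds (default 2, 0.05, adjusted).
#' @param enhFc,enhAlpha enhancer call thresholds (default 1.5, 0.05, raw).
#' @return An [IntegrationReport-class].
#' @export
integrateReport <- function(geneDE, enhDE, genes, enhancers, peaks,
                            seMap, teMap, geneFc = 2, geneAlpha = 0.05,
                            enhFc = 1.5, enhAlpha = 0.05) {
    gcall <- callFeatures(geneDE, geneFc, geneAlpha, useAdjusted = TRUE)
    down <- as.character(gcall$feature_id[gcall$call == "down"])
    up <- as.character(gcall$feature_id[gcall$call == "up"])
    boundGenes <- genes$gene_id[
        countOverlaps(genes, peaks, ignore.strand = TRUE) > 0]
    list1 <- intersect(down, boundGenes)
    occ <- annotateOccupancy(enhancers, peaks, enhDE, enhFc, enhAlpha,
                             useAdjusted = FALSE)
    classes <- classifyGenes(down, seMap, teMap)
    dtr <- directTargets(list1, occ, seMap, teMap)
    comparisons <- list(SE = compareBoundUnbound(occ, "SE"),
                        TE = compareBoundUnbound(occ, "TE"))
    nOf <- function(kl) sum(occ$klass == kl)
    nBound <- function(kl) sum(occ$klass == kl & occ$bound)
    nDown <- function(kl) sum(occ$klass == kl & occ$down_called)
    nBD <- function(kl) sum(occ$klass == kl & occ$bound & occ$down_called)
    clsN <- table(classes$class)
    labels <- c("SE bound", "TE bound", "SE down", "TE down",
                "down SE bound", "down TE bound",
                "down genes SE & TE", "down genes only SE",
                "down genes only TE", "down genes not assigned")
    nums <- c(nBound("SE"), nBound("TE"), nDown("SE"), nDown("TE"),
              nBD("SE"), nBD("TE"), clsN[["SE_and_TE"]], clsN[["Only_SE"]],
              clsN[["Only_TE"]], clsN[["Not_assigned"]])
    dens <- c(nOf("SE"), nOf("TE"), nOf("SE"), nOf("TE"),
              nDown("SE"), nDown("TE"), rep(length(down), 4))
    if (length(up)) {
        labels <- c(labels, "up genes bound")
        nums <- c(nums, length(intersect(up, boundGenes)))
        dens <- c(dens, length(up))
    }
    keep <- dens > 0
    pr <- percentageReport(labels[keep], unname(nums[keep]),
                           unname(dens[keep]))
    new("IntegrationReport", occupancy = occ, geneClasses = classes,
        percentages = pr, directTargets = dtr, downGenes = down,
        upGenes = up, boundDownGenes = sort(list1),
        comparisons = comparisons)
}
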