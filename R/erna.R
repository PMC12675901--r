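## De novo transcript-unit calling from stranded coverage, exclusion
## filtering against the gene annotation, eRNA designation by
## TSS-in-enhancer, and proximity target assignment.

#' Call transcript units from stranded coverage
#'
#' Per strand, maximal runs of bases with depth `>= minCov` are merged when
#' separated by at most `maxGap` sub-threshold bases; merged segments
#' shorter than `minLength` are discarded.  The TSS of a unit is its 5' end
#' by strand.  `mean_depth` averages depth over the above-threshold bases of
#' the unit (gap bases excluded), so `mean_depth >= minCov` always holds.
#'
#' @param cov a [StrandedCoverage-class].
#' @param minCov minimum depth for a base to be covered (default 2,
#'   normalized depth units).
#' @param maxGap maximum uncovered gap bridged within a unit (default 250).
#' @param minLength minimum unit width in bases (default 200).
#' @return `GRanges` (strand `+`/`-`) with metadata `unit_id`, `tss`,
#'   `mean_depth`, sorted by position.
#' @export
callTranscriptUnits <- function(cov, minCov = 2, maxGap = 250L,
                                minLength = 200L) {
    stopifnot(is(cov, "StrandedCoverage"), minCov > 0, maxGap >= 0,
              minLength >= 1)
    one <- function(track, strandChar) {
        keep <- track[track$score >= minCov]
        if (!length(keep)) {
            u <- GRanges()
            mcols(u)$mean_depth <- numeric()
            return(u)
        }
        units <- reduce(keep, min.gapwidth = maxGap + 1L)
        units <- units[width(units) >= minLength]
        hits <- findOverlaps(units, keep)
        ov <- pintersect(units[queryHits(hits)], keep[subjectHits(hits)])
        w <- width(ov)
        num <- tapply(w * keep$score[subjectHits(hits)], queryHits(hits), sum)
        den <- tapply(w, queryHits(hits), sum)
        md <- numeric(length(units))
        md[as.integer(names(num))] <- num / den
        strand(units) <- strandChar
        mcols(units)$mean_depth <- md
        units
    }
    units <- c(one(covPlus(cov), "+"), one(covMinus(cov), "-"))
    units <- sort(units, ignore.strand = TRUE)
    mcols(units)$unit_id <- sprintf("TU%04d", seq_along(units))
    mcols(units)$tss <- geneTSS(units)
    units[, c("unit_id", "tss", "mean_depth")]
}

#' Exclude units overlapping annotated genes
#'
#' A unit is removed when it overlaps a protein-coding gene on the same
#' strand (genic), a protein-coding gene on the opposite strand (antisense),
#' or any gene whose biotype is in `excludedBiotypes` on either strand.
#' The per-reason tallies account for every input unit exactly once
#' (genic > antisense > excluded-biotype precedence when several apply).
#'
#' @param units `GRanges` from [callTranscriptUnits()].
#' @param genes `GRanges` with `gene_id` and `biotype` columns.
#' @param excludedBiotypes structural-ncRNA biotypes removed on any-strand
#'   overlap (default `rRNA`, `snRNA`, `miRNA`, `snoRNA`; note tRNA genes
#'   are not excluded by default).
#' @return list with `units` (survivors), `removed` (`data.frame` of
#'   `unit_id`, `reason`) and `tally` (named counts incl. `retained`).
#' @export
excludeAnnotated <- function(units, genes,
                             excludedBiotypes = c("rRNA", "snRNA", "miRNA",
                                                  "snoRNA")) {
    pc <- genes[genes$biotype == "protein_coding"]
    exg <- genes[genes$biotype %in% excludedBiotypes]
    idx <- function(pairs) unique(pairs$queryIdx)
    genic <- idx(overlapPairs(units, pc, "same"))
    antisense <- setdiff(idx(overlapPairs(units, pc, "opposite")), genic)
    ncrna <- setdiff(idx(overlapPairs(units, exg, "ignore")),
                     c(genic, antisense))
    removedIdx <- c(genic, antisense, ncrna)
    reason <- rep(c("genic", "antisense", "excluded_biotype"),
                  c(length(genic), length(antisense), length(ncrna)))
    keep <- setdiff(seq_along(units), removedIdx)
    tally <- c(genic = length(genic), antisense = length(antisense),
               excluded_biotype = length(ncrna), retained = length(keep))
    list(units = units[keep],
         removed = data.frame(
             unit_id = if (length(removedIdx)) units$unit_id[removedIdx]
                       else character(),
             reason = reason),
         tally = tally)
}

#' Designate transcript units as enhancer RNAs
#'
#' A unit becomes an eRNA iff its TSS lies within at least one enhancer
#' interval (strand ignored; enhancer transcription is bidirectional).  When
#' several enhancers contain the TSS, the one whose midpoint is closest to
#' the TSS wins; remaining ties go to the lexicographically smallest
#' `enhancer_id`.
#'
#' @param units `GRanges` from [callTranscriptUnits()] (after exclusion
#'   filtering).
#' @param enhancers `GRanges` with `enhancer_id` and `klass` (`"SE"`/`"TE"`)
#'   columns.
#' @return `data.frame` with `unit_id`, `chrom`, `tss`, `strand`,
#'   `enhancer_id`, `klass`, `target_gene` (`NA`, see [assignTargets()]).
#' @export
designateErnas <- function(units, enhancers) {
    if (!length(units))
        return(data.frame(unit_id = character(), chrom = character(),
                          tss = integer(), strand = character(),
                          enhancer_id = character(), klass = character(),
                          target_gene = character()))
    pts <- GRanges(seqnames(units), IRanges(units$tss, units$tss))
    hits <- findOverlaps(pts, enhancers, ignore.strand = TRUE)
    qi <- queryHits(hits); si <- subjectHits(hits)
    if (!length(qi))
        return(data.frame(unit_id = character(), chrom = character(),
                          tss = integer(), strand = character(),
                          enhancer_id = character(), klass = character(),
                          target_gene = character()))
    middist <- abs(units$tss[qi] -
                   (start(enhancers)[si] + end(enhancers)[si]) / 2)
    o <- order(qi, middist, enhancers$enhancer_id[si])
    first <- !duplicated(qi[o])
    qi <- qi[o][first]; si <- si[o][first]
    data.frame(unit_id = units$unit_id[qi],
               chrom = as.character(seqnames(units))[qi],
               tss = units$tss[qi],
               strand = as.character(strand(units))[qi],
               enhancer_id = enhancers$enhancer_id[si],
               klass = enhancers$klass[si],
               target_gene = NA_character_)
}

#' Assign putative target genes to eRNAs by TSS proximity
#'
#' Fills `target_gene` with the protein-coding gene whose TSS is nearest to
#' the eRNA TSS within `maxDistance` (default 100 kb); `NA` when none
#' qualifies.
#'
#' @param ernas `data.frame` from [designateErnas()].
#' @param genes `GRanges` with `gene_id` and `biotype` columns.
#' @param maxDistance maximum TSS-to-TSS distance in bases.
#' @return `ernas` with `target_gene` and `target_distance` filled.
#' @export
assignTargets <- function(ernas, genes, maxDistance = 1e5) {
    pc <- genes[genes$biotype == "protein_coding"]
    tg <- nearestTSS(ernas$chrom, ernas$tss, pc, maxDistance)
    ernas$target_gene <- as.character(tg)
    ernas$target_distance <- attr(tg, "distance")
    ernas
}
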