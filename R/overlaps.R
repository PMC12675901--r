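## Overlap engine shared by every downstream stage.  All queries are plain
## interval intersection on the same chromosome (exact string match, no
## "chr" aliasing); strand is only consulted in the "same"/"opposite" modes.

.checkChromSets <- function(query, subject) {
    if (length(query) && length(subject) &&
        !length(intersect(as.character(seqnames(query)),
                          as.character(seqnames(subject)))))
        warning("query and subject share no chromosome names; ",
                "check naming conventions", call. = FALSE)
}

#' Pairwise interval overlap test
#'
#' Element-wise overlap verdicts for two `GRanges` of equal length (or with
#' one of length 1).  Intervals overlap iff they are on the same chromosome
#' and intersect; adjacency does not count (BED-style half-open semantics at
#' the file boundary translate to closed-interval intersection here).
#'
#' @param a,b `GRanges` objects, recycled to a common length.
#' @param strandMode `"ignore"` (default), `"same"` (strand labels equal), or
#'   `"opposite"` (one `+`, the other `-`).
#' @return logical vector.
#' @examples
#' a <- readBed(textConnection("chr1\t0\t10"))
#' b <- readBed(textConnection("chr1\t10\t20"))
#' intervalsOverlap(a, b)  # FALSE: half-open adjacency
#' @export
intervalsOverlap <- function(a, b, strandMode = c("ignore", "same",
                                                  "opposite")) {
    strandMode <- match.arg(strandMode)
    n <- max(length(a), length(b))
    ia <- rep_len(seq_along(a), n)
    ib <- rep_len(seq_along(b), n)
    ok <- as.character(seqnames(a))[ia] == as.character(seqnames(b))[ib] &
        start(a)[ia] <= end(b)[ib] & start(b)[ib] <= end(a)[ia]
    sa <- as.character(strand(a))[ia]
    sb <- as.character(strand(b))[ib]
    if (strandMode == "same")
        ok <- ok & sa == sb
    else if (strandMode == "opposite")
        ok <- ok & ((sa == "+" & sb == "-") | (sa == "-" & sb == "+"))
    ok
}

#' All overlapping query/subject index pairs
#'
#' Strand-aware wrapper around [GenomicRanges::findOverlaps()].  In
#' `"same"` mode the strand labels must be equal (so `"*"` matches `"*"`
#' only); in `"opposite"` mode one interval must be `+` and the other `-`.
#'
#' @param query,subject `GRanges`.
#' @param strandMode `"ignore"`, `"same"` or `"opposite"`.
#' @return `data.frame` with integer columns `queryIdx`, `subjectIdx`,
#'   ordered by query index then subject index.
#' @export
overlapPairs <- function(query, subject,
                         strandMode = c("ignore", "same", "opposite")) {
    strandMode <- match.arg(strandMode)
    .checkChromSets(query, subject)
    hits <- findOverlaps(query, subject, ignore.strand = TRUE)
    qi <- queryHits(hits); si <- subjectHits(hits)
    if (strandMode != "ignore") {
        sq <- as.character(strand(query))[qi]
        ss <- as.character(strand(subject))[si]
        keep <- if (strandMode == "same") sq == ss
                else (sq == "+" & ss == "-") | (sq == "-" & ss == "+")
        qi <- qi[keep]; si <- si[keep]
    }
    o <- order(qi, si)
    data.frame(queryIdx = qi[o], subjectIdx = si[o])
}

#' Transcription start sites of gene models
#'
#' The biological 5' end: `start` for `+`-strand genes, `end` for `-`-strand
#' genes (1-based positions).
#'
#' @param genes `GRanges` of gene models.
#' @return integer vector of TSS positions.
#' @export
geneTSS <- function(genes) {
    ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
}

#' Nearest gene TSS to genomic points
#'
#' For each query point, the gene on the same chromosome whose TSS has
#' minimal absolute distance, subject to `maxDistance`.  Ties are broken by
#' the lexicographically smallest `gene_id`, making the assignment
#' deterministic.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions (recycled with `chrom`).
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param maxDistance maximum allowed |TSS - pos| (default unlimited).
#' @return character vector of gene ids (`NA` where no gene qualifies), with
#'   the achieved distance in attribute `"distance"`.
#' @export
nearestTSS <- function(chrom, pos, genes, maxDistance = Inf) {
    n <- max(length(chrom), length(pos))
    chrom <- rep_len(as.character(chrom), n)
    pos <- rep_len(pos, n)
    tss <- geneTSS(genes)
    gchr <- as.character(seqnames(genes))
    gid <- genes$gene_id
    out <- rep(NA_character_, n)
    dist <- rep(NA_real_, n)
    for (i in seq_len(n)) {
        sel <- which(gchr == chrom[i])
        if (!length(sel)) next
        d <- abs(tss[sel] - pos[i])
        ok <- d <= maxDistance
        if (!any(ok)) next
        dmin <- min(d[ok])
        cand <- gid[sel][ok & d == dmin]
        out[i] <- sort(cand)[1]
        dist[i] <- dmin
    }
    attr(out, "distance") <- dist
    out
}
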