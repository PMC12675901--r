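## Plain-text interval I/O.  Files follow the usual UCSC conventions:
## BED and bedGraph are 0-based half-open, GTF is 1-based inclusive.  All
## coordinates are converted to the GRanges convention (1-based closed) at
## the parse boundary, so overlap arithmetic inside the package is uniform.

.INT_RE <- "^-?[0-9]+$"

.readLinesAny <- function(file) {
    if (inherits(file, "connection")) readLines(file) else readLines(file)
}

.field <- function(parts, i) {
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_,
           character(1))
}

.badRecord <- function(format, line, why)
    stop(sprintf("malformed %s record at line %d: %s", format, line, why),
         call. = FALSE)

#' Read a BED3/BED6 file into a GRanges
#'
#' BED coordinates are 0-based half-open; the returned `GRanges` is 1-based
#' closed (`start_bed + 1`, `end_bed`).  A missing strand column yields
#' strand `"*"` (the BED `"."` placeholder maps to `"*"`).
#'
#' @param file path, connection, or anything `readLines()` accepts.
#' @return `GRanges` with metadata columns `name` and `score` when the file
#'   carries them.
#' @details Records with fewer than three fields, non-integer or negative
#'   coordinates, or `start >= end` raise an error naming the offending line.
#'   `track`, `browser` and `#` comment lines are skipped (line numbering in
#'   error messages refers to the physical file).
#' @examples
#' bed <- textConnection("chr1\t100\t200\te1\t0\t+")
#' readBed(bed)
#' @export
readBed <- function(file) {
    lines <- .readLinesAny(file)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines))
        return(GRanges(name = character(), score = numeric()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 3))
        .badRecord("BED", lineno[which(nf < 3)[1]], "fewer than 3 fields")
    chrom <- .field(parts, 1)
    s <- .field(parts, 2)
    e <- .field(parts, 3)
    badint <- !grepl(.INT_RE, s) | !grepl(.INT_RE, e)
    if (any(badint))
        .badRecord("BED", lineno[which(badint)[1]],
                   "coordinates are not integers")
    s <- as.numeric(s); e <- as.numeric(e)
    if (any(s < 0))
        .badRecord("BED", lineno[which(s < 0)[1]], "negative start")
    if (any(e <= s))
        .badRecord("BED", lineno[which(e <= s)[1]], "start >= end")
    name <- .field(parts, 4)
    score <- suppressWarnings(as.numeric(.field(parts, 5)))
    strand <- .field(parts, 6)
    strand[is.na(strand) | strand == "."] <- "*"
    bad <- !strand %in% c("+", "-", "*")
    if (any(bad))
        .badRecord("BED", lineno[which(bad)[1]],
                   sprintf("invalid strand '%s'", strand[which(bad)[1]]))
    gr <- GRanges(chrom, IRanges(s + 1, e), strand = strand)
    mcols(gr)$name <- name
    mcols(gr)$score <- score
    gr
}

#' Write a GRanges as BED6
#'
#' Inverse of [readBed()]: emits 0-based half-open coordinates, `"*"` strand
#' as `"."`, missing names as `"."` and missing scores as `0`.
#'
#' @param gr a `GRanges`; `mcols(gr)$name` and `$score` are used if present,
#'   else `names(gr)`.
#' @param file path or connection.
#' @export
writeBed <- function(gr, file) {
    name <- if (!is.null(mcols(gr)$name)) mcols(gr)$name else names(gr)
    if (is.null(name)) name <- rep(NA_character_, length(gr))
    name[is.na(name)] <- "."
    score <- if (!is.null(mcols(gr)$score)) mcols(gr)$score else
        rep(NA_real_, length(gr))
    score[is.na(score)] <- 0
    strand <- as.character(strand(gr))
    strand[strand == "*"] <- "."
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(seqnames(gr)), start(gr) - 1L, end(gr),
                   name, format(score, trim = TRUE, scientific = FALSE),
                   strand)
    writeLines(out, file)
}

.BIOTYPES <- c("protein_coding", "rRNA", "snRNA", "miRNA", "snoRNA", "tRNA",
               "other")

.gtfAttr <- function(attrs, key) {
    m <- regmatches(attrs, regexec(sprintf('%s "([^"]*)"', key), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
}

#' Read gene records from a GTF file
#'
#' Keeps `gene`-type records only.  GTF coordinates (1-based inclusive) map
#' directly onto the returned `GRanges`.  The transcription start site of
#' each gene is `start` on the `+` strand and `end` on the `-` strand; see
#' [geneTSS()].
#'
#' @param file path or connection.
#' @return `GRanges` with metadata columns `gene_id` and `biotype`.  Biotypes
#'   outside `protein_coding`, `rRNA`, `snRNA`, `miRNA`, `snoRNA`, `tRNA` are
#'   mapped to `"other"` with a warning.  A record lacking `gene_id`, or a
#'   duplicated `gene_id`, is an error.
#' @export
readGtfGenes <- function(file) {
    lines <- .readLinesAny(file)
    keep <- !grepl("^#", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 9))
        .badRecord("GTF", lineno[which(nf < 9)[1]], "fewer than 9 fields")
    feat <- .field(parts, 3)
    gene <- feat == "gene"
    if (!any(gene))
        return(GRanges(gene_id = character(), biotype = character()))
    parts <- parts[gene]; lineno <- lineno[gene]
    chrom <- .field(parts, 1)
    s <- .field(parts, 4); e <- .field(parts, 5)
    badint <- !grepl(.INT_RE, s) | !grepl(.INT_RE, e)
    if (any(badint))
        .badRecord("GTF", lineno[which(badint)[1]],
                   "coordinates are not integers")
    s <- as.numeric(s); e <- as.numeric(e)
    if (any(s < 1 | e < s))
        .badRecord("GTF", lineno[which(s < 1 | e < s)[1]],
                   "invalid coordinate range")
    strand <- .field(parts, 7)
    bad <- !strand %in% c("+", "-")
    if (any(bad))
        .badRecord("GTF", lineno[which(bad)[1]],
                   "gene records must be stranded (+/-)")
    attrs <- .field(parts, 9)
    gene_id <- .gtfAttr(attrs, "gene_id")
    if (anyNA(gene_id))
        .badRecord("GTF", lineno[which(is.na(gene_id))[1]],
                   "missing gene_id attribute")
    if (anyDuplicated(gene_id))
        stop("duplicated gene_id: ",
             paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
    biotype <- .gtfAttr(attrs, "gene_biotype")
    alt <- .gtfAttr(attrs, "gene_type")
    biotype[is.na(biotype)] <- alt[is.na(biotype)]
    biotype[is.na(biotype)] <- "other"
    unknown <- !biotype %in% .BIOTYPES
    if (any(unknown)) {
        warning("unknown biotype(s) mapped to 'other': ",
                paste(unique(biotype[unknown]), collapse = ", "))
        biotype[unknown] <- "other"
    }
    gr <- GRanges(chrom, IRanges(s, e), strand = strand)
    mcols(gr)$gene_id <- gene_id
    mcols(gr)$biotype <- biotype
    gr
}

#' Write gene records as GTF
#'
#' @param genes `GRanges` with `gene_id` and `biotype` metadata columns.
#' @param file path or connection.
#' @param source source field for column 2.
#' @export
writeGtfGenes <- function(genes, file, source = "degronseq") {
    out <- sprintf(
        "%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; gene_biotype \"%s\";",
        as.character(seqnames(genes)), source, start(genes), end(genes),
        as.character(strand(genes)), genes$gene_id, genes$biotype)
    writeLines(out, file)
}

#' Read a 4-column bedGraph into a GRanges of depth runs
#'
#' @param file path or connection.
#' @return `GRanges` with a numeric `score` column; coordinates converted
#'   from 0-based half-open to 1-based closed.
#' @export
readBedGraph <- function(file) {
    lines <- .readLinesAny(file)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
    lineno <- which(keep)
    lines <- lines[keep]
    if (!length(lines)) return(GRanges(score = numeric()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf < 4))
        .badRecord("bedGraph", lineno[which(nf < 4)[1]],
                   "fewer than 4 fields")
    s <- .field(parts, 2); e <- .field(parts, 3)
    badint <- !grepl(.INT_RE, s) | !grepl(.INT_RE, e)
    if (any(badint))
        .badRecord("bedGraph", lineno[which(badint)[1]],
                   "coordinates are not integers")
    s <- as.numeric(s); e <- as.numeric(e)
    if (any(s < 0 | e <= s))
        .badRecord("bedGraph", lineno[which(s < 0 | e <= s)[1]],
                   "invalid coordinate range")
    score <- suppressWarnings(as.numeric(.field(parts, 4)))
    if (anyNA(score))
        .badRecord("bedGraph", lineno[which(is.na(score))[1]],
                   "value is not numeric")
    gr <- GRanges(.field(parts, 1), IRanges(s + 1, e))
    mcols(gr)$score <- score
    gr
}

#' Write depth runs as bedGraph
#'
#' @param gr `GRanges` with a `score` column.
#' @param file path or connection.
#' @export
writeBedGraph <- function(gr, file) {
    out <- sprintf("%s\t%d\t%d\t%s", as.character(seqnames(gr)),
                   start(gr) - 1L, end(gr),
                   format(gr$score, trim = TRUE, scientific = FALSE))
    writeLines(out, file)
}
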