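## Independent brute-force oracles used to check the fast implementations.
## These deliberately share no code with the package internals.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(S4Vectors)
})

# random intervals on a small genome
rGR <- function(n, chroms = c("chr1", "chr2"), maxStart = 1000, maxW = 60,
                strands = c("+", "-", "*")) {
    s <- sample.int(maxStart, n, replace = TRUE)
    w <- sample.int(maxW, n, replace = TRUE)
    GRanges(sample(chroms, n, replace = TRUE), IRanges(s, s + w - 1L),
            strand = sample(strands, n, replace = TRUE))
}

# all-pairs overlap scan (1-based closed intervals)
bfOverlapPairs <- function(q, s, mode = "ignore") {
    qc <- as.character(seqnames(q)); sc <- as.character(seqnames(s))
    qs <- start(q); qe <- end(q); ss <- start(s); se <- end(s)
    qst <- as.character(strand(q)); sst <- as.character(strand(s))
    out <- list()
    for (i in seq_along(q)) for (j in seq_along(s)) {
        ok <- qc[i] == sc[j] && qs[i] <= se[j] && ss[j] <= qe[i]
        if (ok && mode == "same") ok <- qst[i] == sst[j]
        if (ok && mode == "opposite")
            ok <- (qst[i] == "+" && sst[j] == "-") ||
                  (qst[i] == "-" && sst[j] == "+")
        if (ok) out[[length(out) + 1L]] <- c(i, j)
    }
    if (!length(out))
        return(data.frame(queryIdx = integer(), subjectIdx = integer()))
    m <- do.call(rbind, out)
    m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
    data.frame(queryIdx = m[, 1], subjectIdx = m[, 2])
}

# exhaustive nearest-TSS scan with lexicographic tie-break
bfNearestTSS <- function(chrom, pos, gchr, gtss, gid, maxd = Inf) {
    best <- NA_character_; bd <- Inf
    for (k in seq_along(gid)) {
        if (gchr[k] != chrom) next
        d <- abs(gtss[k] - pos)
        if (d > maxd) next
        if (d < bd || (d == bd && gid[k] < best)) { best <- gid[k]; bd <- d }
    }
    best
}

# position-by-position segmentation of a depth vector (positions 1..L)
bfSegment <- function(depth, minCov, maxGap, minLength) {
    cov <- which(depth >= minCov)
    if (!length(cov)) return(matrix(numeric(0), ncol = 2))
    segs <- list(); s <- cov[1]; p <- cov[1]
    for (i in cov[-1]) {
        if (i - p - 1 > maxGap) { segs[[length(segs) + 1L]] <- c(s, p); s <- i }
        p <- i
    }
    segs[[length(segs) + 1L]] <- c(s, p)
    m <- do.call(rbind, segs)
    m[m[, 2] - m[, 1] + 1 >= minLength, , drop = FALSE]
}

# depth vector -> run GRanges, and random rectangle tracks
depthToRuns <- function(depth, chrom = "chr1") {
    r <- rle(depth)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    keep <- r$values > 0
    gr <- GRanges(chrom, IRanges(s[keep], e[keep]))
    mcols(gr)$score <- r$values[keep]
    gr
}

randomDepth <- function(len = 1500, nBox = 8) {
    depth <- numeric(len)
    for (b in seq_len(nBox)) {
        s <- sample.int(len - 50, 1)
        w <- sample(20:300, 1)
        depth[s:min(len, s + w)] <- depth[s:min(len, s + w)] +
            sample(0:4, 1)
    }
    depth
}

# full-enumeration two-sided rank-sum p (symmetric-band convention)
bfMannWhitneyExact <- function(x, y) {
    n1 <- length(x); vals <- c(x, y); n <- length(vals)
    U <- sum(outer(x, y, ">"))
    mu <- n1 * (n - n1) / 2
    Us <- apply(utils::combn(n, n1), 2, function(idx)
        sum(outer(vals[idx], vals[-idx], ">")))
    list(U = U, p = mean(abs(Us - mu) >= abs(U - mu)))
}

# step-up BH from the definition
bfBH <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- pmin(rev(cummin(rev(adj))), 1)
    out <- numeric(n); out[o] <- adj
    out
}
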