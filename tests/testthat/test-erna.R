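bedCov <- function(plusLines, minusLines = character()) {
    StrandedCoverage(
        plus = readBedGraph(textConnection(plusLines)),
        minus = readBedGraph(textConnection(minusLines)))
}

test_that("unit calling thresholds, bridges gaps and enforces minimum length", {
    expect_length(callTranscriptUnits(StrandedCoverage()), 0)
    # depth 5 over [100,200) and [205,300): 5-base gap <= maxGap 10 -> one unit
    cov <- bedCov(c("chr1\t100\t200\t5", "chr1\t205\t300\t5"))
    u <- callTranscriptUnits(cov, minCov = 2, maxGap = 10, minLength = 50)
    expect_length(u, 1)
    expect_equal(start(u), 101L)   # bed 100
    expect_equal(end(u), 300L)
    expect_equal(u$tss, 101L)
    expect_equal(as.character(strand(u)), "+")
    expect_equal(u$mean_depth, 5)
    # gap wider than maxGap -> two units (if long enough), short ones dropped
    u2 <- callTranscriptUnits(bedCov(c("chr1\t0\t100\t5",
                                       "chr1\t150\t400\t5")),
                              minCov = 2, maxGap = 10, minLength = 120)
    expect_length(u2, 1)
    expect_equal(start(u2), 151L)
    # sub-threshold coverage acts as a gap
    u3 <- callTranscriptUnits(bedCov("chr1\t0\t500\t1"), minCov = 2,
                              maxGap = 10, minLength = 100)
    expect_length(u3, 0)
    # minus-strand TSS is the 3'-coordinate end of the interval
    u4 <- callTranscriptUnits(bedCov(character(), "chr1\t100\t400\t3"),
                              minCov = 2, maxGap = 10, minLength = 100)
    expect_equal(u4$tss, 400L)
    expect_true(u4$mean_depth >= 2)
})

test_that("unit calling equals a position-by-position segmenter on random tracks", {
    set.seed(71)
    for (i in 1:100) {
        depth <- randomDepth()
        minCov <- sample(2:4, 1)
        maxGap <- sample(c(0, 5, 30), 1)
        minLength <- sample(c(10, 50, 120), 1)
        cov <- StrandedCoverage(plus = depthToRuns(depth))
        u <- callTranscriptUnits(cov, minCov, maxGap, minLength)
        want <- bfSegment(depth, minCov, maxGap, minLength)
        expect_equal(length(u), nrow(want), label = paste("instance", i))
        if (nrow(want)) {
            expect_equal(start(u), as.integer(want[, 1]))
            expect_equal(end(u), as.integer(want[, 2]))
            expect_true(all(u$mean_depth >= minCov))
        }
    }
})

mkGenes <- function(starts, ends, strands, biotypes) {
    g <- GRanges("chr1", IRanges(starts, ends), strand = strands)
    g$gene_id <- sprintf("gene%02d", seq_along(g))
    g$biotype <- biotypes
    g
}

mkUnits <- function(starts, ends, strands) {
    u <- GRanges("chr1", IRanges(starts, ends), strand = strands)
    u$unit_id <- sprintf("TU%04d", seq_along(u))
    u$tss <- geneTSS(u)
    u$mean_depth <- 5
    u
}

test_that("annotation exclusion removes genic, antisense and structural-ncRNA overlaps", {
    genes <- mkGenes(c(100, 1000, 2000, 3000), c(500, 1500, 2500, 3500),
                     c("+", "+", "+", "+"),
                     c("protein_coding", "protein_coding", "rRNA", "tRNA"))
    units <- mkUnits(c(200, 1100, 2100, 3100, 5000),
                     c(400, 1300, 2300, 3300, 5400),
                     c("+", "-", "-", "+", "+"))
    res <- excludeAnnotated(units, genes)
    # unit 1 genic, unit 2 antisense, unit 3 rRNA; unit 4 only tRNA -> kept
    expect_setequal(res$units$unit_id, c("TU0004", "TU0005"))
    expect_equal(unname(res$tally),
                 c(1, 1, 1, 2))
    expect_equal(res$removed$reason[res$removed$unit_id == "TU0002"],
                 "antisense")
    expect_equal(sum(res$tally), length(units))
    # enlarging the excluded set is monotone
    res2 <- excludeAnnotated(units, genes,
                             excludedBiotypes = c("rRNA", "snRNA", "miRNA",
                                                  "snoRNA", "tRNA"))
    expect_lte(length(res2$units), length(res$units))
    expect_setequal(res2$units$unit_id, "TU0005")
})

test_that("eRNA designation is point-in-interval on the TSS with half-open boundaries", {
    enh <- readBed(textConnection(c("chr1\t100\t200\tenhA",
                                    "chr1\t400\t600\tenhB")))
    enh$enhancer_id <- enh$name
    enh$klass <- c("SE", "TE")
    inUnit <- mkUnits(151, 450, "+")     # tss 151 (bed 150) inside enhA
    edgeUnit <- mkUnits(201, 500, "+")   # tss at bed 200: outside (half-open)
    expect_equal(designateErnas(inUnit, enh)$enhancer_id, "enhA")
    expect_equal(nrow(designateErnas(edgeUnit, enh)), 0)
    # containment invariant holds for every designated record
    d <- designateErnas(inUnit, enh)
    hit <- enh[match(d$enhancer_id, enh$enhancer_id)]
    expect_true(all(d$tss >= start(hit) & d$tss <= end(hit)))
})

test_that("designation ties go to the closest midpoint, then the smaller id", {
    enh <- GRanges("chr1", IRanges(c(100, 120, 100), c(300, 244, 300)))
    enh$enhancer_id <- c("enhC", "enhB", "enhA")
    enh$klass <- "TE"
    u <- mkUnits(190, 600, "+")  # tss 190: mid(enhB)=182 is closest
    expect_equal(designateErnas(u, enh)$enhancer_id, "enhB")
    # exact midpoint tie between enhA and enhC -> lexicographic
    u2 <- mkUnits(200, 600, "+")
    enh2 <- enh[c(1, 3)]
    expect_equal(designateErnas(u2, enh2)$enhancer_id, "enhA")
})

test_that("designation matches a brute-force point-in-interval scan", {
    set.seed(73)
    for (i in 1:30) {
        enh <- rGR(40, maxStart = 2000, maxW = 150, strands = "*")
        enh$enhancer_id <- sprintf("e%03d", sample(40))
        enh$klass <- sample(c("SE", "TE"), 40, replace = TRUE)
        units <- rGR(60, maxStart = 2000, maxW = 200, strands = c("+", "-"))
        units$unit_id <- sprintf("TU%04d", seq_along(units))
        units$tss <- geneTSS(units)
        units$mean_depth <- 3
        d <- designateErnas(units, enh)
        inAny <- vapply(seq_along(units), function(k) {
            any(as.character(seqnames(enh)) ==
                    as.character(seqnames(units))[k] &
                start(enh) <= units$tss[k] & end(enh) >= units$tss[k])
        }, logical(1))
        expect_setequal(d$unit_id, units$unit_id[inAny])
    }
})

test_that("target assignment uses nearest protein-coding TSS within range", {
    genes <- mkGenes(c(10000, 200000), c(12000, 202000), c("+", "+"),
                     c("protein_coding", "protein_coding"))
    enh <- GRanges("chr1", IRanges(19900, 20100))
    enh$enhancer_id <- "e1"; enh$klass <- "SE"
    u <- mkUnits(20000, 20500, "+")
    er <- assignTargets(designateErnas(u, enh), genes)
    expect_equal(er$target_gene, "gene01")  # 10 kb away
    expect_equal(er$target_distance, 10000)
    # nearest gene beyond the cutoff -> absent
    farGenes <- mkGenes(200000, 202000, "+", "protein_coding")
    er2 <- assignTargets(designateErnas(u, enh), farGenes)
    expect_true(is.na(er2$target_gene))
    # non-coding genes are never targets
    ncG <- mkGenes(20100, 20400, "+", "miRNA")
    er3 <- assignTargets(designateErnas(u, enh), ncG)
    expect_true(is.na(er3$target_gene))
})
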