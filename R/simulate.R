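## Deterministic generator of a miniature depletion study: annotation,
## enhancer catalogs, ChIP-seq peaks, spike-in-bearing count matrices across
## a 0 h / 4 h / 24 h time course, and stranded coverage with planted
## transcript units.  One seed drives every draw; the three stages use
## seed, seed + 1 and seed + 2 so each is independently reproducible.

#' Simulation configuration
#'
#' Collects the knobs of the synthetic study in one validated list.  The
#' defaults describe the emulated design: three timepoints with
#' `replicates` biological replicates each, a dominant global
#' down-regulation (60% of genes truly down, 4-fold at the early and 8-fold
#' at the late timepoint), constant-abundance spike-ins, a fraction of
#' enhancers bound by the depleted factor with extra down-shift, and
#' coverage tracks carrying plantable intergenic transcript units.
#'
#' @param seed integer master seed.
#' @param nChromosomes,chromLength genome shape.
#' @param nGenes,nSe,nTe,nSpikeins feature counts (`nSpikeins >= 10`).
#' @param replicates replicates per timepoint.
#' @param dispersion NB dispersion `alpha` (`Var = mu + alpha mu^2`).
#' @param fracDirectDown fraction of genes truly down-regulated.
#' @param downFc4h,downFc24h true fold reductions at 4 h and 24 h.
#' @param fracEnhBound fraction of enhancers bound by the factor.
#' @param boundDownShift extra log2 fold-change depression of bound
#'   enhancers (negative).
#' @param meanGeneCount,meanSpikeCount expected normalized counts.
#' @param plantedUnits,plantedInEnhancers transcript units planted into the
#'   coverage tracks, and how many of them start inside enhancers.
#' @param minCov,maxGap,minLength segmentation parameters the planted tracks
#'   are designed against (see [callTranscriptUnits()]).
#' @return a validated named list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L, nChromosomes = 2L,
                             chromLength = 5e6, nGenes = 2000L,
                             nSe = 40L, nTe = 200L, nSpikeins = 100L,
                             replicates = 3L, dispersion = 0.05,
                             fracDirectDown = 0.6, downFc4h = 4,
                             downFc24h = 8, fracEnhBound = 0.55,
                             boundDownShift = -0.5,
                             meanGeneCount = 200, meanSpikeCount = 500,
                             plantedUnits = 30L, plantedInEnhancers = 20L,
                             minCov = 2, maxGap = 250L, minLength = 200L) {
    cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
                chromLength = chromLength, nGenes = as.integer(nGenes),
                nSe = as.integer(nSe), nTe = as.integer(nTe),
                nSpikeins = as.integer(nSpikeins),
                replicates = as.integer(replicates),
                dispersion = dispersion, fracDirectDown = fracDirectDown,
                downFc4h = downFc4h, downFc24h = downFc24h,
                fracEnhBound = fracEnhBound,
                boundDownShift = boundDownShift,
                meanGeneCount = meanGeneCount,
                meanSpikeCount = meanSpikeCount,
                plantedUnits = as.integer(plantedUnits),
                plantedInEnhancers = as.integer(plantedInEnhancers),
                minCov = minCov, maxGap = as.integer(maxGap),
                minLength = as.integer(minLength))
    stopifnot(cfg$nSpikeins >= 10, cfg$replicates >= 2,
              cfg$fracDirectDown >= 0, cfg$fracDirectDown <= 1,
              cfg$fracEnhBound >= 0, cfg$fracEnhBound <= 1,
              cfg$dispersion > 0, cfg$downFc4h > 1, cfg$downFc24h > 1,
              cfg$plantedInEnhancers <= cfg$plantedUnits)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Simulate a gene and enhancer annotation
#'
#' Lays out non-overlapping genes (mostly protein-coding, with a sprinkling
#' of structural-ncRNA biotypes), super-enhancers (wider) and typical
#' enhancers across the genome in shuffled order with random inter-feature
#' gaps.  Every enhancer is assigned its nearest-TSS protein-coding target
#' gene, recorded in both the catalog and the truth.
#'
#' @param config a [simulationConfig()].
#' @return list with `genes` (`GRanges`: `gene_id`, `biotype`), `enhancers`
#'   (`GRanges`: `enhancer_id`, `klass`, `target_gene`), `spikeins`
#'   (character ids), and `truth` (`targets`: named enhancer to gene map).
#' @export
simulateAnnotation <- function(config) {
    set.seed(config$seed)
    type <- sample(c(rep("gene", config$nGenes), rep("SE", config$nSe),
                     rep("TE", config$nTe)))
    n <- length(type)
    w <- integer(n)
    w[type == "gene"] <- round(runif(sum(type == "gene"), 1000, 3000))
    w[type == "SE"] <- round(runif(sum(type == "SE"), 3000, 6000))
    w[type == "TE"] <- round(runif(sum(type == "TE"), 600, 1500))
    gap <- round(runif(n, 200, 1500))
    chromIdx <- integer(n); starts <- integer(n)
    ci <- 1L; pos <- 1L
    for (i in seq_len(n)) {
        if (pos + gap[i] + w[i] > config$chromLength) {
            ci <- ci + 1L
            pos <- 1L
            if (ci > config$nChromosomes)
                stop("annotation does not fit in the genome; ",
                     "increase chromLength or nChromosomes")
        }
        pos <- pos + gap[i]
        chromIdx[i] <- ci
        starts[i] <- pos
        pos <- pos + w[i]
    }
    gr <- GRanges(paste0("chr", chromIdx), IRanges(starts, starts + w - 1L))
    isGene <- type == "gene"
    genes <- gr[isGene]
    strand(genes) <- sample(c("+", "-"), sum(isGene), replace = TRUE)
    genes$gene_id <- sprintf("gene%05d", seq_len(sum(isGene)))
    genes$biotype <- sample(
        .BIOTYPES,
        sum(isGene), replace = TRUE,
        prob = c(0.92, 0.015, 0.015, 0.015, 0.015, 0.01, 0.01))
    enh <- gr[!isGene]
    enh$klass <- type[!isGene]
    enh$enhancer_id <- ifelse(enh$klass == "SE",
                              sprintf("SE%04d", cumsum(enh$klass == "SE")),
                              sprintf("TE%04d", cumsum(enh$klass == "TE")))
    pc <- genes[genes$biotype == "protein_coding"]
    mid <- floor((start(enh) + end(enh)) / 2)
    enh$target_gene <- as.character(
        nearestTSS(as.character(seqnames(enh)), mid, pc))
    list(genes = genes, enhancers = enh,
         spikeins = sprintf("spike%03d", seq_len(config$nSpikeins)),
         truth = list(targets = setNames(enh$target_gene, enh$enhancer_id)))
}

#' Simulate the time-course count matrix
#'
#' Counts are drawn as `NB(mean = s_j * q_f * FC_f(t), dispersion alpha)`.
#' Spike-ins keep `FC = 1` and constant abundance; a `fracDirectDown`
#' fraction of genes gets `FC = 1/downFc4h` at 4 h and `1/downFc24h` at
#' 24 h.  True per-sample depth factors `s_j` are drawn log-uniformly in
#' `[0.5, 2]` — the quantity spike-in normalization must recover.
#'
#' @param config a [simulationConfig()].
#' @param annotation output of [simulateAnnotation()].
#' @return list with `se` (a [DegronExperiment-class], samples
#'   `0h/4h/24h x replicates`) and `truth` (`fc4h`, `fc24h` named fold
#'   changes, `sizeFactors`, `downGenes`).
#' @export
simulateCounts <- function(config, annotation) {
    set.seed(config$seed + 1L)
    geneIds <- annotation$genes$gene_id
    nG <- length(geneIds); nS <- length(annotation$spikeins)
    q <- c(rlnorm(nG, log(config$meanGeneCount), 1),
           rlnorm(nS, log(config$meanSpikeCount), 0.25))
    downGenes <- sample(geneIds, round(config$fracDirectDown * nG))
    fc4 <- setNames(rep(1, nG), geneIds)
    fc24 <- fc4
    fc4[downGenes] <- 1 / config$downFc4h
    fc24[downGenes] <- 1 / config$downFc24h
    condition <- rep(c("0h", "4h", "24h"), each = config$replicates)
    nsamp <- length(condition)
    sf <- exp(runif(nsamp, log(0.5), log(2)))
    fcmat <- cbind(`0h` = 1, `4h` = c(fc4, rep(1, nS)),
                   `24h` = c(fc24, rep(1, nS)))
    mu <- q * fcmat[, condition] * rep(sf, each = nG + nS)
    k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
                nrow = nG + nS)
    dimnames(k) <- list(c(geneIds, annotation$spikeins),
                        paste0(condition, "_r",
                               rep(seq_len(config$replicates), 3)))
    se <- DegronExperiment(k,
                           isSpikein = c(rep(FALSE, nG), rep(TRUE, nS)),
                           condition = condition,
                           replicate = rep(seq_len(config$replicates), 3))
    list(se = se,
         truth = list(fc4h = fc4, fc24h = fc24,
                      sizeFactors = setNames(sf, colnames(k)),
                      downGenes = sort(downGenes)))
}

## Gaps between placed features, per chromosome (internal).
.annotationGaps <- function(annotation) {
    all <- sort(c(granges(annotation$genes), granges(annotation$enhancers)),
                ignore.strand = TRUE)
    out <- GRanges()
    for (chr in unique(as.character(seqnames(all)))) {
        sub <- all[seqnames(all) == chr]
        if (length(sub) < 2) next
        gs <- end(sub)[-length(sub)] + 1L
        ge <- start(sub)[-1] - 1L
        keep <- ge >= gs
        out <- suppressWarnings(
            c(out, GRanges(chr, IRanges(gs[keep], ge[keep]))))
    }
    out
}

#' Simulate stranded coverage with planted transcript units
#'
#' Plants rectangular depth profiles (depth 4-8, i.e. at least twice the
#' default `minCov`) over `plantedUnits` transcript units:
#' `plantedInEnhancers` of them start (and lie) inside distinct enhancers,
#' the rest in intergenic gaps clear of all annotation.  Unit strands
#' alternate along the genome so no two same-strand units fall within
#' `maxGap` of each other, making recovery boundary-exact by design.
#' Uniform depth-1 noise runs (below `minCov`) are sprinkled on top.
#'
#' @param config a [simulationConfig()].
#' @param annotation output of [simulateAnnotation()].
#' @return list with `coverage` (a [StrandedCoverage-class]) and `truth`
#'   (`data.frame`: `chrom`, `start`, `end`, `strand`, `depth`,
#'   `in_enhancer`, `enhancer_id`, `target_gene`).
#' @export
simulateCoverage <- function(config, annotation) {
    set.seed(config$seed + 2L)
    enh <- annotation$enhancers
    hosts <- which(width(enh) >= 600)
    if (length(hosts) < config$plantedInEnhancers)
        stop("not enough enhancers of width >= 600 to host planted units")
    hosts <- sort(sample(hosts, config$plantedInEnhancers))
    hw <- width(enh)[hosts]
    uw <- pmin(hw - 100L, round(runif(length(hosts), 400, 1200)))
    off <- floor(runif(length(hosts)) * (hw - uw))
    ustart <- start(enh)[hosts] + off
    units <- GRanges(seqnames(enh)[hosts], IRanges(ustart, ustart + uw - 1L))
    inEnh <- rep(TRUE, length(units))
    hostId <- enh$enhancer_id[hosts]
    nInter <- config$plantedUnits - config$plantedInEnhancers
    if (nInter > 0) {
        margin <- config$maxGap + 10L
        gaps <- .annotationGaps(annotation)
        big <- gaps[width(gaps) >= 300 + 2 * margin]
        if (length(big) < nInter)
            stop("not enough intergenic room for planted units; ",
                 "increase chromLength")
        pick <- sort(sample(length(big), nInter))
        gw <- pmin(width(big)[pick] - 2 * margin, 700L)
        gs <- start(big)[pick] + margin
        units <- c(units, GRanges(seqnames(big)[pick],
                                  IRanges(gs, gs + gw - 1L)))
        inEnh <- c(inEnh, rep(FALSE, nInter))
        hostId <- c(hostId, rep(NA_character_, nInter))
    }
    o <- order(as.character(seqnames(units)), start(units))
    units <- units[o]; inEnh <- inEnh[o]; hostId <- hostId[o]
    strand(units) <- rep_len(c("+", "-"), length(units))
    depth <- sample(4:8, length(units), replace = TRUE)
    # depth-1 noise, pairwise disjoint within a strand so it can never
    # reach minCov by stacking
    nNoise <- 150L
    nchr <- sample(seq_len(config$nChromosomes), nNoise, replace = TRUE)
    npos <- floor(runif(nNoise, 1, config$chromLength - 200))
    noise <- GRanges(paste0("chr", nchr),
                     IRanges(npos, npos + round(runif(nNoise, 50, 150))))
    strand(noise) <- sample(c("+", "-"), nNoise, replace = TRUE)
    noise <- noise[!duplicated(paste(seqnames(noise), strand(noise),
                                     floor(start(noise) / 500)))]
    oneStrand <- function(s) {
        u <- units[strand(units) == s]
        nz <- noise[strand(noise) == s]
        nz <- nz[countOverlaps(nz, nz) == 1]  # drop self-overlapping noise
        # keep noise clear of planted units so their depth stays exact
        nz <- nz[countOverlaps(nz, units, ignore.strand = TRUE) == 0]
        gr <- c(granges(u), granges(nz))
        wt <- c(depth[as.logical(strand(units) == s)], rep(1, length(nz)))
        if (!length(gr)) return(GRanges(score = numeric()))
        cv <- coverage(gr, weight = wt)
        runs <- as(cv, "GRanges")
        runs <- runs[runs$score > 0]
        strand(runs) <- "*"
        runs
    }
    cov <- StrandedCoverage(plus = oneStrand("+"), minus = oneStrand("-"))
    truth <- data.frame(chrom = as.character(seqnames(units)),
                        start = start(units), end = end(units),
                        strand = as.character(strand(units)),
                        depth = depth, in_enhancer = inEnh,
                        enhancer_id = hostId,
                        target_gene = ifelse(
                            is.na(hostId), NA_character_,
                            unname(annotation$truth$targets[hostId])))
    list(coverage = cov, truth = truth)
}

#' Deterministic reference fixture for the integration bookkeeping
#'
#' A fully structural dataset (no random draws) encoding the catalog sizes
#' and planted effect assignments of a depletion study: 231 super-enhancers
#' (169 factor-bound, 104 down-called, 84 bound-and-down), 8,563 typical
#' enhancers (4,577 bound, 295 down, 201 bound-and-down), a 604-gene down
#' set partitioned 20 / 22 / 311 / 251 across the SE&TE / only-SE /
#' only-TE / not-assigned enhancer classes, 22 up genes (7 bound), 288
#' bound down genes, and direct-target branch overlaps of 26 and 86 genes
#' sharing one gene (union 111).  The DE tables are planted, not simulated,
#' so [integrateReport()] on this fixture is exact and fast.
#'
#' @return list with `genes`, `enhancers`, `peaks` (`GRanges`), `geneDE`,
#'   `enhDE` (DE tables), and `seMap`, `teMap` (enhancer to target-gene
#'   maps).
#' @examples
#' fx <- referenceFixture()
#' rep <- integrateReport(fx$geneDE, fx$enhDE, fx$genes, fx$enhancers,
#'                        fx$peaks, fx$seMap, fx$teMap)
#' rep
#' @export
referenceFixture <- function() {
    g <- function(i) sprintf("g%04d", i)
    f <- function(i) sprintf("f%04d", i)
    downGenes <- g(1:604)
    upGenes <- sprintf("u%03d", 1:22)
    filler <- f(1:500)
    geneIds <- c(downGenes, upGenes, filler)
    nGene <- length(geneIds)
    gs <- (seq_len(nGene) - 1L) * 2500L + 1L
    genes <- GRanges("chr1", IRanges(gs, gs + 1999L), strand = "+")
    genes$gene_id <- geneIds
    genes$biotype <- "protein_coding"

    # bound genes: the 288 of list 1, plus 7 of the 22 up genes
    list1 <- c(g(1:4), g(21:42), g(43:127), g(354:530))
    boundGenes <- c(list1, sprintf("u%03d", 1:7))

    # SE catalog, ordered: bound&down 1:84, down-only 85:104,
    # bound-only 105:189, neither 190:231
    seIds <- sprintf("SE%03d", 1:231)
    ss <- (0:230) * 6000L + 1L
    ses <- GRanges("chr2", IRanges(ss, ss + 4999L))
    ses$enhancer_id <- seIds
    ses$klass <- "SE"
    seBound <- seq_len(231) %in% c(1:84, 105:189)
    seDown <- seq_len(231) <= 104
    seMap <- character(231)
    seMap[1:26] <- c(g(1:4), g(21:42))
    seMap[27:84] <- f(1:58)
    seMap[85:104] <- f(59:78)
    seMap[105:120] <- g(5:20)
    seMap[121:231] <- f(79:189)
    names(seMap) <- seIds

    # TE catalog, ordered: bound&down 1:201, down-only 202:295,
    # bound-only 296:4671, neither 4672:8563
    teIds <- sprintf("TE%04d", 1:8563)
    ts <- (0:8562) * 1600L + 1L
    tes <- GRanges("chr3", IRanges(ts, ts + 999L))
    tes$enhancer_id <- teIds
    tes$klass <- "TE"
    teBound <- seq_len(8563) %in% c(1:201, 296:4671)
    teDown <- seq_len(8563) <= 295
    teMap <- character(8563)
    teMap[1:86] <- c(g(1), g(43:127))
    teMap[87:201] <- rep_len(filler, 115)
    teMap[202:295] <- rep_len(filler, 94)
    teMap[296:540] <- c(g(2:20), g(128:353))
    teMap[541:8563] <- rep_len(filler, 8023)
    names(teMap) <- teIds

    enhancers <- suppressWarnings(c(ses, tes))
    midPeak <- function(gr, bound) {
        m <- floor((start(gr) + end(gr)) / 2)[bound]
        GRanges(seqnames(gr)[bound], IRanges(m - 100L, m + 100L))
    }
    peaks <- suppressWarnings(
        c(midPeak(genes, genes$gene_id %in% boundGenes),
          midPeak(ses, seBound), midPeak(tes, teBound)))
    peaks$peak_id <- sprintf("peak%05d", seq_along(peaks))

    enhDown <- c(seDown, teDown)
    enhBound <- c(seBound, teBound)
    n <- length(enhDown)
    enhLfc <- ifelse(enhDown, -1 - 0.0002 * seq_len(n), 0.05)
    enhLfc[enhDown & enhBound] <- enhLfc[enhDown & enhBound] - 0.6
    enhP <- ifelse(enhDown, 1e-4, 0.9)
    enhDE <- DataFrame(feature_id = c(seIds, teIds),
                       baseMean = 100, log2fc = enhLfc, lfcSE = 0.2,
                       pvalue = enhP, padj = bhAdjust(enhP))

    classDepth <- c(rep(-3.0, 20), rep(-2.5, 22), rep(-1.8, 311),
                    rep(-1.3, 251))
    geneLfc <- c(classDepth - 0.0005 * seq_len(604),
                 rep(1.5, 22), rep(0.02, 500))
    geneSig <- geneIds %in% c(downGenes, upGenes)
    geneP <- ifelse(geneSig, 1e-6, 0.9)
    geneDE <- DataFrame(feature_id = geneIds,
                        baseMean = 100, log2fc = geneLfc, lfcSE = 0.2,
                        pvalue = geneP, padj = ifelse(geneSig, 1e-5, 0.95))

    list(genes = genes, enhancers = enhancers, peaks = peaks,
         geneDE = geneDE, enhDE = enhDE, seMap = seMap, teMap = teMap)
}
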