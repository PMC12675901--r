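mkExp <- function(k, cond, spike = NULL) {
    if (is.null(rownames(k))) rownames(k) <- paste0("f", seq_len(nrow(k)))
    if (is.null(colnames(k))) colnames(k) <- paste0("s", seq_len(ncol(k)))
    DegronExperiment(k, isSpikein = spike, condition = cond)
}

test_that("size factors follow the median-of-ratios definition", {
    # identical samples -> unit factors
    k <- cbind(a = c(5, 10, 20), b = c(5, 10, 20))
    sf <- calcSizeFactors(mkExp(k, c("x", "y")))
    expect_equal(unname(sf), c(1, 1), ignore_attr = TRUE)
    # two samples, three spike-ins, consistent 2-fold depth difference
    k2 <- cbind(A = c(10, 20, 40), B = c(20, 40, 80))
    sf2 <- calcSizeFactors(mkExp(k2, c("x", "y"), spike = rep(TRUE, 3)))
    expect_equal(unname(sf2), c(1 / sqrt(2), sqrt(2)),
                 ignore_attr = TRUE)
    expect_equal(exp(mean(log(sf2))), 1)
    expect_identical(attr(sf2, "method"), "spikein")
    # no usable reference features
    expect_error(calcSizeFactors(mkExp(k, c("x", "y")),
                                 useSpikeinsOnly = TRUE),
                 "no spike-in features")
    k3 <- cbind(a = c(0, 5), b = c(3, 0))
    expect_error(calcSizeFactors(mkExp(k3, c("x", "y"))),
                 "non-zero counts in every sample")
})

test_that("spike-in factors recover known depth ratios within 5%", {
    set.seed(31)
    depth <- c(1, 0.5, 2)
    k <- sapply(depth, function(d) rpois(100, 500 * d))
    dimnames(k) <- list(paste0("sp", 1:100), paste0("s", 1:3))
    sf <- calcSizeFactors(mkExp(k, paste0("c", 1:3), spike = rep(TRUE, 100)))
    truth <- depth / exp(mean(log(depth)))
    expect_true(all(abs(sf / truth - 1) < 0.05))
})

test_that("spike-in factors are invariant to fold changes on biological rows", {
    set.seed(37)
    k <- rbind(matrix(rpois(300, 200), 100, 3),
               matrix(rpois(150, 500), 50, 3))
    dimnames(k) <- list(c(paste0("g", 1:100), paste0("sp", 1:50)),
                        paste0("s", 1:3))
    spike <- c(rep(FALSE, 100), rep(TRUE, 50))
    x1 <- mkExp(k, paste0("c", 1:3), spike = spike)
    k2 <- k
    k2[1:100, 2:3] <- round(k2[1:100, 2:3] * 0.1)  # global shutdown
    x2 <- mkExp(k2, paste0("c", 1:3), spike = spike)
    sf1 <- calcSizeFactors(x1, TRUE)
    sf2 <- calcSizeFactors(x2, TRUE)
    expect_true(max(abs(sf1 - sf2)) < 1e-6)
})

test_that("method-of-moments dispersion behaves at its limits and recovers truth", {
    set.seed(41)
    sf1 <- function(n) setNames(rep(1, n), paste0("s", seq_len(n)))
    # Poisson counts: variance ~ mean, most features at the floor
    kp <- matrix(rpois(200 * 100, 200), 200, 100)
    xp <- mkExp(kp, rep(c("a", "b"), each = 50))
    dp <- momDispersion(xp, sf1(100))
    expect_gt(mean(dp < 0.01), 0.9)
    # NB truth alpha = 0.1, 50 replicates per group
    kn <- matrix(rnbinom(300 * 100, mu = 200, size = 10), 300, 100)
    xn <- mkExp(kn, rep(c("a", "b"), each = 50))
    dn <- momDispersion(xn, sf1(100))
    expect_gt(median(dn), 0.05)
    expect_lt(median(dn), 0.2)
    # constant feature -> zero variance -> floor
    kc <- matrix(7, 1, 4, dimnames = list("c1", paste0("s", 1:4)))
    xc <- mkExp(kc, rep(c("a", "b"), each = 2))
    expect_equal(unname(momDispersion(xc, sf1(4))), 1e-8,
                 ignore_attr = TRUE)
    # all-zero feature flagged at the floor
    kz <- rbind(z = rep(0, 4), y = c(5, 6, 7, 8))
    colnames(kz) <- paste0("s", 1:4)
    dz <- momDispersion(mkExp(kz, rep(c("a", "b"), each = 2)), sf1(4))
    expect_equal(unname(dz["z"]), 1e-8)
    expect_true(attr(dz, "allZero")[1])
})

test_that("the Wald test is null-centred and recovers planted fold changes", {
    set.seed(43)
    sf <- setNames(rep(1, 6), paste0("s", 1:6))
    # identical groups: zero fold change, p ~ 1
    k <- matrix(rep(c(10, 20, 30), 6), 3, 6, byrow = FALSE,
                dimnames = list(paste0("f", 1:3), paste0("s", 1:6)))
    r0 <- waldTest(mkExp(k, rep(c("a", "b"), each = 3)), "a", "b",
                   sizeFactors = sf)
    expect_true(all(r0$log2fc == 0))
    expect_true(all(r0$pvalue > 0.99))
    # silent features are reported neutral
    kz <- rbind(k, z = rep(0, 6))
    rz <- waldTest(mkExp(kz, rep(c("a", "b"), each = 3)), "a", "b",
                   sizeFactors = sf)
    expect_equal(unname(rz["z", "log2fc"]), 0)
    expect_equal(unname(rz["z", "pvalue"]), 1)
    # planted 4-fold decrease, mean 200, 3 vs 3
    mu <- cbind(matrix(200, 500, 3), matrix(50, 500, 3))
    k4 <- matrix(rnbinom(length(mu), mu = mu, size = 20), 500, 6,
                 dimnames = list(paste0("f", 1:500), paste0("s", 1:6)))
    r4 <- waldTest(mkExp(k4, rep(c("c", "t"), each = 3)), "c", "t",
                   sizeFactors = sf)
    expect_lt(abs(median(r4$log2fc) - (-2)), 0.3)
    expect_error(waldTest(mkExp(k, rep("a", 6)), "a", "b"),
                 "must be present")
})

test_that("null Wald p-values are calibrated when dispersion is known", {
    set.seed(47)
    k <- matrix(rnbinom(2000 * 6, mu = 200, size = 20), 2000, 6,
                dimnames = list(paste0("f", 1:2000), paste0("s", 1:6)))
    x <- mkExp(k, rep(c("a", "b"), each = 3))
    sf <- setNames(rep(1, 6), colnames(k))
    r <- waldTest(x, "a", "b", sizeFactors = sf,
                  dispersions = rep(0.05, 2000))
    t1 <- mean(r$pvalue < 0.05)
    expect_gt(t1, 0.03)
    expect_lt(t1, 0.08)
    ks <- suppressWarnings(
        stats::ks.test(r$pvalue, "punif")$statistic)
    expect_lt(unname(ks), 0.05)
    # plug-in moment dispersion at n = 3 is at most mildly anti-conservative
    rp <- waldTest(x, "a", "b", sizeFactors = sf)
    expect_lt(mean(rp$pvalue < 0.05), 0.15)
})

test_that("BH adjustment matches the step-up definition", {
    expect_equal(bhAdjust(0.03), 0.03)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(53)
    for (n in c(10, 100, 2000, 10000)) {
        p <- runif(n)^2
        expect_equal(bhAdjust(p), bfBH(p), label = paste("n =", n))
    }
    # permutation equivariance and pointwise padj >= p
    p <- runif(200)
    perm <- sample(200)
    expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
    expect_true(all(bhAdjust(p) >= p))
})

test_that("threshold calling partitions features exhaustively", {
    res <- S4Vectors::DataFrame(
        feature_id = c("a", "b", "c", "d"),
        log2fc = c(-1.2, -0.9, 1.1, 0.2),
        pvalue = c(0.001, 0.0005, 0.01, 0.5),
        padj = c(0.01, 0.001, 0.03, 0.8))
    called <- callFeatures(res, 2, 0.05, useAdjusted = TRUE)
    expect_equal(as.character(called$call), c("down", "ns", "up", "ns"))
    set.seed(59)
    res2 <- S4Vectors::DataFrame(
        feature_id = sprintf("f%03d", 1:300),
        log2fc = rnorm(300, 0, 1.5),
        pvalue = runif(300))
    res2$padj <- bhAdjust(res2$pvalue)
    sets <- featureSets(callFeatures(res2, 1.5, 0.05, FALSE))
    expect_equal(sum(lengths(sets)), 300)
    expect_equal(sort(unlist(sets, use.names = FALSE)),
                 sort(res2$feature_id))
})

test_that("rank-sum test: exact enumeration path and approximation agree", {
    mw <- mannWhitney(c(1, 2), c(3, 4))
    expect_equal(mw$U, 0)
    expect_equal(mw$p.value, 2 / 6)
    expect_true(mw$exact)
    # identical samples -> p = 1
    expect_equal(mannWhitney(c(1, 2), c(1, 2))$p.value, 1)
    expect_equal(mannWhitney(c(5, 5), c(5, 5))$p.value, 1)
    expect_error(mannWhitney(numeric(), 1), "non-empty")
    # exact path vs full enumeration on random tie-free instances
    set.seed(61)
    for (i in 1:200) {
        n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
        v <- sample(1000, n1 + n2)  # distinct -> no ties
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        got <- mannWhitney(x, y)
        want <- bfMannWhitneyExact(x, y)
        expect_true(got$exact)
        expect_equal(got$p.value, want$p, tolerance = 1e-12,
                     label = paste("instance", i))
    }
    # approximate path close to the exact distribution at n1 = n2 = 15
    set.seed(67)
    for (i in 1:20) {
        v <- sample(10000, 30)
        x <- v[1:15]; y <- v[16:30]
        approx <- mannWhitney(x, y)
        expect_false(approx$exact)
        exact <- stats::wilcox.test(x, y, exact = TRUE)$p.value
        expect_lt(abs(approx$p.value - exact), 0.02)
    }
})
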