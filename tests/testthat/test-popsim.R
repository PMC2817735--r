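test_that("genotype simulation reproduces the RI1 two-locus law", {
    set.seed(101)
    ## adjacent loci: switch frequency = rilExpand(haldaneRecomb(d)) exactly
    for (d in c(5, 10, 20, 50)) {
        map2 <- GeneticMap(chrom = c(1L, 1L), name = c("a", "b"), pos = c(0, d))
        g <- simulateGenotypes(map2, n = 10000)
        expected <- rilExpand(haldaneRecomb(d))
        tol <- 3 * sqrt(expected * (1 - expected) / 10000)
        expect_equal(mean(g[, 1] != g[, 2]), expected, tolerance = tol / expected)
    }
})

test_that("coincident loci are identical; different chromosomes independent", {
    set.seed(102)
    loci <- data.frame(chrom = c(1L, 1L), name = c("a", "b"), pos = c(7, 7))
    g <- qtlci:::.simulate_geno(loci, 500)
    expect_identical(g[, 1], g[, 2])
    map2 <- GeneticMap(chrom = c(1L, 2L), name = c("a", "b"), pos = c(0, 0))
    g2 <- simulateGenotypes(map2, n = 4000)
    expect_lt(abs(cor(g2[, 1], g2[, 2])), 4 / sqrt(4000))
})

test_that("marginal class frequencies are balanced at every locus", {
    set.seed(103)
    g <- simulateGenotypes(benchmarkMap(), n = 2000)
    freq <- colMeans(g == 1)
    expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 2000)))
    expect_true(all(g %in% c(-1L, 1L)))
})

test_that("trait model delivers the prescribed variance decomposition", {
    set.seed(104)
    ## sigma_e^2 = 4 a^2 (1-h2)/h2 = 8/3 at a = 1, h2 = 0.6, 4 QTL
    q <- matrix(sign(runif(4000 * 4) - 0.5), ncol = 4)
    y <- simulateTrait(q, effect = 1, h2 = 0.6)
    e <- y - rowSums(q)
    expect_equal(var(e), 8 / 3, tolerance = 0.1)
    ## law of large numbers: realized R^2 -> 0.6
    q <- matrix(sign(runif(1e5 * 4) - 0.5), ncol = 4)
    y <- simulateTrait(q, effect = 1, h2 = 0.6)
    r2 <- summary(lm(y ~ q))$r.squared
    expect_equal(r2, 0.6, tolerance = 0.01 / 0.6)
    ## null trait: pure noise, no association
    y0 <- simulateTrait(q[1:1000, ], effect = 0, h2 = 0.6)
    expect_gt(var(y0), 0.5)
    expect_lt(summary(lm(y0 ~ q[1:1000, ]))$r.squared, 0.02)
    expect_error(simulateTrait(q, 1, h2 = 1.2), "h2")
})

test_that("simulated cross releases markers only and is seed-reproducible", {
    cross <- simulateCross(n = 50, D = 0, seed = 99)
    expect_s4_class(cross, "RILCross")
    expect_equal(nrow(cross), 92)                    # 4 x 23 markers
    expect_equal(ncol(cross), 50)
    expect_true(all(genotypeMatrix(cross) %in% c(-1, 1)))
    expect_equal(qtlTruth(cross)$pos, c(11, 23, 69, 114))
    cross2 <- simulateCross(n = 50, D = 0, seed = 99)
    expect_identical(genotypeMatrix(cross), genotypeMatrix(cross2))
    expect_identical(trait(cross), trait(cross2))
    ## D = 0: QTL coincides with its left flanking marker, so the marker
    ## column carries the full genetic signal
    q <- genotypeMatrix(cross)[, match(c(11, 23, 69, 114),
        SummarizedExperiment::rowData(cross)$pos[1:23])]
    expect_equal(ncol(q), 4)
})

test_that("realized heritability averages to the nominal 0.6", {
    set.seed(105)
    h2r <- vapply(1:200, function(i) {
        cross <- simulateCross(n = 200, D = 0)
        rd <- SummarizedExperiment::rowData(cross)
        qcols <- which(paste(rd$chrom, rd$pos) %in%
                       c("1 11", "2 23", "3 69", "4 114"))
        g <- rowSums(genotypeMatrix(cross)[, qcols])
        var(g) / var(trait(cross))
    }, numeric(1))
    expect_equal(mean(h2r), 0.6, tolerance = 0.03 / 0.6)
})
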