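test_that("regression LOD matches a brute-force least-squares oracle", {
    set.seed(201)
    for (i in 1:5) {
        y <- rnorm(50); x <- rnorm(50); cov <- matrix(rnorm(100), ncol = 2)
        expect_equal(regressionLOD(y, x, cov), ols_lod_oracle(y, x, cov),
                     tolerance = 1e-10)
        expect_equal(regressionLOD(y, x), ols_lod_oracle(y, x), tolerance = 1e-10)
    }
    ## perfect fit hits the cap; collinear covariates warn
    y <- rnorm(30)
    expect_equal(regressionLOD(y, y), 1000)
    expect_warning(regressionLOD(y, rnorm(30), cbind(1:30, 2 * (1:30))),
                   "collinear")
})

test_that("null-data LOD has the chi-square(1)/2ln10 median", {
    set.seed(202)
    n <- 200; nsim <- 4000
    Y <- matrix(rnorm(n * nsim), n); X <- matrix(rnorm(n * nsim), n)
    Yc <- scale(Y); Xc <- scale(X)
    r2 <- (colSums(Yc * Xc) / (n - 1))^2
    lods <- -(n / 2) * log10(1 - r2)
    expect_equal(median(lods), 0.098788, tolerance = 0.12)
})

test_that("conditional QTL expectation agrees with chain enumeration", {
    expect_identical(conditionalExpectation(1, 1, 0, 7), 1)    # at the marker
    expect_identical(conditionalExpectation(-1, 1, 0, 7), -1)
    expect_equal(conditionalExpectation(1, -1, 10, 10), 0)     # symmetry
    for (dL in c(1, 5, 10, 25)) for (dR in c(2, 10, 40))
        for (mL in c(1, -1)) for (mR in c(1, -1))
            expect_equal(conditionalExpectation(mL, mR, dL, dR),
                         cond_exp_oracle(mL, mR, dL, dR), tolerance = 1e-12)
    expect_equal(conditionalExpectation(1, 1, 10, 10), 0.9363735911,
                 tolerance = 1e-8)
    expect_error(conditionalExpectation(1, -1, 0, 0), "impossible")
    expect_error(conditionalExpectation(1, 1, -1, 5), "non-negative")
})

test_that("stepwise selection matches an exhaustive lm-based oracle", {
    set.seed(203)
    map3 <- GeneticMap(chrom = rep(1L, 3), name = c("a", "b", "c"),
                       pos = c(0, 20, 40))
    for (i in 1:10) {
        g <- simulateGenotypes(map3, n = 40)
        y <- 0.8 * g[, sample(3, 1)] + rnorm(40)
        cross <- RILCross(g, map3, y)
        got <- stepwiseCofactors(cross)
        ## identical selected set, every partial F recomputed independently
        expect_setequal(got@idx, as.integer(stepwise_oracle(g, y)))
        ## returned ranking is by final drop-one p-value, strongest first
        if (length(got) > 1) {
            pd <- qtlci:::.drop_pvalues(g, got@idx, y)
            expect_true(!is.unsorted(pd))
        }
    }
})

test_that("stepwise honors entry threshold, step bound and dominant markers", {
    set.seed(204)
    cross <- simulateCross(n = 200, D = 0, seed = 12)
    g <- genotypeMatrix(cross)
    ## overwhelming single effect enters first
    y <- 10 * g[, 7] + rnorm(200, 0, 0.1)           # marker at 11 cM, chr 1
    strong <- stepwiseCofactors(RILCross(g, geneticMap(cross), y))
    expect_equal(strong@idx[1], 7L)
    ## independent trait: <= 10 members, all with final drop p < 0.05
    y0 <- rnorm(200)
    s0 <- stepwiseCofactors(RILCross(g, geneticMap(cross), y0))
    expect_lte(length(s0), 10)
    if (length(s0) > 0) {
        pd <- qtlci:::.drop_pvalues(g, s0@idx, y0)
        expect_true(all(pd <= 0.05))
    }
})

test_that("scan grid covers each chromosome end to end at the walk step", {
    cross <- simulateCross(n = 60, D = 0, seed = 31)
    prof <- cimScan(cross)
    d <- as.data.frame(prof)
    for (c in 1:4) {
        p <- d$pos[d$chrom == c]
        expect_length(p, 166)                 # 165 cM at 1 cM walk, both ends
        expect_equal(p, 0:165)
    }
    expect_true(all(d$lod >= 0))
    expect_error(cimScan(cross, settings = scanSettings(walk = 0)))
})

test_that("cofactor-free scan equals single-marker regression at markers", {
    set.seed(205)
    cross <- simulateCross(n = 120, D = 0.3, seed = 77)
    prof <- cimScan(cross)                     # SIM
    d <- as.data.frame(prof)
    g <- genotypeMatrix(cross); y <- trait(cross)
    rd <- SummarizedExperiment::rowData(cross)
    for (j in c(1, 7, 30, 50, 92)) {
        at <- which(d$chrom == rd$chrom[j] & abs(d$pos - rd$pos[j]) < 1e-9)
        expect_equal(d$lod[at], ols_lod_oracle(y, g[, j]), tolerance = 1e-8)
    }
})

test_that("blockout window removes same-chromosome cofactors, boundary included", {
    cross <- simulateCross(n = 80, D = 0, seed = 41)
    rd <- SummarizedExperiment::rowData(cross)
    cof <- c(which(rd$chrom == 1 & rd$pos == 20),   # on the scanned chromosome
             which(rd$chrom == 2 & rd$pos == 23))   # never blocked on chr 1
    prof <- cimScan(cross, cof)
    d <- as.data.frame(prof)
    on1 <- d[d$chrom == 1, ]
    ## blocked iff the cofactor at 20 cM is within 10 cM of the test
    ## position or flanks its marker interval; on this map that is exactly
    ## the radius, i.e. positions 10..30 (boundary blocked)
    expect_equal(on1$ncov, ifelse(on1$pos >= 10 & on1$pos <= 30, 1L, 2L))
    ## the scan contract: a cofactor at 20 is excluded when testing 15
    expect_equal(on1$ncov[on1$pos == 15], 1L)
    expect_equal(on1$ncov[on1$pos == 9], 2L)      # just outside radius & interval
    expect_true(all(d$ncov[d$chrom == 3] == 2))
    ## flanking markers of a wide test interval are blocked beyond the radius
    rd4 <- which(rd$chrom == 4 & rd$pos == 114)
    prof4 <- cimScan(cross, c(rd4, cof[2]))
    d4 <- as.data.frame(prof4)
    on4 <- d4[d4$chrom == 4, ]
    ## at 133 cM the 114 cofactor is 19 cM away yet flanks the (114,134)
    ## interval, so it is still excluded
    expect_equal(on4$ncov[on4$pos == 133], 1L)
    expect_equal(on4$ncov[on4$pos == 135], 2L)    # next interval: 114 active
})

test_that("LOD profile is invariant to affine trait rescaling", {
    cross <- simulateCross(n = 80, D = 0, seed = 51)
    cof <- stepwiseCofactors(cross)
    p1 <- cimScan(cross, cof)
    cross2 <- RILCross(genotypeMatrix(cross), geneticMap(cross),
                       3.7 * trait(cross) - 11)
    p2 <- cimScan(cross2, cof)
    expect_equal(p1@lod, p2@lod, tolerance = 1e-8)
})

test_that("scan localizes a strong isolated QTL", {
    set.seed(206)
    hit <- vapply(1:100, function(i) {
        cross <- one_qtl_cross(n = 200, effect = 3, h2 = 0.9, qtlPos = 11)
        pk <- peakPositions(cimScan(cross))
        abs(pk$pos[1] - 11) <= 2
    }, logical(1))
    expect_gte(mean(hit), 0.95)
})
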