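test_that("support interval follows the LOD drop on hand-built curves", {
    ## tent: LOD 5 at 50 cM falling 1 per cM; drop 2 keeps [48, 52]
    pos <- 0:100
    tent <- profile_from(pos, pmax(0, 5 - abs(pos - 50)))
    si <- supportInterval(tent, drop = 2)
    expect_equal(c(si$lower, si$upper, si$width), c(48, 52, 4))
    expect_equal(si$peak, 50)
    ## flat curve: whole chromosome
    flat <- profile_from(pos, rep(1, 101))
    sif <- supportInterval(flat, drop = 2)
    expect_equal(c(sif$lower, sif$upper), c(0, 100))
    ## monotone increasing: truncated at the right end
    mono <- profile_from(pos, pos / 10)
    sim <- supportInterval(mono, drop = 2)
    expect_equal(sim$peak, 100)
    expect_equal(sim$upper, 100)
    expect_equal(sim$lower, 80)
    ## a dip below the drop cuts the interval even if the curve recovers
    dip <- profile_from(0:10, c(4, 4, 0, 4, 5, 4, 4, 4, 4, 4, 4))
    sid <- supportInterval(dip, drop = 2)
    expect_equal(c(sid$peak, sid$lower, sid$upper), c(4, 3, 10))
    ## SI always contains the scan argmax
    expect_true(with(supportInterval(tent), lower <= peak & peak <= upper))
})

test_that("percentile interval applies the order-statistic rule", {
    expect_equal(unname(percentileInterval(1:1000)), c(25, 975))
    expect_equal(unname(percentileInterval(1:40)), c(1, 39))
    expect_equal(unname(percentileInterval(rep(7, 50))), c(7, 7))
    expect_equal(unname(percentileInterval(sample(1:1000))), c(25, 975))
    ## equivariance under monotone relabeling
    x <- runif(200)
    ci <- percentileInterval(x)
    expect_equal(unname(percentileInterval(exp(x))), unname(exp(ci)))
    expect_error(percentileInterval(5), "at least 2")
})

test_that("selective filter keeps supra-threshold peaks and errors when empty", {
    pk <- data.frame(chrom = 1, pos = 1:4, height = 1:4)
    expect_identical(selectiveFilter(pk, 0), pk)
    expect_equal(nrow(selectiveFilter(pk, 2.5)), 2)
    expect_equal(selectiveFilter(pk, 2.5)$height, c(3, 4))
    expect_error(selectiveFilter(pk, Inf), class = "qtlci_no_significant_peaks")
})

test_that("permutation threshold is the ceiling(P(1-alpha)) order statistic", {
    cross <- makeFixture("tiny-one-qtl")
    set.seed(301)
    th <- permutationThreshold(cross, P = 20, alpha = 0.05)
    expect_length(th$nullMaxLods, 20)
    expect_equal(th$threshold, sort(th$nullMaxLods)[19])
    expect_error(permutationThreshold(cross, P = 10, alpha = 0.05),
                 "quantile undefined")
    ## constant trait: degenerate, warned, threshold ~ 0
    flat <- RILCross(genotypeMatrix(cross), geneticMap(cross),
                     rep(1, ncol(cross)))
    expect_warning(th0 <- permutationThreshold(flat, P = 20), "degenerate")
    expect_equal(th0$threshold, 0)
})

test_that("bootstrap peaks: frozen cofactors, determinism, localization", {
    cross <- one_qtl_cross(n = 200, effect = 3, h2 = 0.9, qtlPos = 11)
    cof <- stepwiseCofactors(cross)
    set.seed(302)
    bp <- bootstrapPeaks(cross, B = 30, reselect = FALSE, cofactors = cof)
    ## frozen: every replicate reports the identical cofactor set
    expect_true(all(vapply(bp$cofactors, identical, logical(1), y = cof@idx)))
    set.seed(302)
    bp2 <- bootstrapPeaks(cross, B = 30, reselect = FALSE, cofactors = cof)
    expect_identical(bp$peaks, bp2$peaks)          # same seed, same peaks
    ## strong QTL at 11 cM: peaks concentrate there
    set.seed(303)
    bp3 <- bootstrapPeaks(cross, B = 50, reselect = TRUE)
    on1 <- bp3$peaks[bp3$peaks$chrom == 1, ]
    expect_gte(mean(abs(on1$pos - 11) <= 3), 0.9)
})

test_that("NPCI and CIM-NPCI coincide when re-selection is forced identical", {
    ## with a single dominant marker and a tiny entry p-value, stepwise can
    ## only ever pick that marker, so freezing vs re-selecting is identical
    set.seed(304)
    map2 <- GeneticMap(chrom = rep(1:2, each = 2), name = c("a", "b", "c", "d"),
                       pos = rep(c(0, 80), 2))
    g <- simulateGenotypes(map2, n = 120)
    y <- 3 * g[, 1] + rnorm(120, 0, 0.5)
    cross <- RILCross(g, map2, y)
    st <- scanSettings(pEntry = 1e-8)
    set.seed(42)
    a <- npci(cross, B = 40, P = 20, settings = st)
    set.seed(42)
    b <- cimNPCI(cross, B = 40, P = 20, settings = st)
    expect_equal(a[, c("lower", "upper", "peak", "threshold")],
                 b[, c("lower", "upper", "peak", "threshold")])
})

test_that("bootstrap CI orchestration: significance gating and variants", {
    cross <- one_qtl_cross(n = 200, effect = 3, h2 = 0.9, qtlPos = 11)
    set.seed(305)
    ci <- cimNPCI(cross, B = 60, P = 20)
    expect_equal(nrow(ci), 1)                      # one chromosome
    expect_true(ci$significant)
    expect_true(ci$lower <= ci$peak & ci$peak <= ci$upper)
    expect_true(ci$lower <= 11 & 11 <= ci$upper)
    expect_equal(ci$method, "CIM-NPCI")
    ## selective positions are a subset of the non-selective ones
    set.seed(306)
    bp <- bootstrapPeaks(cross, B = 60, reselect = TRUE)
    th <- 2
    kept <- selectiveFilter(bp$peaks, th)
    expect_true(all(kept$pos %in% bp$peaks$pos))
    ci_sel <- percentileInterval(kept$pos)
    ci_all <- percentileInterval(bp$peaks$pos)
    expect_gte(ci_sel[1], min(bp$peaks$pos))
    expect_lte(ci_sel[2], max(bp$peaks$pos))
    ## a null trait yields no significant chromosome
    null <- makeFixture("tiny-null")
    set.seed(307)
    ci0 <- npci(null, B = 20, P = 20)
    expect_true(all(is.na(ci0$width[!ci0$significant])))
})
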