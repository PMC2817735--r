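tiny_cfg <- function(N = 2, seed = 5)
    studyConfig(n = 120, N = N, B = 40, P = 20, seed = seed)

test_that("sub-simulation records and summaries are complete and consistent", {
    cfg <- tiny_cfg()
    res <- runSubsimulation(0, cfg, methods = c("si", "npci", "cim-npci"))
    r <- res$records
    ## per dataset: 4 SI rows + 4 chrom x 2 methods x 2 variants
    expect_equal(nrow(r), cfg$N * (4 + 16))
    expect_setequal(unique(r$method), c("SI", "NPCI", "CIM-NPCI"))
    s <- res$summary
    ## coverage and its SE match a brute-force recount
    for (k in seq_len(nrow(s))) {
        sel <- r$chrom == s$chrom[k] & r$method == s$method[k] &
               (is.na(r$selective) == is.na(s$selective[k])) &
               (is.na(s$selective[k]) | r$selective %in% s$selective[k])
        expect_equal(s$coverage[k], mean(r$covered[sel]))
        expect_equal(s$seCoverage[k],
                     sqrt(s$coverage[k] * (1 - s$coverage[k]) / sum(sel)))
    }
    expect_true(all(s$N == cfg$N))
})

test_that("studies are deterministic under the master seed", {
    cfg <- tiny_cfg()
    a <- runSubsimulation(0.3, cfg, methods = "si")
    b <- runSubsimulation(0.3, cfg, methods = "si")
    expect_identical(a$summary, b$summary)
    expect_identical(a$records, b$records)
})

test_that("full study emits one cell per D x QTL x method", {
    cfg <- studyConfig(n = 100, N = 1, B = 30, P = 20, seed = 9)
    out <- runFullStudy(cfg, methods = c("si", "cim-npci"))
    expect_equal(nrow(out$widths), 4 * 4 * 2)      # 4 D x 4 QTL x 2 methods
    expect_equal(nrow(out$coverage), 32)
    expect_setequal(unique(out$widths$D), c(0, 0.10, 0.30, 0.50))
})

test_that("end-effect study relocates Q1 to 154/152/148/144", {
    cfg <- studyConfig(n = 100, N = 1, B = 30, P = 20, seed = 9)
    out <- runEndEffectStudy(cfg, methods = "si")
    q1 <- out$summary[out$summary$chrom == 1, ]
    expect_setequal(q1$qtlPos, c(154, 152, 148, 144))
    ## the 0% variant sits 11 cM from the 165 cM telomere
    expect_equal(165 - max(q1$qtlPos), 11)
    ## Q2-Q4 placements unchanged
    r <- out$records
    expect_true(all(r$chrom %in% 1:4))
    badmap <- GeneticMap(chrom = rep(1:4, each = 3),
                         name = paste0("m", 1:12),
                         pos = rep(c(0, 80, 165), 4))
    cfg2 <- studyConfig(N = 1, map = badmap)
    expect_error(runEndEffectStudy(cfg2), "134 and 154")
})

test_that("selective/non-selective comparison pairs the same peak lists", {
    ## identical variant records -> correlation 1, zero mean difference
    rec <- expand.grid(D = c(0, 0.1, 0.3, 0.5), chrom = 1:4,
                       selective = c(TRUE, FALSE))
    rec$method <- "CIM-NPCI"
    rec$width <- 5 + rec$D * 10 + rec$chrom          # varies across cells
    rec$covered <- rec$chrom %% 2 == 0
    cmp <- compareSelective(rec)
    expect_equal(nrow(cmp$cells), 16)
    expect_equal(cmp$correlationWidth, 1)
    expect_equal(cmp$meanWidthDifference, 0)
    ## a real (tiny) run produces finite paired summaries for all 16 cells
    cfg <- studyConfig(n = 100, N = 1, B = 40, P = 20, seed = 13)
    out <- runFullStudy(cfg, methods = "cim-npci")
    cmp2 <- compareSelective(out$records)
    expect_equal(nrow(cmp2$cells), 16)
    expect_true(is.finite(cmp2$meanWidthDifference))
})
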