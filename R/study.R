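#' Configuration of the benchmark simulation study
#'
#' Bundles the population design (4 x 165 cM chromosomes, 23 markers each,
#' four equal additive QTL, n lines at heritability h2), the analysis
#' settings, and the replication counts for a coverage/width study. The full
#' study uses N = 1000 datasets per sub-simulation with B = 1000 bootstraps
#' and P = 1000 permutations; `reduced = TRUE` installs desk-scale counts
#' (N = 50, B = 200, P = 100) whose estimates carry sqrt(N_full/N_reduced)
#' wider standard errors.
#'
#' @param n lines per dataset (200).
#' @param N datasets per sub-simulation.
#' @param B bootstrap replicates per dataset.
#' @param P permutations per dataset.
#' @param h2 heritability (0.6).
#' @param effect common additive QTL effect a (1).
#' @param D fractional distances from the left flanking marker defining the
#'   sub-simulations (0, 0.10, 0.30, 0.50).
#' @param map the genetic map (benchmark map by default).
#' @param settings a \linkS4class{ScanSettings}.
#' @param lodDrop LOD drop for support intervals (2.0).
#' @param alpha interval/threshold level (0.05).
#' @param seed master seed; every dataset derives its own reproducible
#'   stream from it by counter.
#' @param reduced install the desk-scale replication counts.
#' @return a list of class `StudyConfig`.
#' @export
studyConfig <- function(n = 200, N = 1000, B = 1000, P = 1000, h2 = 0.6,
                        effect = 1, D = c(0, 0.10, 0.30, 0.50),
                        map = benchmarkMap(), settings = scanSettings(),
                        lodDrop = 2.0, alpha = 0.05, seed = 1,
                        reduced = FALSE) {
    if (reduced) { N <- 50; B <- 200; P <- 100 }
    stopifnot(n >= 10, N >= 1, B >= 1, P >= 1, h2 > 0, h2 < 1,
              all(D >= 0 & D < 1))
    structure(list(n = n, N = N, B = B, P = P, h2 = h2, effect = effect,
                   D = D, map = map, settings = settings, lodDrop = lodDrop,
                   alpha = alpha, seed = seed),
              class = "StudyConfig")
}

## Analyze one simulated dataset with the requested interval methods.
## Returns one data.frame row per (chromosome, method, selective-variant).
.analyze_dataset <- function(cross, config, methods) {
    settings <- config$settings
    core <- .core_from_cross(cross, settings)
    y <- trait(cross)
    truth <- qtlTruth(cross)
    tpos <- truth$pos[match(core$chroms, truth$chrom)]
    cof0 <- .stepwise(core$M, y, settings@pEntry, settings@maxForwardSteps)
    sc <- .lod_scan(core, core$M, core$X, y, cof0, settings)
    rows <- list()
    if ("si" %in% methods) {
        prof <- new("LODProfile", chrom = as.integer(core$gchrom),
                    pos = core$gpos, lod = sc$lod, ncov = sc$ncov)
        si <- supportInterval(prof, drop = config$lodDrop)
        rows[[length(rows) + 1L]] <- data.frame(
            chrom = si$chrom, method = "SI", selective = NA,
            lower = si$lower, upper = si$upper, width = si$width,
            covered = si$lower - 1e-9 <= tpos & tpos <= si$upper + 1e-9,
            significant = TRUE, threshold = NA_real_, fallback = FALSE,
            stringsAsFactors = FALSE)
    }
    boot <- intersect(c("npci", "cim-npci"), methods)
    if (length(boot)) {
        thr <- sort(.perm_null_maxima(core, y, config$P, settings))[
            ceiling(config$P * (1 - config$alpha))]
        orig <- .scan_peaks(core, sc$lod)
        for (m in boot) {
            bp <- .boot_peaks(core, y, config$B, reselect = (m == "cim-npci"),
                              frozen = cof0, settings = settings)
            used <- !bp$skipped
            for (ci in seq_along(core$chroms)) {
                sig <- orig[ci, 2L] > thr
                for (sel in c(TRUE, FALSE)) {
                    row <- data.frame(chrom = core$chroms[ci],
                                      method = toupper(m), selective = sel,
                                      lower = NA_real_, upper = NA_real_,
                                      width = NA_real_, covered = FALSE,
                                      significant = sig, threshold = thr,
                                      fallback = FALSE, stringsAsFactors = FALSE)
                    if (sig) {
                        r <- .percentile_from_peaks(bp$pos[used, ci],
                                                    bp$height[used, ci],
                                                    thr, config$alpha, sel)
                        row$lower <- r[1L]; row$upper <- r[2L]
                        row$width <- r[2L] - r[1L]
                        row$covered <- r[1L] - 1e-9 <= tpos[ci] &
                                       tpos[ci] <= r[2L] + 1e-9
                        row$fallback <- r[4L] > 0
                    }
                    rows[[length(rows) + 1L]] <- row
                }
            }
        }
    }
    do.call(rbind, rows)
}

## Coverage/width summaries over a block of per-dataset records.
## Coverage is reported in two accountings: `coverage` counts datasets with
## no interval (non-significant original peak) as non-covering; the
## `coverageEffective` column conditions on an interval existing.
.summarize_records <- function(records) {
    key <- paste(records$chrom, records$method, records$selective)
    out <- do.call(rbind, lapply(unique(key[order(records$chrom, records$method)]),
                                 function(k) {
        r <- records[key == k, , drop = FALSE]
        w <- r$width[!is.na(r$width)]
        data.frame(qtl = paste0("Q", r$chrom[1L]), chrom = r$chrom[1L],
                   method = r$method[1L], selective = r$selective[1L],
                   N = nrow(r),
                   coverage = mean(r$covered),
                   coverageEffective = if (length(w)) mean(r$covered[!is.na(r$width)]) else NA_real_,
                   seCoverage = sqrt(mean(r$covered) * (1 - mean(r$covered)) / nrow(r)),
                   meanWidth = if (length(w)) mean(w) else NA_real_,
                   seWidth = if (length(w) > 1L) sd(w) / sqrt(length(w)) else NA_real_,
                   nEffective = length(w),
                   nNoInterval = sum(is.na(r$width)),
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Run one sub-simulation of the benchmark study
#'
#' Simulates `N` RI1 datasets with the four QTL at fractional distance `D`
#' from their left flanking markers, analyzes each by CIM (stepwise cofactor
#' selection, LOD scan), and extracts the requested positional intervals:
#' 2.0-LOD support intervals ("si"), frozen-cofactor bootstrap percentile
#' intervals ("npci") and re-selection bootstrap percentile intervals
#' ("cim-npci"); bootstrap methods are recorded in both their selective and
#' non-selective variants from the same peak lists. Per-QTL interval widths
#' and containment of the true position are summarized.
#'
#' Each dataset runs in its own seed stream derived from the master seed, so
#' any dataset (and the study as a whole) is reproducible in isolation and
#' results do not depend on execution order. A dataset whose analysis fails
#' is dropped with a message and `N` decremented in the summary.
#'
#' @param D fractional distance from the left flanking marker.
#' @param config a [studyConfig()].
#' @param methods subset of c("si", "npci", "cim-npci").
#' @param truthFn placement function(map, D, effect) -> data.frame, by
#'   default [placeQTLs()]; the chromosome-end study substitutes its own.
#' @param seedBlock internal offset separating seed streams of different
#'   experiment arms.
#' @return list with `records` (per-dataset rows) and `summary`
#'   (per qtl x method x variant), both carrying a `D` column.
#' @export
runSubsimulation <- function(D, config, methods = c("si", "npci", "cim-npci"),
                             truthFn = NULL, seedBlock = 0) {
    methods <- match.arg(methods, c("si", "npci", "cim-npci"), several.ok = TRUE)
    if (is.null(truthFn))
        truthFn <- function(map, D, effect) placeQTLs(map, D, effect)
    block <- seedBlock * 1e6 + round(D * 1000)
    recs <- vector("list", config$N)
    for (i in seq_len(config$N)) {
        seed_i <- .derive_seed(config$seed, block, i)
        set.seed(seed_i)
        recs[[i]] <- tryCatch({
            qtl <- truthFn(config$map, D, config$effect)
            cross <- simulateCross(map = config$map, qtl = qtl, n = config$n,
                                   h2 = config$h2)
            r <- .analyze_dataset(cross, config, methods)
            r$dataset <- i
            r$seed <- seed_i
            r
        }, error = function(e) {
            message(sprintf("dataset %d failed and was excluded: %s", i,
                            conditionMessage(e)))
            NULL
        })
    }
    records <- do.call(rbind, recs)
    records$D <- D
    summary <- .summarize_records(records)
    summary$D <- D
    list(D = D, records = records, summary = summary)
}

#' Run the full benchmark study over all sub-simulations
#'
#' Concatenates [runSubsimulation()] over the configured `D` values and
#' assembles the interval-width table (one row per D x QTL x method cell,
#' the benchmark comparison shape) and the matching coverage table.
#'
#' @param config a [studyConfig()].
#' @param methods interval methods to run.
#' @param selective which bootstrap variant the `widths`/`coverage` tables
#'   report (records retain both).
#' @return list with `widths`, `coverage`, `summary`, `records`.
#' @export
runFullStudy <- function(config, methods = c("si", "npci", "cim-npci"),
                         selective = TRUE) {
    subs <- lapply(config$D, runSubsimulation, config = config, methods = methods)
    records <- do.call(rbind, lapply(subs, `[[`, "records"))
    summary <- do.call(rbind, lapply(subs, `[[`, "summary"))
    keep <- is.na(summary$selective) | summary$selective == selective
    tab <- summary[keep, c("D", "qtl", "method", "meanWidth", "seWidth",
                           "coverage", "seCoverage", "nEffective")]
    rownames(tab) <- NULL
    list(widths = tab[, c("D", "qtl", "method", "meanWidth", "seWidth", "nEffective")],
         coverage = tab[, c("D", "qtl", "method", "coverage", "seCoverage", "nEffective")],
         summary = summary, records = records)
}

#' Chromosome-end control experiment
#'
#' Re-runs the sub-simulations with Q1 relocated into the sparse (134, 154)
#' interval of chromosome 1, at 0/10/30/50\% of the distance from the marker
#' at 154 cM toward the marker at 134 cM -- i.e. at 154, 152, 148 and 144 cM.
#' The 0\% variant places Q1 11 cM from the 165 cM telomeric marker,
#' mirroring the distance of the original Q1 (at 11 cM) from the 0 cM
#' telomere, so differences from the original Q1 results isolate marker
#' density from chromosome-end proximity. Q2-Q4 are unchanged.
#'
#' @param config a [studyConfig()].
#' @param methods interval methods to run.
#' @return list with `summary` (rows for all QTL; Q1 rows carry the
#'   relocated positions in `qtlPos`) and `records`.
#' @export
runEndEffectStudy <- function(config, methods = c("si", "cim-npci")) {
    p1 <- markerPositions(config$map, 1)
    if (!(154 %in% p1) || !(134 %in% p1))
        stop("configuration error: map lacks the chromosome-1 markers at 134 and 154 cM")
    truthFn <- function(map, D, effect) {
        qtl <- placeQTLs(map, D, effect)
        qtl$pos[qtl$chrom == 1] <- 154 - D * (154 - 134)
        qtl
    }
    subs <- lapply(config$D, function(D)
        runSubsimulation(D, config, methods, truthFn = truthFn, seedBlock = 500))
    records <- do.call(rbind, lapply(subs, `[[`, "records"))
    summary <- do.call(rbind, lapply(subs, `[[`, "summary"))
    summary$qtlPos <- ifelse(summary$chrom == 1, 154 - summary$D * 20, NA)
    list(summary = summary, records = records)
}

#' Selective versus non-selective interval estimation
#'
#' Pairs the selective and non-selective variants of a bootstrap interval
#' method computed from the same bootstrap peak lists, summarizes both per
#' (D, QTL) cell, and reports the paired mean width difference and the
#' correlations of cell mean widths and coverages across the 16 cells.
#'
#' @param x a [studyConfig()] (the study is run) or the `records`
#'   data.frame of a previous [runFullStudy()].
#' @param method which bootstrap method to compare ("CIM-NPCI" or "NPCI").
#' @return list with `cells`, `correlationWidth`, `correlationCoverage`,
#'   `meanWidthDifference` (selective minus non-selective, cM).
#' @export
compareSelective <- function(x, method = "CIM-NPCI") {
    records <- if (inherits(x, "StudyConfig"))
        runFullStudy(x, methods = tolower(method))$records else x
    r <- records[records$method == method & !is.na(records$selective), , drop = FALSE]
    if (nrow(r) == 0L) stop("no records for method ", method)
    cells <- do.call(rbind, lapply(split(r, list(r$D, r$chrom), drop = TRUE),
        function(g) {
            s <- g[g$selective, ]; ns <- g[!g$selective, ]
            data.frame(D = g$D[1L], chrom = g$chrom[1L],
                       widthSel = mean(s$width, na.rm = TRUE),
                       widthNonsel = mean(ns$width, na.rm = TRUE),
                       coverageSel = mean(s$covered),
                       coverageNonsel = mean(ns$covered))
        }))
    rownames(cells) <- NULL
    .safe_cor <- function(a, b) {
        ok <- is.finite(a) & is.finite(b)
        if (sum(ok) > 2 && sd(a[ok]) > 0 && sd(b[ok]) > 0) cor(a[ok], b[ok])
        else NA_real_
    }
    list(cells = cells,
         correlationWidth = .safe_cor(cells$widthSel, cells$widthNonsel),
         correlationCoverage = .safe_cor(cells$coverageSel, cells$coverageNonsel),
         meanWidthDifference = mean(cells$widthSel - cells$widthNonsel,
                                    na.rm = TRUE))
}
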