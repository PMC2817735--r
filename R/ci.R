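#' LOD support intervals
#'
#' For each chromosome, takes the leftmost LOD-curve argmax as the peak and
#' extends the interval to the furthest grid positions on each side that can
#' be reached from the peak without the curve dropping more than `drop` LOD
#' units below the peak height (truncating at the chromosome ends). Endpoints
#' are reported on the scan grid, i.e. at walking-speed resolution.
#'
#' @param profile a \linkS4class{LODProfile}.
#' @param drop LOD drop defining the interval (benchmark study: 2.0).
#' @param chrom optional chromosome subset.
#' @return data.frame with columns chrom, peak, height, lower, upper, width,
#'   method ("SI").
#' @examples
#' cross <- simulateCross(n = 150, D = 0, seed = 4)
#' supportInterval(cimScan(cross, stepwiseCofactors(cross)))
#' @export
supportInterval <- function(profile, drop = 2.0, chrom = NULL) {
    stopifnot(is(profile, "LODProfile"), drop >= 0)
    cs <- sort(unique(profile@chrom))
    if (!is.null(chrom)) cs <- intersect(cs, chrom)
    out <- do.call(rbind, lapply(cs, function(c) {
        i <- which(profile@chrom == c)
        lod <- profile@lod[i]; pos <- profile@pos[i]
        k <- which.max(lod)                       # leftmost argmax
        thr <- lod[k] - drop
        below <- which(lod < thr)
        lo <- below[below < k]; hi <- below[below > k]
        lo <- if (length(lo)) max(lo) + 1L else 1L
        hi <- if (length(hi)) min(hi) - 1L else length(lod)
        data.frame(chrom = c, peak = pos[k], height = lod[k],
                   lower = pos[lo], upper = pos[hi],
                   width = pos[hi] - pos[lo], method = "SI",
                   stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Genome-wide permutation significance threshold
#'
#' Shuffles the trait against the genotypes `P` times; each permuted dataset
#' receives the complete CIM analysis (by default including stepwise cofactor
#' re-selection) and its genome-wide maximum LOD is recorded. The threshold
#' is the ceiling(P * (1 - alpha))-th order statistic of these null maxima,
#' an experiment-wise (all chromosomes jointly) alpha-level cutoff.
#'
#' @param cross a \linkS4class{RILCross}.
#' @param P number of permutations (>= 1/alpha).
#' @param alpha significance level.
#' @param settings a \linkS4class{ScanSettings}.
#' @param reselect re-run cofactor selection on each permuted dataset
#'   (default TRUE); if FALSE, `cofactors` is reused throughout.
#' @param cofactors frozen \linkS4class{CofactorSet} when `reselect = FALSE`.
#' @return list with elements threshold, P, alpha, nullMaxLods.
#' @export
permutationThreshold <- function(cross, P = 1000, alpha = 0.05,
                                 settings = scanSettings(), reselect = TRUE,
                                 cofactors = NULL) {
    if (P * alpha < 1) stop("P * alpha < 1: quantile undefined")
    y <- trait(cross)
    if (var(y) == 0) warning("constant trait: threshold is degenerate")
    core <- .core_from_cross(cross, settings)
    frozen <- if (is.null(cofactors)) integer(0)
              else if (is(cofactors, "CofactorSet")) cofactors@idx else as.integer(cofactors)
    maxl <- .perm_null_maxima(core, y, P, settings, reselect, frozen)
    k <- ceiling(P * (1 - alpha))
    list(threshold = sort(maxl)[k], P = P, alpha = alpha, nullMaxLods = maxl)
}

.perm_null_maxima <- function(core, y, P, settings, reselect = TRUE,
                              frozen = integer(0)) {
    vapply(seq_len(P), function(p) {
        yp <- y[sample.int(length(y))]
        cof <- if (reselect) .stepwise(core$M, yp, settings@pEntry,
                                       settings@maxForwardSteps) else frozen
        .max_lod(core, core$M, core$X, yp, cof, settings)
    }, numeric(1))
}

#' Bootstrap the per-chromosome LOD peaks
#'
#' Draws `B` bootstrap resamples of the individuals (with replacement, trait
#' kept paired with its genotypes), runs the CIM scan on each, and records
#' the leftmost per-chromosome LOD peak position and height. With
#' `reselect = TRUE` stepwise cofactor selection is redone on every replicate
#' (the CIM-NPCI recipe); with `reselect = FALSE` the original dataset's
#' cofactor set is reused throughout (the naive NPCI recipe). Replicates with
#' a degenerate (constant) trait are skipped with a warning.
#'
#' @param cross a \linkS4class{RILCross}.
#' @param B number of bootstrap replicates.
#' @param reselect logical; see above.
#' @param settings a \linkS4class{ScanSettings}.
#' @param cofactors \linkS4class{CofactorSet} to freeze when
#'   `reselect = FALSE` (selected from the original data when NULL).
#' @return list with `peaks` (data.frame replicate, chrom, pos, height),
#'   `cofactors` (per-replicate list of marker-index vectors) and `nSkipped`.
#' @export
bootstrapPeaks <- function(cross, B = 1000, reselect = TRUE,
                           settings = scanSettings(), cofactors = NULL) {
    stopifnot(B >= 1)
    core <- .core_from_cross(cross, settings)
    y <- trait(cross)
    frozen <- if (is.null(cofactors)) .stepwise(core$M, y, settings@pEntry,
                                                settings@maxForwardSteps)
              else if (is(cofactors, "CofactorSet")) cofactors@idx
              else as.integer(cofactors)
    bp <- .boot_peaks(core, y, B, reselect, frozen, settings)
    used <- which(!bp$skipped)
    C <- length(core$chroms)
    peaks <- data.frame(replicate = rep(used, each = C),
                        chrom = rep(core$chroms, length(used)),
                        pos = as.vector(t(bp$pos[used, , drop = FALSE])),
                        height = as.vector(t(bp$height[used, , drop = FALSE])))
    list(peaks = peaks, cofactors = bp$cofList[used], nSkipped = sum(bp$skipped))
}

## Matrix-level bootstrap worker shared with the study driver.
.boot_peaks <- function(core, y, B, reselect, frozen, settings) {
    C <- length(core$chroms)
    pos <- matrix(NA_real_, B, C)
    height <- matrix(NA_real_, B, C)
    skipped <- logical(B)
    cofList <- vector("list", B)
    n <- core$n
    for (b in seq_len(B)) {
        idx <- sample.int(n, n, replace = TRUE)
        yb <- y[idx]
        if (var(yb) == 0) {
            skipped[b] <- TRUE
            warning("bootstrap replicate with constant trait skipped")
            next
        }
        Mb <- core$M[idx, , drop = FALSE]
        Xb <- core$X[idx, , drop = FALSE]
        cof <- if (reselect) .stepwise(Mb, yb, settings@pEntry,
                                       settings@maxForwardSteps) else frozen
        cofList[[b]] <- cof
        sc <- .lod_scan(core, Mb, Xb, yb, cof, settings)
        pk <- .scan_peaks(core, sc$lod)
        pos[b, ] <- pk[, 1L]
        height[b, ] <- pk[, 2L]
    }
    list(pos = pos, height = height, skipped = skipped, cofList = cofList)
}

#' Filter bootstrap peaks by the original dataset's threshold
#'
#' Keeps the peak records whose LOD height strictly exceeds the significance
#' threshold (the "selective method"), preserving order. Signals an error of
#' class `qtlci_no_significant_peaks` when nothing survives, so the caller
#' can decide on a fallback.
#'
#' @param peaks data.frame with at least a `height` column.
#' @param threshold LOD threshold from the original data's permutation test.
#' @return the filtered data.frame.
#' @export
selectiveFilter <- function(peaks, threshold) {
    keep <- peaks$height > threshold
    if (!any(keep))
        stop(structure(class = c("qtlci_no_significant_peaks", "error", "condition"),
                       list(message = "no bootstrap peaks exceed the threshold",
                            call = sys.call())))
    peaks[keep, , drop = FALSE]
}

#' Bootstrap percentile interval of QTL position
#'
#' Orders the bootstrap peak positions and reports the
#' ceiling(B * alpha/2)-th and ceiling(B * (1 - alpha/2))-th order statistics
#' as the central (1 - alpha) interval.
#'
#' @param positions numeric cM positions (>= 2 values).
#' @param alpha level (0.05 gives the central 95\%).
#' @return numeric c(lower, upper).
#' @examples
#' percentileInterval(1:1000)   # c(25, 975)
#' @export
percentileInterval <- function(positions, alpha = 0.05) {
    B <- length(positions)
    if (B < 2L) stop("need at least 2 positions")
    s <- sort(positions)
    c(lower = s[ceiling(B * alpha / 2)], upper = s[ceiling(B * (1 - alpha / 2))])
}

## Shared percentile-CI builder for one chromosome's peak list.
## Returns c(lower, upper, nUsed, fallback): selective filtering falls back
## to the full peak list (flagged) when fewer than minFrac * B peaks survive.
.percentile_from_peaks <- function(pos, height, threshold, alpha, selective,
                                   minFrac = 0.2) {
    B <- length(pos)
    fallback <- FALSE
    use <- rep(TRUE, B)
    if (selective) {
        use <- height > threshold
        if (sum(use) < minFrac * B) {
            warning(sprintf("selective filter kept %d/%d peaks; reporting non-selective interval",
                            sum(use), B))
            use <- rep(TRUE, B)
            fallback <- TRUE
        }
    }
    ci <- percentileInterval(pos[use], alpha)
    c(ci[1L], ci[2L], sum(use), fallback)
}

#' Bootstrap percentile confidence intervals for QTL position
#'
#' `cimNPCI()` implements the CIM-tailored bootstrap interval: the
#' significance threshold is set by permutation on the original data, `B`
#' bootstrap resamples each receive the complete CIM analysis including
#' stepwise re-selection of background markers, per-chromosome peak positions
#' are collected, peaks are filtered against the original threshold (the
#' selective method; disable with `selective = FALSE`), and the central
#' (1 - alpha) percentile interval of the surviving positions is reported
#' for every chromosome whose original-data peak is significant. `npci()` is
#' the naive comparator that freezes the original cofactor set for all
#' replicates; everything else is identical.
#'
#' Chromosomes whose original peak does not exceed the threshold yield no
#' interval (NA bounds, `significant = FALSE`). If selective filtering
#' retains fewer than 20\% of the replicates, the non-selective interval is
#' reported and flagged in the `fallback` column.
#'
#' @param cross a \linkS4class{RILCross}.
#' @param B bootstrap replicates (benchmark study: 1000).
#' @param P permutations for the threshold (benchmark study: 1000).
#' @param alpha interval level (0.05).
#' @param selective apply the selective filter (default TRUE).
#' @param settings a \linkS4class{ScanSettings}.
#' @return data.frame with one row per chromosome: chrom, method, selective,
#'   lower, upper, width, peak, height, threshold, nReplicatesUsed,
#'   fallback, significant.
#' @examples
#' \donttest{
#' cross <- simulateCross(n = 100, D = 0, seed = 7)
#' cimNPCI(cross, B = 50, P = 20)
#' }
#' @export
cimNPCI <- function(cross, B = 1000, P = 1000, alpha = 0.05, selective = TRUE,
                    settings = scanSettings()) {
    .bootstrap_ci(cross, reselect = TRUE, B = B, P = P, alpha = alpha,
                  selective = selective, settings = settings)
}

#' @rdname cimNPCI
#' @export
npci <- function(cross, B = 1000, P = 1000, alpha = 0.05, selective = TRUE,
                 settings = scanSettings()) {
    .bootstrap_ci(cross, reselect = FALSE, B = B, P = P, alpha = alpha,
                  selective = selective, settings = settings)
}

.bootstrap_ci <- function(cross, reselect, B, P, alpha, selective, settings) {
    core <- .core_from_cross(cross, settings)
    y <- trait(cross)
    cof0 <- .stepwise(core$M, y, settings@pEntry, settings@maxForwardSteps)
    thr <- sort(.perm_null_maxima(core, y, P, settings))[ceiling(P * (1 - alpha))]
    sc <- .lod_scan(core, core$M, core$X, y, cof0, settings)
    orig <- .scan_peaks(core, sc$lod)
    bp <- .boot_peaks(core, y, B, reselect, cof0, settings)
    used <- !bp$skipped
    method <- if (reselect) "CIM-NPCI" else "NPCI"
    out <- do.call(rbind, lapply(seq_along(core$chroms), function(ci) {
        c0 <- core$chroms[ci]
        sig <- orig[ci, 2L] > thr
        row <- data.frame(chrom = c0, method = method, selective = selective,
                          lower = NA_real_, upper = NA_real_, width = NA_real_,
                          peak = orig[ci, 1L], height = orig[ci, 2L],
                          threshold = thr, nReplicatesUsed = 0L,
                          fallback = FALSE, significant = sig,
                          stringsAsFactors = FALSE)
        if (sig) {
            r <- .percentile_from_peaks(bp$pos[used, ci], bp$height[used, ci],
                                        thr, alpha, selective)
            row$lower <- r[1L]; row$upper <- r[2L]; row$width <- r[2L] - r[1L]
            row$nReplicatesUsed <- as.integer(r[3L]); row$fallback <- r[4L] > 0
        }
        row
    }))
    rownames(out) <- NULL
    out
}
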