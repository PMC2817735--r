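#' Scan settings for composite interval mapping
#'
#' Benchmark defaults: 1 cM walking speed, 10 cM blockout window, up to 5
#' cofactor covariates, stepwise entry/removal at p = 0.05 with at most 10
#' forward steps.
#'
#' @param walk cM spacing between test positions.
#' @param window blockout half-width in cM.
#' @param nCofactors maximum cofactors used in a scan.
#' @param pEntry stepwise partial-F significance level.
#' @param maxForwardSteps hard bound on forward stepwise additions.
#' @return a \linkS4class{ScanSettings}
#' @export
scanSettings <- function(walk = 1, window = 10, nCofactors = 5,
                         pEntry = 0.05, maxForwardSteps = 10) {
    new("ScanSettings", walk = as.numeric(walk), window = as.numeric(window),
        nCofactors = as.integer(nCofactors), pEntry = as.numeric(pEntry),
        maxForwardSteps = as.integer(maxForwardSteps))
}

#' @rdname ScanSettings-class
#' @param object a ScanSettings
#' @export
setMethod("show", "ScanSettings", function(object) {
    cat(sprintf("ScanSettings: walk %g cM, window %g cM, <=%d cofactors, p-entry %g, <=%d forward steps\n",
                object@walk, object@window, object@nCofactors, object@pEntry,
                object@maxForwardSteps))
})

#' LOD score for adding one predictor to a linear model
#'
#' LOD = (n/2) log10(RSS0 / RSS1), where RSS0 is the residual sum of squares
#' of the trait regressed on the covariates (plus intercept) and RSS1 that of
#' the model with the predictor added. A perfect fit (RSS1 = 0) is capped at
#' a large finite value (1000). Collinear covariates are dropped with a
#' warning; a predictor lying in the span of the covariates scores 0.
#'
#' @param y numeric trait vector.
#' @param x numeric predictor column (e.g. a marker or a conditional
#'   expectation).
#' @param covariates optional numeric matrix of covariate columns.
#' @return a single non-negative LOD score.
#' @examples
#' set.seed(1)
#' y <- rnorm(50); x <- rnorm(50)
#' regressionLOD(y, x)
#' @export
regressionLOD <- function(y, x, covariates = NULL) {
    n <- length(y)
    Z <- if (is.null(covariates)) matrix(1, n, 1L) else cbind(1, as.matrix(covariates))
    if (n <= ncol(Z) + 1L) stop("too few observations for the model")
    qrZ <- qr(Z)
    if (qrZ$rank < ncol(Z)) warning("rank-deficient covariates; dropping collinear columns")
    res <- qr.resid(qrZ, cbind(y, x))
    as.numeric(.lod_from_resid(res[, 1L], res[, 2L, drop = FALSE], n))
}

#' Expected QTL genotype given flanking markers
#'
#' For a putative QTL between two flanking markers (+1/-1 codes `mL`, `mR` at
#' distances `dL`, `dR` cM), returns E\[q | mL, mR\] in \[-1, +1\] under the
#' RI1 Markov model: with RI1-expanded recombination fractions R1, R2 for the
#' two intervals and R12 = R1(1-R2) + R2(1-R1) for the flanking pair,
#' P(q = mL-class) is (1-R1)(1-R2)/(1-R12) when mL = mR and (1-R1)R2/R12
#' otherwise. This is the Haley-Knott regression predictor used by the scan.
#'
#' @param mL,mR flanking marker codes (+1 or -1), vectorized.
#' @param dL,dR distances (cM) from the QTL position to the left and right
#'   flanking markers; non-negative scalars.
#' @return numeric vector of conditional expectations.
#' @examples
#' conditionalExpectation(1, 1, 10, 10)
#' conditionalExpectation(1, -1, 5, 5)   # 0 by symmetry
#' @export
conditionalExpectation <- function(mL, mR, dL, dR) {
    if (dL < 0 || dR < 0) stop("distances must be non-negative")
    if (dL == 0 && dR == 0) {
        if (any(mL != mR)) stop("impossible configuration: coincident loci with different codes")
        return(mL + 0)
    }
    if (dL == 0) return(mL + 0)
    if (dR == 0) return(mR + 0)
    cc <- .cond_coef(dL, dR)
    ifelse(mL == mR, mL * cc[["same"]], mL * cc[["diff"]])
}

#' Stepwise selection of CIM background markers
#'
#' Forward/backward stepwise regression of the trait on the markers: each
#' forward step adds the marker with the smallest partial-F p-value if it is
#' below `pEntry` (ties broken leftmost in genome order); after each addition,
#' backward elimination removes included markers whose drop-one p-value
#' exceeds `pEntry` until stable. The search stops when no candidate enters
#' or after `maxForwardSteps` forward additions. The returned set is ranked
#' by final-model strength (ascending drop-one partial-F p-value), standing
#' in for the cofactor ranking of classic CIM software; the scan uses at
#' most the first `nCofactors` of them, i.e. the strongest.
#'
#' @param cross a \linkS4class{RILCross}.
#' @param settings a \linkS4class{ScanSettings}.
#' @return a \linkS4class{CofactorSet} (possibly empty).
#' @examples
#' cross <- simulateCross(n = 100, D = 0, seed = 1)
#' stepwiseCofactors(cross)
#' @export
stepwiseCofactors <- function(cross, settings = scanSettings()) {
    M <- genotypeMatrix(cross)
    if (ncol(M) < 2L) stop("need at least 2 markers")
    idx <- .stepwise(M, trait(cross), pEntry = settings@pEntry,
                     maxSteps = settings@maxForwardSteps)
    rd <- SummarizedExperiment::rowData(cross)
    new("CofactorSet", idx = as.integer(idx), chrom = as.integer(rd$chrom[idx]),
        pos = as.numeric(rd$pos[idx]), name = as.character(rd$name[idx]))
}

#' @rdname CofactorSet-class
#' @param x a CofactorSet
#' @export
setMethod("length", "CofactorSet", function(x) length(x@idx))

#' @rdname CofactorSet-class
#' @param object a CofactorSet
#' @export
setMethod("show", "CofactorSet", function(object) {
    if (length(object) == 0L) { cat("CofactorSet: empty\n"); return(invisible()) }
    cat(sprintf("CofactorSet (%d, ranked): %s\n", length(object),
                paste(sprintf("%s[chr%d:%.1f]", object@name, object@chrom,
                              object@pos), collapse = ", ")))
})

#' @rdname CofactorSet-class
#' @param row.names,optional,... S3 compatibility (unused)
#' @export
as.data.frame.CofactorSet <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(idx = x@idx, chrom = x@chrom, pos = x@pos, name = x@name,
               stringsAsFactors = FALSE)
}

#' Composite interval mapping LOD scan
#'
#' Walks each chromosome on a constant-step grid that includes both ends
#' (166 positions on a 165 cM chromosome at a 1 cM walk). At each test
#' position the predictor is the flanking-marker conditional expectation
#' (the marker column itself at exact marker positions), the covariates are
#' the first `nCofactors` cofactors minus any on the test chromosome within
#' `window` cM of the test position's marker interval -- the interval's own
#' flanking markers are always blocked, and the window boundary is blocked
#' -- and the LOD is the regression LOD of adding the predictor. Blocking
#' whole intervals (rather than a radius around the bare test position)
#' keeps the LOD curve coherent across a sparse interval whose two flanking
#' markers are both cofactors. With an empty cofactor set this reduces to
#' standard interval mapping (SIM).
#'
#' @param cross a \linkS4class{RILCross}.
#' @param cofactors a \linkS4class{CofactorSet}, integer marker indices, or
#'   NULL for SIM.
#' @param settings a \linkS4class{ScanSettings}.
#' @return a \linkS4class{LODProfile}
#' @examples
#' cross <- simulateCross(n = 100, D = 0, seed = 1)
#' prof <- cimScan(cross, stepwiseCofactors(cross))
#' peakPositions(prof)
#' @export
cimScan <- function(cross, cofactors = NULL, settings = scanSettings()) {
    if (settings@window < 0 || settings@walk <= 0)
        stop("invalid settings: window must be >= 0 and walk > 0")
    cof <- if (is.null(cofactors)) integer(0)
           else if (is(cofactors, "CofactorSet")) cofactors@idx
           else as.integer(cofactors)
    if (length(cof) && (any(cof < 1L) || any(cof > nrow(cross))))
        stop("cofactor indices outside the marker set")
    core <- .core_from_cross(cross, settings)
    sc <- .lod_scan(core, core$M, core$X, trait(cross), cof, settings)
    new("LODProfile", chrom = as.integer(core$gchrom), pos = core$gpos,
        lod = sc$lod, ncov = sc$ncov)
}

#' @rdname LODProfile-class
#' @export
setMethod("peakPositions", "LODProfile", function(x) {
    out <- do.call(rbind, lapply(sort(unique(x@chrom)), function(c) {
        i <- which(x@chrom == c)
        k <- i[which.max(x@lod[i])]      # leftmost argmax
        data.frame(chrom = c, pos = x@pos[k], height = x@lod[k])
    }))
    rownames(out) <- NULL
    out
})

#' @rdname LODProfile-class
#' @param object a LODProfile
#' @export
setMethod("show", "LODProfile", function(object) {
    pk <- peakPositions(object)
    cat(sprintf("LODProfile: %d positions on %d chromosome(s)\n",
                length(object@pos), nrow(pk)))
    for (i in seq_len(nrow(pk)))
        cat(sprintf("  chr %d peak: LOD %.2f at %.1f cM\n",
                    pk$chrom[i], pk$height[i], pk$pos[i]))
})

#' @rdname LODProfile-class
#' @param row.names,optional,... S3 compatibility (unused)
#' @export
as.data.frame.LODProfile <- function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(chrom = x@chrom, pos = x@pos, lod = x@lod, ncov = x@ncov)
}
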