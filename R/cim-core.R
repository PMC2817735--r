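## Internal computational core of the CIM engine.
##
## All heavy loops (permutations, bootstraps, study replicates) run on plain
## matrices through the functions in this file; the exported S4 interface in
## cim.R wraps them. A "core" is a per-dataset precomputation: the marker
## matrix, the scan grid, and the n x G matrix of flanking-marker conditional
## expectations E[q | mL, mR] at every grid position. The predictor matrix
## depends only on genotypes, so bootstrap replicates reuse it by row
## indexing and permutation replicates reuse it unchanged.

.LOD_CAP <- 1000

## Conditional expectation machinery -----------------------------------------

## P(QTL genotype equals the left-marker class | mL, mR) for a locus between
## two flanking loci at RI1-expanded recombination fractions R1 (left) and
## R2 (right), under the per-interval Markov approximation: the L-R
## two-locus difference probability is the chain composition
## R12 = R1(1-R2) + R2(1-R1).
.cond_coef <- function(dL, dR) {
    R1 <- rilExpand(haldaneRecomb(dL))
    R2 <- rilExpand(haldaneRecomb(dR))
    R12 <- R1 * (1 - R2) + R2 * (1 - R1)
    pSame <- (1 - R1) * (1 - R2) / (1 - R12)
    pDiff <- (1 - R1) * R2 / R12
    ## expectation multipliers: E = mL * (2p - 1)
    c(same = 2 * pSame - 1, diff = 2 * pDiff - 1)
}

## Build the scan grid and predictor matrix for one dataset.
## M: n x L marker matrix; mchrom/mpos/lengths: locus metadata.
.make_core <- function(M, mchrom, mpos, lengths, walk = 1) {
    n <- nrow(M)
    chroms <- sort(unique(mchrom))
    gchrom <- integer(0); gpos <- numeric(0)
    for (c in chroms) {
        g <- seq(0, lengths[c], by = walk)
        if (g[length(g)] < lengths[c] - 1e-9) g <- c(g, lengths[c])
        gchrom <- c(gchrom, rep.int(c, length(g)))
        gpos <- c(gpos, g)
    }
    G <- length(gpos)
    X <- matrix(0, n, G)
    fL <- numeric(G)                  # flanking-marker positions of the test
    fR <- numeric(G)                  # interval (both equal at exact markers)
    for (c in chroms) {
        j <- which(mchrom == c)
        p <- mpos[j]
        gi <- which(gchrom == c)
        fi <- findInterval(gpos[gi], p)
        for (t in seq_along(gi)) {
            g <- gpos[gi[t]]
            k <- fi[t]
            if (k >= 1L && abs(g - p[k]) < 1e-9) {        # exactly at a marker
                X[, gi[t]] <- M[, j[k]]
                ## the marker belongs to the interval it starts (its right
                ## interval), or the left one at the chromosome end
                if (k < length(p)) { fL[gi[t]] <- p[k]; fR[gi[t]] <- p[k + 1L] }
                else if (k > 1L)   { fL[gi[t]] <- p[k - 1L]; fR[gi[t]] <- p[k] }
                else fL[gi[t]] <- fR[gi[t]] <- p[k]
            } else if (k == 0L) {                          # left of first marker
                R <- rilExpand(haldaneRecomb(p[1L] - g))
                X[, gi[t]] <- M[, j[1L]] * (1 - 2 * R)
                fL[gi[t]] <- g; fR[gi[t]] <- p[1L]
            } else if (k == length(p)) {                   # right of last marker
                R <- rilExpand(haldaneRecomb(g - p[k]))
                X[, gi[t]] <- M[, j[k]] * (1 - 2 * R)
                fL[gi[t]] <- p[k]; fR[gi[t]] <- g
            } else {
                cc <- .cond_coef(g - p[k], p[k + 1L] - g)
                mL <- M[, j[k]]; mR <- M[, j[k + 1L]]
                same <- mL == mR
                X[, gi[t]] <- mL * ifelse(same, cc[["same"]], cc[["diff"]])
                fL[gi[t]] <- p[k]; fR[gi[t]] <- p[k + 1L]
            }
        }
    }
    list(n = n, M = M, mchrom = mchrom, mpos = mpos, lengths = lengths,
         chroms = chroms, walk = walk, gchrom = gchrom, gpos = gpos, X = X,
         fL = fL, fR = fR,
         gidx = lapply(chroms, function(c) which(gchrom == c)))
}

## Residuals of the columns of A on span(Z). The covariate block Z is tiny
## (<= 6 columns), so a Cholesky solve of Z'Z is much cheaper than a QR of
## Z; exact collinearity (possible in bootstrap resamples) falls back to a
## rank-revealing QR, whose projection is well-defined regardless of rank.
.make_projector <- function(Z) {
    cp <- crossprod(Z)
    R <- tryCatch(chol(cp), error = function(e) NULL)
    if (is.null(R) || min(diag(R)) < sqrt(nrow(Z)) * 1e-7) {
        qrZ <- qr(Z)
        function(A) qr.resid(qrZ, A)
    } else {
        C <- chol2inv(R)
        function(A) A - Z %*% (C %*% crossprod(Z, A))
    }
}

.proj_resid <- function(Z, A) .make_projector(Z)(A)

## LOD of adding one predictor column to a projection residual.
## ry: residual of y; Xr: residuals of predictors; returns LOD vector.
.lod_from_resid <- function(ry, Xr, n) {
    rss0 <- sum(ry * ry)
    if (rss0 <= 0) return(numeric(ncol(Xr)))
    s2 <- .colSums(Xr * Xr, nrow(Xr), ncol(Xr))
    b <- crossprod(Xr, ry)
    dim(b) <- NULL
    bad <- s2 < n * 1e-12                        # predictor in span(Z): no test
    s2[bad] <- 1
    rss1 <- rss0 - b * b / s2
    rss1[bad] <- rss0
    floor <- rss0 * 10^(-2 * .LOD_CAP / n)       # caps a perfect fit at .LOD_CAP
    rss1[rss1 < floor] <- floor
    lod <- 0.5 * n * log10(rss0 / rss1)
    lod[lod < 0] <- 0
    lod
}

## Full-genome CIM scan on a core (optionally with resampled rows).
## M, X: marker and grid-predictor matrices aligned with y (already
## row-resampled for bootstrap replicates). cof: cofactor marker indices in
## entry order; the first `nCofactors` are used, and at each position those
## on the test chromosome within `window` cM (boundary included) are blocked.
.lod_scan <- function(core, M, X, y, cof, settings) {
    ncof <- settings@nCofactors
    window <- settings@window
    cofUse <- if (length(cof) > ncof) cof[seq_len(ncof)] else cof
    n <- length(y)
    lod <- numeric(length(core$gpos))
    ncov <- integer(length(core$gpos))
    for (ci in seq_along(core$chroms)) {
        c <- core$chroms[ci]
        gi <- core$gidx[[ci]]
        onchr <- cofUse[core$mchrom[cofUse] == c]
        if (length(onchr) == 0L) {
            sig <- rep.int(0, length(gi))
            blocked <- NULL
        } else {
            ## blocked iff the cofactor is within `window` cM of the test
            ## position OR is one of the two markers flanking the test
            ## interval (which are always excluded, however wide the
            ## interval); boundary distances are blocked
            cp <- core$mpos[onchr]
            blocked <- abs(outer(core$gpos[gi], cp, "-")) <= window + 1e-9 |
                       abs(outer(core$fL[gi], cp, "-")) < 1e-9 |
                       abs(outer(core$fR[gi], cp, "-")) < 1e-9
            sig <- as.vector(blocked %*% 2^(seq_along(onchr) - 1L))
        }
        for (s in unique(sig)) {
            rows <- which(sig == s)
            if (is.null(blocked)) active <- cofUse
            else {
                drop <- onchr[blocked[rows[1L], ]]
                active <- cofUse[!(cofUse %in% drop)]
            }
            Z <- if (length(active)) cbind(1, M[, active, drop = FALSE])
                 else matrix(1, n, 1L)
            pr <- .make_projector(Z)
            ry <- pr(y)
            Xr <- pr(X[, gi[rows], drop = FALSE])
            lod[gi[rows]] <- .lod_from_resid(ry, Xr, n)
            ncov[gi[rows]] <- length(active)
        }
    }
    list(lod = lod, ncov = ncov)
}

## Genome-wide maximum LOD (cheaper entry point for permutations).
.max_lod <- function(core, M, X, y, cof, settings) {
    max(.lod_scan(core, M, X, y, cof, settings)$lod)
}

## Per-chromosome leftmost argmax peaks from a scan.
.scan_peaks <- function(core, lod) {
    t(vapply(seq_along(core$chroms), function(ci) {
        gi <- core$gidx[[ci]]
        k <- which.max(lod[gi])
        c(core$gpos[gi[k]], lod[gi[k]])
    }, numeric(2)))
}

## Stepwise forward/backward cofactor selection --------------------------------
##
## Forward: add the marker with the smallest partial-F p-value when p < pEntry
## (ties broken by genome order, i.e. leftmost, since columns are map-ordered).
## After each forward addition, backward elimination repeatedly removes the
## worst included marker whose drop-one partial-F p-value exceeds pEntry.
## Stops after `maxSteps` forward additions or when no candidate can enter.
## The selected set is returned ranked by final-model strength (ascending
## drop-one partial-F p-value), so truncation to the scan's nCofactors keeps
## the strongest background markers. Entry order is a poor truncation key:
## in bootstrap resamples a noise marker can enter early and push a true
## QTL's marker out of the top five, leaving that QTL's signal unblocked
## elsewhere on its chromosome and producing spurious far peaks.
.stepwise <- function(M, y, pEntry = 0.05, maxSteps = 10L) {
    n <- length(y)
    L <- ncol(M)
    incl <- integer(0)
    forward <- 0L
    repeat {
        if (forward >= maxSteps) break
        Z <- if (length(incl)) cbind(1, M[, incl, drop = FALSE]) else matrix(1, n, 1L)
        cand <- setdiff(seq_len(L), incl)
        pr <- .make_projector(Z)
        ry <- as.vector(pr(y))
        rss0 <- sum(ry * ry)
        df2 <- n - (length(incl) + 1L) - 1L
        if (df2 < 1L || rss0 <= 0) break
        Mr <- pr(M[, cand, drop = FALSE])
        s2 <- colSums(Mr * Mr)
        b <- as.vector(crossprod(Mr, ry))
        rss1 <- rss0 - b * b / pmax(s2, 1e-300)
        Fv <- (rss0 - rss1) / (rss1 / df2)
        p <- pf(Fv, 1, df2, lower.tail = FALSE)
        p[s2 < n * 1e-12 | rss1 <= 0] <- 1      # collinear or degenerate
        j <- which.min(p)
        if (p[j] >= pEntry) break
        incl <- c(incl, cand[j])
        forward <- forward + 1L
        ## backward elimination until stable
        repeat {
            if (length(incl) < 1L) break
            pd <- .drop_pvalues(M, incl, y)
            w <- which.max(pd)
            if (pd[w] > pEntry) incl <- incl[-w] else break
        }
        if (length(incl) == 0L) break  # everything eliminated; no progress possible
    }
    if (length(incl) > 1L) incl <- incl[order(.drop_pvalues(M, incl, y))]
    incl
}

## Drop-one partial-F p-values for each marker currently in the model.
## Fast path: from one fit of the full model, the drop-one F of marker j is
## its squared coefficient t-statistic, beta_j^2 / (sigma^2 * [(W'W)^-1]_jj).
## Exact collinearity falls back to explicit refits via projections.
.drop_pvalues <- function(M, incl, y) {
    n <- length(y)
    W <- cbind(1, M[, incl, drop = FALSE])
    df2 <- n - ncol(W)
    cp <- crossprod(W)
    R <- tryCatch(chol(cp), error = function(e) NULL)
    if (!is.null(R) && min(diag(R)) >= sqrt(n) * 1e-7) {
        C <- chol2inv(R)
        Wy <- crossprod(W, y)
        beta <- C %*% Wy
        rssF <- max(sum(y * y) - sum(beta * Wy), 0)
        if (rssF <= 0 || df2 < 1L) return(rep(0, length(incl)))
        t2 <- (beta[-1L]^2) / ((rssF / df2) * diag(C)[-1L])
        return(pf(t2, 1, df2, lower.tail = FALSE))
    }
    rssF <- sum(.proj_resid(W, y)^2)
    vapply(seq_along(incl), function(j) {
        Zm <- if (length(incl) > 1L) cbind(1, M[, incl[-j], drop = FALSE])
              else matrix(1, n, 1L)
        rssM <- sum(.proj_resid(Zm, y)^2)
        if (rssF <= 0 || df2 < 1L) return(0)
        Fv <- (rssM - rssF) / (rssF / df2)
        pf(Fv, 1, df2, lower.tail = FALSE)
    }, numeric(1))
}

## Build a core directly from a RILCross.
.core_from_cross <- function(cross, settings) {
    M <- genotypeMatrix(cross)
    rd <- SummarizedExperiment::rowData(cross)
    map <- geneticMap(cross)
    .make_core(M, as.integer(rd$chrom), as.numeric(rd$pos),
               chromLengths(map), walk = settings@walk)
}
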