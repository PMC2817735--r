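# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check: plain lm()/enumeration/brute force.

# LOD from two explicit least-squares fits.
ols_lod_oracle <- function(y, x, covariates = NULL) {
    n <- length(y)
    d0 <- if (is.null(covariates)) data.frame(y = y)
          else data.frame(y = y, covariates)
    f0 <- lm(y ~ ., data = d0)
    f1 <- lm(y ~ ., data = cbind(d0, ..x = x))
    (n / 2) * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
}

# E[q | mL, mR] by enumerating the two-interval Markov chain over QTL states.
cond_exp_oracle <- function(mL, mR, dL, dR) {
    R1 <- rilExpand(haldaneRecomb(dL))
    R2 <- rilExpand(haldaneRecomb(dR))
    w <- vapply(c(1, -1), function(q) {
        p1 <- if (q == mL) 1 - R1 else R1
        p2 <- if (mR == q) 1 - R2 else R2
        p1 * p2
    }, numeric(1))
    (w[1] - w[2]) / sum(w)
}

# Forward/backward stepwise selection recomputing every partial F with lm()
# at every step; returns entry-ordered column indices.
stepwise_oracle <- function(M, y, p_entry = 0.05, max_steps = 10) {
    incl <- integer(0)
    forward <- 0
    repeat {
        if (forward >= max_steps) break
        cand <- setdiff(seq_len(ncol(M)), incl)
        ps <- vapply(cand, function(j) {
            d <- data.frame(y = y, M[, c(incl, j), drop = FALSE])
            f <- lm(y ~ ., data = d)
            a <- anova(f)
            a[["Pr(>F)"]][nrow(a) - 1L]    # last predictor added (type-I = partial here)
        }, numeric(1))
        ## type-I anova p for the last term equals the partial-F p of adding it
        j <- cand[which.min(ps)]
        if (min(ps) >= p_entry) break
        incl <- c(incl, j)
        forward <- forward + 1
        repeat {
            pd <- vapply(seq_along(incl), function(k) {
                dfull <- data.frame(y = y, M[, incl, drop = FALSE])
                ffull <- lm(y ~ ., data = dfull)
                dred <- data.frame(y = y, M[, incl[-k], drop = FALSE])
                fred <- lm(y ~ ., data = dred)
                anova(fred, ffull)[["Pr(>F)"]][2L]
            }, numeric(1))
            w <- which.max(pd)
            if (pd[w] > p_entry) incl <- incl[-w] else break
        }
        if (length(incl) == 0) break
    }
    incl
}

# Hand-built LOD profile on one chromosome.
profile_from <- function(pos, lod, chrom = 1L) {
    new("LODProfile", chrom = rep(as.integer(chrom), length(pos)),
        pos = as.numeric(pos), lod = as.numeric(lod),
        ncov = integer(length(pos)))
}

# A single-QTL cross on one benchmark-style chromosome (for scan sanity).
one_qtl_cross <- function(n = 200, effect = 3, h2 = 0.9, qtlPos = 11) {
    p <- c(0, 2, 4, 6, 8, 10, 11, 12, 14, 17, 20, 23, 26, 33, 43, 55, 69,
           84, 99, 114, 134, 154, 165)
    map1 <- GeneticMap(chrom = rep(1L, length(p)), name = paste0("m", seq_along(p)),
                       pos = p, lengths = 165)
    qtl <- data.frame(qtl = "Q1", chrom = 1L, pos = qtlPos, effect = effect)
    simulateCross(map = map1, qtl = qtl, n = n, h2 = h2)
}
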