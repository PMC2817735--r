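#' Simulate RI1 genotypes along a genetic map
#'
#' Genotypes of fully inbred recombinant lines (RI1, produced by repeated
#' selfing) are simulated chromosome by chromosome as a first-order Markov
#' chain along the ordered loci: the first locus of a chromosome is +1 or -1
#' with probability 1/2, and adjacent loci at distance d cM differ with
#' probability R = rilExpand(haldaneRecomb(d)). Chromosomes are independent
#' and individuals are i.i.d. (The exact multilocus RI1 process is not
#' Markov; this is the standard simulator approximation and is accurate at
#' the marker densities used here.)
#'
#' @param map a \linkS4class{GeneticMap} (loci ordered within chromosome).
#' @param n number of individuals (lines).
#' @return n x L matrix of +1/-1 codes, columns named by marker, with
#'   attributes `chrom` and `pos` echoing the locus metadata.
#' @examples
#' g <- simulateGenotypes(benchmarkMap(), n = 5)
#' dim(g)
#' @export
simulateGenotypes <- function(map, n) {
    stopifnot(is(map, "GeneticMap"), n >= 1)
    .simulate_geno(map@markers, n)
}

## Worker on a plain locus table (chrom, name, pos); tolerates coincident
## loci (distance 0 => identical columns), which GeneticMap validity forbids
## but QTL pseudo-locus insertion requires.
.simulate_geno <- function(mk, n) {
    out <- matrix(0L, nrow = n, ncol = nrow(mk))
    for (c in unique(mk$chrom)) {
        j <- which(mk$chrom == c)
        p <- mk$pos[j]
        if (is.unsorted(p, strictly = FALSE)) stop("loci must be ordered by position")
        L <- length(j)
        g1 <- ifelse(runif(n) < 0.5, 1L, -1L)
        if (L == 1L) { out[, j] <- g1; next }
        R <- rilExpand(haldaneRecomb(diff(p)))
        ## switch indicators; genotype = g1 * (-1)^(# switches so far)
        S <- matrix(runif(n * (L - 1L)) < rep(R, each = n), nrow = n)
        cs <- S %*% upper.tri(matrix(0, L - 1L, L - 1L), diag = TRUE)
        out[, j] <- g1 * cbind(1L, 1L - 2L * (cs %% 2))
    }
    colnames(out) <- mk$name
    attr(out, "chrom") <- mk$chrom
    attr(out, "pos") <- mk$pos
    out
}

#' Simulate a quantitative trait from QTL genotypes
#'
#' The trait is y_i = a * sum_k q_ik + e_i with e_i ~ Normal(0, s2e). The
#' residual variance is set from the expected genetic variance of the +1/-1
#' loci (each contributes a^2 when the two classes are equally frequent):
#' s2e = K * a^2 * (1 - h2) / h2 for K QTL, so the expected heritability is
#' exactly `h2` while the realized per-dataset heritability fluctuates around
#' it, as in standard trait simulators. The expected trait mean is 0. With
#' `effect = 0` (a null trait) the residual variance is set to 1.
#'
#' @param qtlGeno n x K matrix of +1/-1 QTL genotype codes.
#' @param effect common additive effect a.
#' @param h2 heritability in (0, 1).
#' @return numeric trait vector of length n.
#' @export
simulateTrait <- function(qtlGeno, effect, h2) {
    qtlGeno <- as.matrix(qtlGeno)
    if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0, 1)")
    s2e <- if (effect == 0) 1 else ncol(qtlGeno) * effect^2 * (1 - h2) / h2
    effect * rowSums(qtlGeno) + rnorm(nrow(qtlGeno), 0, sqrt(s2e))
}

## Insert QTL pseudo-loci into a map; returns the augmented GeneticMap plus
## the column indices of the pseudo-loci in the augmented marker table.
.augment_map <- function(map, qtl) {
    mk <- map@markers
    add <- data.frame(chrom = as.integer(qtl$chrom), name = paste0(".", qtl$qtl),
                      pos = qtl$pos, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(add)))
        if (add$pos[i] < 0 || add$pos[i] > map@lengths[add$chrom[i]])
            stop("QTL position outside its chromosome")
    all <- rbind(mk, add)
    ## stable sort: pseudo-locus coincident with a marker sorts after it, so
    ## the Markov step between them has distance 0 (identical columns)
    all <- all[order(all$chrom, all$pos), , drop = FALSE]
    rownames(all) <- NULL
    list(loci = all, qtlCols = match(add$name, all$name))
}

#' Simulate a complete RIL mapping dataset
#'
#' Builds one simulated RI1 population on the given map: QTL pseudo-loci are
#' inserted into the map, genotypes are simulated for markers and pseudo-loci
#' jointly (so marker-QTL linkage is exact), the trait is generated from the
#' pseudo-locus genotypes, and the pseudo-loci are then dropped from the
#' released genotype matrix. The true placements are retained (hidden) in the
#' metadata for coverage scoring.
#'
#' @param map a \linkS4class{GeneticMap}; defaults to [benchmarkMap()].
#' @param qtl data.frame of placements (columns qtl, chrom, pos, effect), as
#'   returned by [placeQTLs()]; may be NULL for a QTL-free null population.
#' @param n number of lines (benchmark study: 200).
#' @param h2 heritability (benchmark study: 0.6).
#' @param D convenience: if `qtl` is missing, placements are
#'   `placeQTLs(map, D, effect)`.
#' @param effect common additive effect (benchmark study: 1).
#' @param seed optional integer; when given, the dataset is simulated from
#'   `set.seed(seed)` and is bit-reproducible in isolation.
#' @return a \linkS4class{RILCross}
#' @examples
#' cross <- simulateCross(n = 50, D = 0, seed = 1)
#' cross
#' @export
simulateCross <- function(map = benchmarkMap(), qtl = NULL, n = 200, h2 = 0.6,
                          D = 0, effect = 1, seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(qtl)) qtl <- placeQTLs(map, D, effect)
    aug <- .augment_map(map, qtl)
    g <- .simulate_geno(aug$loci, n)
    q <- g[, aug$qtlCols, drop = FALSE]
    y <- simulateTrait(q, effect = qtl$effect[1], h2 = h2)
    m <- g[, -aug$qtlCols, drop = FALSE]
    RILCross(genotypes = m, map = map, trait = y, truth = qtl)
}

#' Construct a RILCross
#'
#' @param genotypes n x L matrix of +1/-1 codes, individuals in rows,
#'   columns named by marker (map order).
#' @param map a \linkS4class{GeneticMap} whose markers match the columns.
#' @param trait numeric phenotype vector of length n.
#' @param truth optional data.frame of true QTL placements (simulations).
#' @return a \linkS4class{RILCross}
#' @export
RILCross <- function(genotypes, map, trait, truth = NULL) {
    genotypes <- as.matrix(genotypes)
    if (!identical(colnames(genotypes), map@markers$name))
        stop("genotype columns must match the map markers (same order)")
    if (length(trait) != nrow(genotypes))
        stop("trait length must equal the number of individuals")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(genotype = t(genotypes)),
        rowData = S4Vectors::DataFrame(chrom = map@markers$chrom,
                                       pos = map@markers$pos,
                                       name = map@markers$name),
        colData = S4Vectors::DataFrame(trait = as.numeric(trait)))
    metadata <- S4Vectors::metadata(se)
    metadata$map <- map
    metadata$truth <- truth
    S4Vectors::metadata(se) <- metadata
    new("RILCross", se)
}

#' @rdname RILCross-class
#' @export
setMethod("genotypeMatrix", "RILCross", function(x)
    t(SummarizedExperiment::assay(x, "genotype")))

#' @rdname RILCross-class
#' @export
setMethod("trait", "RILCross", function(x)
    SummarizedExperiment::colData(x)$trait)

#' @rdname RILCross-class
#' @export
setMethod("geneticMap", "RILCross", function(x)
    S4Vectors::metadata(x)$map)

#' @rdname RILCross-class
#' @export
setMethod("qtlTruth", "RILCross", function(x)
    S4Vectors::metadata(x)$truth)

#' @rdname RILCross-class
#' @param object a RILCross
#' @export
setMethod("show", "RILCross", function(object) {
    cat(sprintf("RILCross: %d lines x %d markers on %d chromosome(s)\n",
                ncol(object), nrow(object),
                length(unique(SummarizedExperiment::rowData(object)$chrom))))
    tr <- qtlTruth(object)
    if (!is.null(tr))
        cat(sprintf("  simulated QTL: %s\n",
                    paste(sprintf("%s@chr%d:%.1f", tr$qtl, tr$chrom, tr$pos),
                          collapse = ", ")))
})

## Deterministic per-dataset seed stream: master seed plus counters, kept
## inside the 32-bit integer range.
.derive_seed <- function(master, block, i) {
    as.integer((as.numeric(master) * 8191 + block * 1000003 + i * 97) %% 2147483629L) + 1L
}
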