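#' Map-function math: cM distance to recombination fraction
#'
#' `haldaneRecomb()` converts a genetic distance in centimorgans into an F2
#' (single-meiosis) recombination fraction under the Haldane mapping function
#' (no crossover interference): r = (1 - exp(-2 d)) / 2 with d in Morgans.
#' `inverseHaldane()` is its inverse. `kosambiRecomb()` is provided as an
#' alternative map function (moderate interference); it is not used by the
#' benchmark study. `rilExpand()` applies the standard expansion for
#' recombinant inbred lines produced by repeated selfing (RI1):
#' R = 2r / (1 + 2r), the probability that two fixed lines differ at two loci
#' with per-meiosis recombination fraction r.
#'
#' @param distance genetic distance(s) in cM, non-negative.
#' @param r recombination fraction(s) in \[0, 0.5\] (\[0, 0.5) for
#'   `inverseHaldane`).
#' @return numeric vector of recombination fractions (or, for
#'   `inverseHaldane`, distances in cM).
#' @examples
#' haldaneRecomb(10)            # 0.0906...
#' rilExpand(haldaneRecomb(10)) # RI1 two-locus difference probability
#' @export
haldaneRecomb <- function(distance) {
    if (any(distance < 0)) stop("distance must be non-negative (cM)")
    (1 - exp(-2 * distance / 100)) / 2
}

#' @rdname haldaneRecomb
#' @export
inverseHaldane <- function(r) {
    if (any(r < 0 | r >= 0.5)) stop("r must be in [0, 0.5)")
    -50 * log(1 - 2 * r)
}

#' @rdname haldaneRecomb
#' @export
kosambiRecomb <- function(distance) {
    if (any(distance < 0)) stop("distance must be non-negative (cM)")
    tanh(2 * distance / 100) / 2
}

#' @rdname haldaneRecomb
#' @export
rilExpand <- function(r) {
    if (any(r < 0 | r > 0.5)) stop("r must be in [0, 0.5]")
    2 * r / (1 + 2 * r)
}

#' Construct a GeneticMap
#'
#' @param chrom integer chromosome id per marker (contiguous 1..C).
#' @param name character marker names (unique).
#' @param pos numeric cM positions, strictly increasing within chromosome.
#' @param lengths chromosome lengths in cM; defaults to the last marker
#'   position of each chromosome.
#' @return a \linkS4class{GeneticMap}
#' @export
GeneticMap <- function(chrom, name, pos, lengths = NULL) {
    chrom <- as.integer(chrom)
    df <- data.frame(chrom = chrom, name = as.character(name), pos = as.numeric(pos),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    rownames(df) <- NULL
    if (is.null(lengths))
        lengths <- as.numeric(tapply(df$pos, df$chrom, max))
    new("GeneticMap", markers = df, lengths = as.numeric(lengths))
}

#' @rdname GeneticMap-class
#' @export
setMethod("nChromosomes", "GeneticMap", function(x) length(x@lengths))

#' @rdname GeneticMap-class
#' @export
setMethod("chromLengths", "GeneticMap", function(x) x@lengths)

#' @rdname GeneticMap-class
#' @export
setMethod("markerPositions", "GeneticMap", function(x, chrom = NULL) {
    if (is.null(chrom)) return(x@markers$pos)
    x@markers$pos[x@markers$chrom == chrom]
})

#' @rdname GeneticMap-class
#' @export
setMethod("markerNames", "GeneticMap", function(x, chrom = NULL) {
    if (is.null(chrom)) return(x@markers$name)
    x@markers$name[x@markers$chrom == chrom]
})

#' @rdname GeneticMap-class
#' @export
setMethod("nMarkers", "GeneticMap", function(x, chrom = NULL) {
    if (is.null(chrom)) return(nrow(x@markers))
    sum(x@markers$chrom == chrom)
})

#' @rdname GeneticMap-class
#' @param object a GeneticMap
#' @export
setMethod("show", "GeneticMap", function(object) {
    cat(sprintf("GeneticMap: %d chromosome(s), %d markers\n",
                nChromosomes(object), nMarkers(object)))
    for (c in seq_len(nChromosomes(object)))
        cat(sprintf("  chr %d: %d markers, %.1f cM\n",
                    c, nMarkers(object, c), object@lengths[c]))
})

#' @rdname GeneticMap-class
#' @param row.names,optional,... passed for S3 compatibility (unused)
#' @export
as.data.frame.GeneticMap <- function(x, row.names = NULL, optional = FALSE, ...) {
    x@markers
}

## Per-chromosome marker template for the benchmark map (cM positions).
## Density grades dense -> sparse along the chromosome; the four assayed
## flanking intervals are (11,12), (23,26), (69,84) and (114,134), i.e.
## widths 1, 3, 15 and 20 cM, with telomeric markers at 0 and 165 and
## distal markers at 134, 154 used by the chromosome-end control study.
.benchmark_positions <- c(0, 2, 4, 6, 8, 10, 11, 12, 14, 17, 20, 23, 26,
                          33, 43, 55, 69, 84, 99, 114, 134, 154, 165)

## The four flanking intervals that house Q1..Q4, one per chromosome.
.benchmark_intervals <- function() {
    data.frame(chrom = 1:4, left = c(11, 23, 69, 114), right = c(12, 26, 84, 134))
}

#' The benchmark four-chromosome RIL map
#'
#' Four identical 165 cM chromosomes with 23 whole-cM markers each, graded
#' from dense to sparse along the chromosome. Each chromosome carries one
#' assay interval of distinct width -- (11,12), (23,26), (69,84), (114,134)
#' cM, i.e. 1, 3, 15 and 20 cM between consecutive markers -- used to place
#' one QTL per chromosome at a controlled fractional distance from the left
#' flanking marker. Telomeric markers sit at 0 and 165 cM and distal markers
#' at 134 and 154 cM support the chromosome-end control experiment.
#'
#' @return a \linkS4class{GeneticMap} with 4 x 23 markers.
#' @examples
#' m <- benchmarkMap()
#' diff(markerPositions(m, 1))  # intermarker distances, chromosome 1
#' @export
benchmarkMap <- function() {
    p <- .benchmark_positions
    k <- length(p)
    GeneticMap(chrom = rep(1:4, each = k),
               name = paste0("c", rep(1:4, each = k), "m", rep(seq_len(k), 4)),
               pos = rep(p, 4),
               lengths = rep(165, 4))
}

#' Place the four benchmark QTL
#'
#' Places Q1..Q4 on chromosomes 1..4 of the benchmark map, each inside its
#' assay interval at fractional distance `D` from the left flanking marker:
#' position = left + D * (right - left). All four QTL receive the same
#' additive effect.
#'
#' @param map a \linkS4class{GeneticMap} containing the benchmark assay
#'   intervals as consecutive markers.
#' @param D fractional distance from the left flanking marker, in \[0, 1);
#'   the benchmark sub-simulations use 0, 0.10, 0.30, 0.50.
#' @param effect common additive effect `a` of each QTL (trait units per
#'   genotype code unit).
#' @return data.frame with columns qtl, chrom, pos, effect.
#' @examples
#' placeQTLs(benchmarkMap(), D = 0.3)  # Q3 lands at 73.5 cM
#' @export
placeQTLs <- function(map, D, effect = 1) {
    if (length(D) != 1L || D < 0 || D >= 1)
        stop("D must be a single fraction in [0, 1)")
    iv <- .benchmark_intervals()
    for (i in seq_len(nrow(iv))) {
        p <- markerPositions(map, iv$chrom[i])
        jl <- match(iv$left[i], p)
        if (is.na(jl) || jl == length(p) || p[jl + 1L] != iv$right[i])
            stop(sprintf("map lacks the consecutive marker pair (%g, %g) on chromosome %d",
                         iv$left[i], iv$right[i], iv$chrom[i]))
    }
    data.frame(qtl = paste0("Q", 1:4), chrom = iv$chrom,
               pos = iv$left + D * (iv$right - iv$left),
               effect = rep(effect, 4), stringsAsFactors = FALSE)
}
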