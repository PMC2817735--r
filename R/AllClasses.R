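#' @import methods
#' @importFrom stats pf rnorm runif sd var cor median quantile setNames
#' @importFrom utils read.csv read.delim write.csv write.table head packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' GeneticMap: ordered marker positions on a set of linkage groups
#'
#' A genetic linkage map: markers with centimorgan (cM) positions on one or
#' more chromosomes, plus a total cM length per chromosome. Positions are
#' continuous, non-negative, and strictly increasing within a chromosome.
#' The map is the coordinate frame for simulation, scanning and interval
#' estimation.
#'
#' @slot markers data.frame with columns \code{chrom} (integer, 1-based and
#'   contiguous), \code{name} (character, unique) and \code{pos} (numeric cM).
#' @slot lengths numeric vector of chromosome lengths in cM, one per
#'   chromosome, in chromosome order.
#'
#' @seealso [benchmarkMap()], [readMap()], [markerPositions()]
#' @export
setClass("GeneticMap",
    representation(markers = "data.frame", lengths = "numeric"))

setValidity("GeneticMap", function(object) {
    mk <- object@markers
    msgs <- character(0)
    need <- c("chrom", "name", "pos")
    if (!all(need %in% names(mk)))
        return(paste("markers must have columns:", paste(need, collapse = ", ")))
    if (nrow(mk) == 0L) return("map has no markers")
    chr <- sort(unique(mk$chrom))
    if (!identical(as.integer(chr), seq_along(chr)))
        msgs <- c(msgs, "chromosome ids must be contiguous 1..C")
    if (length(object@lengths) != length(chr))
        msgs <- c(msgs, "one length per chromosome required")
    if (anyDuplicated(mk$name))
        msgs <- c(msgs, "marker names must be unique")
    for (c in chr) {
        p <- mk$pos[mk$chrom == c]
        if (any(p < 0)) msgs <- c(msgs, sprintf("chromosome %d: negative position", c))
        if (is.unsorted(p, strictly = TRUE))
            msgs <- c(msgs, sprintf("chromosome %d: positions not strictly increasing", c))
        if (length(object@lengths) >= c && any(p > object@lengths[c] + 1e-9))
            msgs <- c(msgs, sprintf("chromosome %d: marker beyond chromosome length", c))
    }
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' RILCross: a recombinant inbred line mapping population
#'
#' Extends \linkS4class{SummarizedExperiment}: the \code{"genotype"} assay
#' holds marker genotypes (rows = markers, columns = individuals) coded
#' +1/-1 for the two fully inbred homozygote classes; \code{rowData}
#' carries the marker map (chrom, pos, name); \code{colData$trait} is the
#' quantitative phenotype. For simulated populations, the hidden true QTL
#' placements are kept in \code{metadata(x)$truth} and the full
#' \linkS4class{GeneticMap} in \code{metadata(x)$map}.
#'
#' @seealso [simulateCross()], [genotypeMatrix()], [trait()], [qtlTruth()]
#' @export
setClass("RILCross", contains = "SummarizedExperiment")

setValidity("RILCross", function(object) {
    a <- SummarizedExperiment::assays(object)
    if (!"genotype" %in% names(a)) return("needs a 'genotype' assay")
    g <- a[["genotype"]]
    if (!all(g %in% c(-1, 1))) return("genotype codes must be +1/-1 (no missing values)")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("chrom", "pos", "name") %in% names(rd)))
        return("rowData must have chrom, pos, name")
    if (!"trait" %in% names(SummarizedExperiment::colData(object)))
        return("colData must have a 'trait' column")
    TRUE
})

#' ScanSettings: tuning parameters of the CIM scan
#'
#' @slot walk cM spacing of test positions along each chromosome (default 1).
#' @slot window cM blockout half-width: cofactors on the test chromosome
#'   lying within this distance of the test position's marker interval
#'   (its flanking markers always included) are excluded from the model;
#'   the boundary is blocked. Default 10.
#' @slot nCofactors maximum number of background markers used as covariates
#'   in any scan (default 5).
#' @slot pEntry partial-F significance level for stepwise cofactor
#'   entry/removal (default 0.05).
#' @slot maxForwardSteps hard bound on forward additions in the stepwise
#'   search (default 10).
#'
#' @seealso [scanSettings()], [cimScan()], [stepwiseCofactors()]
#' @export
setClass("ScanSettings",
    representation(walk = "numeric", window = "numeric", nCofactors = "integer",
                   pEntry = "numeric", maxForwardSteps = "integer"))

setValidity("ScanSettings", function(object) {
    if (object@walk <= 0) return("walk must be positive")
    if (object@window < 0) return("window must be non-negative")
    if (object@nCofactors < 0L) return("nCofactors must be non-negative")
    if (object@pEntry <= 0 || object@pEntry >= 1) return("pEntry must be in (0,1)")
    if (object@maxForwardSteps < 0L) return("maxForwardSteps must be non-negative")
    TRUE
})

#' CofactorSet: background markers for composite interval mapping
#'
#' Markers selected (by stepwise regression) as covariates for the CIM scan,
#' ranked by final-model strength (strongest first); the scan truncates to
#' its `nCofactors` strongest members.
#'
#' @slot idx integer indices into the marker rows of the cross.
#' @slot chrom integer chromosome of each cofactor.
#' @slot pos numeric cM position of each cofactor.
#' @slot name character marker names.
#' @seealso [stepwiseCofactors()], [cimScan()]
#' @export
setClass("CofactorSet",
    representation(idx = "integer", chrom = "integer", pos = "numeric",
                   name = "character"))

setValidity("CofactorSet", function(object) {
    k <- length(object@idx)
    if (length(object@chrom) != k || length(object@pos) != k ||
        length(object@name) != k) return("slot lengths differ")
    if (anyDuplicated(object@idx)) return("duplicate cofactors")
    TRUE
})

#' LODProfile: LOD scores on the genome scan grid
#'
#' Per-chromosome grids of test positions (constant step, covering the whole
#' chromosome including both ends) with the LOD score and the number of
#' cofactor covariates actually used at each position (cofactors inside the
#' blockout window are excluded position-by-position).
#'
#' @slot chrom integer chromosome of each grid point.
#' @slot pos numeric cM position of each grid point.
#' @slot lod numeric non-negative LOD scores.
#' @slot ncov integer count of cofactor covariates used at each position.
#' @seealso [cimScan()], [peakPositions()], [supportInterval()]
#' @export
setClass("LODProfile",
    representation(chrom = "integer", pos = "numeric", lod = "numeric",
                   ncov = "integer"))

setValidity("LODProfile", function(object) {
    k <- length(object@pos)
    if (length(object@chrom) != k || length(object@lod) != k ||
        length(object@ncov) != k) return("slot lengths differ")
    if (any(object@lod < 0)) return("LOD scores must be non-negative")
    TRUE
})
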