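#' @rdname GeneticMap-class
#' @param x a \linkS4class{GeneticMap} (or object carrying one)
#' @export
setGeneric("nChromosomes", function(x) standardGeneric("nChromosomes"))

#' @rdname GeneticMap-class
#' @export
setGeneric("chromLengths", function(x) standardGeneric("chromLengths"))

#' @rdname GeneticMap-class
#' @param chrom optional chromosome id to restrict to
#' @export
setGeneric("markerPositions", function(x, chrom = NULL) standardGeneric("markerPositions"))

#' @rdname GeneticMap-class
#' @export
setGeneric("markerNames", function(x, chrom = NULL) standardGeneric("markerNames"))

#' @rdname GeneticMap-class
#' @export
setGeneric("nMarkers", function(x, chrom = NULL) standardGeneric("nMarkers"))

#' @rdname RILCross-class
#' @param x a \linkS4class{RILCross}
#' @export
setGeneric("genotypeMatrix", function(x) standardGeneric("genotypeMatrix"))

#' @rdname RILCross-class
#' @export
setGeneric("trait", function(x) standardGeneric("trait"))

#' @rdname RILCross-class
#' @export
setGeneric("geneticMap", function(x) standardGeneric("geneticMap"))

#' @rdname RILCross-class
#' @export
setGeneric("qtlTruth", function(x) standardGeneric("qtlTruth"))

#' @rdname LODProfile-class
#' @param x a \linkS4class{LODProfile}
#' @export
setGeneric("peakPositions", function(x) standardGeneric("peakPositions"))
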