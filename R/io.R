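#' Read / write a genetic map as TSV
#'
#' The map format is a tab-separated file with a header line and columns
#' `chromosome_id`, `marker_name`, `position_cM` (UTF-8, decimal positions).
#' Reading validates ordering: positions must be strictly increasing within
#' a chromosome, and violations are reported with their line number.
#'
#' @param path file path.
#' @param map a \linkS4class{GeneticMap}.
#' @param lengths optional chromosome lengths to install on read (defaults
#'   to the last marker position of each chromosome).
#' @return `readMap` returns a \linkS4class{GeneticMap}; `writeMap` returns
#'   the path invisibly.
#' @export
readMap <- function(path, lengths = NULL) {
    df <- read.delim(path, stringsAsFactors = FALSE)
    need <- c("chromosome_id", "marker_name", "position_cM")
    if (!all(need %in% names(df)))
        stop("map file must have columns: ", paste(need, collapse = ", "))
    if (nrow(df) == 0L) stop("empty map file: ", path)
    for (c in unique(df$chromosome_id)) {
        i <- which(df$chromosome_id == c)
        p <- df$position_cM[i]
        bad <- which(diff(p) <= 0)
        if (length(bad))
            stop(sprintf("map positions not strictly increasing on chromosome %s at line %d",
                         c, i[bad[1L] + 1L] + 1L))   # +1 for the header line
    }
    GeneticMap(chrom = df$chromosome_id, name = df$marker_name,
               pos = df$position_cM, lengths = lengths)
}

#' @rdname readMap
#' @export
writeMap <- function(map, path) {
    df <- data.frame(chromosome_id = map@markers$chrom,
                     marker_name = map@markers$name,
                     position_cM = map@markers$pos)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write a genotype-phenotype dataset as CSV
#'
#' One row per individual; one column per marker (named as in the map, map
#' order) followed by a `trait` column. Genotypes are written either as
#' +1/-1 (`coding = "numeric"`) or as AA/BB (`coding = "letter"`, AA = +1);
#' reading detects the coding and rejects any other value, listing the
#' offending cells.
#'
#' @param mapPath,dataPath file paths (the dataset is always accompanied by
#'   its map).
#' @param cross a \linkS4class{RILCross}.
#' @param coding genotype coding for writing.
#' @return `readCross` returns a \linkS4class{RILCross} (with no hidden
#'   truth); `writeCross` returns `dataPath` invisibly.
#' @export
readCross <- function(mapPath, dataPath) {
    map <- readMap(mapPath)
    df <- read.csv(dataPath, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"trait" %in% names(df)) stop("schema error: dataset lacks a 'trait' column")
    miss <- setdiff(map@markers$name, names(df))
    if (length(miss))
        stop("dataset lacks marker columns: ", paste(head(miss, 5), collapse = ", "))
    g <- as.matrix(df[, map@markers$name, drop = FALSE])
    if (is.character(g)) {
        ok <- g %in% c("AA", "BB")
        if (!all(ok)) .bad_cells(g, !ok, dataPath)
        g <- matrix(ifelse(g == "AA", 1, -1), nrow = nrow(g),
                    dimnames = dimnames(g))
    } else {
        ok <- g == 1 | g == -1
        if (!all(ok)) .bad_cells(g, !ok, dataPath)
    }
    RILCross(genotypes = g, map = map, trait = df$trait)
}

.bad_cells <- function(g, bad, path) {
    w <- which(bad, arr.ind = TRUE)
    w <- w[seq_len(min(5L, nrow(w))), , drop = FALSE]
    stop(sprintf("unknown genotype codes in %s at (row, marker): %s", path,
                 paste(sprintf("(%d, %s)", w[, 1L], colnames(g)[w[, 2L]]),
                       collapse = ", ")))
}

#' @rdname readCross
#' @export
writeCross <- function(cross, dataPath, mapPath = NULL,
                       coding = c("numeric", "letter")) {
    coding <- match.arg(coding)
    g <- genotypeMatrix(cross)
    if (coding == "letter")
        g <- matrix(ifelse(g == 1, "AA", "BB"), nrow = nrow(g),
                    dimnames = dimnames(g))
    df <- data.frame(g, trait = trait(cross), check.names = FALSE)
    write.csv(df, dataPath, row.names = FALSE, quote = FALSE)
    if (!is.null(mapPath)) writeMap(geneticMap(cross), mapPath)
    invisible(dataPath)
}

#' Deterministic fixture datasets
#'
#' Tiny fixed-seed datasets for examples and tests: `"tiny-null"` and
#' `"tiny-one-qtl"` use a 2-chromosome x 5-marker map (markers every 10 cM,
#' 40 cM chromosomes) with n = 60 lines -- the one-QTL variant has a single
#' QTL exactly at the middle marker of chromosome 1; `"benchmark-mini"`
#' returns one full benchmark dataset (n = 200) per sub-simulation distance
#' D in 0, 0.10, 0.30, 0.50 (a named list).
#'
#' @param kind one of "tiny-null", "tiny-one-qtl", "benchmark-mini".
#' @param seed fixture seed.
#' @return a \linkS4class{RILCross}, or a named list of them.
#' @export
makeFixture <- function(kind = c("tiny-null", "tiny-one-qtl", "benchmark-mini"),
                        seed = 123) {
    kind <- match.arg(kind)
    tinyMap <- GeneticMap(chrom = rep(1:2, each = 5),
                          name = paste0("t", rep(1:2, each = 5), "m", rep(1:5, 2)),
                          pos = rep(seq(0, 40, by = 10), 2),
                          lengths = c(40, 40))
    switch(kind,
        "tiny-null" = {
            qtl <- data.frame(qtl = "Q1", chrom = 1L, pos = 20, effect = 0)
            simulateCross(map = tinyMap, qtl = qtl, n = 60, h2 = 0.5, seed = seed)
        },
        "tiny-one-qtl" = {
            qtl <- data.frame(qtl = "Q1", chrom = 1L, pos = 20, effect = 1)
            simulateCross(map = tinyMap, qtl = qtl, n = 60, h2 = 0.5, seed = seed)
        },
        "benchmark-mini" = {
            out <- lapply(c(0, 0.10, 0.30, 0.50), function(D)
                simulateCross(D = D, n = 200, h2 = 0.6,
                              seed = seed + round(100 * D)))
            names(out) <- c("D0", "D10", "D30", "D50")
            out
        })
}

#' Run manifest
#'
#' A small record sufficient to reproduce a run bit-for-bit: master seed,
#' configuration echo, package version, replication counts and a timestamp.
#' `writeManifest` serializes it as JSON.
#'
#' @param config a [studyConfig()].
#' @param path output path for `writeManifest`.
#' @param extra optional named list of additional fields.
#' @return `runManifest` returns a list; `writeManifest` the path, invisibly.
#' @export
runManifest <- function(config, extra = list()) {
    st <- config$settings
    c(list(package = "qtlci",
           version = as.character(packageVersion("qtlci")),
           seed = config$seed,
           n = config$n, N = config$N, B = config$B, P = config$P,
           h2 = config$h2, effect = config$effect, D = config$D,
           walk = st@walk, window = st@window, nCofactors = st@nCofactors,
           pEntry = st@pEntry, maxForwardSteps = st@maxForwardSteps,
           lodDrop = config$lodDrop, alpha = config$alpha,
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
      extra)
}

#' @rdname runManifest
#' @export
writeManifest <- function(config, path, extra = list()) {
    jsonlite::write_json(runManifest(config, extra), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(path)
}
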