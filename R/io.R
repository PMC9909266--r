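.delimFor <- function(path) {
    if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a band-presence matrix
#'
#' Reads a genotypes-by-bands scoring sheet: first column genotype ids,
#' header row band ids, cells 0/1 (or the missing-data token). The
#' band-to-primer assignment is taken from a row whose id is
#' \code{"primer"} (the layout written by \code{\link{writeBandMatrix}}),
#' or from the \code{primerMap} argument when the file has no such row.
#' Comma- or tab-delimited is chosen by file extension (.tsv/.txt = tab).
#'
#' @param file Path to a CSV/TSV file.
#' @param missingCode Token encoding a missing call (default \code{"NA"}).
#' @param primerMap Optional named character vector band id -> primer name,
#'   used when the file carries no primer row.
#' @return A \linkS4class{BandMatrix}.
#' @seealso \code{\link{writeBandMatrix}}
#' @export
readBandMatrix <- function(file, missingCode = "NA", primerMap = NULL) {
    d <- utils::read.table(file, sep = .delimFor(file), header = TRUE,
                           row.names = NULL, check.names = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
    if (ncol(d) < 2L) stop("band matrix file needs an id column and >= 1 band")
    ids <- d[[1L]]
    m <- as.matrix(d[, -1L, drop = FALSE])
    prow <- which(tolower(ids) == "primer")
    if (length(prow) == 1L) {
        primerMap <- stats::setNames(m[prow, ], colnames(m))
        m <- m[-prow, , drop = FALSE]
        ids <- ids[-prow]
    } else if (is.null(primerMap)) {
        stop("no 'primer' assignment row in file and no 'primerMap' given")
    }
    if (anyDuplicated(ids))
        stop(sprintf("duplicate genotype ids: %s",
                     paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (anyDuplicated(colnames(m)))
        stop("duplicate band ids in header")
    rownames(m) <- ids
    m[m == missingCode] <- NA
    bad <- which(!(m %in% c("0", "1") | is.na(m)), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
        stop(sprintf("non-binary cell '%s' at genotype '%s', band '%s'",
                     m[bad[1L, 1L], bad[1L, 2L]],
                     rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
    }
    storage.mode(m) <- "integer"
    BandMatrix(m, primer = primerMap)
}

#' Write a band-presence matrix
#'
#' Writes the layout read back by \code{\link{readBandMatrix}}: header of
#' band ids, a \code{primer} assignment row, then one row per genotype.
#' Round-trips exactly.
#'
#' @param x A \linkS4class{BandMatrix}.
#' @param file Destination path (.csv or .tsv/.txt).
#' @param missingCode Token written for missing calls.
#' @return \code{file}, invisibly.
#' @export
writeBandMatrix <- function(x, file, missingCode = "NA") {
    stopifnot(is(x, "BandMatrix"))
    m <- bandCalls(x)
    mode(m) <- "character"          # preserves dimnames, NA stays NA
    out <- rbind(primer = primerOf(x), m)
    out[is.na(out)] <- missingCode
    d <- data.frame(id = rownames(out), out, check.names = FALSE)
    utils::write.table(d, file, sep = .delimFor(file), quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(file)
}

#' Read and write mixed trait tables
#'
#' \code{readTraitTable} reads a genotypes-by-variables CSV/TSV (first
#' column genotype ids). Columns that parse as numbers become quantitative
#' variables; everything else becomes a qualitative factor whose level
#' order is first appearance unless overridden via \code{levels}. The
#' \code{types} argument forces a declaration (e.g. a numeric-looking
#' score that is really categorical).
#'
#' @param file Path to a CSV/TSV file.
#' @param missingCode Missing-value token.
#' @param types Optional named character vector variable ->
#'   \code{"quantitative"} or \code{"qualitative"}.
#' @param levels Optional named list of level orders for qualitative
#'   variables.
#' @return A \linkS4class{TraitTable}.
#' @export
readTraitTable <- function(file, missingCode = "NA", types = NULL,
                           levels = NULL) {
    d <- utils::read.table(file, sep = .delimFor(file), header = TRUE,
                           row.names = 1L, check.names = FALSE,
                           na.strings = missingCode,
                           colClasses = "character",
                           fileEncoding = "UTF-8")
    for (v in colnames(d)) {
        ty <- if (!is.null(types) && v %in% names(types)) types[[v]] else {
            num <- suppressWarnings(as.numeric(d[[v]]))
            if (all(is.na(num) == is.na(d[[v]]))) "quantitative" else "qualitative"
        }
        if (ty == "quantitative") d[[v]] <- as.numeric(d[[v]])
    }
    TraitTable(d, levels = levels)
}

#' @rdname readTraitTable
#' @param x A \code{TraitTable}.
#' @export
writeTraitTable <- function(x, file, missingCode = "NA") {
    stopifnot(is(x, "TraitTable"))
    d <- as.data.frame(x@data)
    d <- data.frame(id = rownames(d), d, check.names = FALSE)
    utils::write.table(d, file, sep = .delimFor(file), quote = FALSE,
                       row.names = FALSE, na = missingCode,
                       fileEncoding = "UTF-8")
    invisible(file)
}

#' Read and write CIELab color tables
#'
#' Long format: columns \code{genotype}, \code{organ}, \code{L}, \code{a},
#' \code{b} and optionally derived \code{C}, \code{H}.
#'
#' @param file Path to a CSV/TSV file.
#' @param missingCode Missing-value token.
#' @return A \linkS4class{ColorTable}.
#' @export
readColorTable <- function(file, missingCode = "NA") {
    d <- utils::read.table(file, sep = .delimFor(file), header = TRUE,
                           check.names = FALSE, na.strings = missingCode,
                           fileEncoding = "UTF-8")
    ColorTable(d)
}

#' @rdname readColorTable
#' @param x A \code{ColorTable}.
#' @export
writeColorTable <- function(x, file, missingCode = "NA") {
    stopifnot(is(x, "ColorTable"))
    utils::write.table(as.data.frame(x@data), file, sep = .delimFor(file),
                       quote = FALSE, row.names = FALSE, na = missingCode,
                       fileEncoding = "UTF-8")
    invisible(file)
}

#' Read a primer table
#'
#' Expects columns \code{name} (or \code{primer}) and \code{sequence};
#' any further columns are kept as annotation.
#'
#' @param file Path to a CSV/TSV file.
#' @return A \linkS4class{PrimerPanel}.
#' @export
readPrimerPanel <- function(file) {
    d <- utils::read.table(file, sep = .delimFor(file), header = TRUE,
                           check.names = FALSE, fileEncoding = "UTF-8")
    nm <- intersect(c("name", "primer"), colnames(d))[1L]
    if (is.na(nm) || !("sequence" %in% colnames(d)))
        stop("primer table needs 'name' (or 'primer') and 'sequence' columns")
    ann <- d[, setdiff(colnames(d), c(nm, "sequence")), drop = FALSE]
    PrimerPanel(d[[nm]], toupper(gsub("\\s", "", d$sequence)),
                annotation = if (ncol(ann)) ann else NULL)
}

.roundHalfUp <- function(x, digits = 1L) {
    p <- 10^digits
    floor(x * p + 0.5) / p
}

#' GC content of primer sequences
#'
#' Percent G+C of a nucleotide sequence, reported to one decimal with
#' half-up rounding (the convention of published primer tables, where e.g.
#' 47.06 prints as 47.1).
#'
#' @param x Character vector of A/C/G/T sequences, or a
#'   \linkS4class{PrimerPanel}.
#' @param ... Unused.
#' @return Numeric vector of GC percentages, one decimal.
#' @examples
#' gcContent("TGAGTCCAAACCGGATA")  # 47.1
#' @export
setMethod("gcContent", "character", function(x, ...) {
    if (any(!nzchar(x))) stop("empty sequence")
    if (any(grepl("[^ACGTacgt]", x)))
        stop("sequence contains characters outside A/C/G/T")
    s <- Biostrings::DNAStringSet(toupper(x))
    f <- Biostrings::letterFrequency(s, letters = c("G", "C"))
    p <- 100 * rowSums(f) / Biostrings::width(s)
    stats::setNames(.roundHalfUp(p, 1L), names(x))
})

#' @rdname gcContent
#' @export
setMethod("gcContent", "PrimerPanel", function(x, ...) {
    f <- Biostrings::letterFrequency(x@sequences, letters = c("G", "C"))
    p <- 100 * rowSums(f) / Biostrings::width(x@sequences)
    stats::setNames(.roundHalfUp(p, 1L), names(x@sequences))
})

#' Write a dendrogram as Newick
#'
#' Branch lengths are derived from the merge heights so that the path
#' length between two leaves through the tree equals their cophenetic
#' distance (each child branch spans the height difference halved at the
#' leaf-depth scale, the standard ultrametric convention: a two-leaf tree
#' merged at height h is written \code{(A:h/2,B:h/2);}).
#'
#' @param x A \linkS4class{Dendrogram}.
#' @param file Destination path.
#' @return \code{file}, invisibly.
#' @seealso \code{\link{readNewick}}
#' @export
writeNewick <- function(x, file) {
    stopifnot(is(x, "Dendrogram"))
    if (any(!nzchar(x@labels))) stop("all leaves must be labeled")
    phy <- ape::as.phylo(as.hclust.Dendrogram(x))
    ape::write.tree(phy, file = file)
    invisible(file)
}

#' Read an ultrametric Newick tree as a Dendrogram
#'
#' The inverse of \code{\link{writeNewick}} for ultrametric (clustering)
#' trees: topology and merge heights are recovered exactly (up to floating
#' point) from the branch lengths.
#'
#' @param file Path to a Newick file.
#' @return A \linkS4class{Dendrogram}.
#' @export
readNewick <- function(file) {
    phy <- ape::read.tree(file)
    hc <- ape::as.hclust.phylo(phy)
    o <- hc$order
    Dendrogram(hc$labels, hc$merge, hc$height, o)
}
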