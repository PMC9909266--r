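#' Construct a BandMatrix
#'
#' Builds a validated \linkS4class{BandMatrix} from a genotypes-by-bands
#' scoring matrix (the orientation of a typical scoring sheet) and a
#' band-to-primer assignment.
#'
#' @param calls Numeric or integer matrix, genotypes in rows (row names =
#'   genotype ids), bands in columns (column names = band ids); values 0, 1
#'   or NA.
#' @param primer Character vector assigning each band (column of
#'   \code{calls}) to the primer or primer combination that produced it.
#'   Recycled if length 1; may be named by band id.
#'
#' @return A \code{BandMatrix}.
#' @examples
#' m <- matrix(c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1, 1, 0), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), paste0("b", 1:4)))
#' bm <- BandMatrix(m, primer = c("P1", "P1", "P2", "P2"))
#' bandFrequency(bm)
#' @export
BandMatrix <- function(calls, primer) {
    if (is.data.frame(calls)) calls <- as.matrix(calls)
    if (!is.matrix(calls))
        stop("'calls' must be a matrix (genotypes x bands)")
    storage.mode(calls) <- "integer"
    nb <- ncol(calls)
    if (length(primer) == 1L) primer <- rep(primer, nb)
    if (length(primer) != nb)
        stop("'primer' must assign every band to exactly one primer")
    if (!is.null(names(primer))) {
        if (!setequal(names(primer), colnames(calls)))
            stop("names of 'primer' do not match band ids")
        primer <- primer[colnames(calls)]
    }
    bad <- which(!(calls %in% c(0L, 1L) | is.na(calls)), arr.ind = FALSE)
    if (length(bad)) {
        ij <- arrayInd(bad[1L], dim(calls))
        stop(sprintf(
            "non-binary band call %s at genotype '%s', band '%s'",
            calls[bad[1L]], rownames(calls)[ij[1L]], colnames(calls)[ij[2L]]))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(calls = t(calls)),
        rowData = S4Vectors::DataFrame(primer = unname(primer),
                                       row.names = colnames(calls)))
    new("BandMatrix", se)
}

#' Accessors for BandMatrix
#'
#' \code{bandCalls} returns the calls in genotypes-by-bands orientation;
#' \code{primerOf} the band-to-primer map; \code{genotypeIds} and
#' \code{bandIds} the two id vectors.
#'
#' @param x A \linkS4class{BandMatrix}.
#' @return \code{bandCalls}: integer matrix genotypes x bands;
#'   \code{primerOf}: named character vector band -> primer;
#'   \code{genotypeIds}, \code{bandIds}: character vectors.
#' @name bandCalls
#' @aliases primerOf genotypeIds bandIds
#' @examples
#' bm <- BandMatrix(matrix(c(1, 0, 0, 1), 2,
#'                  dimnames = list(c("g1", "g2"), c("b1", "b2"))), "P1")
#' bandCalls(bm)
#' primerOf(bm)
NULL

#' @rdname bandCalls
#' @export
setMethod("bandCalls", "BandMatrix", function(x)
    t(SummarizedExperiment::assay(x, "calls")))

#' @rdname bandCalls
#' @export
setMethod("primerOf", "BandMatrix", function(x) {
    p <- SummarizedExperiment::rowData(x)$primer
    names(p) <- rownames(x)
    p
})

#' @rdname bandCalls
#' @export
setMethod("genotypeIds", "BandMatrix", function(x) colnames(x))

#' @rdname bandCalls
#' @export
setMethod("bandIds", "BandMatrix", function(x) rownames(x))

setMethod("show", "BandMatrix", function(object) {
    cat(sprintf("BandMatrix: %d genotypes x %d bands from %d primers\n",
                ncol(object), nrow(object),
                length(unique(primerOf(object)))))
    nmiss <- sum(is.na(SummarizedExperiment::assay(object, "calls")))
    if (nmiss) cat(sprintf("  %d missing calls\n", nmiss))
    callNextMethod()
})

#' Construct a PrimerPanel
#'
#' @param names Character vector of unique primer names.
#' @param sequences Character vector (or \code{DNAStringSet}) of 5'->3'
#'   primer sequences over A/C/G/T, parallel to \code{names}.
#' @param annotation Optional data.frame of per-primer annotation.
#' @return A \linkS4class{PrimerPanel}.
#' @examples
#' pp <- PrimerPanel(c("me1", "em1"),
#'                   c("TGAGTCCAAACCGGATA", "GACTGCGTACGAATTAAT"))
#' gcContent(pp)
#' @export
PrimerPanel <- function(names, sequences, annotation = NULL) {
    sequences <- as.character(sequences)
    if (any(grepl("[^ACGT]", sequences)))
        stop("primer sequences must use only A, C, G, T")
    s <- Biostrings::DNAStringSet(sequences)
    names(s) <- as.character(names)
    ann <- if (is.null(annotation)) {
        S4Vectors::DataFrame(matrix(nrow = length(s), ncol = 0),
                             row.names = names(s))
    } else {
        S4Vectors::DataFrame(annotation, row.names = names(s))
    }
    new("PrimerPanel", sequences = s, annotation = ann)
}

#' @describeIn PrimerPanel Number of primers in the panel.
#' @param x A \code{PrimerPanel}.
#' @export
setMethod("length", "PrimerPanel", function(x) length(x@sequences))

#' @describeIn PrimerPanel Primer names.
#' @export
setMethod("names", "PrimerPanel", function(x) names(x@sequences))

#' @describeIn PrimerPanel The sequences as a named character vector.
#' @param object A \code{PrimerPanel}.
#' @export
primerSequences <- function(object) {
    stopifnot(is(object, "PrimerPanel"))
    structure(as.character(object@sequences), names = names(object@sequences))
}

setMethod("show", "PrimerPanel", function(object) {
    cat(sprintf("PrimerPanel: %d primers, widths %d-%d nt\n",
                length(object),
                min(Biostrings::width(object@sequences)),
                max(Biostrings::width(object@sequences))))
    utils::head(as.data.frame(list(
        sequence = as.character(object@sequences),
        gc = gcContent(object))), 5) |> print()
    if (length(object) > 5L) cat("  ...\n")
})

#' Construct a TraitTable
#'
#' Declares each phenotype variable as quantitative (numeric) or
#' qualitative (factor). Character columns of a data.frame input are
#' promoted to factors with levels in order of first appearance unless a
#' level order is supplied; the declared level order is the ordinal
#' codebook used downstream.
#'
#' @param data data.frame or DataFrame, genotypes in rows (row names = ids).
#' @param levels Optional named list: variable -> character vector giving
#'   the level order for qualitative variables.
#' @param units Optional named character vector of units for quantitative
#'   variables.
#' @return A \linkS4class{TraitTable}.
#' @examples
#' tt <- TraitTable(data.frame(
#'     height = c(10.2, 12.5, 9.8),
#'     vigor  = c("low", "high", "high"),
#'     row.names = paste0("g", 1:3)),
#'     levels = list(vigor = c("low", "medium", "high")))
#' traitTypes(tt)
#' @export
TraitTable <- function(data, levels = NULL, units = character()) {
    d <- as.data.frame(data)
    for (v in colnames(d)) {
        if (is.character(d[[v]]) || is.logical(d[[v]]))
            d[[v]] <- factor(d[[v]], levels = unique(d[[v]]))
        if (!is.null(levels[[v]])) {
            obs <- unique(as.character(d[[v]]))
            miss <- setdiff(obs[!is.na(obs)], levels[[v]])
            if (length(miss))
                stop(sprintf("variable '%s' has values outside declared levels: %s",
                             v, paste(miss, collapse = ", ")))
            d[[v]] <- factor(as.character(d[[v]]), levels = levels[[v]])
        }
    }
    new("TraitTable", data = S4Vectors::DataFrame(d, row.names = rownames(d)),
        units = units)
}

#' @rdname TraitTable
#' @param x A \code{TraitTable}.
#' @return \code{traitTypes}: named character vector, "quantitative" or
#'   "qualitative" per variable.
#' @export
setMethod("traitTypes", "TraitTable", function(x) {
    vapply(seq_len(ncol(x@data)), function(j)
        if (is.numeric(x@data[[j]])) "quantitative" else "qualitative",
        character(1)) |> stats::setNames(colnames(x@data))
})

#' @rdname TraitTable
#' @export
setMethod("dim", "TraitTable", function(x) dim(x@data))

#' @rdname TraitTable
#' @export
setMethod("rownames", "TraitTable", function(x) rownames(x@data))

#' @describeIn TraitTable The underlying DataFrame.
#' @export
traitData <- function(x) {
    stopifnot(is(x, "TraitTable"))
    x@data
}

setMethod("show", "TraitTable", function(object) {
    ty <- traitTypes(object)
    cat(sprintf("TraitTable: %d genotypes x %d variables (%d quantitative, %d qualitative)\n",
                nrow(object@data), ncol(object@data),
                sum(ty == "quantitative"), sum(ty == "qualitative")))
})

#' Construct a ColorTable
#'
#' @param data data.frame with columns \code{genotype}, \code{organ},
#'   \code{L}, \code{a}, \code{b} (and optionally derived \code{C},
#'   \code{H}); one row per genotype x organ region.
#' @return A \linkS4class{ColorTable}.
#' @examples
#' ct <- ColorTable(data.frame(genotype = c("g1", "g1"),
#'     organ = c("slip", "eye"), L = c(80, 35),
#'     a = c(10, 45), b = c(-5, 20)))
#' @export
ColorTable <- function(data) {
    d <- as.data.frame(data)
    d$genotype <- as.character(d$genotype)
    d$organ <- as.character(d$organ)
    new("ColorTable", data = S4Vectors::DataFrame(d))
}

#' @describeIn ColorTable The underlying DataFrame.
#' @param x A \code{ColorTable}.
#' @export
colorData <- function(x) {
    stopifnot(is(x, "ColorTable"))
    x@data
}

setMethod("show", "ColorTable", function(object) {
    d <- object@data
    cat(sprintf("ColorTable: %d genotypes x %d organ regions%s\n",
                length(unique(d$genotype)), length(unique(d$organ)),
                if ("C" %in% colnames(d)) " (chroma/hue derived)" else ""))
})

#' @describeIn GermplasmPanel Constructor; checks that all layers share
#'   the same genotypes in the same order.
#' @param bands A \linkS4class{BandMatrix}.
#' @param traits A \linkS4class{TraitTable}.
#' @param colors A \linkS4class{ColorTable}.
#' @param groups Optional named character vector genotype -> group.
#' @param config Optional list echoing a simulation configuration.
#' @export
GermplasmPanel <- function(bands, traits, colors,
                           groups = character(), config = list()) {
    new("GermplasmPanel", bands = bands, traits = traits, colors = colors,
        groups = groups, config = config)
}

#' @describeIn GermplasmPanel Layer accessors.
#' @param x A \code{GermplasmPanel}.
#' @export
panelBands <- function(x) { stopifnot(is(x, "GermplasmPanel")); x@bands }

#' @rdname GermplasmPanel
#' @export
panelTraits <- function(x) { stopifnot(is(x, "GermplasmPanel")); x@traits }

#' @rdname GermplasmPanel
#' @export
panelColors <- function(x) { stopifnot(is(x, "GermplasmPanel")); x@colors }

#' @rdname GermplasmPanel
#' @export
trueGroups <- function(x) { stopifnot(is(x, "GermplasmPanel")); x@groups }

setMethod("show", "GermplasmPanel", function(object) {
    cat(sprintf("GermplasmPanel: %d genotypes%s\n",
                ncol(object@bands),
                if (length(object@groups))
                    sprintf(" in %d latent groups",
                            length(unique(object@groups))) else ""))
    show(object@bands); show(object@traits); show(object@colors)
})

#' Construct a Dendrogram
#'
#' Low-level constructor used by \code{\link{upgma}} and the Newick reader;
#' most users never call it directly.
#'
#' @param labels Leaf labels.
#' @param merge hclust-style merge matrix.
#' @param height Merge heights, nondecreasing.
#' @param order Displayed leaf order (defaults to the canonical order
#'   implied by the merge matrix).
#' @return A \linkS4class{Dendrogram}.
#' @export
Dendrogram <- function(labels, merge, height, order = NULL) {
    merge <- matrix(as.integer(merge), ncol = 2L)
    if (is.null(order))
        order <- .orderFromMerge(merge, logical(nrow(merge)))
    new("Dendrogram", labels = as.character(labels), merge = merge,
        height = as.numeric(height), order = as.integer(order))
}

#' @rdname leafOrder
#' @name leafOrder
#' @title Displayed leaf order of a dendrogram
#' @description Leaf labels left to right as the tree is displayed. This is
#'   the order entanglement is computed from.
#' @param x A \linkS4class{Dendrogram}.
#' @return Character vector of labels.
#' @export
setMethod("leafOrder", "Dendrogram", function(x) x@labels[x@order])

#' @describeIn Dendrogram Number of leaves.
#' @param x A \code{Dendrogram}.
#' @export
nLeaves <- function(x) { stopifnot(is(x, "Dendrogram")); length(x@labels) }

#' Convert a Dendrogram to hclust
#'
#' @param x A \linkS4class{Dendrogram}.
#' @param ... Ignored.
#' @return A \code{\link[stats]{hclust}} object.
#' @export
as.hclust.Dendrogram <- function(x, ...) {
    structure(list(merge = x@merge, height = x@height, order = x@order,
                   labels = x@labels, method = "average",
                   call = match.call(), dist.method = NULL),
              class = "hclust")
}

setMethod("show", "Dendrogram", function(object) {
    cat(sprintf("Dendrogram: %d leaves, heights %.4g .. %.4g\n",
                length(object@labels), min(object@height),
                max(object@height)))
    o <- leafOrder(object)
    cat("  order: ", paste(utils::head(o, 8), collapse = " "),
        if (length(o) > 8) "...", "\n")
})

setMethod("show", "TanglegramResult", function(object) {
    cat(sprintf("TanglegramResult: %d shared leaves, entanglement %.4f (L = %g)\n",
                nLeaves(object@tree1), object@entanglement, object@L))
    if (!is.na(object@k))
        cat(sprintf("  %d/%d leaves keep their cluster at k = %d\n",
                    length(object@matched), nLeaves(object@tree1), object@k))
})

#' @rdname untangle
#' @param x A \linkS4class{TanglegramResult}.
#' @export
setMethod("entanglementOf", "TanglegramResult",
          function(x) x@entanglement)

#' @describeIn untangle Accessors for the rotated trees and rank table.
#' @export
tanglegramTrees <- function(x) {
    stopifnot(is(x, "TanglegramResult"))
    list(tree1 = x@tree1, tree2 = x@tree2)
}

#' @rdname untangle
#' @export
matchedSet <- function(x) {
    stopifnot(is(x, "TanglegramResult"))
    x@matched
}
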