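#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom Biostrings DNAStringSet
NULL

#' BandMatrix: dominant-marker band calls for a genotype panel
#'
#' An S4 container for binary band-presence scores from dominant PCR
#' fingerprinting assays (SRAP, SCoT, ISSR, RAPD and similar). It extends
#' \linkS4class{SummarizedExperiment}: rows are scored bands, columns are
#' genotypes, and the single \code{"calls"} assay holds values in
#' \{0, 1, NA\} (NA marks a band that could not be scored for a genotype).
#' Each band is annotated with the primer (or primer combination) that
#' produced it, carried in \code{rowData()$primer}.
#'
#' @details
#' Dominant markers are observed only as band presence/absence; a present
#' band cannot distinguish a heterozygote from a dominant homozygote. All
#' downstream statistics in this package therefore operate on band-presence
#' frequencies, never on inferred allele dosages. Missing calls are excluded
#' from frequency denominators band by band.
#'
#' Use the \code{\link{BandMatrix}} constructor rather than \code{new()};
#' it accepts the genotypes-by-bands orientation used in scoring sheets and
#' validates the encoding.
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso \code{\link{bandCalls}}, \code{\link{primerOf}},
#'   \code{\link{bandStats}}, \code{\link{readBandMatrix}}
#' @exportClass BandMatrix
setClass("BandMatrix", contains = "SummarizedExperiment")

.validBandMatrix <- function(object) {
    msg <- character()
    a <- SummarizedExperiment::assayNames(object)
    if (!identical(a, "calls"))
        msg <- c(msg, "assays must be a single matrix named 'calls'")
    else {
        m <- SummarizedExperiment::assay(object, "calls")
        bad <- !(m %in% c(0, 1) | is.na(m))
        if (any(bad))
            msg <- c(msg, "band calls must be 0, 1 or NA")
    }
    if (ncol(object) < 2L)
        msg <- c(msg, "a BandMatrix needs at least 2 genotypes")
    if (nrow(object) < 1L)
        msg <- c(msg, "a BandMatrix needs at least 1 band")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "genotype ids must be present and unique")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "band ids must be present and unique")
    rd <- SummarizedExperiment::rowData(object)
    if (!("primer" %in% colnames(rd)))
        msg <- c(msg, "rowData must carry a 'primer' column")
    else if (any(is.na(rd$primer)) || any(rd$primer == ""))
        msg <- c(msg, "every band must be assigned to a primer")
    if (length(msg)) msg else TRUE
}
setValidity("BandMatrix", .validBandMatrix)

#' PrimerPanel: the primers behind a marker assay
#'
#' Holds the primer (or primer-combination component) sequences used to
#' generate a dominant-marker fingerprint, as a named
#' \code{\link[Biostrings]{DNAStringSet}} restricted to the unambiguous
#' alphabet A/C/G/T, plus an optional per-primer annotation table.
#' GC content is derived, not stored: see \code{\link{gcContent}}.
#'
#' @slot sequences A named \code{DNAStringSet}; names are primer names.
#' @slot annotation A \code{DataFrame} with one row per primer.
#'
#' @seealso \code{\link{PrimerPanel}}, \code{\link{gcContent}},
#'   \code{\link{readPrimerPanel}}
#' @exportClass PrimerPanel
setClass("PrimerPanel",
    representation(sequences = "DNAStringSet", annotation = "DataFrame"))

.validPrimerPanel <- function(object) {
    msg <- character()
    s <- object@sequences
    if (length(s) == 0L)
        msg <- c(msg, "panel must contain at least one primer")
    if (is.null(names(s)) || anyDuplicated(names(s)) || any(names(s) == ""))
        msg <- c(msg, "primer names must be present and unique")
    if (any(Biostrings::width(s) == 0L))
        msg <- c(msg, "primer sequences must be non-empty")
    freq <- Biostrings::alphabetFrequency(s)
    if (length(s) && any(rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
                         != Biostrings::width(s)))
        msg <- c(msg, "primer sequences must use only A, C, G, T")
    if (nrow(object@annotation) != length(s))
        msg <- c(msg, "annotation must have one row per primer")
    if (length(msg)) msg else TRUE
}
setValidity("PrimerPanel", .validPrimerPanel)

#' TraitTable: mixed quantitative/qualitative phenotypes
#'
#' A genotypes-by-variables phenotype table in which every variable is
#' declared either quantitative (a numeric column) or qualitative (a factor
#' column with a finite, ordered level set). The declared level order of
#' qualitative variables doubles as the codebook for ordinal coding when
#' such variables enter Euclidean distances or PCA
#' (\code{\link{ordinalCode}}).
#'
#' @slot data A \code{DataFrame}; row names are genotype ids, columns are
#'   numeric or factor.
#' @slot units Named character vector of measurement units for quantitative
#'   variables (may be empty).
#'
#' @seealso \code{\link{TraitTable}}, \code{\link{gowerDistance}},
#'   \code{\link{ordinalCode}}
#' @exportClass TraitTable
setClass("TraitTable",
    representation(data = "DataFrame", units = "character"))

.validTraitTable <- function(object) {
    msg <- character()
    d <- object@data
    if (nrow(d) < 1L || ncol(d) < 1L)
        msg <- c(msg, "trait table must have at least one genotype and one variable")
    if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
        msg <- c(msg, "genotype ids must be present and unique")
    ok <- vapply(seq_len(ncol(d)), function(j)
        is.numeric(d[[j]]) || is.factor(d[[j]]), logical(1))
    if (!all(ok))
        msg <- c(msg, sprintf(
            "variables must be numeric (quantitative) or factor (qualitative): %s",
            paste(colnames(d)[!ok], collapse = ", ")))
    extra <- setdiff(names(object@units), colnames(d))
    if (length(extra))
        msg <- c(msg, "units refer to unknown variables")
    if (length(msg)) msg else TRUE
}
setValidity("TraitTable", .validTraitTable)

#' ColorTable: CIELab measurements per genotype and organ region
#'
#' Long-format CIELab color records: one row per genotype and organ region
#' (e.g. petal slip, petal eye, sepal, petiole, dark lamina, silver lamina)
#' with lightness L* in [0, 100], the green-red axis a* and the blue-yellow
#' axis b*. Chroma C* and hue angle H-deg (in [0, 360)) are optional derived
#' columns filled in by \code{\link{deriveColorFeatures}}.
#'
#' @slot data A \code{DataFrame} with columns \code{genotype}, \code{organ},
#'   \code{L}, \code{a}, \code{b} and optionally \code{C} and \code{H}.
#'
#' @seealso \code{\link{ColorTable}}, \code{\link{chroma}},
#'   \code{\link{hueAngle}}, \code{\link{deriveColorFeatures}}
#' @exportClass ColorTable
setClass("ColorTable", representation(data = "DataFrame"))

.validColorTable <- function(object) {
    msg <- character()
    d <- object@data
    need <- c("genotype", "organ", "L", "a", "b")
    if (!all(need %in% colnames(d)))
        return(sprintf("color table needs columns: %s",
                       paste(need, collapse = ", ")))
    if (anyDuplicated(d[, c("genotype", "organ")]))
        msg <- c(msg, "one row per genotype x organ region")
    L <- d$L
    if (any(!is.na(L) & (L < 0 | L > 100)))
        msg <- c(msg, "L* must lie in [0, 100]")
    if ("H" %in% colnames(d)) {
        H <- d$H
        if (any(!is.na(H) & (H < 0 | H >= 360)))
            msg <- c(msg, "hue angle must lie in [0, 360)")
    }
    if (length(msg)) msg else TRUE
}
setValidity("ColorTable", .validColorTable)

#' GermplasmPanel: one panel, three data layers
#'
#' Bundles the three data layers measured on the same set of genotypes --
#' a \linkS4class{BandMatrix} (molecular), a \linkS4class{TraitTable}
#' (morphology) and a \linkS4class{ColorTable} (CIELab) -- together with
#' the latent group labels when the panel was simulated. All layers share
#' identical genotype ids in identical order.
#'
#' @slot bands A \code{BandMatrix}.
#' @slot traits A \code{TraitTable}.
#' @slot colors A \code{ColorTable}.
#' @slot groups Named character vector: genotype -> latent group ("" names
#'   allowed to be absent for real data, where groups are unknown).
#' @slot config List echoing the simulation configuration (empty for real
#'   data).
#'
#' @seealso \code{\link{simulatePanel}}
#' @exportClass GermplasmPanel
setClass("GermplasmPanel",
    representation(bands = "BandMatrix", traits = "TraitTable",
                   colors = "ColorTable", groups = "character",
                   config = "list"))

.validGermplasmPanel <- function(object) {
    msg <- character()
    g <- colnames(object@bands)
    if (!identical(g, rownames(object@traits@data)))
        msg <- c(msg, "band and trait genotype ids differ (or are reordered)")
    gc <- unique(as.character(object@colors@data$genotype))
    if (!identical(sort(g), sort(gc)))
        msg <- c(msg, "color table genotypes differ from band matrix")
    if (length(object@groups) &&
        !identical(names(object@groups), g))
        msg <- c(msg, "group labels must be named by genotype, in panel order")
    if (length(msg)) msg else TRUE
}
setValidity("GermplasmPanel", .validGermplasmPanel)

#' Dendrogram: a rooted binary merge tree with displayed leaf order
#'
#' The result of agglomerative clustering: \code{n - 1} binary merges with
#' nondecreasing heights, in the \code{\link[stats]{hclust}} encoding
#' (negative entries of \code{merge} are leaves, positive entries earlier
#' merges), plus the permutation of leaves in display order. The displayed
#' order is what tanglegram entanglement is computed from; rotating an
#' internal node changes \code{order} but not the merges.
#'
#' @slot labels Character vector of leaf labels.
#' @slot merge Integer (n-1) x 2 matrix, hclust encoding.
#' @slot height Numeric vector of merge heights, nondecreasing.
#' @slot order Integer permutation of \code{seq_along(labels)}: leaf indices
#'   left to right as displayed.
#'
#' @seealso \code{\link{upgma}}, \code{\link{copheneticMatrix}},
#'   \code{\link{entanglement}}, \code{\link{writeNewick}}
#' @exportClass Dendrogram
setClass("Dendrogram",
    representation(labels = "character", merge = "matrix",
                   height = "numeric", order = "integer"))

.validDendrogram <- function(object) {
    msg <- character()
    n <- length(object@labels)
    if (n < 2L)
        msg <- c(msg, "a dendrogram needs at least 2 leaves")
    if (anyDuplicated(object@labels) || any(object@labels == ""))
        msg <- c(msg, "leaf labels must be present and unique")
    if (!identical(dim(object@merge), c(n - 1L, 2L)))
        msg <- c(msg, "merge must be an (n-1) x 2 matrix")
    if (length(object@height) != n - 1L)
        msg <- c(msg, "one height per merge")
    else if (is.unsorted(object@height + 1e-12 * cummax(abs(object@height))))
        msg <- c(msg, "merge heights must be nondecreasing")
    if (!identical(sort(object@order), seq_len(n)))
        msg <- c(msg, "order must be a permutation of the leaves")
    if (length(msg)) msg else TRUE
}
setValidity("Dendrogram", .validDendrogram)

#' TanglegramResult: an aligned pair of dendrograms
#'
#' Returned by \code{\link{untangle}}: the two input trees with their
#' displayed leaf orders rotated to minimize entanglement, the achieved
#' entanglement coefficient, the exponent used in its norm, per-leaf rank
#' pairs, and (when a cut level \code{k} was requested) the set of leaves
#' whose k-cluster membership agrees between the two trees.
#'
#' @slot tree1,tree2 The rotated \linkS4class{Dendrogram}s.
#' @slot entanglement Achieved coefficient in [0, 1]; 0 = perfectly aligned.
#' @slot L Exponent of the rank-difference norm.
#' @slot ranks \code{DataFrame} with columns \code{label}, \code{pos1},
#'   \code{pos2}: 1-based display positions of each leaf in the two trees.
#' @slot matched Character vector of leaves with concordant k-cluster
#'   membership (empty when no \code{k} was requested).
#' @slot k Integer cut level used for \code{matched} (NA if none).
#'
#' @seealso \code{\link{untangle}}, \code{\link{matchedLeaves}}
#' @exportClass TanglegramResult
setClass("TanglegramResult",
    representation(tree1 = "Dendrogram", tree2 = "Dendrogram",
                   entanglement = "numeric", L = "numeric",
                   ranks = "DataFrame", matched = "character",
                   k = "integer"))
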