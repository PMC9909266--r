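#' @rdname gcContent
#' @export
setGeneric("gcContent", function(x, ...) standardGeneric("gcContent"))

#' @rdname bandCalls
#' @export
setGeneric("bandCalls", function(x) standardGeneric("bandCalls"))

#' @rdname bandCalls
#' @export
setGeneric("primerOf", function(x) standardGeneric("primerOf"))

#' @rdname bandCalls
#' @export
setGeneric("genotypeIds", function(x) standardGeneric("genotypeIds"))

#' @rdname bandCalls
#' @export
setGeneric("bandIds", function(x) standardGeneric("bandIds"))

#' @rdname TraitTable
#' @export
setGeneric("traitTypes", function(x) standardGeneric("traitTypes"))

#' @rdname diversityTable
#' @export
setGeneric("diversityTable", function(x, ...) standardGeneric("diversityTable"))

#' @rdname gowerDistance
#' @export
setGeneric("gowerDistance", function(x, ...) standardGeneric("gowerDistance"))

#' @rdname euclideanDistance
#' @export
setGeneric("euclideanDistance",
    function(x, ...) standardGeneric("euclideanDistance"))

#' @rdname binaryDistance
#' @export
setGeneric("binaryDistance",
    function(x, ...) standardGeneric("binaryDistance"))

#' @rdname pearsonSimilarity
#' @export
setGeneric("pearsonSimilarity",
    function(x, ...) standardGeneric("pearsonSimilarity"))

#' @rdname pcaMorpho
#' @export
setGeneric("pcaMorpho", function(x, ...) standardGeneric("pcaMorpho"))

#' @rdname leafOrder
#' @export
setGeneric("leafOrder", function(x) standardGeneric("leafOrder"))

#' @rdname untangle
#' @export
setGeneric("entanglementOf", function(x) standardGeneric("entanglementOf"))
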