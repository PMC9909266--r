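#' Ecological diversity indices of a nonnegative profile
#'
#' Given a nonnegative abundance vector \eqn{x} with proportions
#' \eqn{p_i = x_i / \sum x} over its nonzero entries:
#' \describe{
#'   \item{Shannon-Wiener}{\eqn{H' = -\sum p_i \ln p_i} (natural log).}
#'   \item{Gini-Simpson}{\eqn{\lambda = 1 - \sum p_i^2}.}
#'   \item{Pielou evenness}{\eqn{J = H' / \ln S} with \eqn{S} the number
#'     of nonzero categories; defined only for \eqn{S \ge 2}.}
#' }
#' Shannon and Simpson are computed through \code{\link[vegan]{diversity}};
#' both are invariant to positive rescaling of \eqn{x}.
#'
#' @param x Nonnegative numeric vector with a positive sum.
#' @return A single numeric value.
#' @examples
#' shannonIndex(rep(1, 4))   # ln 4
#' simpsonIndex(rep(1, 4))   # 0.75
#' pielouEvenness(c(2, 1, 1))
#' @name diversity-indices
NULL

.checkProfile <- function(x) {
    if (any(is.na(x))) stop("profile contains missing values")
    if (any(x < 0)) stop("profile must be nonnegative")
    if (sum(x) <= 0) stop("profile is all zero")
    x
}

#' @rdname diversity-indices
#' @export
shannonIndex <- function(x) {
    x <- .checkProfile(x)
    unname(vegan::diversity(x, index = "shannon"))
}

#' @rdname diversity-indices
#' @export
simpsonIndex <- function(x) {
    x <- .checkProfile(x)
    unname(vegan::diversity(x, index = "simpson"))
}

#' @rdname diversity-indices
#' @export
pielouEvenness <- function(x) {
    x <- .checkProfile(x)
    S <- sum(x > 0)
    if (S < 2L) stop("evenness undefined for a single-category profile")
    shannonIndex(x) / log(S)
}

#' Per-genotype diversity table
#'
#' Computes Shannon-Wiener, Gini-Simpson and Pielou evenness for every
#' genotype's profile (row) of a nonnegative feature matrix, plus a
#' min / median / max / average summary block. For a
#' \linkS4class{BandMatrix}, the profile is the genotype's band-call row
#' (missing calls treated as absent, with a message); for a
#' \linkS4class4{TraitTable} or numeric matrix of mixed sign, variables are
#' ordinal-coded and min-max scaled to [0, 1] first so that profiles are
#' nonnegative.
#'
#' All-zero profiles are flagged and excluded from the summary with a
#' warning.
#'
#' @param x A \linkS4class{BandMatrix}, \linkS4class{TraitTable} or
#'   nonnegative numeric matrix (genotypes in rows).
#' @param ... Unused.
#' @return A list with \code{perGenotype} (data.frame: id, S, shannon,
#'   simpson, pielou) and \code{summary} (data.frame with rows min,
#'   median, max, average).
#' @examples
#' m <- matrix(rbinom(40, 1, 0.6), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("b", 1:10)))
#' diversityTable(m)$summary
#' @export
setMethod("diversityTable", "matrix", function(x, ...) {
    if (any(x < 0, na.rm = TRUE))
        stop("feature matrix must be nonnegative; scale first")
    x[is.na(x)] <- 0
    ids <- rownames(x)
    if (is.null(ids)) ids <- paste0("unit", seq_len(nrow(x)))
    zero <- rowSums(x) <= 0
    if (any(zero))
        warning(sprintf("all-zero profile(s) excluded from summary: %s",
                        paste(ids[zero], collapse = ", ")))
    per <- data.frame(
        id = ids,
        S = apply(x, 1L, function(r) sum(r > 0)),
        shannon = ifelse(zero, NA,
                         apply(x, 1L, function(r)
                             if (sum(r) > 0) shannonIndex(r) else NA)),
        simpson = ifelse(zero, NA,
                         apply(x, 1L, function(r)
                             if (sum(r) > 0) simpsonIndex(r) else NA)),
        row.names = NULL)
    per$pielou <- ifelse(per$S >= 2, per$shannon / log(pmax(per$S, 2)), NA)
    ok <- per[!zero, c("shannon", "simpson", "pielou")]
    summ <- data.frame(
        statistic = c("min", "median", "max", "average"),
        shannon = c(min(ok$shannon, na.rm = TRUE),
                    stats::median(ok$shannon, na.rm = TRUE),
                    max(ok$shannon, na.rm = TRUE),
                    mean(ok$shannon, na.rm = TRUE)),
        simpson = c(min(ok$simpson, na.rm = TRUE),
                    stats::median(ok$simpson, na.rm = TRUE),
                    max(ok$simpson, na.rm = TRUE),
                    mean(ok$simpson, na.rm = TRUE)),
        pielou = c(min(ok$pielou, na.rm = TRUE),
                   stats::median(ok$pielou, na.rm = TRUE),
                   max(ok$pielou, na.rm = TRUE),
                   mean(ok$pielou, na.rm = TRUE)))
    list(perGenotype = per, summary = summ)
})

#' @rdname diversityTable
#' @export
setMethod("diversityTable", "BandMatrix", function(x, ...) {
    m <- bandCalls(x)
    if (anyNA(m)) message("missing band calls treated as absent")
    m[is.na(m)] <- 0L
    diversityTable(m)
})

#' @rdname diversityTable
#' @export
setMethod("diversityTable", "TraitTable", function(x, ...) {
    diversityTable(minMaxScale(ordinalCode(x)))
})

#' Min-max scale the columns of a matrix to [0, 1]
#'
#' Shifts every feature to the unit interval, the nonnegative profile
#' construction used before diversity indices on trait and color layers.
#' Constant features map to 0.
#'
#' @param x Numeric matrix.
#' @return Matrix of the same shape with columns in [0, 1].
#' @export
minMaxScale <- function(x) {
    x <- as.matrix(x)
    apply(x, 2L, function(col) {
        r <- range(col, na.rm = TRUE)
        if (diff(r) == 0) rep(0, length(col)) else (col - r[1L]) / diff(r)
    }) |> matrix(nrow = nrow(x), dimnames = dimnames(x))
}
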