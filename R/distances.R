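.asDist <- function(m, method) {
    d <- stats::as.dist(m)
    attr(d, "method") <- method
    d
}

#' Ordinal-code a mixed trait table
#'
#' Qualitative variables become integers following their declared level
#' order; quantitative variables pass through. This is the codebook used
#' when mixed tables enter Euclidean distance or PCA.
#'
#' @param x A \linkS4class{TraitTable} or data.frame.
#' @return Numeric matrix, genotypes x variables.
#' @export
ordinalCode <- function(x) {
    d <- if (is(x, "TraitTable")) as.data.frame(x@data) else as.data.frame(x)
    out <- vapply(seq_len(ncol(d)), function(j) {
        col <- d[[j]]
        if (is.numeric(col)) as.numeric(col) else as.numeric(as.integer(col))
    }, numeric(nrow(d)))
    out <- matrix(out, nrow = nrow(d),
                  dimnames = list(rownames(d), colnames(d)))
    out
}

#' Euclidean distance with optional z-score standardization
#'
#' Pairwise \eqn{\sqrt{\sum_f (x_f - y_f)^2}}. With
#' \code{standardize = TRUE} (default) every feature is centred and scaled
#' by its population standard deviation (divisor N, for bit-reproducible
#' results); constant features are dropped with a warning. Mixed trait
#' tables are ordinal-coded first. Missing values are an error: impute
#' explicitly, or use \code{\link{gowerDistance}} which handles
#' missingness pairwise.
#'
#' @param x Numeric matrix (units in rows) or \linkS4class{TraitTable}.
#' @param standardize Z-score features first?
#' @param ... Unused.
#' @return A \code{\link[stats]{dist}} object.
#' @examples
#' euclideanDistance(rbind(u = c(0, 0), v = c(3, 4)), standardize = FALSE)
#' @export
setMethod("euclideanDistance", "matrix", function(x, standardize = TRUE, ...) {
    if (anyNA(x))
        stop("missing values in input; impute first or use gowerDistance()")
    if (nrow(x) < 2L) stop("need at least 2 units")
    if (standardize) {
        sds <- apply(x, 2L, function(c) sqrt(mean((c - mean(c))^2)))
        keep <- sds > 0
        if (!all(keep))
            warning(sprintf("constant feature(s) dropped: %s",
                            paste(colnames(x)[!keep], collapse = ", ")))
        if (!any(keep)) stop("no non-constant features left")
        x <- scale(x[, keep, drop = FALSE],
                   center = colMeans(x[, keep, drop = FALSE]),
                   scale = sds[keep])
    }
    .asDist(as.matrix(stats::dist(x, method = "euclidean")), "euclidean")
})

#' @rdname euclideanDistance
#' @export
setMethod("euclideanDistance", "TraitTable",
    function(x, standardize = TRUE, ...)
        euclideanDistance(ordinalCode(x), standardize = standardize))

#' Gower distance for mixed trait tables
#'
#' Per pair of genotypes, the mean over comparable features of the feature
#' dissimilarity: \eqn{|x - y| / \mathrm{range}} for quantitative
#' variables (range taken over the whole table), 0/1 mismatch for
#' qualitative variables. Features missing in either member of a pair are
#' excluded from both numerator and denominator; a pair with no comparable
#' feature is an error.
#'
#' @param x A \linkS4class{TraitTable} or data.frame (factor columns are
#'   qualitative).
#' @param ... Unused.
#' @return A \code{\link[stats]{dist}} in [0, 1].
#' @examples
#' tt <- TraitTable(data.frame(q = c(2, 7), f = factor(c("x", "x")),
#'                             row.names = c("g1", "g2")))
#' gowerDistance(tt)  # (|2-7|/5 + 0)/2 = 0.5
#' @export
setMethod("gowerDistance", "TraitTable", function(x, ...) {
    d <- x@data
    n <- nrow(d)
    if (n < 2L) stop("need at least 2 genotypes")
    quant <- vapply(seq_len(ncol(d)), function(j) is.numeric(d[[j]]),
                    logical(1))
    rng <- vapply(seq_len(ncol(d)), function(j)
        if (quant[j]) diff(range(d[[j]], na.rm = TRUE)) else NA_real_,
        numeric(1))
    num <- matrix(0, n, n)
    den <- matrix(0L, n, n)
    for (j in seq_len(ncol(d))) {
        col <- d[[j]]
        obs <- !is.na(col)
        cmp <- outer(obs, obs, "&")
        contrib <- matrix(0, n, n)
        if (quant[j]) {
            if (is.na(rng[j]) || rng[j] == 0) {
                # constant observed values: zero dissimilarity, still compared
            } else {
                v <- as.numeric(col)
                contrib <- abs(outer(v, v, "-")) / rng[j]
                contrib[!cmp] <- 0
            }
        } else {
            v <- as.character(col)
            contrib <- outer(v, v, "!=") * 1
            contrib[!cmp] <- 0
        }
        num <- num + contrib
        den <- den + cmp
    }
    if (any(den[lower.tri(den)] == 0)) {
        bad <- which(den == 0 & lower.tri(den), arr.ind = TRUE)[1L, ]
        stop(sprintf("no comparable features between '%s' and '%s'",
                     rownames(d)[bad[2L]], rownames(d)[bad[1L]]))
    }
    g <- num / den
    diag(g) <- 0
    dimnames(g) <- list(rownames(d), rownames(d))
    .asDist(g, "gower")
})

#' @rdname gowerDistance
#' @export
setMethod("gowerDistance", "data.frame", function(x, ...)
    gowerDistance(TraitTable(x)))

#' Binary distances for band matrices
#'
#' Pairwise dissimilarity between band-presence profiles, with missing
#' calls excluded pairwise:
#' \describe{
#'   \item{simple-matching}{mismatches / compared bands, in [0, 1].}
#'   \item{jaccard}{\eqn{1 - |both| / |either|} over compared bands
#'     (0 when neither genotype carries any compared band: identical
#'     all-absent profiles).}
#'   \item{euclidean}{\eqn{\sqrt{\mathrm{mismatches}}} over compared
#'     bands -- the value Euclidean distance takes on 0/1 data.}
#' }
#'
#' @param x A \linkS4class{BandMatrix} or 0/1 matrix (genotypes in rows).
#' @param method One of \code{"simple-matching"}, \code{"jaccard"},
#'   \code{"euclidean"}.
#' @param ... Unused.
#' @return A \code{\link[stats]{dist}} object.
#' @examples
#' m <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 0, 1, 0))
#' binaryDistance(m, "jaccard")  # 1 - 1/3
#' @export
setMethod("binaryDistance", "matrix",
    function(x, method = c("simple-matching", "jaccard", "euclidean"), ...) {
    method <- match.arg(method)
    if (!all(x %in% c(0, 1) | is.na(x)))
        stop("matrix must be binary 0/1 (NA allowed)")
    n <- nrow(x)
    if (n < 2L) stop("need at least 2 genotypes")
    out <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        cmp <- !is.na(x[i, ]) & !is.na(x[j, ])
        if (!any(cmp))
            stop(sprintf("no compared bands between '%s' and '%s'",
                         rownames(x)[i], rownames(x)[j]))
        xi <- x[i, cmp]; xj <- x[j, cmp]
        d <- switch(method,
            "simple-matching" = mean(xi != xj),
            "jaccard" = {
                either <- sum(xi == 1 | xj == 1)
                if (either == 0) 0 else 1 - sum(xi == 1 & xj == 1) / either
            },
            "euclidean" = sqrt(sum(xi != xj)))
        out[i, j] <- out[j, i] <- d
    }
    .asDist(out, method)
})

#' @rdname binaryDistance
#' @export
setMethod("binaryDistance", "BandMatrix",
    function(x, method = c("simple-matching", "jaccard", "euclidean"), ...)
        binaryDistance(bandCalls(x), method = match.arg(method)))

#' Pearson similarity and 1 - r distance between unit profiles
#'
#' Pairwise Pearson correlation between the rows of a feature matrix
#' (e.g. genotype band profiles), and the derived dissimilarity
#' \eqn{1 - r \in [0, 2]}.
#'
#' @param x Numeric matrix (units in rows, >= 3 features) or
#'   \linkS4class{BandMatrix}.
#' @param ... Unused.
#' @return \code{pearsonSimilarity}: the symmetric correlation matrix;
#'   \code{pearsonDistance}: a \code{dist} of 1 - r.
#' @examples
#' m <- rbind(u = c(1, 2, 3), v = c(2, 4, 6), w = c(3, 1, 2))
#' pearsonSimilarity(m)["u", "v"]  # 1: affine invariance
#' @export
setMethod("pearsonSimilarity", "matrix", function(x, ...) {
    if (ncol(x) < 3L) stop("need at least 3 features per profile")
    if (anyNA(x)) stop("missing values in input; impute first")
    sds <- apply(x, 1L, stats::sd)
    if (any(sds == 0))
        stop(sprintf("constant profile(s), correlation undefined: %s",
                     paste(rownames(x)[sds == 0], collapse = ", ")))
    r <- stats::cor(t(x), method = "pearson")
    dimnames(r) <- list(rownames(x), rownames(x))
    r
})

#' @rdname pearsonSimilarity
#' @export
setMethod("pearsonSimilarity", "BandMatrix", function(x, ...)
    pearsonSimilarity(bandCalls(x) * 1))

#' @rdname pearsonSimilarity
#' @export
pearsonDistance <- function(x) {
    r <- pearsonSimilarity(x)
    d <- 1 - r
    diag(d) <- 0
    .asDist(d, "pearson")
}
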