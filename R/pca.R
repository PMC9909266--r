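#' Principal component analysis of trait matrices
#'
#' Eigen-decomposition of the correlation matrix (default) or covariance
#' matrix of a genotypes-by-variables table. Mixed trait tables are
#' ordinal-coded first (\code{\link{ordinalCode}}). Constant variables are
#' dropped with a warning under standardization. The loading sign
#' convention is deterministic: in every component the largest-magnitude
#' loading is positive, so results are reproducible across platforms.
#'
#' @param x Numeric matrix (genotypes in rows) or
#'   \linkS4class{TraitTable}. No missing values (impute first).
#' @param standardize Use the correlation matrix (TRUE, default) or the
#'   covariance matrix.
#' @param ... Unused.
#' @return A list of class \code{"pcaMorpho"}: \code{eigenvalues}
#'   (descending, clamped at 0), \code{explained} (percent, sums to 100),
#'   \code{cumulative}, \code{loadings} (variables x components,
#'   orthonormal columns), \code{scores} (genotypes x components) and
#'   \code{contributions} (percent contribution of each variable to each
#'   component, columns sum to 100).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' x <- cbind(x, x[, 1] * 2)        # a perfectly correlated pair
#' res <- pcaMorpho(x)
#' sum(res$explained)               # 100
#' @export
setMethod("pcaMorpho", "matrix", function(x, standardize = TRUE, ...) {
    if (anyNA(x)) stop("missing values in input; impute first")
    if (nrow(x) < 2L || ncol(x) < 2L)
        stop("need at least 2 genotypes and 2 variables")
    if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
    if (is.null(rownames(x))) rownames(x) <- paste0("g", seq_len(nrow(x)))
    sds <- apply(x, 2L, stats::sd)
    if (standardize && any(sds == 0)) {
        warning(sprintf("constant variable(s) dropped: %s",
                        paste(colnames(x)[sds == 0], collapse = ", ")))
        x <- x[, sds > 0, drop = FALSE]
        if (ncol(x) < 2L) stop("fewer than 2 non-constant variables")
    }
    xc <- scale(x, center = TRUE, scale = standardize)
    S <- if (standardize) stats::cor(x) else stats::cov(x)
    e <- eigen(S, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    V <- e$vectors
    # sign convention: largest |loading| positive per component
    for (j in seq_len(ncol(V))) {
        i <- which.max(abs(V[, j]))
        if (V[i, j] < 0) V[, j] <- -V[, j]
    }
    dimnames(V) <- list(colnames(x), paste0("PC", seq_len(ncol(V))))
    explained <- 100 * ev / sum(ev)
    scores <- xc %*% V
    contrib <- 100 * V^2
    structure(list(
        eigenvalues = ev,
        explained = explained,
        cumulative = cumsum(explained),
        loadings = V,
        scores = scores,
        contributions = contrib,
        standardized = standardize), class = "pcaMorpho")
})

#' @rdname pcaMorpho
#' @export
setMethod("pcaMorpho", "TraitTable", function(x, standardize = TRUE, ...)
    pcaMorpho(ordinalCode(x), standardize = standardize))

#' @export
print.pcaMorpho <- function(x, ...) {
    cat(sprintf("PCA of %d genotypes x %d variables (%s matrix)\n",
                nrow(x$scores), nrow(x$loadings),
                if (x$standardized) "correlation" else "covariance"))
    k <- min(5L, length(x$eigenvalues))
    print(round(data.frame(eigenvalue = x$eigenvalues[1:k],
                           explained = x$explained[1:k],
                           cumulative = x$cumulative[1:k]), 3))
    invisible(x)
}

#' Choose how many principal components to keep
#'
#' \code{rule = "kaiser"} keeps components with eigenvalue > 1 (meaningful
#' only on the correlation scale, where 1 is the variance of one
#' standardized variable); if none qualifies, 1 is returned with a
#' warning. \code{rule = "cumulative"} keeps the smallest count whose
#' cumulative explained variance reaches \code{threshold} percent.
#'
#' @param x A \code{pcaMorpho} result.
#' @param rule \code{"kaiser"} or \code{"cumulative"}.
#' @param threshold Percent of variance for the cumulative rule.
#' @return Integer component count.
#' @export
selectComponents <- function(x, rule = c("kaiser", "cumulative"),
                             threshold = 80) {
    rule <- match.arg(rule)
    if (rule == "kaiser") {
        n <- sum(x$eigenvalues > 1)
        if (n == 0L) {
            warning("no eigenvalue exceeds 1; keeping 1 component")
            n <- 1L
        }
        return(as.integer(n))
    }
    as.integer(which(x$cumulative >= threshold - 1e-9)[1L])
}
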