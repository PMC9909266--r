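#' Chroma and hue angle from CIELab coordinates
#'
#' \code{chroma} is the color intensity \eqn{C^* = \sqrt{a^{*2} + b^{*2}}}.
#' \code{hueAngle} is the shade \eqn{H^\circ}, the angle of the point
#' \eqn{(a^*, b^*)} in degrees mapped to [0, 360). The naive
#' \eqn{\tan^{-1}(b^*/a^*)} is quadrant-ambiguous and undefined at
#' \eqn{a^* = 0}; the colorimetric standard two-argument arctangent is
#' used instead, so (0, 1) -> 90 and (-1, 1) -> 135. The hue of an
#' achromatic point (a* = b* = 0) is undefined and returned as NA with a
#' warning (or an error with \code{strict = TRUE}).
#'
#' @param a,b Numeric vectors: CIELab a* (green-red) and b* (blue-yellow).
#' @param strict If TRUE, an achromatic point is an error instead of NA.
#' @return Numeric vector: chroma (nonnegative) or hue in degrees [0, 360).
#' @examples
#' chroma(3, 4)       # 5
#' hueAngle(0, 1)     # 90
#' hueAngle(-1, 1)    # 135
#' @export
chroma <- function(a, b) {
    stopifnot(is.numeric(a), is.numeric(b))
    sqrt(a^2 + b^2)
}

#' @rdname chroma
#' @export
hueAngle <- function(a, b, strict = FALSE) {
    stopifnot(is.numeric(a), is.numeric(b))
    achro <- !is.na(a) & !is.na(b) & a == 0 & b == 0
    if (any(achro)) {
        if (strict) stop("hue undefined for achromatic point a* = b* = 0")
        warning("hue undefined for achromatic point(s); returning NA")
    }
    h <- atan2(b, a) * 180 / pi
    h <- ifelse(h < 0, h + 360, h)
    h[h >= 360] <- 0          # guard against 360 from rounding
    h[achro] <- NA_real_
    h
}

#' Derive chroma and hue columns, and a wide color feature matrix
#'
#' \code{deriveColorFeatures} adds \code{C} (chroma) and \code{H} (hue
#' angle) columns to a \linkS4class{ColorTable}.
#' \code{colorFeatureMatrix} then spreads the table to one row per
#' genotype with \code{organ.L}, \code{organ.a}, \code{organ.b},
#' \code{organ.C}, \code{organ.H} columns, the input expected by the
#' distance and clustering stages. Every genotype must have been measured
#' on the same organ regions.
#'
#' @param x A \linkS4class{ColorTable}.
#' @return \code{deriveColorFeatures}: the \code{ColorTable} with derived
#'   columns; \code{colorFeatureMatrix}: a numeric matrix genotypes x
#'   (organs x 5 channels).
#' @examples
#' ct <- ColorTable(data.frame(genotype = "g1", organ = "slip",
#'                             L = 80, a = 3, b = 4))
#' colorData(deriveColorFeatures(ct))
#' @export
deriveColorFeatures <- function(x) {
    stopifnot(is(x, "ColorTable"))
    d <- x@data
    d$C <- chroma(d$a, d$b)
    d$H <- suppressWarnings(hueAngle(d$a, d$b))
    new("ColorTable", data = d)
}

#' @rdname deriveColorFeatures
#' @export
colorFeatureMatrix <- function(x) {
    stopifnot(is(x, "ColorTable"))
    d <- as.data.frame(colorData(x))
    if (!("C" %in% colnames(d)))
        d <- as.data.frame(colorData(deriveColorFeatures(x)))
    organs <- unique(d$organ)
    genos <- unique(d$genotype)
    bad <- vapply(genos, function(g)
        !setequal(d$organ[d$genotype == g], organs), logical(1))
    if (any(bad))
        stop(sprintf("organ regions inconsistent across genotypes: %s",
                     paste(genos[bad], collapse = ", ")))
    chans <- c("L", "a", "b", "C", "H")
    out <- matrix(NA_real_, length(genos), length(organs) * length(chans),
                  dimnames = list(genos, as.vector(
                      outer(chans, organs, function(ch, o)
                          paste(o, ch, sep = ".")))))
    for (i in seq_len(nrow(d))) {
        for (ch in chans)
            out[d$genotype[i], paste(d$organ[i], ch, sep = ".")] <- d[[ch]][i]
    }
    out
}
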