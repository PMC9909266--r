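#' Band presence frequency
#'
#' Fraction of non-missing genotypes carrying each band. Missing calls are
#' excluded from the denominator band by band.
#'
#' @param x A \linkS4class{BandMatrix}, or a single band's call vector
#'   (0/1/NA).
#' @return Named numeric vector of frequencies in [0, 1].
#' @examples
#' bandFrequency(c(1, 0, NA, 0))  # 1/3
#' @export
bandFrequency <- function(x) {
    if (is(x, "BandMatrix")) {
        m <- bandCalls(x)
        p <- colMeans(m == 1L, na.rm = TRUE)
        if (any(!is.finite(p)))
            stop(sprintf("band(s) with no scored genotype: %s",
                         paste(colnames(m)[!is.finite(p)], collapse = ", ")))
        return(p)
    }
    if (all(is.na(x))) stop("band has no scored genotype")
    mean(x == 1L, na.rm = TRUE)
}

#' Per-band informativeness statistics for dominant markers
#'
#' For a band with presence frequency \eqn{p} among scored genotypes:
#' \describe{
#'   \item{gene diversity}{\eqn{H = 1 - p^2 - (1-p)^2 = 2p(1-p)}, the
#'     expected heterozygosity of a two-state locus; at most 0.5.}
#'   \item{PIC}{\eqn{1 - (p^2 + q^2) - 2p^2q^2} with \eqn{q = 1-p}, the
#'     two-state (dominant/biallelic) reduction of Botstein's polymorphic
#'     information content; at most 0.375 at \eqn{p = 0.5}.}
#'   \item{band informativeness}{\eqn{I_b = 1 - 2|0.5 - p|}, which is 1
#'     for a band present in half the genotypes and 0 for a fixed band;
#'     its per-primer sum is the resolving power.}
#' }
#'
#' @param p Numeric vector of band frequencies in [0, 1].
#' @return Numeric vector of the same length.
#' @examples
#' geneDiversity(0.5)        # 0.5
#' picDominant(0.5)          # 0.375
#' bandInformativeness(0.75) # 0.5
#' @name band-statistics
NULL

#' @rdname band-statistics
#' @export
geneDiversity <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    2 * p * (1 - p)
}

#' @rdname band-statistics
#' @export
picDominant <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    q <- 1 - p
    1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' @rdname band-statistics
#' @export
bandInformativeness <- function(p) {
    stopifnot(all(p >= 0 & p <= 1))
    1 - 2 * abs(0.5 - p)
}

.isPolymorphic <- function(p, criterion = 1) {
    # strict: both states observed; 0.95-criterion: major state freq <= 0.95
    if (criterion >= 1) p > 0 & p < 1 else pmax(p, 1 - p) <= criterion
}

#' Per-band statistics table
#'
#' @param x A \linkS4class{BandMatrix}.
#' @param criterion Polymorphism criterion: 1 (default, strict -- both
#'   states observed) or e.g. 0.95 (major-state frequency at most 0.95).
#' @return A \code{DataFrame} with one row per band: \code{primer},
#'   \code{p}, \code{polymorphic}, \code{H}, \code{PIC}, \code{Ib}.
#' @seealso \code{\link{primerStats}}, \code{\link{panelSummary}}
#' @export
bandStats <- function(x, criterion = 1) {
    stopifnot(is(x, "BandMatrix"))
    p <- bandFrequency(x)
    S4Vectors::DataFrame(
        primer = unname(primerOf(x)),
        p = unname(p),
        polymorphic = unname(.isPolymorphic(p, criterion)),
        H = unname(geneDiversity(p)),
        PIC = unname(picDominant(p)),
        Ib = unname(bandInformativeness(p)),
        row.names = bandIds(x))
}

#' Discriminating power of a primer
#'
#' Tessier's discriminating power: with \eqn{p_i} the relative frequency
#' of the i-th distinct multi-band banding pattern among the \eqn{N}
#' scored genotypes,
#' \deqn{DP = 1 - \sum_i p_i \frac{N p_i - 1}{N - 1}.}
#' It is the probability that two genotypes drawn without replacement show
#' different patterns: 0 when all genotypes share one pattern, 1 when all
#' patterns are unique. Genotypes with any missing call among the primer's
#' bands are excluded and N adjusted.
#'
#' @param x A \linkS4class{BandMatrix} (DP computed per primer), or a
#'   genotypes-by-bands 0/1 matrix for a single primer.
#' @return Named numeric vector of DP values in [0, 1] (single value for a
#'   matrix input).
#' @examples
#' m <- rbind(g1 = c(1, 0), g2 = c(1, 0), g3 = c(0, 1), g4 = c(1, 1))
#' discriminatingPower(m)  # patterns {2,1,1}: 1 - 0.5/3 = 0.8333
#' @export
discriminatingPower <- function(x) {
    if (is(x, "BandMatrix")) {
        m <- bandCalls(x)
        pr <- primerOf(x)
        v <- vapply(unique(unname(pr)), function(pp)
            .dpOne(m[, names(pr)[pr == pp], drop = FALSE]), numeric(1))
        return(stats::setNames(v, unique(unname(pr))))
    }
    .dpOne(as.matrix(x))
}

.dpOne <- function(m) {
    keep <- stats::complete.cases(m)
    m <- m[keep, , drop = FALSE]
    N <- nrow(m)
    if (N < 2L)
        stop("fewer than 2 fully scored genotypes for this primer")
    pat <- apply(m, 1L, paste, collapse = "")
    cnt <- table(pat)
    p <- as.numeric(cnt) / N
    1 - sum(p * (N * p - 1) / (N - 1))
}

#' Per-primer summary statistics
#'
#' Aggregates band statistics by primer. For a primer with \eqn{n} scored
#' bands of which \eqn{PB} are polymorphic:
#' \describe{
#'   \item{pctP}{percent polymorphic, \eqn{100 \cdot PB/n}.}
#'   \item{E}{effective multiplex ratio. Default \code{emr = "count"}:
#'     \eqn{E = PB \cdot (PB/n)}, the band count weighted by its
#'     polymorphic fraction; \code{emr = "fraction"} gives the bare
#'     fraction \eqn{PB/n}.}
#'   \item{MI}{marker index, mean PIC times PB. With
#'     \code{micOver = "all"} (default) the PIC mean runs over all n
#'     bands; \code{"polymorphic"} restricts it to polymorphic bands.}
#'   \item{DP}{discriminating power (\code{\link{discriminatingPower}}).}
#'   \item{RP}{resolving power, \eqn{\sum I_b} over the primer's bands.}
#' }
#'
#' @param x A \linkS4class{BandMatrix}.
#' @param criterion Polymorphism criterion, see \code{\link{bandStats}}.
#' @param emr Effective-multiplex-ratio form: \code{"count"} or
#'   \code{"fraction"}.
#' @param micOver Bands over which mean PIC (and mean H) are taken for MI:
#'   \code{"all"} or \code{"polymorphic"}.
#' @return A data.frame with one row per primer: \code{n}, \code{PB},
#'   \code{pctP}, \code{meanH}, \code{meanPIC}, \code{E}, \code{MI},
#'   \code{DP}, \code{RP}.
#' @examples
#' bm <- BandMatrix(matrix(c(1, 0, 1, 0, 1, 1, 0, 0), nrow = 4,
#'     dimnames = list(paste0("g", 1:4), c("b1", "b2"))), "P1")
#' primerStats(bm)
#' @export
primerStats <- function(x, criterion = 1, emr = c("count", "fraction"),
                        micOver = c("all", "polymorphic")) {
    stopifnot(is(x, "BandMatrix"))
    emr <- match.arg(emr)
    micOver <- match.arg(micOver)
    bs <- bandStats(x, criterion)
    dp <- discriminatingPower(x)
    primers <- unique(bs$primer)
    rows <- lapply(primers, function(pp) {
        b <- bs[bs$primer == pp, ]
        n <- nrow(b)
        PB <- sum(b$polymorphic)
        sel <- if (micOver == "all") rep(TRUE, n) else b$polymorphic
        meanPIC <- if (any(sel)) mean(b$PIC[sel]) else 0
        meanH <- if (any(sel)) mean(b$H[sel]) else 0
        data.frame(primer = pp, n = n, PB = PB, pctP = 100 * PB / n,
                   meanH = meanH, meanPIC = meanPIC,
                   E = if (emr == "count") PB * PB / n else PB / n,
                   MI = meanPIC * PB, DP = unname(dp[pp]),
                   RP = sum(b$Ib))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Panel-level summary of marker informativeness
#'
#' Totals and per-primer averages over a whole marker panel. Two percent-
#' polymorphic figures are reported, which differ whenever primers carry
#' unequal band counts: \code{pctPolymorphicPooled} is the pooled ratio
#' \eqn{100 \cdot \sum PB / \sum n}, and the \code{pctP} entry of
#' \code{averages} is the unweighted mean of per-primer percentages.
#'
#' @inheritParams primerStats
#' @return A list with \code{totals} (bands, polymorphic bands, pooled
#'   percent polymorphic, number of primers), \code{perPrimer} (the
#'   \code{\link{primerStats}} table) and \code{averages} (unweighted
#'   per-primer means of PB, pctP, meanH, meanPIC, E, MI, DP, RP).
#' @examples
#' m <- matrix(rbinom(64, 1, 0.5), nrow = 8,
#'             dimnames = list(paste0("g", 1:8), paste0("b", 1:8)))
#' bm <- BandMatrix(m, primer = rep(c("P1", "P2"), each = 4))
#' panelSummary(bm)$totals
#' @export
panelSummary <- function(x, criterion = 1, emr = c("count", "fraction"),
                         micOver = c("all", "polymorphic")) {
    ps <- primerStats(x, criterion, emr, micOver)
    totals <- list(
        primers = nrow(ps),
        bands = sum(ps$n),
        polymorphicBands = sum(ps$PB),
        pctPolymorphicPooled = 100 * sum(ps$PB) / sum(ps$n))
    averages <- colMeans(ps[, c("PB", "pctP", "meanH", "meanPIC",
                                "E", "MI", "DP", "RP")])
    list(totals = totals, perPrimer = ps, averages = averages)
}
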