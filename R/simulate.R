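#' Configuration for a synthetic germplasm panel
#'
#' Describes a panel of genotypes in K latent groups with coupled marker,
#' trait and color signals. The defaults mirror a realistic ornamental-
#' germplasm study: 32 genotypes in 4 groups, a 26-primer SRAP-like layer
#' (349 bands) plus a 12-primer SCoT-like layer (204 bands), 19
#' quantitative and 17 qualitative morphological traits, and CIELab
#' triplets for six organ regions (petal slip, petal eye, sepal, petiole,
#' dark and silver lamina).
#'
#' The marker model works directly on band-presence frequencies, the
#' phenotypic level at which dominant markers are scored: each band gets
#' a baseline frequency drawn from Beta(\code{freqShape1},
#' \code{freqShape2}); for a random subset (\code{shiftFraction}) of
#' bands, each group is independently shifted by \code{+delta/2} or
#' \code{-delta/2} (equal probability), so two groups pulled in opposite
#' directions differ by \code{delta} in presence frequency; frequencies
#' are clamped to [0.02, 0.98]. Quantitative
#' traits are Normal with group means separated by \code{Delta} noise-SD
#' units; qualitative traits are categorical with a group-favored level
#' of probability \code{qualBias}; color channels are Normal per organ
#' and group with L* clipped to [0, 100].
#'
#' @param nGenotypes Number of genotypes (>= K).
#' @param K Number of latent groups (>= 1).
#' @param primers Data frame with columns \code{name}, \code{nBands}; the
#'   default lays out the two-assay panel described above.
#' @param freqShape1,freqShape2 Beta shape parameters of baseline band
#'   frequencies.
#' @param delta Group frequency shift for shifted bands (0 = no marker
#'   group structure).
#' @param shiftFraction Fraction of bands receiving group shifts.
#' @param nQuantTraits,nQualTraits Trait counts.
#' @param Delta Group mean separation of quantitative traits, in noise-SD
#'   units (0 = no trait group structure).
#' @param noiseSD Within-group SD of quantitative traits.
#' @param qualLevels Number of levels per qualitative trait.
#' @param qualBias Probability of the group-favored level.
#' @param colorOrgans Organ region labels.
#' @param colorSD Within-group SD of each color channel.
#' @param missingRate Fraction of band calls set missing.
#' @param seed Integer seed fixing all randomness of the simulation.
#' @return A list of class \code{"PanelConfig"}.
#' @seealso \code{\link{simulatePanel}}
#' @export
panelConfig <- function(nGenotypes = 32L, K = 4L,
                        primers = defaultPrimerLayout(),
                        freqShape1 = 2, freqShape2 = 2,
                        delta = 0.6, shiftFraction = 0.5,
                        nQuantTraits = 19L, nQualTraits = 17L,
                        Delta = 3, noiseSD = 1,
                        qualLevels = 3L, qualBias = 0.7,
                        colorOrgans = c("slip", "eye", "sepal", "petiole",
                                        "dark.lamina", "silver.lamina"),
                        colorSD = 4,
                        missingRate = 0, seed = 1L) {
    cfg <- list(nGenotypes = as.integer(nGenotypes), K = as.integer(K),
                primers = primers, freqShape1 = freqShape1,
                freqShape2 = freqShape2, delta = delta,
                shiftFraction = shiftFraction,
                nQuantTraits = as.integer(nQuantTraits),
                nQualTraits = as.integer(nQualTraits),
                Delta = Delta, noiseSD = noiseSD,
                qualLevels = as.integer(qualLevels), qualBias = qualBias,
                colorOrgans = colorOrgans, colorSD = colorSD,
                missingRate = missingRate, seed = as.integer(seed))
    class(cfg) <- "PanelConfig"
    .checkConfig(cfg)
    cfg
}

.checkConfig <- function(cfg) {
    if (cfg$K < 1L) stop("K must be >= 1")
    if (cfg$nGenotypes < max(2L, cfg$K))
        stop("more groups than genotypes (or fewer than 2 genotypes)")
    if (cfg$delta < 0 || cfg$Delta < 0)
        stop("group shifts must be nonnegative")
    if (cfg$missingRate < 0 || cfg$missingRate >= 1)
        stop("missingRate must lie in [0, 1)")
    if (!all(c("name", "nBands") %in% names(cfg$primers)))
        stop("primers must have columns 'name' and 'nBands'")
    invisible(cfg)
}

#' @rdname panelConfig
#' @export
defaultPrimerLayout <- function() {
    data.frame(
        name = c(sprintf("srap%02d", 1:26), sprintf("scot%02d", 1:12)),
        nBands = c(rep(14L, 11), rep(13L, 15), rep(17L, 12)),
        assay = c(rep("SRAP", 26), rep("SCoT", 12)))
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(expr)
}

#' Simulate a band matrix with latent group structure
#'
#' The band-frequency model of \code{\link{simulatePanel}}, exposed for
#' unit testing: band calls are Bernoulli draws from group-specific
#' presence frequencies.
#'
#' @param groups Character or factor vector of group labels, one per
#'   genotype (names become genotype ids).
#' @param primers Data frame with columns \code{name}, \code{nBands}.
#' @param freqShape1,freqShape2,delta,shiftFraction,missingRate See
#'   \code{\link{panelConfig}}.
#' @param baseFreq Optional explicit baseline presence frequency (scalar
#'   or one per band), replacing the Beta draw. Used as given -- including
#'   degenerate 0 or 1 -- whereas Beta-drawn baselines are clamped to
#'   [0.02, 0.98]; group shifts on top of it are still clamped to [0, 1].
#' @param seed Integer seed.
#' @return A \linkS4class{BandMatrix}.
#' @export
simulateBandMatrix <- function(groups, primers,
                               freqShape1 = 2, freqShape2 = 2,
                               delta = 0.6, shiftFraction = 0.5,
                               missingRate = 0, baseFreq = NULL,
                               seed = 1L) {
    .withSeed(seed, {
        groups <- as.character(groups)
        n <- length(groups)
        ids <- names(groups)
        if (is.null(ids)) ids <- sprintf("g%02d", seq_len(n))
        glev <- unique(groups)
        K <- length(glev)
        nb <- sum(primers$nBands)
        bandNames <- unlist(mapply(function(nm, k)
            sprintf("%s.b%02d", nm, seq_len(k)),
            primers$name, primers$nBands, SIMPLIFY = FALSE))
        primer <- rep(primers$name, primers$nBands)

        if (is.null(baseFreq)) {
            p0 <- pmin(pmax(stats::rbeta(nb, freqShape1, freqShape2),
                            0.02), 0.98)
        } else {
            p0 <- rep_len(baseFreq, nb)
            if (any(p0 < 0 | p0 > 1)) stop("baseFreq must lie in [0, 1]")
        }
        shifted <- stats::runif(nb) < shiftFraction
        # group x band frequency table; signed shifts of delta/2 so that
        # two groups pulled apart differ by delta in frequency
        pf <- matrix(rep(p0, each = K), nrow = K)
        if (delta > 0 && K > 1L) {
            sgn <- matrix(sample(c(-1, 1), K * nb, replace = TRUE),
                          nrow = K)
            pf <- pf + (delta / 2) * sgn *
                matrix(rep(shifted, each = K), nrow = K)
        }
        pf <- if (is.null(baseFreq)) pmin(pmax(pf, 0.02), 0.98)
              else pmin(pmax(pf, 0), 1)

        gi <- match(groups, glev)
        calls <- matrix(0L, n, nb, dimnames = list(ids, bandNames))
        for (i in seq_len(n))
            calls[i, ] <- as.integer(stats::runif(nb) < pf[gi[i], ])
        if (missingRate > 0) {
            miss <- matrix(stats::runif(n * nb) < missingRate, n, nb)
            calls[miss] <- NA_integer_
        }
        BandMatrix(calls, primer = stats::setNames(primer, bandNames))
    })
}

#' Simulate a full germplasm panel with known group structure
#'
#' Draws a \linkS4class{GermplasmPanel} whose three layers (bands, traits,
#' colors) all carry the same latent K-group signal, so that trees built
#' from different layers of the same panel are genuinely coupled. Given
#' the same configuration (including its seed) the result is identical on
#' every run.
#'
#' @param config A \code{\link{panelConfig}} list.
#' @param seed Optional seed overriding \code{config$seed}.
#' @return A \linkS4class{GermplasmPanel}; \code{\link{trueGroups}}
#'   returns the latent labels.
#' @examples
#' p <- simulatePanel(panelConfig(nGenotypes = 12, K = 3, seed = 7))
#' table(trueGroups(p))
#' @export
simulatePanel <- function(config = panelConfig(), seed = NULL) {
    .checkConfig(config)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    .withSeed(config$seed, {
        n <- config$nGenotypes
        K <- config$K
        ids <- sprintf("g%02d", seq_len(n))
        groups <- stats::setNames(
            sprintf("G%d", sort(rep(seq_len(K), length.out = n))), ids)

        bandSeed <- sample.int(.Machine$integer.max %/% 2L, 3L)
        bm <- simulateBandMatrix(groups, config$primers,
                                 config$freqShape1, config$freqShape2,
                                 config$delta, config$shiftFraction,
                                 config$missingRate, seed = bandSeed[1L])

        tt <- .simulateTraits(groups, config, seed = bandSeed[2L])
        ct <- .simulateColors(groups, config, seed = bandSeed[3L])
        GermplasmPanel(bm, tt, ct, groups = groups,
                       config = unclass(config))
    })
}

.simulateTraits <- function(groups, cfg, seed) {
    .withSeed(seed, {
        n <- length(groups)
        gi <- match(groups, unique(groups))
        K <- length(unique(groups))
        d <- list()
        for (t in seq_len(cfg$nQuantTraits)) {
            mu <- cfg$Delta * cfg$noiseSD * stats::rnorm(K)
            d[[sprintf("qt%02d", t)]] <-
                mu[gi] + stats::rnorm(n, sd = cfg$noiseSD)
        }
        levs <- paste0("L", seq_len(cfg$qualLevels))
        for (t in seq_len(cfg$nQualTraits)) {
            fav <- sample.int(cfg$qualLevels, K, replace = TRUE)
            col <- character(n)
            for (i in seq_len(n)) {
                pr <- rep((1 - cfg$qualBias) / (cfg$qualLevels - 1),
                          cfg$qualLevels)
                pr[fav[gi[i]]] <- cfg$qualBias
                col[i] <- sample(levs, 1L, prob = pr)
            }
            d[[sprintf("ql%02d", t)]] <- factor(col, levels = levs)
        }
        df <- as.data.frame(d, row.names = names(groups))
        TraitTable(df)
    })
}

.simulateColors <- function(groups, cfg, seed) {
    .withSeed(seed, {
        gi <- match(groups, unique(groups))
        K <- length(unique(groups))
        rows <- list()
        for (org in cfg$colorOrgans) {
            muL <- stats::runif(K, 20, 85)
            muA <- stats::runif(K, -30, 40)
            muB <- stats::runif(K, -30, 40)
            L <- pmin(pmax(
                muL[gi] + stats::rnorm(length(gi), sd = cfg$colorSD), 0), 100)
            a <- muA[gi] + stats::rnorm(length(gi), sd = cfg$colorSD)
            b <- muB[gi] + stats::rnorm(length(gi), sd = cfg$colorSD)
            rows[[org]] <- data.frame(genotype = names(groups), organ = org,
                                      L = L, a = a, b = b)
        }
        ColorTable(do.call(rbind, rows))
    })
}
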