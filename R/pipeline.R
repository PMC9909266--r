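#' Combine several marker layers into one band matrix
#'
#' Column-concatenates band matrices scored on the same genotypes (e.g.
#' an SRAP-like and a SCoT-like assay) preserving primer annotations, for
#' a combined molecular analysis.
#'
#' @param ... Two or more \linkS4class{BandMatrix} objects.
#' @return A \linkS4class{BandMatrix} whose band count is the sum of the
#'   inputs'.
#' @export
combineMarkerLayers <- function(...) {
    layers <- list(...)
    if (length(layers) == 1L && is.list(layers[[1L]]) &&
        !is(layers[[1L]], "BandMatrix"))
        layers <- layers[[1L]]
    stopifnot(length(layers) >= 2L,
              all(vapply(layers, is, logical(1), "BandMatrix")))
    ids <- genotypeIds(layers[[1L]])
    for (l in layers[-1L]) {
        d1 <- setdiff(ids, genotypeIds(l))
        d2 <- setdiff(genotypeIds(l), ids)
        if (length(d1) || length(d2))
            stop(sprintf("genotype sets differ: missing [%s], extra [%s]",
                         paste(d1, collapse = ","),
                         paste(d2, collapse = ",")))
    }
    allBands <- unlist(lapply(layers, bandIds))
    if (anyDuplicated(allBands))
        stop(sprintf("duplicate band ids across layers: %s",
                     paste(unique(allBands[duplicated(allBands)]),
                           collapse = ", ")))
    calls <- do.call(cbind, lapply(layers, function(l)
        bandCalls(l)[ids, , drop = FALSE]))
    primer <- do.call(c, lapply(layers, primerOf))
    BandMatrix(calls, primer = primer)
}

#' Read a pipeline run configuration
#'
#' A YAML file with any of the keys understood by
#' \code{\link{runPipeline}}: either \code{synthetic} (arguments for
#' \code{\link{panelConfig}}) or input paths \code{bands}, \code{traits},
#' \code{colors}; plus options \code{markerMetric}, \code{traitMetric},
#' \code{k}, \code{L}, \code{tanglegrams}, \code{seed}.
#'
#' @param file Path to a YAML file.
#' @return The configuration list.
#' @export
readRunConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    .checkRunConfig(cfg)
    cfg
}

.checkRunConfig <- function(cfg) {
    if (is.null(cfg$synthetic) &&
        is.null(cfg$bands) && is.null(cfg$traits) && is.null(cfg$colors))
        stop("config error: no data layer (synthetic or input paths) present")
    for (f in c("bands", "traits", "colors")) {
        if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
            stop(sprintf("config error: file not found: %s", cfg[[f]]))
    }
    ok <- c("simple-matching", "jaccard", "euclidean", "pearson")
    if (!is.null(cfg$markerMetric) && !(cfg$markerMetric %in% ok))
        stop("config error: markerMetric must be one of ",
             paste(ok, collapse = ", "))
    if (!is.null(cfg$traitMetric) &&
        !(cfg$traitMetric %in% c("gower", "euclidean")))
        stop("config error: traitMetric must be gower or euclidean")
    invisible(cfg)
}

#' Run the full diversity-analysis pipeline
#'
#' Reproduces the canonical workflow shape on any panel: marker
#' informativeness statistics, diversity indices, distance matrices per
#' layer, UPGMA trees with cophenetic validation, tanglegram comparisons
#' between the layers, and PCA of the trait layer -- writing every
#' artifact under \code{outDir}. Identical configuration and seed give
#' byte-identical numeric outputs.
#'
#' @param config Configuration list (see \code{\link{readRunConfig}}) or
#'   a path to a YAML file. Layers not configured are simply skipped.
#' @param outDir Output directory, created if needed.
#' @param seed Integer seed (overrides \code{config$seed}) used for the
#'   synthetic panel and untangling restarts.
#' @return Invisibly, a list with the computed objects: panel layers,
#'   distances, trees, cophenetic correlations, tanglegram results and
#'   the paths written.
#' @export
runPipeline <- function(config = list(synthetic = list()),
                        outDir = tempfile("germdiv_run"), seed = NULL) {
    if (is.character(config)) config <- readRunConfig(config)
    .checkRunConfig(config)
    if (is.null(seed)) seed <- if (!is.null(config$seed)) config$seed else 1L
    seed <- as.integer(seed)
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(...) file.path(outDir, paste0(...))

    markerMetric <- if (!is.null(config$markerMetric))
        config$markerMetric else "simple-matching"
    traitMetric <- if (!is.null(config$traitMetric))
        config$traitMetric else "gower"
    k <- if (!is.null(config$k)) as.integer(config$k) else 4L
    L <- if (!is.null(config$L)) config$L else 1.5

    bands <- traits <- colors <- NULL
    groups <- character()
    if (!is.null(config$synthetic)) {
        pc <- do.call(panelConfig, c(config$synthetic, list(seed = seed)))
        panel <- simulatePanel(pc)
        bands <- panelBands(panel); traits <- panelTraits(panel)
        colors <- panelColors(panel); groups <- trueGroups(panel)
    } else {
        if (!is.null(config$bands)) bands <- readBandMatrix(config$bands)
        if (!is.null(config$traits)) traits <- readTraitTable(config$traits)
        if (!is.null(config$colors)) colors <- readColorTable(config$colors)
    }

    dists <- list(); trees <- list(); cophr <- list()
    addLayer <- function(name, d) {
        dists[[name]] <<- d
        t <- upgma(d)
        trees[[name]] <<- t
        cophr[[name]] <<- copheneticCorrelation(d, t)
        utils::write.csv(as.matrix(d), pth("distance_", name, ".csv"))
        writeNewick(t, pth("tree_", name, ".nwk"))
        utils::write.csv(
            data.frame(label = names(cutTree(t, min(k, nLeaves(t)))),
                       cluster = unname(cutTree(t, min(k, nLeaves(t))))),
            pth("clusters_", name, ".csv"), row.names = FALSE)
    }

    if (!is.null(bands)) {
        utils::write.csv(as.data.frame(bandStats(bands)),
                         pth("band_stats.csv"))
        utils::write.csv(primerStats(bands), pth("primer_stats.csv"),
                         row.names = FALSE)
        ps <- panelSummary(bands)
        jsonlite::write_json(
            list(totals = ps$totals, averages = as.list(ps$averages)),
            pth("panel_summary.json"), auto_unbox = TRUE, digits = NA)
        dv <- diversityTable(bands)
        utils::write.csv(dv$perGenotype, pth("diversity_markers.csv"),
                         row.names = FALSE)
        utils::write.csv(dv$summary, pth("diversity_markers_summary.csv"),
                         row.names = FALSE)
        d <- if (markerMetric == "pearson") pearsonDistance(bands)
             else binaryDistance(bands, markerMetric)
        addLayer("markers", d)
    }
    if (!is.null(traits)) {
        d <- if (traitMetric == "gower") gowerDistance(traits)
             else euclideanDistance(traits)
        addLayer("traits", d)
        dv <- diversityTable(traits)
        utils::write.csv(dv$perGenotype, pth("diversity_traits.csv"),
                         row.names = FALSE)
        pca <- pcaMorpho(traits)
        utils::write.csv(data.frame(eigenvalue = pca$eigenvalues,
                                    explained = pca$explained,
                                    cumulative = pca$cumulative),
                         pth("pca_eigenvalues.csv"), row.names = FALSE)
        utils::write.csv(pca$loadings, pth("pca_loadings.csv"))
        utils::write.csv(pca$scores, pth("pca_scores.csv"))
        utils::write.csv(pca$contributions, pth("pca_contributions.csv"))
    }
    if (!is.null(colors)) {
        cf <- colorFeatureMatrix(deriveColorFeatures(colors))
        utils::write.csv(cf, pth("color_features.csv"))
        # hue of achromatic points is undefined; drop all-NA columns
        keep <- colSums(is.na(cf)) == 0
        addLayer("colors",
                 euclideanDistance(cf[, keep, drop = FALSE]))
    }

    pairs <- if (!is.null(config$tanglegrams)) {
        lapply(config$tanglegrams, function(p) unlist(p))
    } else {
        nm <- names(trees)
        if (length(nm) >= 2L) utils::combn(nm, 2L, simplify = FALSE)
        else list()
    }
    tangles <- list()
    for (p in pairs) {
        key <- paste(p, collapse = "_vs_")
        res <- untangle(trees[[p[1L]]], trees[[p[2L]]],
                        method = "step2side", L = L,
                        k = min(k, nLeaves(trees[[p[1L]]])),
                        nStarts = 5L, seed = seed)
        tangles[[key]] <- res
        jsonlite::write_json(list(
            pair = p, entanglement = entanglementOf(res), L = res@L,
            k = res@k, order1 = leafOrder(res@tree1),
            order2 = leafOrder(res@tree2), matched = matchedSet(res)),
            pth("tanglegram_", key, ".json"), auto_unbox = TRUE,
            digits = NA)
    }

    jsonlite::write_json(list(
        package = "germdiv",
        version = as.character(utils::packageVersion("germdiv")),
        seed = seed, k = k, L = L,
        markerMetric = markerMetric, traitMetric = traitMetric,
        conventions = list(
            upgmaTieBreak = "lexicographically smallest representative pair",
            mergeHeight = "raw merge distance (hclust scale)",
            entanglement = "0 = perfectly aligned",
            zscore = "population SD (divisor N)"),
        cophenetic = cophr),
        pth("run_log.json"), auto_unbox = TRUE, digits = NA)

    invisible(list(bands = bands, traits = traits, colors = colors,
                   groups = groups, distances = dists, trees = trees,
                   cophenetic = cophr, tanglegrams = tangles,
                   outDir = outDir))
}
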