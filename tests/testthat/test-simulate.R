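test_that("simulation is deterministic given the seed", {
    cfg <- panelConfig(nGenotypes = 12, K = 3, seed = 99)
    p1 <- simulatePanel(cfg)
    p2 <- simulatePanel(cfg)
    expect_identical(bandCalls(panelBands(p1)), bandCalls(panelBands(p2)))
    expect_equal(as.data.frame(traitData(panelTraits(p1))),
                 as.data.frame(traitData(panelTraits(p2))))
    expect_equal(as.data.frame(colorData(panelColors(p1))),
                 as.data.frame(colorData(panelColors(p2))))
    expect_identical(trueGroups(p1), trueGroups(p2))
    # a different seed changes the draw
    p3 <- simulatePanel(cfg, seed = 100)
    expect_false(identical(bandCalls(panelBands(p1)),
                           bandCalls(panelBands(p3))))
    # the simulator does not disturb the caller's RNG stream
    set.seed(1); a <- runif(1)
    set.seed(1); invisible(simulatePanel(cfg)); b <- runif(1)
    expect_identical(a, b)
})

test_that("degenerate frequency settings produce the expected matrices", {
    groups <- stats::setNames(rep("G1", 6), paste0("g", 1:6))
    primers <- data.frame(name = "P1", nBands = 10)
    bm <- simulateBandMatrix(groups, primers, baseFreq = 1, delta = 0,
                             seed = 4)
    expect_true(all(bandCalls(bm) == 1L))
    expect_equal(panelSummary(bm)$totals$polymorphicBands, 0)

    bm0 <- simulateBandMatrix(groups, primers, baseFreq = 0, delta = 0,
                              seed = 4)
    expect_true(all(bandCalls(bm0) == 0L))
})

test_that("empirical band frequencies match the generating model", {
    groups <- stats::setNames(rep("G1", 400), sprintf("g%03d", 1:400))
    primers <- data.frame(name = "P1", nBands = 25)
    bm <- simulateBandMatrix(groups, primers, baseFreq = 0.5, delta = 0,
                             seed = 8)
    phat <- bandFrequency(bm)
    se <- sqrt(0.5 * 0.5 / 400)
    expect_true(all(abs(phat - 0.5) < 3 * se + 1e-12))

    bmm <- simulateBandMatrix(groups, primers, baseFreq = 0.5, delta = 0,
                              missingRate = 0.1, seed = 9)
    fmiss <- mean(is.na(bandCalls(bmm)))
    seM <- sqrt(0.1 * 0.9 / (400 * 25))
    expect_lt(abs(fmiss - 0.1), 3 * seM)
})

test_that("a null panel shows no within/between group contrast", {
    cfg <- panelConfig(nGenotypes = 24, K = 4, delta = 0, Delta = 0,
                       seed = 51)
    p <- simulatePanel(cfg)
    d <- as.matrix(binaryDistance(panelBands(p), "simple-matching"))
    g <- trueGroups(p)
    same <- outer(g, g, "==") & upper.tri(d)
    diff <- outer(g, g, "!=") & upper.tri(d)
    # difference of mean distances is within Monte-Carlo noise of zero
    delta <- mean(d[diff]) - mean(d[same])
    pooledSD <- stats::sd(d[upper.tri(d)])
    expect_lt(abs(delta), 3 * pooledSD / sqrt(sum(same)))
})

test_that("between-group separation grows with the marker shift", {
    meanBetween <- function(delta, seed) {
        groups <- stats::setNames(sort(rep(c("G1", "G2"), 12)),
                                  sprintf("g%02d", 1:24))
        bm <- simulateBandMatrix(groups,
                                 data.frame(name = "P1", nBands = 120),
                                 delta = delta, shiftFraction = 0.5,
                                 seed = seed)
        d <- as.matrix(binaryDistance(bm, "simple-matching"))
        g <- groups[rownames(d)]
        mean(d[outer(g, g, "!=") & upper.tri(d)])
    }
    res <- vapply(c(0, 0.3, 0.6), function(dl)
        mean(vapply(1:8, function(s) meanBetween(dl, s), numeric(1))),
        numeric(1))
    expect_true(all(diff(res) > 0))
})

test_that("infeasible configurations are rejected", {
    expect_error(panelConfig(nGenotypes = 3, K = 5), "more groups")
    expect_error(panelConfig(K = 0), "K must be")
    expect_error(panelConfig(missingRate = 1.2), "missingRate")
    expect_error(
        simulateBandMatrix(c(g1 = "G1", g2 = "G1"),
                           data.frame(name = "P1", nBands = 2),
                           baseFreq = 1.5, seed = 1),
        "baseFreq")
})

test_that("panel layers share genotype ids in identical order", {
    p <- simulatePanel(panelConfig(nGenotypes = 9, K = 3, seed = 2))
    ids <- genotypeIds(panelBands(p))
    expect_identical(rownames(traitData(panelTraits(p))), ids)
    expect_setequal(unique(colorData(panelColors(p))$genotype), ids)
    expect_identical(names(trueGroups(p)), ids)
    expect_identical(length(unique(trueGroups(p))), 3L)
})
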