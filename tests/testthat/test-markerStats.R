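test_that("band frequency excludes missing calls from the denominator", {
    expect_equal(bandFrequency(c(1, 1, 1, 1)), 1)
    expect_equal(bandFrequency(c(1, 0, NA, 0)), 1 / 3)
    expect_equal(bandFrequency(c(1, 0, 1, 0)), 0.5)
    expect_error(bandFrequency(c(NA, NA)), "no scored genotype")

    bm <- tinyBandMatrix(withMissing = TRUE)
    p <- bandFrequency(bm)
    expect_named(p, paste0("b", 1:4))
    expect_equal(unname(p["b3"]), 0.5)   # one of three calls missing
})

test_that("per-band statistics match their closed forms", {
    expect_equal(geneDiversity(0.5), 0.5)
    expect_equal(geneDiversity(0), 0)
    expect_equal(geneDiversity(0.2), 0.32)
    expect_equal(picDominant(0.5), 0.375)
    expect_equal(picDominant(1), 0)
    expect_equal(picDominant(0.2), 0.2688)
    expect_equal(bandInformativeness(0.5), 1)
    expect_equal(bandInformativeness(1), 0)
    expect_equal(bandInformativeness(0.75), 0.5)
})

test_that("band statistics obey ordering, bounds and symmetry", {
    p <- seq(0, 1, by = 0.01)
    H <- geneDiversity(p)
    PIC <- picDominant(p)
    Ib <- bandInformativeness(p)
    expect_true(all(PIC <= H + 1e-12))
    expect_true(all(H <= 0.5 + 1e-12))
    expect_true(all(PIC >= -1e-12))
    expect_true(all(Ib >= -1e-12 & Ib <= 1 + 1e-12))
    # equality PIC = H only at monomorphic bands
    eq <- abs(PIC - H) < 1e-12
    expect_identical(which(eq), which(p %in% c(0, 1)))
    # symmetry under p -> 1 - p
    expect_equal(H, rev(H))
    expect_equal(PIC, rev(PIC))
    expect_equal(Ib, rev(Ib))
})

test_that("discriminating power matches hand values and the pairwise oracle", {
    # all genotypes share one pattern -> 0
    expect_equal(discriminatingPower(matrix(1, 4, 2)), 0)
    # all patterns unique -> 1
    u <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    expect_equal(discriminatingPower(u), 1)
    # pattern counts {2,1,1} over 4 genotypes
    m <- rbind(c(1, 0), c(1, 0), c(0, 1), c(1, 1))
    expect_equal(discriminatingPower(m), 1 - 0.5 / 3)

    # random instances vs brute-force ordered-pair counting
    set.seed(11)
    for (i in 1:50) {
        n <- sample(3:6, 1)
        b <- sample(1:4, 1)
        m <- matrix(rbinom(n * b, 1, runif(1, 0.2, 0.8)), n, b)
        expect_equal(discriminatingPower(m), dpBrute(m), tolerance = 1e-12)
    }

    # genotypes with missing calls are excluded, N adjusted
    mm <- rbind(c(1, 0), c(1, NA), c(0, 1), c(1, 1))
    expect_equal(discriminatingPower(mm), dpBrute(mm))
    expect_error(discriminatingPower(rbind(c(1, NA), c(NA, 1), c(0, 1))),
                 "fewer than 2")
})

test_that("primer summaries aggregate the per-band formulas", {
    # 10 bands all at p = 0.5: PB=10, %P=100, E=10, MI=3.75, RP=10
    calls <- matrix(rep(c(1L, 0L), each = 1, times = 10), nrow = 2)
    dimnames(calls) <- list(c("g1", "g2"), paste0("b", 1:10))
    bm <- BandMatrix(calls, primer = "P1")
    ps <- primerStats(bm)
    expect_equal(ps$PB, 10)
    expect_equal(ps$pctP, 100)
    expect_equal(ps$E, 10)
    expect_equal(ps$MI, 3.75)
    expect_equal(ps$RP, 10)
    expect_equal(ps$DP, 1)   # the two genotypes differ on every band

    # all monomorphic: everything zero
    calls1 <- matrix(1L, 3, 4,
                     dimnames = list(paste0("g", 1:3), paste0("b", 1:4)))
    ps1 <- primerStats(BandMatrix(calls1, "P1"))
    expect_equal(ps1$PB, 0)
    expect_equal(ps1$pctP, 0)
    expect_equal(ps1$E, 0)
    expect_equal(ps1$MI, 0)
    expect_equal(ps1$RP, 0)

    # 16 bands, 9 polymorphic -> %P = 56.25
    calls2 <- rbind(g1 = c(rep(1L, 9), rep(1L, 7)),
                    g2 = c(rep(0L, 9), rep(1L, 7)))
    colnames(calls2) <- paste0("b", 1:16)
    expect_equal(primerStats(BandMatrix(calls2, "P1"))$pctP, 56.25)

    # the alternative formula switches
    psf <- primerStats(bm, emr = "fraction")
    expect_equal(psf$E, 1)          # PB / n
})

test_that("the 95% polymorphism criterion is available but off by default", {
    # 1 of 21 genotypes carries the band: p = 1/21 < 0.05
    calls <- matrix(0L, 21, 1,
                    dimnames = list(sprintf("g%02d", 1:21), "b1"))
    calls[1, 1] <- 1L
    bm <- BandMatrix(cbind(calls, b2 = rep(c(0L, 1L), length.out = 21)), "P1")
    expect_equal(primerStats(bm)$PB, 2)                     # strict
    expect_equal(primerStats(bm, criterion = 0.95)$PB, 1)   # 95% rule
})

test_that("panel summaries are permutation-invariant and internally consistent", {
    set.seed(5)
    calls <- matrix(rbinom(12 * 30, 1, 0.5), 12, 30,
                    dimnames = list(sprintf("g%02d", 1:12),
                                    sprintf("b%02d", 1:30)))
    bm <- BandMatrix(calls, primer = rep(c("P1", "P2", "P3"), each = 10))
    s <- panelSummary(bm)
    expect_equal(s$totals$bands, sum(s$perPrimer$n))
    expect_equal(s$totals$polymorphicBands, sum(s$perPrimer$PB))
    expect_equal(unname(s$averages["PB"]),
                 s$totals$polymorphicBands / s$totals$primers)

    gp <- sample(nrow(calls)); bp <- sample(ncol(calls))
    bm2 <- BandMatrix(calls[gp, bp],
                      primer = rep(c("P1", "P2", "P3"), each = 10)[bp])
    s2 <- panelSummary(bm2)
    expect_equal(s2$totals, s$totals)
    expect_equal(s2$averages, s$averages)

    # single-primer panel: averages equal that primer's values
    bm1 <- BandMatrix(calls[, 1:10], primer = "P1")
    s1 <- panelSummary(bm1)
    expect_equal(unname(s1$averages["RP"]), s1$perPrimer$RP)
    expect_equal(unname(s1$averages["DP"]), s1$perPrimer$DP)
})
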