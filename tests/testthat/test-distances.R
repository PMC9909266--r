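test_that("euclidean distance matches hand values and handles scaling", {
    m <- rbind(u = c(0, 0), v = c(3, 4))
    expect_equal(as.matrix(euclideanDistance(m, standardize = FALSE))["u", "v"], 5)
    expect_equal(as.matrix(euclideanDistance(rbind(a = 1:3, b = 1:3),
                                             standardize = FALSE))["a", "b"], 0)

    # constant feature dropped under standardization, distance from the rest
    m3 <- cbind(x = c(0, 1, 2), k = c(5, 5, 5))
    rownames(m3) <- c("a", "b", "c")
    expect_warning(d <- euclideanDistance(m3), "constant feature")
    sdx <- sqrt(mean((c(0, 1, 2) - 1)^2))
    expect_equal(as.matrix(d)["a", "c"], 2 / sdx)

    expect_error(euclideanDistance(rbind(c(1, NA), c(2, 3))), "missing")

    # invariance to affine rescaling of any feature under standardization
    set.seed(2)
    x <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("g", 1:8), NULL))
    y <- x
    y[, 3] <- 10 * y[, 3] - 7
    expect_equal(as.matrix(euclideanDistance(x)),
                 as.matrix(euclideanDistance(y)), tolerance = 1e-12)
})

test_that("gower distance averages per-feature dissimilarities", {
    # 4 qualitative features, 1 mismatch -> 0.25
    tq <- TraitTable(data.frame(
        f1 = c("a", "a"), f2 = c("b", "b"), f3 = c("c", "c"),
        f4 = c("d", "e"), row.names = c("g1", "g2")))
    expect_equal(as.matrix(gowerDistance(tq))["g1", "g2"], 0.25)

    # quantitative range 10 at values 2 and 7, plus matching qualitative
    tm <- TraitTable(data.frame(
        q = c(2, 7, 12), f = c("x", "x", "y"),
        row.names = c("g1", "g2", "g3")))
    expect_equal(as.matrix(gowerDistance(tm))["g1", "g2"], (0.5 + 0) / 2)

    # identical rows -> 0
    ti <- TraitTable(data.frame(q = c(1, 1), f = c("u", "u"),
                                row.names = c("g1", "g2")))
    expect_equal(as.matrix(gowerDistance(ti))["g1", "g2"], 0)

    # missing features drop out of numerator and denominator pairwise
    tn <- TraitTable(data.frame(
        q = c(0, 10, NA), f = c("x", "y", "x"),
        row.names = c("g1", "g2", "g3")))
    g <- as.matrix(gowerDistance(tn))
    expect_equal(g["g1", "g3"], 0)        # only f comparable, equal
    expect_equal(g["g2", "g3"], 1)        # only f comparable, different

    tb <- TraitTable(data.frame(q = c(1, NA), f = c(NA, "x"),
                                row.names = c("g1", "g2")))
    expect_error(gowerDistance(tb), "no comparable features")
})

test_that("gower agrees with an independent implementation on mixed data", {
    skip_if_not_installed("cluster")
    set.seed(17)
    d <- data.frame(
        q1 = rnorm(10), q2 = runif(10, 0, 100),
        f1 = sample(letters[1:3], 10, TRUE),
        f2 = sample(c("u", "v"), 10, TRUE),
        row.names = sprintf("g%02d", 1:10))
    ours <- as.matrix(gowerDistance(TraitTable(d)))
    ref <- as.matrix(cluster::daisy(
        data.frame(d[1:2], lapply(d[3:4], factor)), metric = "gower"))
    expect_equal(ours, ref[rownames(ours), colnames(ours)],
                 tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gower reduces to simple matching on all-binary qualitative data", {
    set.seed(23)
    m <- matrix(rbinom(48, 1, 0.5), 6, 8,
                dimnames = list(paste0("g", 1:6), paste0("b", 1:8)))
    tt <- TraitTable(as.data.frame(lapply(as.data.frame(m),
                                          function(c) factor(c, c(0, 1)))) |>
                     `rownames<-`(rownames(m)))
    expect_equal(as.matrix(gowerDistance(tt)),
                 as.matrix(binaryDistance(m, "simple-matching")),
                 tolerance = 1e-12)
})

test_that("binary distances count agreements as defined", {
    m <- rbind(g1 = c(1, 0, 1, 0), g2 = c(0, 1, 0, 1))
    expect_equal(as.matrix(binaryDistance(m, "simple-matching"))["g1", "g2"], 1)
    m2 <- rbind(g1 = c(1, 1, 0, 0), g2 = c(1, 0, 1, 0))
    expect_equal(as.matrix(binaryDistance(m2, "jaccard"))["g1", "g2"], 1 - 1 / 3)
    expect_equal(as.matrix(binaryDistance(m2, "euclidean"))["g1", "g2"],
                 sqrt(2))
    same <- rbind(g1 = c(1, 0, 1), g2 = c(1, 0, 1))
    for (meth in c("simple-matching", "jaccard", "euclidean"))
        expect_equal(as.matrix(binaryDistance(same, meth))["g1", "g2"], 0)

    # missing excluded pairwise; fully incomparable pair errors
    mn <- rbind(g1 = c(1, NA), g2 = c(NA, 1))
    expect_error(binaryDistance(mn), "no compared bands")
    mp <- rbind(g1 = c(1, NA, 0), g2 = c(1, 1, 1))
    expect_equal(as.matrix(binaryDistance(mp, "simple-matching"))["g1", "g2"],
                 0.5)
})

test_that("pearson profile similarity behaves like a correlation", {
    m <- rbind(u = c(1, 2, 3), v = c(2, 4, 6), w = c(3, 1, 2))
    r <- pearsonSimilarity(m)
    expect_equal(r["u", "u"], 1)
    expect_equal(r["u", "v"], 1)            # affine invariance
    neg <- rbind(a = c(1, 2, 3), b = c(3, 2, 1))
    expect_equal(pearsonSimilarity(neg)["a", "b"], -1)
    expect_equal(as.matrix(pearsonDistance(neg))["a", "b"], 2)
    expect_error(pearsonSimilarity(rbind(k = c(1, 1, 1), u = c(1, 2, 3))),
                 "constant profile.*k")
    expect_error(pearsonSimilarity(rbind(c(1, 2), c(2, 1))), "3 features")
})

test_that("all dissimilarities are symmetric, zero-diagonal and bounded", {
    p <- simulatePanel(panelConfig(nGenotypes = 10, K = 2, seed = 5))
    ds <- list(
        binaryDistance(panelBands(p), "simple-matching"),
        binaryDistance(panelBands(p), "jaccard"),
        gowerDistance(panelTraits(p)),
        suppressWarnings(euclideanDistance(ordinalCode(panelTraits(p)))),
        pearsonDistance(bandCalls(panelBands(p))))
    for (d in ds) {
        m <- as.matrix(d)
        expect_equal(m, t(m), tolerance = 1e-12)
        expect_equal(unname(diag(m)), rep(0, nrow(m)))
        expect_true(all(m >= -1e-12))
    }
    for (d in ds[c(1, 2, 3)])
        expect_true(all(as.matrix(d) <= 1 + 1e-12))
})
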