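test_that("upgma reproduces hand-computed merges and cophenetic values", {
    m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    t <- upgma(m)
    expect_equal(t@height, c(2, 8))
    cm <- as.matrix(copheneticMatrix(t))
    expect_equal(cm["A", "B"], 2)
    expect_equal(cm["A", "C"], 8)
    expect_equal(cm["B", "C"], 8)

    # two leaves: single merge at their distance
    m2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
    t2 <- upgma(m2)
    expect_equal(t2@height, 3)
    expect_equal(as.matrix(copheneticMatrix(t2))["A", "B"], 3)
})

test_that("upgma on an ultrametric input reproduces it exactly", {
    m <- ultra5()
    t <- upgma(m)
    expect_equal(as.matrix(copheneticMatrix(t))[rownames(m), colnames(m)],
                 m)
    expect_equal(copheneticCorrelation(m, t), 1)
})

test_that("upgma equals the brute-force re-averaging reference on random inputs", {
    set.seed(101)
    for (i in 1:60) {
        n <- sample(3:8, 1)
        m <- randomDist(n, integerValued = (i %% 3 == 0))  # ties likely
        t <- upgma(m)
        ref <- upgmaRef(m)
        expect_equal(t@merge, ref$merge)
        expect_equal(t@height, ref$height)
        # and, independently, heights never decrease
        expect_true(all(diff(t@height) >= -1e-12))
    }
})

test_that("upgma agrees with stats::hclust average linkage off ties", {
    set.seed(55)
    for (i in 1:20) {
        n <- sample(4:9, 1)
        m <- randomDist(n)          # continuous: ties a.s. absent
        t <- upgma(m)
        hc <- stats::hclust(stats::as.dist(m), method = "average")
        expect_equal(sort(t@height), sort(hc$height), tolerance = 1e-12)
        expect_equal(as.matrix(copheneticMatrix(t))[hc$labels, hc$labels],
                     as.matrix(stats::cophenetic(hc)), tolerance = 1e-12)
    }
})

test_that("cophenetic matrices are ultrametric", {
    set.seed(77)
    for (i in 1:20) {
        n <- sample(3:7, 1)
        cm <- as.matrix(copheneticMatrix(upgma(randomDist(n))))
        for (a in 1:(n - 2)) for (b in (a + 1):(n - 1)) for (cc in (b + 1):n) {
            tri <- sort(c(cm[a, b], cm[a, cc], cm[b, cc]), decreasing = TRUE)
            expect_equal(tri[1], tri[2], tolerance = 1e-12)
        }
    }
})

test_that("cophenetic correlation equals a direct Pearson computation", {
    set.seed(12)
    m <- randomDist(3)
    t <- upgma(m)
    cm <- as.matrix(copheneticMatrix(t))
    a <- m[lower.tri(m)]
    b <- cm[lower.tri(cm)]
    expect_equal(copheneticCorrelation(m, t), stats::cor(a, b),
                 tolerance = 1e-12)

    # invariant to label permutation of the distance matrix
    mm <- randomDist(6)
    tt <- upgma(mm)
    perm <- sample(rownames(mm))
    expect_equal(copheneticCorrelation(mm[perm, perm], tt),
                 copheneticCorrelation(mm, tt), tolerance = 1e-12)
})

test_that("tree cutting produces stable, permutation-invariant partitions", {
    m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
    t <- upgma(m)
    expect_equal(unname(cutTree(t, 1)), rep(1L, 3))
    expect_equal(sort(unname(cutTree(t, 3))), 1:3)
    c2 <- cutTree(t, 2)
    expect_equal(c2[["A"]], c2[["B"]])
    expect_false(c2[["A"]] == c2[["C"]])
    expect_error(cutTree(t, 0), "between 1")
    expect_error(cutTree(t, 4), "between 1")

    set.seed(40)
    mm <- randomDist(8)
    t1 <- upgma(mm)
    perm <- sample(rownames(mm))
    t2 <- upgma(mm[perm, perm])
    for (k in 2:5) {
        p1 <- cutTree(t1, k)
        p2 <- cutTree(t2, k)[names(p1)]
        # same partition up to relabeling
        expect_equal(outer(p1, p1, "=="), outer(p2, p2, "=="),
                     ignore_attr = TRUE)
    }
})

test_that("upgma rejects malformed matrices", {
    m <- randomDist(4)
    m[2, 3] <- NA; m[3, 2] <- NA
    expect_error(upgma(m), "NA")
    m2 <- randomDist(4)
    m2[1, 2] <- m2[1, 2] + 1
    expect_error(upgma(m2), "not symmetric")
})
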