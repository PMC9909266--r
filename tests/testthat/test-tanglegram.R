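test_that("entanglement matches its normalized-norm definition", {
    expect_equal(entanglement(c("A", "B", "C"), c("A", "B", "C")), 0)
    expect_equal(entanglement(c("A", "B", "C", "D"), c("D", "C", "B", "A")), 1)
    expect_equal(entanglement(c("A", "B", "C"), c("B", "A", "C")),
                 2 / (2 * 2^1.5))
    expect_equal(entanglement(c("A", "B", "C"), c("B", "A", "C"), L = 1),
                 2 / 4)
    expect_error(entanglement(c("A", "B"), c("A", "C")), "same label set")
})

test_that("entanglement is symmetric and relabeling-invariant", {
    set.seed(14)
    for (i in 1:20) {
        m <- sample(3:9, 1)
        o1 <- sample(LETTERS[1:m])
        o2 <- sample(LETTERS[1:m])
        expect_equal(entanglement(o1, o2), entanglement(o2, o1))
        # bijective relabeling
        map <- stats::setNames(letters[1:m], LETTERS[1:m])
        expect_equal(entanglement(unname(map[o1]), unname(map[o2])),
                     entanglement(o1, o2))
        # zero iff identical
        if (!identical(o1, o2)) expect_gt(entanglement(o1, o2), 0)
    }
})

test_that("untangle undoes a single internal-node rotation", {
    m <- matrix(c(0, 1, 4, 4,
                  1, 0, 4, 4,
                  4, 4, 0, 2,
                  4, 4, 2, 0), 4,
                dimnames = rep(list(LETTERS[1:4]), 2))
    t1 <- upgma(m)
    t2 <- germdiv:::.flipNode(t1, 1L)       # rotate the (A,B) node
    expect_gt(entanglement(t1, t2), 0)
    res <- untangle(t1, t2, method = "step1side")
    expect_equal(entanglementOf(res), 0)
    expect_identical(leafOrder(res@tree1), leafOrder(res@tree2))

    # identical trees: no-op at zero
    expect_equal(entanglementOf(untangle(t1, t1, method = "step1side")), 0)
})

test_that("untangle never increases entanglement and is idempotent", {
    set.seed(66)
    for (i in 1:10) {
        n <- sample(4:8, 1)
        t1 <- upgma(randomDist(n))
        t2 <- upgma(randomDist(n))
        e0 <- entanglement(t1, t2)
        res <- untangle(t1, t2, method = "step2side")
        expect_lte(entanglementOf(res), e0 + 1e-12)
        res2 <- untangle(res@tree1, res@tree2, method = "step2side")
        expect_equal(entanglementOf(res2), entanglementOf(res),
                     tolerance = 1e-12)
    }
})

test_that("restarted two-sided search reaches the exhaustive minimum on small trees", {
    set.seed(3)
    for (i in 1:6) {
        n <- sample(4:6, 1)
        t1 <- upgma(randomDist(n))
        t2 <- upgma(randomDist(n))
        best <- entanglementExhaustive(t1, t2)
        res <- untangle(t1, t2, method = "step2side", nStarts = 10,
                        seed = 100 + i)
        expect_equal(entanglementOf(res), best, tolerance = 1e-12)
    }
})

test_that("matched leaves reflect concordant cluster membership", {
    set.seed(8)
    m <- randomDist(6)
    t <- upgma(m)
    expect_setequal(matchedLeaves(t, t, 3), t@labels)   # identical trees
    expect_setequal(matchedLeaves(t, t, 1), t@labels)   # single cluster

    # two trees sharing 3 of 4 assignments: build from block matrices
    b1 <- matrix(8, 4, 4, dimnames = rep(list(LETTERS[1:4]), 2))
    diag(b1) <- 0
    b1["A", "B"] <- b1["B", "A"] <- 1    # {A,B} vs {C} vs {D} structure
    b2 <- b1
    b2["A", "B"] <- b2["B", "A"] <- 8
    b2["A", "C"] <- b2["C", "A"] <- 1    # D switches alliance away from C
    tA <- upgma(b1)
    tB <- upgma(b2)
    # partitions at k = 3: {A,B},{C},{D} vs {A,C},{B},{D}; the overlap-
    # maximizing assignment pairs {A,B}<->{B}, {C}<->{A,C}, {D}<->{D},
    # leaving only A discordant
    expect_setequal(matchedLeaves(tA, tB, 3), c("B", "C", "D"))
})

test_that("random search with a fixed seed is reproducible", {
    set.seed(1)
    t1 <- upgma(randomDist(7))
    t2 <- upgma(randomDist(7))
    r1 <- untangle(t1, t2, method = "random", nStarts = 20, seed = 5)
    r2 <- untangle(t1, t2, method = "random", nStarts = 20, seed = 5)
    expect_identical(leafOrder(r1@tree2), leafOrder(r2@tree2))
    expect_equal(entanglementOf(r1), entanglementOf(r2))
    expect_lte(entanglementOf(r1), entanglement(t1, t2) + 1e-12)
})
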