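# Independent reference implementations used as oracles. They deliberately
# avoid the package's code paths: cluster distances are recomputed from the
# raw pairwise matrix at every step instead of being updated incrementally.

# brute-force UPGMA: at each step recompute every cluster-pair average
# linkage as the mean over all leaf pairs, pick the minimum (ties broken by
# the lexicographically smallest pair of smallest member labels)
upgmaRef <- function(m) {
    labels <- rownames(m)
    n <- nrow(m)
    clusters <- lapply(seq_len(n), identity)   # leaf indices per cluster
    ids <- -seq_len(n)
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)
    for (step in seq_len(n - 1L)) {
        k <- length(clusters)
        best <- NULL
        for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
            dd <- mean(m[clusters[[i]], clusters[[j]]])
            repi <- min(labels[clusters[[i]]])
            repj <- min(labels[clusters[[j]]])
            key <- paste(min(repi, repj), max(repi, repj), sep = "\r")
            if (is.null(best) || dd < best$d - 1e-15 ||
                (abs(dd - best$d) <= 1e-15 && key < best$key))
                best <- list(i = i, j = j, d = dd, key = key,
                             repi = repi, repj = repj)
        }
        i <- best$i; j <- best$j
        if (best$repj < best$repi) { tmp <- i; i <- j; j <- tmp }
        merge[step, ] <- c(ids[i], ids[j])
        height[step] <- best$d
        clusters[[i]] <- c(clusters[[i]], clusters[[j]])
        ids[i] <- step
        clusters[[j]] <- NULL
        ids <- ids[-j]
    }
    list(merge = merge, height = height, labels = labels)
}

# random symmetric distance matrix with unique labels
randomDist <- function(n, integerValued = FALSE) {
    v <- if (integerValued) sample(1:20, n * (n - 1) / 2, replace = TRUE)
         else stats::runif(n * (n - 1) / 2, 0.1, 10)
    m <- matrix(0, n, n)
    m[lower.tri(m)] <- v
    m <- m + t(m)
    dimnames(m) <- list(sprintf("L%02d", seq_len(n)),
                        sprintf("L%02d", seq_len(n)))
    m
}

# discriminating power by brute force: one minus the fraction of ordered
# genotype pairs (drawn without replacement) sharing a banding pattern
dpBrute <- function(m) {
    m <- m[stats::complete.cases(m), , drop = FALSE]
    N <- nrow(m)
    pat <- apply(m, 1L, paste, collapse = "")
    same <- 0L
    for (i in seq_len(N)) for (j in seq_len(N)) {
        if (i != j && pat[i] == pat[j]) same <- same + 1L
    }
    1 - same / (N * (N - 1))
}

# exhaustive entanglement minimum over every rotation assignment of both
# trees (2^(n-1) each); feasible for <= 6 leaves
entanglementExhaustive <- function(t1, t2, L = 1.5) {
    flipsOf <- function(nn) {
        g <- expand.grid(rep(list(c(FALSE, TRUE)), nn))
        lapply(seq_len(nrow(g)), function(i) as.logical(g[i, ]))
    }
    f1 <- flipsOf(nrow(t1@merge))
    f2 <- flipsOf(nrow(t2@merge))
    best <- Inf
    for (a in f1) {
        o1 <- germdiv:::.orderFromMerge(t1@merge, a)
        ord1 <- t1@labels[o1]
        for (b in f2) {
            o2 <- germdiv:::.orderFromMerge(t2@merge, b)
            e <- entanglement(ord1, t2@labels[o2], L)
            if (e < best) best <- e
        }
    }
    best
}

# small ultrametric matrix built from a known 5-leaf tree:
# ((A,B)@1, (C,(D,E)@2)@3)@6
ultra5 <- function() {
    labs <- c("A", "B", "C", "D", "E")
    m <- matrix(6, 5, 5, dimnames = list(labs, labs))
    m["A", "B"] <- m["B", "A"] <- 1
    m["D", "E"] <- m["E", "D"] <- 2
    m["C", "D"] <- m["D", "C"] <- 3
    m["C", "E"] <- m["E", "C"] <- 3
    diag(m) <- 0
    m
}

# tiny valid band matrix for IO round trips
tinyBandMatrix <- function(withMissing = FALSE) {
    calls <- matrix(c(1L, 0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L, 1L, 0L),
                    nrow = 3,
                    dimnames = list(paste0("g", 1:3), paste0("b", 1:4)))
    if (withMissing) calls[2, 3] <- NA_integer_
    BandMatrix(calls, primer = c(b1 = "P1", b2 = "P1", b3 = "P2", b4 = "P2"))
}
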