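#' UPGMA hierarchical clustering
#'
#' Unweighted pair-group method with arithmetic mean: at each step the two
#' clusters with the smallest average-linkage distance are merged at a
#' height equal to that distance, and distances to the new cluster are the
#' size-weighted average of the two members' distances (so that the
#' cluster-to-cluster distance always equals the mean of all between-
#' cluster leaf pair distances). Heights are guaranteed nondecreasing.
#' Ties are broken deterministically by the lexicographically smallest
#' pair of cluster representatives (a cluster is represented by its
#' smallest leaf label), so results are reproducible across platforms.
#'
#' The merge height convention is the raw merge distance (as in
#' \code{\link[stats]{hclust}}), so cophenetic values live on the scale of
#' the input distances.
#'
#' @param d A \code{\link[stats]{dist}} or symmetric numeric matrix with
#'   unit labels.
#' @return A \linkS4class{Dendrogram}.
#' @examples
#' m <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' t <- upgma(m)
#' as.matrix(copheneticMatrix(t))
#' @seealso \code{\link{copheneticMatrix}},
#'   \code{\link{copheneticCorrelation}}, \code{\link{cutTree}}
#' @export
upgma <- function(d) {
    m <- as.matrix(d)
    if (anyNA(m)) stop("distance matrix contains NA")
    n <- nrow(m)
    if (n < 2L) stop("need at least 2 units")
    labels <- rownames(m)
    if (is.null(labels)) labels <- paste0("u", seq_len(n))
    if (max(abs(m - t(m))) > 1e-12) stop("distance matrix is not symmetric")

    size <- rep(1L, n)
    id <- -seq_len(n)              # hclust coding of active clusters
    rep_ <- labels                 # smallest member label per cluster
    active <- rep(TRUE, n)
    D <- m
    diag(D) <- Inf
    merge <- matrix(0L, n - 1L, 2L)
    height <- numeric(n - 1L)

    for (step in seq_len(n - 1L)) {
        idx <- which(active)
        sub <- D[idx, idx, drop = FALSE]
        h <- min(sub)
        cand <- which(sub == h, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        key <- vapply(seq_len(nrow(cand)), function(r) {
            a <- rep_[idx[cand[r, 1L]]]; b <- rep_[idx[cand[r, 2L]]]
            paste(min(a, b), max(a, b), sep = "\r")
        }, character(1))
        pick <- cand[order(key, method = "radix")[1L], ]
        i <- idx[pick[1L]]; j <- idx[pick[2L]]
        # left child = lexicographically smaller representative
        if (rep_[j] < rep_[i]) { tmp <- i; i <- j; j <- tmp }
        merge[step, ] <- c(id[i], id[j])
        height[step] <- h
        # size-weighted average update into slot i
        newd <- (size[i] * D[i, ] + size[j] * D[j, ]) / (size[i] + size[j])
        D[i, ] <- newd
        D[, i] <- newd
        D[i, i] <- Inf
        active[j] <- FALSE
        D[j, ] <- Inf; D[, j] <- Inf
        size[i] <- size[i] + size[j]
        id[i] <- step
        rep_[i] <- min(rep_[i], rep_[j])
    }
    Dendrogram(labels, merge, height)
}

# displayed leaf order implied by a merge matrix; flip[i] reverses the
# children of merge i
.orderFromMerge <- function(merge, flip) {
    expand <- function(node) {
        if (node < 0L) return(-node)
        ch <- merge[node, ]
        if (flip[node]) ch <- rev(ch)
        c(expand(ch[1L]), expand(ch[2L]))
    }
    as.integer(expand(nrow(merge)))
}

# leaves (indices) under each merge row
.leavesUnder <- function(merge) {
    out <- vector("list", nrow(merge))
    for (i in seq_len(nrow(merge))) {
        ch <- merge[i, ]
        out[[i]] <- c(if (ch[1L] < 0L) -ch[1L] else out[[ch[1L]]],
                      if (ch[2L] < 0L) -ch[2L] else out[[ch[2L]]])
    }
    out
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the height of the lowest merge that joins leaves i and
#' j. The result is always ultrametric: in every triangle the two largest
#' entries are equal.
#'
#' @param x A \linkS4class{Dendrogram}.
#' @return A \code{\link[stats]{dist}} over the leaf labels.
#' @export
copheneticMatrix <- function(x) {
    stopifnot(is(x, "Dendrogram"))
    n <- length(x@labels)
    under <- .leavesUnder(x@merge)
    m <- matrix(0, n, n, dimnames = list(x@labels, x@labels))
    for (i in seq_len(n - 1L)) {
        ch <- x@merge[i, ]
        left <- if (ch[1L] < 0L) -ch[1L] else under[[ch[1L]]]
        right <- if (ch[2L] < 0L) -ch[2L] else under[[ch[2L]]]
        m[left, right] <- x@height[i]
        m[right, left] <- x@height[i]
    }
    .asDist(m, "cophenetic")
}

#' Cophenetic correlation coefficient
#'
#' Pearson correlation between the n(n-1)/2 original pairwise distances
#' and the tree-implied (cophenetic) distances -- the standard measure of
#' how faithfully a dendrogram represents its input matrix. r = 1 exactly
#' when the input was already ultrametric.
#'
#' @param d The original \code{dist} (or symmetric matrix) the tree was
#'   built from.
#' @param x The \linkS4class{Dendrogram}.
#' @return A single correlation value.
#' @export
copheneticCorrelation <- function(d, x) {
    stopifnot(is(x, "Dendrogram"))
    dm <- as.matrix(d)
    if (!setequal(rownames(dm), x@labels))
        stop("distance matrix and tree label sets differ")
    dm <- dm[x@labels, x@labels]
    cm <- as.matrix(copheneticMatrix(x))
    a <- dm[lower.tri(dm)]
    b <- cm[lower.tri(cm)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("correlation undefined: constant distance vector")
    stats::cor(a, b)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the k - 1 highest merges and returns the resulting partition.
#' Clusters are numbered 1..k by the first appearance of any of their
#' leaves in the displayed leaf order, so the numbering is stable under
#' permutations of the input.
#'
#' @param x A \linkS4class{Dendrogram}.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector: leaf label -> cluster in 1..k.
#' @export
cutTree <- function(x, k) {
    stopifnot(is(x, "Dendrogram"))
    n <- length(x@labels)
    if (k < 1L || k > n) stop("k must lie between 1 and the number of leaves")
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    nKeep <- n - k        # merges retained after removing the k-1 highest
    under <- .leavesUnder(x@merge)
    if (nKeep >= 1L) for (i in seq_len(nKeep)) {
        lv <- under[[i]]
        r <- find(lv[1L])
        for (l in lv[-1L]) parent[find(l)] <- r
    }
    roots <- vapply(seq_len(n), find, integer(1))
    firstSeen <- unique(roots[x@order])
    cl <- match(roots, firstSeen)
    stats::setNames(cl, x@labels)
}
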