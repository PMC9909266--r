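#' Entanglement between two leaf orders
#'
#' The normalized L-norm of leaf-rank discrepancies between two displayed
#' leaf orders over the same label set: with \eqn{u_\ell, v_\ell} the
#' 1-based positions of leaf \eqn{\ell} in the two orders,
#' \deqn{\mathrm{ent} = \frac{\sum_\ell |u_\ell - v_\ell|^L}
#'                           {\sum_i |i - (m + 1 - i)|^L},}
#' the denominator being the worst case (one order fully reversed).
#' 0 means perfectly aligned, 1 maximally entangled. The default exponent
#' L = 1.5 is the conventional compromise between penalizing many small
#' and few large crossings.
#'
#' @param order1,order2 Character vectors: permutations of the same
#'   labels, or \linkS4class{Dendrogram}s (their displayed orders are
#'   used).
#' @param L Positive exponent of the norm.
#' @return Entanglement coefficient in [0, 1].
#' @examples
#' entanglement(c("A", "B", "C"), c("B", "A", "C"))  # 2 / (2 * 2^1.5)
#' @export
entanglement <- function(order1, order2, L = 1.5) {
    if (is(order1, "Dendrogram")) order1 <- leafOrder(order1)
    if (is(order2, "Dendrogram")) order2 <- leafOrder(order2)
    if (!setequal(order1, order2) ||
        length(order1) != length(order2) ||
        anyDuplicated(order1) || anyDuplicated(order2))
        stop("the two orders must be permutations of the same label set")
    m <- length(order1)
    if (m < 2L) stop("need at least 2 leaves")
    u <- seq_len(m)
    v <- match(order1, order2)
    worst <- sum(abs(u - (m + 1 - u))^L)
    sum(abs(u - v)^L) / worst
}

# Dendrogram with children of internal node `node` swapped: recover the
# current rotation state, toggle one node, recompute the displayed order
.flipNode <- function(x, node) {
    st <- .flipStateOf(x@merge, x@order)
    st[node] <- !st[node]
    methods::initialize(x, order = .orderFromMerge(x@merge, st))
}

# xor a flip assignment (logical per merge) onto the current rotation state
.applyFlips <- function(x, flip) {
    st <- xor(.flipStateOf(x@merge, x@order), flip)
    methods::initialize(x, order = .orderFromMerge(x@merge, st))
}

# recover, for each internal node, whether its children are displayed
# swapped relative to the merge matrix
.flipStateOf <- function(merge, ord) {
    posOf <- integer(length(ord))
    posOf[ord] <- seq_along(ord)
    flip <- logical(nrow(merge))
    under <- .leavesUnder(merge)
    for (i in seq_len(nrow(merge))) {
        ch <- merge[i, ]
        left <- if (ch[1L] < 0L) -ch[1L] else under[[ch[1L]]]
        right <- if (ch[2L] < 0L) -ch[2L] else under[[ch[2L]]]
        flip[i] <- min(posOf[left]) > min(posOf[right])
    }
    flip
}

#' Untangle two dendrograms by internal-node rotations
#'
#' Rotating an internal node of a dendrogram reverses the displayed order
#' of the leaves beneath it without changing the tree itself. Untangling
#' searches the rotation space for leaf orders that minimize
#' \code{\link{entanglement}}:
#' \describe{
#'   \item{step1side}{holds \code{t1}'s order fixed and sweeps
#'     \code{t2}'s internal nodes root to leaf, accepting a flip only if
#'     entanglement strictly decreases; sweeps repeat until one makes no
#'     change (guaranteeing termination).}
#'   \item{step2side}{alternates one-sided sweeps on \code{t2} and
#'     \code{t1} until neither improves. With \code{nStarts > 1} the
#'     search restarts from seeded random rotation states and the best
#'     result is kept.}
#'   \item{random}{draws \code{nStarts} seeded random rotation states for
#'     both trees and keeps the best (the initial state is always a
#'     candidate).}
#' }
#' The result never has higher entanglement than the input orders, and
#' re-untangling a converged result is a no-op.
#'
#' @param t1,t2 \linkS4class{Dendrogram}s over the same label set.
#' @param method Search strategy, see above.
#' @param L Entanglement exponent.
#' @param k Optional cut level: when given, the result records which
#'   leaves keep their k-cluster membership across trees
#'   (\code{\link{matchedLeaves}}).
#' @param nStarts Number of restarts for \code{step2side} / \code{random}.
#' @param seed Integer seed for the restart randomness (ignored by
#'   single-start step1side/step2side).
#' @return A \linkS4class{TanglegramResult}.
#' @examples
#' m <- matrix(c(0, 1, 4, 4, 1, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4,
#'             dimnames = rep(list(LETTERS[1:4]), 2))
#' t1 <- upgma(m)
#' res <- untangle(t1, t1, method = "step1side")
#' entanglementOf(res)  # 0
#' @export
untangle <- function(t1, t2, method = c("step2side", "step1side", "random"),
                     L = 1.5, k = NULL, nStarts = 1L, seed = NULL) {
    method <- match.arg(method)
    stopifnot(is(t1, "Dendrogram"), is(t2, "Dendrogram"))
    if (!setequal(t1@labels, t2@labels))
        stop("the two trees must share one label set")
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv()) else NULL
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
        set.seed(seed)
    }

    best1 <- t1; best2 <- t2
    bestE <- entanglement(t1, t2, L)

    consider <- function(a, b) {
        e <- entanglement(a, b, L)
        if (e < bestE) { best1 <<- a; best2 <<- b; bestE <<- e }
    }

    nn1 <- nrow(t1@merge); nn2 <- nrow(t2@merge)
    starts <- if (method == "step1side") 1L else max(1L, as.integer(nStarts))
    for (s in seq_len(starts)) {
        a <- t1; b <- t2
        if (s > 1L || method == "random") {
            a <- .applyFlips(a, stats::runif(nn1) < 0.5)
            b <- .applyFlips(b, stats::runif(nn2) < 0.5)
        }
        if (method == "random") {
            consider(a, b)
            next
        }
        repeat {
            b <- .greedySweep(a, b, L)
            if (method == "step1side") break
            a2 <- .greedySweep(b, a, L)
            improved <- entanglement(a2, b, L) < entanglement(a, b, L) - 1e-15
            a <- a2
            if (!improved) break
        }
        consider(a, b)
    }

    ranks <- S4Vectors::DataFrame(
        label = leafOrder(best1),
        pos1 = seq_along(best1@labels),
        pos2 = match(leafOrder(best1), leafOrder(best2)))
    matched <- character()
    kk <- NA_integer_
    if (!is.null(k)) {
        kk <- as.integer(k)
        matched <- matchedLeaves(best1, best2, kk)
    }
    new("TanglegramResult", tree1 = best1, tree2 = best2,
        entanglement = bestE, L = L, ranks = ranks, matched = matched,
        k = kk)
}

# one full root-to-leaf greedy sweep cycle on `mov` against fixed `fix`,
# repeated until a sweep makes no change
.greedySweep <- function(fix, mov, L) {
    e <- entanglement(fix, mov, L)
    repeat {
        changed <- FALSE
        for (node in rev(seq_len(nrow(mov@merge)))) {
            cand <- .flipNode(mov, node)
            ec <- entanglement(fix, cand, L)
            if (ec < e - 1e-15) {
                mov <- cand; e <- ec; changed <- TRUE
            }
        }
        if (!changed) break
    }
    mov
}

#' Leaves with concordant cluster membership between two trees
#'
#' Cuts both dendrograms into k clusters, matches the two partitions'
#' clusters by maximal overlap (exact assignment over cluster
#' permutations for k <= 7, greedy above), and returns the leaves whose
#' matched cluster agrees -- the "colored lines" of a tanglegram, the
#' genotypes that keep their position between classifications.
#'
#' @param t1,t2 \linkS4class{Dendrogram}s over the same label set.
#' @param k Cut level, valid for both trees.
#' @return Character vector of concordant leaf labels.
#' @export
matchedLeaves <- function(t1, t2, k) {
    stopifnot(is(t1, "Dendrogram"), is(t2, "Dendrogram"))
    if (!setequal(t1@labels, t2@labels))
        stop("the two trees must share one label set")
    c1 <- cutTree(t1, k)
    c2 <- cutTree(t2, k)[names(c1)]
    if (k == 1L) return(names(c1))
    ov <- table(factor(c1, levels = seq_len(k)),
                factor(c2, levels = seq_len(k)))
    perm <- if (k <= 7L) {
        perms <- .allPerms(k)
        scores <- vapply(perms, function(p)
            sum(ov[cbind(seq_len(k), p)]), numeric(1))
        perms[[which.max(scores)]]
    } else {
        # greedy: repeatedly take the largest remaining overlap
        p <- integer(k)
        o <- as.matrix(ov)
        for (step in seq_len(k)) {
            ij <- which(o == max(o), arr.ind = TRUE)[1L, ]
            p[ij[1L]] <- ij[2L]
            o[ij[1L], ] <- -1L
            o[, ij[2L]] <- -1L
        }
        p
    }
    names(c1)[perm[c1] == c2]
}

.allPerms <- function(k) {
    if (k == 1L) return(list(1L))
    sub <- .allPerms(k - 1L)
    out <- list()
    for (p in sub) for (pos in seq_len(k)) {
        out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
    out
}
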