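#' Partition fragments into retention-time windows
#'
#' Groups aligned ion fragments whose retention times fall within a small
#' tolerance of each other, by single-linkage chaining: after sorting by
#' `(rt_s, fragment_id)`, a new window starts wherever the gap between
#' consecutive retention times exceeds `halfWidth` seconds. Two fragments
#' therefore share a window if they are connected through a chain of
#' pairwise gaps `<= halfWidth`; the partition is disjoint, exhaustive and
#' independent of input row order.
#'
#' @param x a [FragmentExperiment-class], or a numeric vector of retention
#'   times named by fragment id.
#' @param halfWidth retention-time tolerance in seconds (default 3, i.e. a
#'   +/- 3 s window).
#' @return A list of character vectors of fragment ids, ordered by
#'   retention time.
#' @export
windowFragments <- function(x, halfWidth = 3) {
    if (halfWidth <= 0) stop("'halfWidth' must be positive")
    rt <- if (is(x, "FragmentExperiment")) retentionTimes(x) else x
    if (!length(rt)) return(list())
    ord <- order(rt, names(rt))
    rt <- rt[ord]
    newCluster <- c(TRUE, diff(rt) > halfWidth)
    unname(split(names(rt), cumsum(newCluster)))
}

## Varimax with multiple deterministic orthogonal starting rotations.
## The pairwise-rotation algorithm in stats::varimax stalls at a
## symmetric local optimum when started from the identity on the
## near-degenerate loading patterns typical of two similar co-eluting
## compounds; restarting from a handful of fixed rotations and keeping
## the best varimax objective is cheap and deterministic.
.varimaxBest <- function(L, nStarts = 8L) {
    k <- ncol(L)
    obj <- function(M) sum(apply(M^2, 2, stats::var))
    best <- L
    bestObj <- obj(L)
    for (s in seq_len(nStarts)) {
        H <- outer(seq_len(k), seq_len(k), function(i, j) sin(i * j + s))
        R0 <- qr.Q(qr(H + diag(k)))
        rot <- tryCatch(stats::varimax(L %*% R0, normalize = FALSE),
                        error = function(e) NULL)
        if (is.null(rot)) next
        M <- L %*% R0 %*% rot$rotmat
        if (obj(M) > bestObj) {
            bestObj <- obj(M)
            best <- M
        }
    }
    best
}

#' Split an RT window into co-elution groups by correlation structure
#'
#' Within one retention-time window, distinct co-eluting compounds are
#' separated using the correlation structure of the fragment profiles:
#' fragments are standardized across samples, principal components of the
#' fragment correlation matrix are computed, components with eigenvalue
#' greater than 1 are retained (at least one), the retained loadings are
#' varimax-rotated (two co-eluting compounds of similar size produce
#' near-degenerate eigenvalues whose raw eigenvectors mix both compounds;
#' the rotation restores one dominant component per compound), and each
#' fragment is assigned to the component on which it has the largest
#' absolute loading (`|e_jk| * sqrt(lambda_k)`, the fragment-component
#' correlation; ties break toward the lower-index component). Each
#' candidate group is then pruned for coherence: while any member's mean
#' Pearson correlation with the rest of its group is below `minCor` (the
#' "strongly correlated" requirement for summation), the least-correlated
#' member is split off as its own group. Constant-across-samples fragments
#' always form their own groups. With fewer than 3 samples the correlation
#' structure is undefined and every fragment becomes its own group, with a
#' warning.
#'
#' @param counts numeric matrix of raw ion counts, fragments x samples,
#'   with fragment ids as rownames.
#' @param minCor minimum mean within-group correlation (default 0.6) for a
#'   fragment to stay in its assigned group.
#' @return A list of character vectors of fragment ids.
#' @export
splitByCoelution <- function(counts, minCor = 0.6) {
    counts <- as.matrix(counts)
    ids <- rownames(counts)
    if (is.null(ids)) stop("'counts' must have fragment ids as rownames")
    m <- nrow(counts)
    if (m == 1L) return(list(ids))
    if (ncol(counts) < 3L) {
        warning("fewer than 3 samples: cannot assess co-elution, ",
                "every fragment kept separate")
        return(as.list(ids))
    }
    sds <- apply(counts, 1, stats::sd)
    constant <- sds == 0
    groups <- as.list(ids[constant])
    active <- which(!constant)
    if (length(active) == 1L)
        return(c(groups, list(ids[active])))
    if (length(active) == 0L)
        return(groups)

    C <- stats::cor(t(counts[active, , drop = FALSE]))
    eig <- eigen(C, symmetric = TRUE)
    keep <- which(eig$values > 1)
    if (!length(keep)) keep <- 1L
    lambda <- pmax(eig$values[keep], 0)
    loading <- eig$vectors[, keep, drop = FALSE] *
        rep(sqrt(lambda), each = length(active))
    ## near-degenerate eigenvalues mix the loading pattern of distinct
    ## co-eluting compounds; a varimax rotation of the retained loadings
    ## restores one dominant component per compound without changing the
    ## spanned space
    if (length(keep) > 1L)
        loading <- .varimaxBest(loading)
    absL <- abs(loading)
    assigned <- apply(absL, 1, which.max)        # ties -> lower index
    for (g in unname(split(seq_along(active), assigned))) {
        ## coherence pruning: members of one compound correlate strongly
        ## and positively; peel off the least-correlated fragment until
        ## the group is coherent
        while (length(g) >= 2) {
            meanr <- vapply(seq_along(g), function(j)
                mean(C[g[j], g[-j]]), numeric(1))
            if (min(meanr) >= minCor) break
            worst <- which.min(meanr)
            groups <- c(groups, list(ids[active[g[worst]]]))
            g <- g[-worst]
        }
        groups <- c(groups, list(ids[active[g]]))
    }
    groups
}

#' Aggregate ion fragments into per-VOC intensities
#'
#' Collapses an aligned fragment table into one intensity per compound per
#' sample: fragments are first partitioned into retention-time windows
#' ([windowFragments()]), each window is split into co-elution groups by
#' correlation structure ([splitByCoelution()]), and the ion counts of each
#' group's members are summed per sample. The retention-time centroid of a
#' VOC is the total-ion-count-weighted mean of its member fragments'
#' retention times. The grand total ion count is conserved exactly.
#'
#' @param x a [FragmentExperiment-class].
#' @param halfWidth retention-time window tolerance in seconds (default 3).
#' @param minCor co-elution correlation gate passed to
#'   [splitByCoelution()].
#' @return A [VOCExperiment-class] with VOCs ordered by retention-time
#'   centroid and ids `V0001, V0002, ...`.
#' @examples
#' sim <- simulateBreathDataset(breathSimConfig(nVocs = 8, nPerGroup = c(8, 3, 4, 5)))
#' aggregateFragments(sim$fragments)
#' @export
aggregateFragments <- function(x, halfWidth = 3, minCor = 0.6) {
    stopifnot(is(x, "FragmentExperiment"))
    counts <- assay(x, "counts")
    rt <- retentionTimes(x)
    windows <- windowFragments(x, halfWidth)
    groups <- list()
    for (w in windows)
        groups <- c(groups,
                    splitByCoelution(counts[w, , drop = FALSE], minCor))

    intensity <- t(vapply(groups, function(g)
        colSums(counts[g, , drop = FALSE]), numeric(ncol(counts))))
    centroid <- vapply(groups, function(g) {
        wgt <- rowSums(counts[g, , drop = FALSE])
        if (sum(wgt) == 0) mean(rt[g]) else sum(rt[g] * wgt) / sum(wgt)
    }, numeric(1))

    ord <- order(centroid)
    groups <- groups[ord]
    intensity <- intensity[ord, , drop = FALSE]
    centroid <- centroid[ord]
    rownames(intensity) <- sprintf("V%04d", seq_along(groups))
    VOCExperiment(intensity, centroid, groups, colData(x))
}
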