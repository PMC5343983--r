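suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(S4Vectors)
})

## Small, fast cohort used by most unit tests (full default sizes are
## exercised in the acceptance suite).
smallConfig <- function(seed = 1, ...) {
    args <- list(nPerGroup = c(10, 4, 5, 6), nVocs = 20, nInformative = 4,
                 nContaminants = 2, seed = seed)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(breathSimConfig, args)
}

## Brute-force AUROC: count case/control pairs directly.
bruteAUROC <- function(cases, controls) {
    wins <- ties <- 0
    for (a in cases) for (b in controls) {
        if (a > b) wins <- wins + 1
        else if (a == b) ties <- ties + 1
    }
    (wins + 0.5 * ties) / (length(cases) * length(controls))
}

## Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
## choose(n1 + n2, n1) assignments of the observed ranks to the first
## group (valid without ties): p = min(1, 2 * min(P(W <= w), P(W >= w))).
enumWilcoxP <- function(x, y) {
    n1 <- length(x); n2 <- length(y)
    r <- rank(c(x, y))
    w <- sum(r[seq_len(n1)])
    all_w <- apply(utils::combn(n1 + n2, n1), 2,
                   function(idx) sum(seq_len(n1 + n2)[idx]))
    lo <- mean(all_w <= w); hi <- mean(all_w >= w)
    min(1, 2 * min(lo, hi))
}

## Connected components of the |rt_i - rt_j| <= h adjacency graph,
## by breadth-first search -- the transitive-closure oracle for RT
## windowing.
bfsWindows <- function(rt, h) {
    n <- length(rt)
    adj <- abs(outer(rt, rt, "-")) <= h
    seen <- rep(FALSE, n)
    comps <- list()
    for (s in seq_len(n)) {
        if (seen[s]) next
        queue <- s; comp <- integer()
        while (length(queue)) {
            v <- queue[1]; queue <- queue[-1]
            if (seen[v]) next
            seen[v] <- TRUE
            comp <- c(comp, v)
            queue <- c(queue, which(adj[v, ] & !seen))
        }
        comps <- c(comps, list(sort(names(rt)[comp])))
    }
    comps
}

## Canonical string form of a partition (list of id vectors) so two
## partitions can be compared as sets of sets.
canonPartition <- function(groups)
    sort(unname(vapply(groups, function(g) paste(sort(g), collapse = ","),
                       "")))

truthPartition <- function(truth)
    canonPartition(split(names(truth$fragmentMap), truth$fragmentMap))

recoveredPartition <- function(voc)
    canonPartition(as.list(memberFragments(voc)))
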