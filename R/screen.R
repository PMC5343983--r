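#' Two-sided Wilcoxon rank-sum p-value
#'
#' Compares two groups of intensities with the Wilcoxon (Mann-Whitney)
#' rank-sum test. The exact null distribution is enumerated when both
#' groups have at most 8 observations and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction is
#' used. If every value in both groups is identical the groups are
#' indistinguishable and p = 1.
#'
#' @param xCases,xControls non-empty numeric vectors.
#' @return The two-sided p-value.
#' @examples
#' wilcoxonP(c(1, 2, 3), c(4, 5, 6))  # exact: 0.1
#' @export
wilcoxonP <- function(xCases, xControls) {
    if (!length(xCases) || !length(xControls))
        stop("both groups must be non-empty")
    all_ <- c(xCases, xControls)
    if (all(all_ == all_[1])) return(1)
    exact <- length(xCases) <= 8 && length(xControls) <= 8 &&
        !anyDuplicated(all_)
    suppressWarnings(
        stats::wilcox.test(xCases, xControls, exact = exact,
                           correct = TRUE)$p.value)
}

#' AUROC from the Mann-Whitney pair-counting identity
#'
#' The directed AUROC is the probability that a random case exceeds a
#' random control, counting ties as one half:
#' `(# pairs case > control + 0.5 * # ties) / (nCases * nControls)`.
#' Because discriminative breath compounds may be *decreased* in cases,
#' the direction-agnostic value `max(d, 1 - d)` is reported alongside.
#'
#' @param xCases,xControls non-empty numeric vectors.
#' @return Named numeric: `directed` and `auroc` (direction-agnostic).
#' @examples
#' aurocStat(c(1, 3), c(2, 4))  # directed 0.25, agnostic 0.75
#' @export
aurocStat <- function(xCases, xControls) {
    n1 <- length(xCases); n2 <- length(xControls)
    if (!n1 || !n2) stop("both groups must be non-empty")
    r <- rank(c(xCases, xControls))
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    d <- u / (n1 * n2)
    c(directed = d, auroc = max(d, 1 - d))
}

## Vectorised rank screen: p-values (normal approximation with tie and
## continuity correction) and directed AUROCs for every row of X at once,
## for one or many case-indicator columns. Used on the permutation path
## where millions of tests must be cheap; checked against wilcox.test.
## X: features x samples; caseInd: logical vector or 0/1 matrix
## (samples x permutations).
.rankScreen <- function(X, caseInd) {
    n <- ncol(X)
    ranks <- t(apply(X, 1, rank))
    ties <- apply(X, 1, function(v) {
        t_ <- table(v); sum(t_^3 - t_)
    })
    ind <- if (is.matrix(caseInd)) caseInd else matrix(as.numeric(caseInd))
    n1 <- colSums(ind)
    n2 <- n - n1
    R1 <- ranks %*% ind                         # features x permutations
    U <- sweep(R1, 2, n1 * (n1 + 1) / 2)
    muU <- outer(rep(1, nrow(X)), n1 * n2 / 2)
    sigma2 <- outer(ties, n1 * n2, function(tt, nn)
        nn / 12 * ((n + 1) - tt / (n * (n - 1))))
    sigma <- sqrt(sigma2)
    z <- (abs(U - muU) - 0.5) / sigma
    z[z < 0] <- 0
    p <- 2 * stats::pnorm(-z)
    p[p > 1] <- 1
    p[sigma == 0] <- 1
    d <- sweep(U, 2, n1 * n2, "/")
    d[sigma == 0] <- 0.5
    list(p = p, directed = d)
}

.comparisonCase <- function(sampleData, comparison) {
    comparison <- match.arg(comparison, c("pneumonia", "culture"))
    grp <- as.character(sampleData$group)
    if (comparison == "pneumonia") {
        use <- grp %in% c("control", "probable")
        isCase <- grp[use] == "probable"
    } else {
        use <- rep(TRUE, length(grp))
        isCase <- as.character(sampleData$culture) == "positive"
    }
    list(use = which(use), isCase = isCase, comparison = comparison)
}

#' Univariate VOC screening with the dual selection gate
#'
#' For every VOC, compares cases and controls of the requested clinical
#' contrast with a two-sided Wilcoxon rank-sum test, a pseudocount-protected
#' median fold change, and the Mann-Whitney AUROC. A VOC passes the
#' selection gate when `p < pMax` **and** its direction-agnostic AUROC
#' exceeds `aurocMin` (defaults 0.05 and 0.7). The `pneumonia` contrast
#' compares probable-pneumonia cases against controls only (intermediate
#' groups dropped); the `culture` contrast compares culture-positive
#' against culture-negative patients across all samples.
#'
#' @param x a [VOCExperiment-class].
#' @param comparison `"pneumonia"` or `"culture"`.
#' @param pMax,aurocMin the two gate thresholds.
#' @return A [S4Vectors::DataFrame] with one row per VOC: `p_value`,
#'   `fold_change`, `log2_fc`, `auroc_directed`, `auroc`, `neglog10_p`
#'   and `selected` (the volcano-plot data: x = `log2_fc`,
#'   y = `neglog10_p`, size = `auroc`). The comparison, thresholds and
#'   group sizes are stored in `metadata()`.
#' @export
screenVOCs <- function(x, comparison = c("pneumonia", "culture"),
                       pMax = 0.05, aurocMin = 0.7) {
    stopifnot(is(x, "VOCExperiment"))
    cmp <- .comparisonCase(colData(x), match.arg(comparison))
    X <- assay(x, "intensity")[, cmp$use, drop = FALSE]
    res <- .screenMatrix(X, cmp$isCase, pMax, aurocMin)
    metadata(res) <- list(comparison = cmp$comparison, pMax = pMax,
                          aurocMin = aurocMin, nCases = sum(cmp$isCase),
                          nControls = sum(!cmp$isCase))
    res
}

.screenMatrix <- function(X, isCase, pMax = 0.05, aurocMin = 0.7) {
    if (sum(isCase) < 2 || sum(!isCase) < 2)
        stop("each group needs at least 2 samples")
    p <- fc <- dir <- numeric(nrow(X))
    for (i in seq_len(nrow(X))) {
        xc <- X[i, isCase]; x0 <- X[i, !isCase]
        p[i] <- wilcoxonP(xc, x0)
        fc[i] <- (stats::median(xc) + 1) / (stats::median(x0) + 1)
        dir[i] <- aurocStat(xc, x0)[["directed"]]
    }
    auroc <- pmax(dir, 1 - dir)
    DataFrame(voc_id = rownames(X), p_value = p, fold_change = fc,
              log2_fc = log2(fc), auroc_directed = dir, auroc = auroc,
              neglog10_p = -log10(p),
              selected = p < pMax & auroc > aurocMin,
              row.names = rownames(X))
}

#' Label-permutation false-discovery assessment
#'
#' Estimates how often the observed screening performance would arise by
#' chance: the case/control labels of the chosen contrast are permuted
#' `nPerm` times (default 1000), the full screen is recomputed for each
#' permutation, and the family-level summary per permutation is compared
#' with the observed one. With `statistic = "best"` the summaries are the
#' minimum p-value and the maximum direction-agnostic AUROC over VOCs, and
#' the reported fractions are the proportion of permutations achieving a
#' similar or better value (p smaller-or-equal, AUROC greater-or-equal).
#' With `statistic = "count"` the summary is the number of VOCs passing
#' the dual gate.
#'
#' @param x a [VOCExperiment-class].
#' @param comparison `"pneumonia"` or `"culture"`.
#' @param nPerm number of label permutations (>= 1).
#' @param seed integer RNG seed.
#' @param statistic `"best"` or `"count"`.
#' @param pMax,aurocMin gate thresholds (used by `statistic = "count"`).
#' @return A [PermutationNull-class] object.
#' @export
permutationNull <- function(x, comparison = c("pneumonia", "culture"),
                            nPerm = 1000L, seed = 1L,
                            statistic = c("best", "count"),
                            pMax = 0.05, aurocMin = 0.7) {
    stopifnot(is(x, "VOCExperiment"))
    nPerm <- as.integer(nPerm)
    if (nPerm < 1L) stop("'nPerm' must be at least 1")
    statistic <- match.arg(statistic)
    cmp <- .comparisonCase(colData(x), match.arg(comparison))
    X <- assay(x, "intensity")[, cmp$use, drop = FALSE]
    isCase <- cmp$isCase
    n <- length(isCase)

    set.seed(as.integer(seed))
    ind <- vapply(seq_len(nPerm), function(i) as.numeric(sample(isCase)),
                  numeric(n))
    obs <- .rankScreen(X, isCase)
    perm <- .rankScreen(X, ind)
    eps <- 1e-12
    if (statistic == "best") {
        obsMinP <- min(obs$p)
        obsMaxA <- max(pmax(obs$directed, 1 - obs$directed))
        permMinP <- apply(perm$p, 2, min)
        permA <- pmax(perm$directed, 1 - perm$directed)
        permMaxA <- apply(permA, 2, max)
        observed <- c(min_p = obsMinP, max_auroc = obsMaxA)
        fractions <- c(min_p = mean(permMinP <= obsMinP + eps),
                       max_auroc = mean(permMaxA >= obsMaxA - eps))
    } else {
        gate <- function(p, d) sum(p < pMax & pmax(d, 1 - d) > aurocMin)
        obsCount <- gate(obs$p, obs$directed)
        permCount <- vapply(seq_len(nPerm), function(j)
            gate(perm$p[, j], perm$directed[, j]), numeric(1))
        observed <- c(n_selected = obsCount)
        fractions <- c(n_selected = mean(permCount >= obsCount))
    }
    new("PermutationNull", observed = observed, fractions = fractions,
        nPerm = nPerm, seed = as.integer(seed), statistic = statistic,
        comparison = cmp$comparison)
}
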