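#' Simulation settings for a synthetic breathomics cohort
#'
#' Bundles and validates the parameters of the synthetic exhaled-breath
#' GC-MS generator. Defaults emulate the cohort structure of a
#' single-centre ventilated-ICU breathomics study: 93 patients in four
#' clinical groups (47 controls, 13 colonized, 21 possible pneumonia, 12
#' probable pneumonia), 145 VOCs each fanned out into 1-6 co-eluting ion
#' fragments, log-normal intensities, and a planted subset of VOCs whose
#' concentration is *decreased* in cases, with the two intermediate groups
#' receiving a configurable fraction of the full effect.
#'
#' @param nPerGroup named or ordered integer vector of group sizes
#'   (control, colonized, possible, probable).
#' @param nVocs number of disease-related VOCs.
#' @param nInformative number of VOCs carrying the planted group effect
#'   (must not exceed `nVocs`).
#' @param effectLog2 log2 decrease of informative VOC intensity in the
#'   probable-pneumonia group (non-negative; 2 = fourfold lower).
#' @param intermediateFraction fraction in `[0, 1]` of the full effect
#'   applied to the colonized and possible-pneumonia groups.
#' @param fragmentsPerVoc integer pair `(min, max)`, both >= 1: each VOC's
#'   fragment count is drawn uniformly from this range.
#' @param rtJitter half-range (s) of the uniform retention-time jitter of a
#'   fragment around its VOC centroid; must keep all of a VOC's fragments
#'   inside one +/- 3 s window (i.e. `rtJitter <= 3`).
#' @param noiseSigmaLog SD of the per-sample biological variation of a
#'   VOC's log2 intensity.
#' @param fragmentNoiseSigma SD of the additional per-fragment measurement
#'   noise on the log2 scale (small, so fragments of one VOC stay strongly
#'   correlated).
#' @param nContaminants number of exogenous contaminant channels
#'   (disease-independent, high-variance, single-fragment).
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   bit-identically.
#' @return A validated list of class `breathSimConfig`.
#' @export
breathSimConfig <- function(nPerGroup = c(control = 47L, colonized = 13L,
                                          possible = 21L, probable = 12L),
                            nVocs = 145L, nInformative = 11L,
                            effectLog2 = 2, intermediateFraction = 0.5,
                            fragmentsPerVoc = c(1L, 6L), rtJitter = 1,
                            noiseSigmaLog = 0.5, fragmentNoiseSigma = 0.05,
                            nContaminants = 5L, seed = 1L) {
    nPerGroup <- as.integer(nPerGroup)
    if (length(nPerGroup) != 4L || any(nPerGroup < 0L))
        stop("'nPerGroup' must be 4 non-negative group sizes")
    if (sum(nPerGroup) == 0L)
        stop("'nPerGroup' must include at least one sample")
    if (nVocs < 1L) stop("'nVocs' must be positive")
    if (nInformative < 0L || nInformative > nVocs)
        stop("'nInformative' must lie in [0, nVocs]")
    if (effectLog2 < 0) stop("'effectLog2' must be non-negative")
    if (intermediateFraction < 0 || intermediateFraction > 1)
        stop("'intermediateFraction' must lie in [0, 1]")
    fragmentsPerVoc <- as.integer(fragmentsPerVoc)
    if (length(fragmentsPerVoc) != 2L || any(fragmentsPerVoc < 1L) ||
        fragmentsPerVoc[1] > fragmentsPerVoc[2])
        stop("'fragmentsPerVoc' must be a non-inverted integer pair >= 1")
    if (rtJitter < 0 || rtJitter > 3)
        stop("'rtJitter' must lie in [0, 3] so a VOC stays in one window")
    if (noiseSigmaLog <= 0) stop("'noiseSigmaLog' must be positive")
    if (nContaminants < 0L) stop("'nContaminants' must be non-negative")
    structure(list(nPerGroup = setNames(nPerGroup, .GROUPS),
                   nVocs = as.integer(nVocs),
                   nInformative = as.integer(nInformative),
                   effectLog2 = effectLog2,
                   intermediateFraction = intermediateFraction,
                   fragmentsPerVoc = fragmentsPerVoc,
                   rtJitter = rtJitter, noiseSigmaLog = noiseSigmaLog,
                   fragmentNoiseSigma = fragmentNoiseSigma,
                   nContaminants = as.integer(nContaminants),
                   seed = as.integer(seed)),
              class = "breathSimConfig")
}

## Positive-culture counts per group, scaled from the reference cohort
## margins (0/13/3/9 positives in groups of 47/13/21/12).
.culturePositives <- function(nPerGroup) {
    ref <- c(control = 0, colonized = 1, possible = 3 / 21, probable = 9 / 12)
    pos <- round(nPerGroup * ref)
    pos["colonized"] <- nPerGroup["colonized"]   # colonized => positive
    pos["control"] <- 0L
    as.integer(pos)
}

#' Simulate a synthetic exhaled-breath GC-MS dataset
#'
#' Generates an aligned ion-fragment count table with sample metadata and
#' the generating ground truth. Each VOC has a latent per-sample log2
#' abundance `mu_v + effect(group) + N(0, noiseSigmaLog)`; informative VOCs
#' are decreased by `effectLog2` in the probable group and by
#' `intermediateFraction * effectLog2` in the colonized and possible
#' groups. A fragment's count is the VOC abundance times a fixed
#' per-fragment response factor times small log-normal measurement noise,
#' rounded to a non-negative integer, so a VOC's fragments are strongly
#' correlated across samples. VOC retention-time centroids are spaced by
#' uniform 10-14 s gaps (disjoint +/- 3 s windows) and fragments jitter
#' uniformly within `+/- rtJitter` of the centroid. Contaminant channels
#' are single fragments with group-independent, high-variance intensities.
#'
#' The RNG stream under `config$seed` is consumed in a fixed documented
#' order: (1) fragments per VOC, (2) inter-VOC retention-time gaps, (3)
#' informative VOC ids, (4) baseline log2 means, (5) fragment response
#' factors, (6) fragment RT jitter, (7) culture-positive assignment, (8)
#' sample-level abundance noise, (9) fragment measurement noise, (10)
#' contaminant channels.
#'
#' @param config a [breathSimConfig()] object.
#' @return A list with elements `fragments` (a
#'   [FragmentExperiment-class] whose `colData` holds the sample metadata)
#'   and `truth` (list: `informative` VOC ids, `fragmentMap` named
#'   character fragment -> VOC, `groupMeans` VOC x group matrix of mean
#'   log2 abundance, `contaminants` channel ids).
#' @examples
#' sim <- simulateBreathDataset(breathSimConfig(nVocs = 10, nPerGroup = c(8, 3, 4, 5)))
#' sim$fragments
#' @export
simulateBreathDataset <- function(config = breathSimConfig()) {
    stopifnot(inherits(config, "breathSimConfig"))
    set.seed(config$seed)
    nV <- config$nVocs
    nG <- config$nPerGroup
    N  <- sum(nG)

    ## (1) fragment fan-out per VOC
    lo <- config$fragmentsPerVoc[1]; hi <- config$fragmentsPerVoc[2]
    nFrag <- if (lo == hi) rep(lo, nV) else
        sample(seq.int(lo, hi), nV, replace = TRUE)
    ## (2) centroids with gaps >= 10 s: disjoint +/- 3 s windows guaranteed
    centroid <- 60 + cumsum(runif(nV, 10, 14))
    ## (3) which VOCs carry the planted effect
    informative <- sort(sample.int(nV, config$nInformative))
    ## (4) baseline abundance, log2 ion counts
    mu <- runif(nV, 8, 16)
    ## (5) per-fragment response factors
    totFrag <- sum(nFrag)
    factorF <- runif(totFrag, 0.2, 1)
    ## (6) fragment RT jitter
    jitter <- runif(totFrag, -config$rtJitter, config$rtJitter)

    vocIds  <- sprintf("VOC%03d", seq_len(nV))
    fragVoc <- rep.int(seq_len(nV), nFrag)
    fragIdx <- sequence(nFrag)
    fragIds <- sprintf("%s_F%d", vocIds[fragVoc], fragIdx)

    group <- factor(rep(.GROUPS, nG), levels = .GROUPS)
    sampleIds <- sprintf("S%03d", seq_len(N))
    ## (7) positive cultures: all colonized plus a random subset of the
    ## possible/probable groups, margins scaled from the reference cohort
    nPos <- .culturePositives(nG)
    culture <- rep("negative", N)
    for (g in c("colonized", "possible", "probable")) {
        idx <- which(group == g)
        k <- nPos[match(g, .GROUPS)]
        if (k > 0)
            culture[idx[sample.int(length(idx), k)]] <- "positive"
    }
    meta <- DataFrame(group = group, culture = factor(culture, .CULTURE),
                      row.names = sampleIds)

    ## group effects on the log2 scale (decrease in cases)
    eff <- rbind(control = 0, colonized = -config$intermediateFraction,
                 possible = -config$intermediateFraction, probable = -1) *
        config$effectLog2
    effectMat <- matrix(0, nV, 4, dimnames = list(vocIds, .GROUPS))
    effectMat[informative, ] <- rep(eff[, 1], each = length(informative))
    groupMeans <- mu + effectMat

    ## (8) latent per-sample VOC abundance (log2)
    logAb <- groupMeans[, as.character(group), drop = FALSE] +
        matrix(rnorm(nV * N, 0, config$noiseSigmaLog), nV, N)
    ## (9) fragment counts = abundance x response factor x measurement noise
    logFrag <- logAb[fragVoc, , drop = FALSE] + log2(factorF) +
        matrix(rnorm(totFrag * N, 0, config$fragmentNoiseSigma), totFrag, N)
    counts <- round(2^logFrag)
    counts[counts < 0] <- 0

    rt <- centroid[fragVoc] + jitter
    fragmentMap <- setNames(vocIds[fragVoc], fragIds)

    ## (10) contaminant channels: exogenous, disease-independent
    nC <- config$nContaminants
    if (nC > 0) {
        contIds <- sprintf("CONT%02d", seq_len(nC))
        contRt <- centroid[nV] + cumsum(runif(nC, 10, 14))
        contMu <- runif(nC, 8, 16)
        contCounts <- round(2^(contMu +
            matrix(rnorm(nC * N, 0, 1.5), nC, N)))
        contCounts[contCounts < 0] <- 0
        contFrag <- sprintf("%s_F1", contIds)
        counts <- rbind(counts, contCounts)
        rt <- c(rt, contRt)
        fragIds <- c(fragIds, contFrag)
        fragmentMap <- c(fragmentMap, setNames(contIds, contFrag))
    } else contIds <- character()

    dimnames(counts) <- list(fragIds, sampleIds)
    fe <- FragmentExperiment(counts, rt, meta)
    list(fragments = fe,
         truth = list(informative = vocIds[informative],
                      fragmentMap = fragmentMap,
                      groupMeans = groupMeans,
                      contaminants = contIds))
}

#' Permute sample labels preserving group margins
#'
#' Reassigns the (group, culture) label pairs uniformly at random across
#' samples, preserving the multiset of labels exactly. Used to build
#' exchangeable null datasets for calibration checks.
#'
#' @param sampleData a `DataFrame`/`data.frame` of sample metadata, or a
#'   `SummarizedExperiment` whose `colData` holds it.
#' @param seed integer RNG seed.
#' @return An object of the same class as the input with labels permuted
#'   (for a `SummarizedExperiment`, the object with permuted `colData`).
#' @export
permuteSampleLabels <- function(sampleData, seed) {
    if (is(sampleData, "SummarizedExperiment")) {
        cd <- colData(sampleData)
        if (nrow(cd) == 0) stop("no samples to permute")
        set.seed(as.integer(seed))
        perm <- sample.int(nrow(cd))
        cd$group <- cd$group[perm]
        cd$culture <- cd$culture[perm]
        colData(sampleData) <- cd
        return(sampleData)
    }
    if (nrow(sampleData) == 0) stop("no samples to permute")
    set.seed(as.integer(seed))
    perm <- sample.int(nrow(sampleData))
    sampleData$group <- sampleData$group[perm]
    sampleData$culture <- sampleData$culture[perm]
    sampleData
}
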