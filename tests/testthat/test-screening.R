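test_that("wilcoxon p-values match full enumeration on the exact branch", {
    expect_equal(wilcoxonP(c(1, 2, 3), c(4, 5, 6)), 0.1)
    set.seed(10)
    for (rep in 1:15) {
        n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
        v <- sample(100, n1 + n2)  # distinct values: no ties
        x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
        expect_equal(wilcoxonP(x, y), enumWilcoxP(x, y), tolerance = 1e-12)
    }
})

test_that("wilcoxon p is symmetric in the groups and 1 for identical data", {
    set.seed(3)
    x <- rnorm(9); y <- rnorm(14)
    expect_equal(wilcoxonP(x, y), wilcoxonP(y, x))
    expect_identical(wilcoxonP(c(2, 2, 2), c(2, 2)), 1)
    expect_equal(wilcoxonP(c(1, 5, 9), c(1, 5, 9)), 1)
    expect_error(wilcoxonP(numeric(0), 1:3), "non-empty")
})

test_that("AUROC equals brute-force pair counting", {
    expect_equal(unname(aurocStat(c(1, 2), c(3, 4))),
                 c(0, 1))  # perfect separation, decreased in cases
    expect_equal(unname(aurocStat(c(1, 3), c(2, 4))), c(0.25, 0.75))
    expect_equal(aurocStat(5, 5)[["directed"]], 0.5)
    set.seed(21)
    for (rep in 1:30) {
        x <- sample(10, sample(2:9, 1), replace = TRUE)
        y <- sample(10, sample(2:9, 1), replace = TRUE)
        expect_equal(aurocStat(x, y)[["directed"]], bruteAUROC(x, y),
                     tolerance = 1e-12)
    }
})

test_that("AUROC from the rank identity equals trapezoidal ROC integration", {
    trapezoidAUC <- function(cases, controls) {
        thr <- sort(unique(c(cases, controls, Inf)), decreasing = TRUE)
        tpr <- vapply(thr, function(t) mean(cases >= t), numeric(1))
        fpr <- vapply(thr, function(t) mean(controls >= t), numeric(1))
        sum(diff(c(0, fpr)) * (utils::head(c(0, tpr), -1) +
                               utils::tail(c(0, tpr), -1)) / 2)
    }
    set.seed(5)
    for (rep in 1:100) {
        x <- round(rnorm(sample(3:10, 1)), 1)
        y <- round(rnorm(sample(3:10, 1)), 1)
        expect_equal(aurocStat(x, y)[["directed"]], trapezoidAUC(x, y),
                     tolerance = 1e-9)
    }
})

test_that("the vectorised rank screen reproduces wilcox.test and the pair-count AUROC", {
    set.seed(8)
    X <- matrix(rpois(30 * 25, 40), 30, 25)
    X[4, ] <- 7                      # constant feature
    X[9, ] <- sample(3, 25, TRUE)    # heavy ties
    isCase <- rep(c(TRUE, FALSE), c(10, 15))
    rs <- breathVOC:::.rankScreen(X, isCase)
    for (i in seq_len(nrow(X))) {
        ref <- if (all(X[i, ] == X[i, 1])) 1 else
            suppressWarnings(wilcox.test(X[i, isCase], X[i, !isCase],
                                         exact = FALSE,
                                         correct = TRUE)$p.value)
        expect_equal(rs$p[i, 1], ref, tolerance = 1e-12)
        expect_equal(rs$directed[i, 1],
                     bruteAUROC(X[i, isCase], X[i, !isCase]),
                     tolerance = 1e-12)
    }
})

test_that("screening applies the dual gate and reports volcano coordinates", {
    sim <- simulateBreathDataset(smallConfig(seed = 12, effectLog2 = 3,
                                             noiseSigmaLog = 0.4))
    voc <- aggregateFragments(sim$fragments)
    scr <- screenVOCs(voc, "pneumonia")
    expect_identical(metadata(scr)$nCases, 6L)      # probable only
    expect_identical(metadata(scr)$nControls, 10L)  # controls only
    expect_true(all(scr$auroc >= 0.5 & scr$auroc <= 1))
    expect_equal(scr$auroc, pmax(scr$auroc_directed, 1 - scr$auroc_directed))
    expect_identical(scr$selected, scr$p_value < 0.05 & scr$auroc > 0.7)
    expect_equal(scr$neglog10_p, -log10(scr$p_value))
    expect_equal(scr$log2_fc, log2(scr$fold_change))
    ## gate monotonicity: a lower AUROC threshold never drops a selection
    relaxed <- screenVOCs(voc, "pneumonia", aurocMin = 0.6)
    expect_true(all(relaxed$selected[scr$selected]))

    ## planted VOCs are recovered (strong effect, small noise)
    truthSets <- split(names(sim$truth$fragmentMap), sim$truth$fragmentMap)
    recKey <- vapply(memberFragments(voc), function(g)
        paste(sort(g), collapse = ","), "")
    infKey <- vapply(sim$truth$informative, function(v)
        paste(sort(truthSets[[v]]), collapse = ","), "")
    infRows <- match(infKey, recKey)
    expect_true(all(scr$selected[infRows]))
})

test_that("fold change is the pseudocount-protected ratio of group medians", {
    counts <- rbind(v1 = c(5, 5, 5, 10, 10, 10))
    colnames(counts) <- sprintf("s%d", 1:6)
    voc <- VOCExperiment(counts, 100, list("v1_f"),
                         data.frame(group = rep(c("probable", "control"),
                                                each = 3),
                                    culture = rep(c("positive", "negative"),
                                                  each = 3),
                                    row.names = colnames(counts)))
    scr <- screenVOCs(voc, "pneumonia")
    expect_equal(scr$fold_change, (5 + 1) / (10 + 1))
    expect_equal(scr$log2_fc, log2(6 / 11))
    ## a VOC constant in both groups is uninformative by construction
    counts2 <- rbind(v1 = rep(4, 6))
    colnames(counts2) <- colnames(counts)
    voc2 <- VOCExperiment(counts2, 100, list("v1_f"), colData(voc))
    scr2 <- screenVOCs(voc2, "pneumonia")
    expect_identical(scr2$p_value, 1)
    expect_identical(scr2$fold_change, 1)
    expect_identical(scr2$auroc, 0.5)
})

test_that("the permutation null is seed-deterministic and tie-saturated on constant data", {
    sim <- simulateBreathDataset(smallConfig(seed = 30))
    voc <- aggregateFragments(sim$fragments)
    a <- permutationNull(voc, "pneumonia", nPerm = 50, seed = 7)
    b <- permutationNull(voc, "pneumonia", nPerm = 50, seed = 7)
    expect_identical(a@fractions, b@fractions)
    expect_true(all(a@fractions >= 0 & a@fractions <= 1))

    ## permutation fractions are invariant to VOC row order
    set.seed(1)
    vocShuf <- voc[sample(nrow(voc)), ]
    c_ <- permutationNull(vocShuf, "pneumonia", nPerm = 50, seed = 7)
    expect_identical(c_@fractions, a@fractions)

    ## constant table: every permutation ties the observed statistics
    cn <- sprintf("s%d", 1:12)
    const <- VOCExperiment(
        matrix(5, 3, 12, dimnames = list(c("a", "b", "c"), cn)),
        c(100, 200, 300), list("a1", "b1", "c1"),
        data.frame(group = rep(c("probable", "control"), each = 6),
                   culture = rep(c("positive", "negative"), each = 6),
                   row.names = cn))
    p <- permutationNull(const, "pneumonia", nPerm = 25, seed = 1)
    expect_identical(unname(p@fractions), c(1, 1))

    expect_error(permutationNull(voc, "pneumonia", nPerm = 0, seed = 1),
                 "nPerm")
})

test_that("the gate-count permutation statistic is available as an option", {
    sim <- simulateBreathDataset(smallConfig(seed = 31, effectLog2 = 3))
    voc <- aggregateFragments(sim$fragments)
    p <- permutationNull(voc, "pneumonia", nPerm = 60, seed = 2,
                         statistic = "count")
    expect_named(p@observed, "n_selected")
    expect_gte(p@observed[["n_selected"]], 1)
    expect_lte(p@fractions[["n_selected"]], 0.2)  # planted signal beats null
})
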