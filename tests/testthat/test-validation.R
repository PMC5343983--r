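test_that("DeLong AUROC and CI match the pROC reference", {
    skip_if_not_installed("pROC")
    set.seed(17)
    for (rep in 1:10) {
        isCase <- sample(c(TRUE, FALSE), 40, replace = TRUE,
                         prob = c(0.3, 0.7))
        if (sum(isCase) < 2 || sum(!isCase) < 2) next
        score <- rnorm(40) + isCase
        ours <- aurocCI(score, isCase)
        ref <- pROC::roc(response = isCase, predictor = score,
                         direction = "<", quiet = TRUE)
        ci <- suppressWarnings(pROC::ci.auc(ref, method = "delong"))
        expect_equal(ours[["auroc"]], as.numeric(pROC::auc(ref)),
                     tolerance = 1e-9)
        expect_equal(ours[["lower"]], max(0, ci[1]), tolerance = 1e-9)
        expect_equal(ours[["upper"]], min(1, ci[3]), tolerance = 1e-9)
    }
})

test_that("AUROC CI clips at perfect separation and mirrors under label swap", {
    isCase <- rep(c(TRUE, FALSE), c(12, 47))
    score <- c(rnorm(12, 10), rnorm(47, 0))
    ci <- aurocCI(score, isCase)
    expect_equal(unname(ci), c(1, 1, 1))
    set.seed(30)
    score <- rnorm(59) + 0.8 * isCase
    a <- aurocCI(score, isCase)
    b <- aurocCI(score, !isCase)
    expect_equal(b[["auroc"]], 1 - a[["auroc"]], tolerance = 1e-12)
    expect_equal(b[["lower"]], 1 - a[["upper"]], tolerance = 1e-12)
    expect_equal(b[["upper"]], 1 - a[["lower"]], tolerance = 1e-12)
    expect_error(aurocCI(score, rep(TRUE, 59)), "both classes")
})

test_that("the CI narrows with sample size at fixed discrimination", {
    widthAt <- function(n, seed) {
        set.seed(seed)
        isCase <- rep(c(TRUE, FALSE), each = n / 2)
        score <- rnorm(n) + isCase
        ci <- aurocCI(score, isCase)
        ci[["upper"]] - ci[["lower"]]
    }
    w20 <- mean(vapply(1:20, function(s) widthAt(20, s), numeric(1)))
    w200 <- mean(vapply(1:20, function(s) widthAt(200, s + 500), numeric(1)))
    expect_lt(w200, w20)
})

test_that("confusion matrices conserve counts with true-class column margins", {
    p <- c(1, 1, 1)
    m <- confusionCounts(p, c(TRUE, TRUE, TRUE))
    expect_identical(m[1, 1], 3L)
    expect_identical(sum(m), 3L)
    set.seed(2)
    prob <- runif(40)
    isCase <- runif(40) < 0.3
    m <- confusionCounts(prob, isCase, threshold = 0.5)
    expect_identical(sum(m), 40L)
    expect_identical(as.integer(colSums(m)), c(sum(isCase), sum(!isCase)))
    expect_error(confusionCounts(c(-0.1, 0.5), c(TRUE, FALSE)), "0, 1")
})

test_that("LOOCV yields one held-out probability per sample without leakage", {
    sim <- simulateBreathDataset(smallConfig(seed = 21, effectLog2 = 2.5))
    voc <- aggregateFragments(sim$fragments)
    cv <- suppressMessages(loocvPLSDA(voc, "pneumonia"))
    nPneu <- sum(colData(voc)$group %in% c("control", "probable"))
    expect_length(cv@heldOutProb, nPneu)
    expect_true(all(cv@heldOutProb >= 0 & cv@heldOutProb <= 1))
    expect_identical(sum(cv@confusionLOOCV), nPneu)
    expect_identical(as.integer(colSums(cv@confusionLOOCV)),
                     c(sum(cv@labels), sum(!cv@labels)))
    ## per-fold selections depend only on that fold's training samples:
    ## recompute fold 1 by hand
    i <- 1L
    cmp <- breathVOC:::.comparisonCase(colData(voc), "pneumonia")
    X <- assay(voc, "intensity")[, cmp$use]
    scr <- breathVOC:::.screenMatrix(X[, -i], cmp$isCase[-i])
    expected <- scr$voc_id[scr$selected]
    if (!length(expected))
        expected <- scr$voc_id[order(scr$p_value)][1:5]
    expect_identical(cv@foldSelected[[i]], expected)

    ## flipping the held-out sample's own label leaves its prediction alone
    flipped <- voc
    cd <- colData(flipped)
    target <- colnames(X)[i]
    stopifnot(cd[target, "group"] == "control")
    cd[target, "group"] <- "probable"
    cd[target, "culture"] <- "positive"
    colData(flipped) <- cd
    cv2 <- suppressMessages(loocvPLSDA(flipped, "pneumonia"))
    expect_equal(cv2@heldOutProb[[target]], cv@heldOutProb[[target]],
                 tolerance = 1e-12)
})

test_that("the culture contrast uses every sample and pneumonia only the extremes", {
    sim <- simulateBreathDataset(smallConfig(seed = 22))
    voc <- aggregateFragments(sim$fragments)
    cvP <- suppressMessages(loocvPLSDA(voc, "pneumonia"))
    cvC <- suppressMessages(loocvPLSDA(voc, "culture"))
    expect_length(cvP@labels, 16L)  # 10 controls + 6 probable
    expect_length(cvC@labels, 25L)  # whole cohort
    expect_identical(sum(cvC@labels),
                     sum(colData(voc)$culture == "positive"))
})

test_that("extrapolated probabilities track the intermediate effect fraction", {
    med <- function(frac, seed) {
        sim <- simulateBreathDataset(
            smallConfig(seed = seed, effectLog2 = 3, noiseSigmaLog = 0.4,
                        intermediateFraction = frac))
        voc <- aggregateFragments(sim$fragments)
        fit <- fitBreathClassifier(voc, "pneumonia")
        ex <- extrapolateProbabilities(fit, voc)
        tapply(ex$probability, ex$group, median)
    }
    m0 <- med(0, 41)
    expect_lt(abs(m0[["colonized"]] - m0[["control"]]),
              abs(m0[["colonized"]] - m0[["probable"]]))
    expect_lt(abs(m0[["possible"]] - m0[["control"]]),
              abs(m0[["possible"]] - m0[["probable"]]))
    m1 <- med(1, 42)
    expect_lt(abs(m1[["colonized"]] - m1[["probable"]]),
              abs(m1[["colonized"]] - m1[["control"]]))
    expect_lt(abs(m1[["possible"]] - m1[["probable"]]),
              abs(m1[["possible"]] - m1[["control"]]))
    ## a fit trained with intermediates present is refused
    sim <- simulateBreathDataset(smallConfig(seed = 43))
    voc <- aggregateFragments(sim$fragments)
    fitC <- fitBreathClassifier(voc, "culture")
    expect_error(extrapolateProbabilities(fitC, voc), "case/control")
})
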