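#' AUROC with DeLong 95% confidence interval
#'
#' Computes the Mann-Whitney AUROC of a score for a binary outcome and its
#' DeLong (1988) variance estimate from the case and control placement
#' values; the 95% CI is the normal approximation clipped to `[0, 1]`.
#'
#' @param scores numeric vector of predicted probabilities or scores.
#' @param isCase logical vector, `TRUE` for cases; both classes must be
#'   present.
#' @return Named numeric: `auroc`, `lower`, `upper`.
#' @export
aurocCI <- function(scores, isCase) {
    isCase <- as.logical(isCase)
    if (!any(isCase) || !any(!isCase))
        stop("both classes must be present")
    x <- scores[isCase]; y <- scores[!isCase]
    m <- length(x); n <- length(y)
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    auc <- mean(psi)
    v10 <- rowMeans(psi)                        # placements of the cases
    v01 <- colMeans(psi)                        # placements of the controls
    s10 <- if (m > 1) stats::var(v10) else 0
    s01 <- if (n > 1) stats::var(v01) else 0
    se <- sqrt(s10 / m + s01 / n)
    z <- stats::qnorm(0.975)
    c(auroc = auc,
      lower = max(0, auc - z * se),
      upper = min(1, auc + z * se))
}

#' Threshold confusion matrix
#'
#' Cross-tabulates predicted against true class at a probability
#' threshold: a sample is called a case when its probability is `>=
#' threshold`. Rows are the predicted class, columns the true class, so
#' the column margins equal the true class counts.
#'
#' @param probabilities numeric in `[0, 1]`.
#' @param isCase logical vector of true labels.
#' @param threshold classification cutoff (default 0.5).
#' @param labels length-2 character: names for (case, control).
#' @return 2 x 2 integer matrix.
#' @export
confusionCounts <- function(probabilities, isCase, threshold = 0.5,
                            labels = c("case", "control")) {
    if (any(probabilities < 0 | probabilities > 1))
        stop("probabilities must lie in [0, 1]")
    predCase <- probabilities >= threshold
    m <- matrix(c(sum(predCase & isCase), sum(predCase & !isCase),
                  sum(!predCase & isCase), sum(!predCase & !isCase)),
                2, 2, byrow = TRUE,
                dimnames = list(predicted = labels, true = labels))
    storage.mode(m) <- "integer"
    m
}

#' Leave-one-out cross-validation with in-fold feature selection
#'
#' Estimates the out-of-sample accuracy of the PLS-DA classifier while
#' repeating the *entire* feature-selection step inside every fold, so no
#' information from the held-out sample leaks into VOC selection, scaling
#' or model fitting. For each sample of the chosen contrast: the sample is
#' removed; the dual-gate screen (`p < pMax` and AUROC > `aurocMin`) is
#' run on the remaining samples; the training intensities of the selected
#' VOCs are log-transformed and autoscaled; a PLS-DA model is fitted; and
#' the held-out sample's probability is predicted with the training
#' preprocessing. When a fold's gate selects no VOC, the `fallbackTopN`
#' VOCs with the smallest p-values are used instead (reported via a
#' message and the `nFallback` slot). The in-set (resubstitution)
#' probabilities come from a model trained and evaluated on all samples
#' with the full-data gate. AUROCs carry DeLong 95% CIs; confusion
#' matrices are built at `threshold`.
#'
#' @param x a [VOCExperiment-class].
#' @param comparison `"pneumonia"` (probable vs control, intermediates
#'   dropped) or `"culture"` (positive vs negative, all samples).
#' @param nComponents PLS components (default 2; capped by fold rank).
#' @param pMax,aurocMin dual-gate thresholds.
#' @param gate `"dual"` (p-value and AUROC) or `"p_only"`.
#' @param threshold classification cutoff for the confusion matrices.
#' @param fallbackTopN VOCs taken by smallest p when a fold selects none.
#' @return A [BreathCV-class].
#' @export
loocvPLSDA <- function(x, comparison = c("pneumonia", "culture"),
                       nComponents = 2L, pMax = 0.05, aurocMin = 0.7,
                       gate = c("dual", "p_only"), threshold = 0.5,
                       fallbackTopN = 5L) {
    stopifnot(is(x, "VOCExperiment"))
    gate <- match.arg(gate)
    cmp <- .comparisonCase(colData(x), match.arg(comparison))
    X <- assay(x, "intensity")[, cmp$use, drop = FALSE]
    isCase <- cmp$isCase
    n <- length(isCase)
    if (sum(isCase) < 2 || sum(!isCase) < 2)
        stop("each class needs at least 2 samples for LOOCV")

    pick <- function(scr) {
        sel <- if (gate == "dual") scr$selected else scr$p_value < pMax
        if (any(sel)) list(ids = scr$voc_id[sel], fallback = FALSE)
        else list(ids = scr$voc_id[order(scr$p_value)][
                      seq_len(min(fallbackTopN, nrow(scr)))],
                  fallback = TRUE)
    }

    heldOut <- numeric(n)
    foldSelected <- vector("list", n)
    nFallback <- 0L
    for (i in seq_len(n)) {
        trainX <- X[, -i, drop = FALSE]
        trainY <- isCase[-i]
        if (!any(trainY) || all(trainY))
            stop("a fold left a single-class training set; ",
                 "comparison not cross-validatable")
        scr <- .screenMatrix(trainX, trainY, pMax, aurocMin)
        sl <- pick(scr)
        if (sl$fallback) nFallback <- nFallback + 1L
        foldSelected[[i]] <- sl$ids
        prep <- preprocessIntensities(trainX, sl$ids)
        fit <- plsdaFit(prep$x, trainY, nComponents, params = prep$params)
        heldOut[i] <- plsdaPredict(fit, X[, i, drop = FALSE])
    }
    names(heldOut) <- colnames(X)
    if (nFallback > 0)
        message(nFallback, " fold(s) selected no VOC at the gate; ",
                "fell back to the top ", fallbackTopN, " by p-value")

    scrAll <- .screenMatrix(X, isCase, pMax, aurocMin)
    slAll <- pick(scrAll)
    prepAll <- preprocessIntensities(X, slAll$ids)
    fitAll <- plsdaFit(prepAll$x, isCase, nComponents,
                       params = prepAll$params)
    inSet <- plsdaPredict(fitAll, X)

    labNames <- if (cmp$comparison == "pneumonia")
        c("probable pneumonia", "control")
    else c("positive culture", "negative culture")
    new("BreathCV", comparison = cmp$comparison,
        labels = setNames(isCase, colnames(X)),
        heldOutProb = heldOut, inSetProb = inSet,
        loocvAUC = aurocCI(heldOut, isCase),
        inSetAUC = aurocCI(inSet, isCase),
        confusionLOOCV = confusionCounts(heldOut, isCase, threshold,
                                         labNames),
        confusionInSet = confusionCounts(inSet, isCase, threshold,
                                         labNames),
        foldSelected = foldSelected, nFallback = nFallback,
        threshold = threshold)
}

#' Fit the case/control PLS-DA model on the full dataset
#'
#' Convenience wrapper: screens the requested contrast with the dual
#' gate, preprocesses the selected VOCs and fits the PLS-DA classifier on
#' all of the contrast's samples. This is the model whose probabilities
#' are extrapolated to the intermediate clinical groups.
#'
#' @inheritParams loocvPLSDA
#' @return A [PLSDAFit-class].
#' @export
fitBreathClassifier <- function(x, comparison = c("pneumonia", "culture"),
                                nComponents = 2L, pMax = 0.05,
                                aurocMin = 0.7, fallbackTopN = 5L) {
    stopifnot(is(x, "VOCExperiment"))
    cmp <- .comparisonCase(colData(x), match.arg(comparison))
    X <- assay(x, "intensity")[, cmp$use, drop = FALSE]
    scr <- .screenMatrix(X, cmp$isCase, pMax, aurocMin)
    ids <- if (any(scr$selected)) scr$voc_id[scr$selected]
           else scr$voc_id[order(scr$p_value)][
               seq_len(min(fallbackTopN, nrow(scr)))]
    prep <- preprocessIntensities(X, ids)
    plsdaFit(prep$x, cmp$isCase, nComponents, params = prep$params)
}

#' Extrapolate predicted probabilities to the intermediate groups
#'
#' Applies a case/control-trained PLS-DA model, with its frozen
#' preprocessing, to every sample of the cohort and returns the predicted
#' pneumonia probability grouped by clinical class, ordered control ->
#' colonized -> possible -> probable for display. The two intermediate
#' groups were never seen during training; their probabilities show where
#' the model places patients between the two extremes of the disease
#' spectrum.
#'
#' @param fit a [PLSDAFit-class] trained on case/control samples.
#' @param x the full-cohort [VOCExperiment-class].
#' @return A [S4Vectors::DataFrame] with `sample_id`, `group` (ordered
#'   factor) and `probability`, sorted by group.
#' @export
extrapolateProbabilities <- function(fit, x) {
    stopifnot(is(fit, "PLSDAFit"), is(x, "VOCExperiment"))
    grp <- sampleGroups(x)
    trainGrp <- grp[names(grp) %in% fit@trainingIds]
    if (any(as.character(trainGrp) %in% c("colonized", "possible")))
        stop("'fit' must be trained on case/control samples only")
    prob <- plsdaPredict(fit, x)
    out <- DataFrame(sample_id = colnames(x),
                     group = factor(as.character(grp), levels = .GROUPS,
                                    ordered = TRUE),
                     probability = unname(prob))
    out[order(out$group), ]
}
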