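#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames rowData colData colData<-
#' @importFrom IRanges CharacterList
NULL

## Clinical group and culture vocabularies used throughout.
.GROUPS  <- c("control", "colonized", "possible", "probable")
.CULTURE <- c("negative", "positive")

.checkSampleData <- function(cd) {
    msgs <- character()
    if (!all(c("group", "culture") %in% colnames(cd)))
        return("colData must contain 'group' and 'culture' columns")
    grp <- as.character(cd$group)
    cul <- as.character(cd$culture)
    bad <- setdiff(unique(grp), .GROUPS)
    if (length(bad))
        msgs <- c(msgs, paste0("unknown group label(s): ",
                               paste(bad, collapse = ", ")))
    bad <- setdiff(unique(cul), .CULTURE)
    if (length(bad))
        msgs <- c(msgs, paste0("unknown culture label(s): ",
                               paste(bad, collapse = ", ")))
    if (!length(msgs)) {
        if (any(grp == "control" & cul != "negative"))
            msgs <- c(msgs, "controls must have negative cultures")
        if (any(grp == "colonized" & cul != "positive"))
            msgs <- c(msgs, "colonized patients must have positive cultures")
    }
    msgs
}

#' Container for an aligned ion-fragment peak table
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding the output of
#' upstream peak detection and retention-time alignment: one row per ion
#' fragment with its retention time (`rowData(x)$rt_s`, seconds), one column
#' per breath sample, and a single `counts` assay of non-negative ion counts.
#' Sample metadata (clinical `group` and `culture` status) lives in
#' `colData`.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @export
setClass("FragmentExperiment", contains = "SummarizedExperiment")

setValidity("FragmentExperiment", function(object) {
    msgs <- character()
    if (!"counts" %in% assayNames(object))
        return("assay 'counts' is required")
    cnt <- assay(object, "counts")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msgs <- c(msgs, "fragment ids (rownames) must be present and unique")
    if (!"rt_s" %in% colnames(rowData(object))) {
        msgs <- c(msgs, "rowData must contain 'rt_s'")
    } else {
        rt <- rowData(object)$rt_s
        if (!is.numeric(rt) || any(!is.finite(rt)))
            msgs <- c(msgs, "'rt_s' must be finite numeric")
    }
    if (any(!is.finite(cnt)) || any(cnt < 0))
        msgs <- c(msgs, "counts must be finite and non-negative")
    if (ncol(object) > 0)
        msgs <- c(msgs, .checkSampleData(colData(object)))
    if (length(msgs)) msgs else TRUE
})

#' Construct a FragmentExperiment
#'
#' @param counts numeric matrix, fragments x samples, non-negative; rownames
#'   are fragment ids, colnames sample ids.
#' @param rt numeric vector of retention times in seconds, one per fragment.
#' @param sampleData a `data.frame`/`DataFrame` with columns `group`
#'   (control/colonized/possible/probable) and `culture`
#'   (negative/positive), one row per sample.
#' @return A [FragmentExperiment-class] object.
#' @examples
#' fe <- FragmentExperiment(
#'     counts = matrix(1:6, 2, 3, dimnames = list(c("f1", "f2"), paste0("s", 1:3))),
#'     rt = c(100, 101),
#'     sampleData = data.frame(group = c("control", "control", "probable"),
#'                             culture = c("negative", "negative", "positive")))
#' retentionTimes(fe)
#' @export
FragmentExperiment <- function(counts, rt, sampleData) {
    counts <- as.matrix(counts)
    se <- SummarizedExperiment(
        assays  = list(counts = counts),
        rowData = DataFrame(rt_s = as.numeric(rt)),
        colData = DataFrame(sampleData, row.names = colnames(counts)))
    new("FragmentExperiment", se)
}

#' Container for an aggregated VOC intensity table
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding per-compound
#' intensities after fragment aggregation: one row per volatile organic
#' compound (VOC) with its retention-time centroid
#' (`rowData(x)$rt_centroid_s`) and the ids of its member ion fragments
#' (`rowData(x)$member_fragments`, a `CharacterList`), one column per
#' sample, and a single `intensity` assay (the per-sample sum of member
#' fragment counts).
#'
#' @export
setClass("VOCExperiment", contains = "SummarizedExperiment")

setValidity("VOCExperiment", function(object) {
    msgs <- character()
    if (!"intensity" %in% assayNames(object))
        return("assay 'intensity' is required")
    x <- assay(object, "intensity")
    if (any(!is.finite(x)) || any(x < 0))
        msgs <- c(msgs, "intensities must be finite and non-negative")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msgs <- c(msgs, "VOC ids (rownames) must be present and unique")
    rd <- rowData(object)
    if (!all(c("rt_centroid_s", "member_fragments") %in% colnames(rd)))
        msgs <- c(msgs, "rowData needs 'rt_centroid_s' and 'member_fragments'")
    else {
        members <- unlist(rd$member_fragments)
        if (anyDuplicated(members))
            msgs <- c(msgs, "a fragment may belong to only one VOC")
    }
    if (ncol(object) > 0)
        msgs <- c(msgs, .checkSampleData(colData(object)))
    if (length(msgs)) msgs else TRUE
})

#' Construct a VOCExperiment
#'
#' @param intensity numeric matrix, VOCs x samples.
#' @param rtCentroid numeric vector of per-VOC retention-time centroids (s).
#' @param members a list (or `CharacterList`) of member fragment ids per VOC.
#' @param sampleData sample metadata as for [FragmentExperiment()].
#' @return A [VOCExperiment-class] object.
#' @export
VOCExperiment <- function(intensity, rtCentroid, members, sampleData) {
    intensity <- as.matrix(intensity)
    se <- SummarizedExperiment(
        assays  = list(intensity = intensity),
        rowData = DataFrame(rt_centroid_s = as.numeric(rtCentroid),
                            member_fragments = CharacterList(members)),
        colData = DataFrame(sampleData, row.names = colnames(intensity)))
    new("VOCExperiment", se)
}

#' Fitted PLS-DA classifier
#'
#' Latent-variable (NIPALS PLS1) discriminant fit of a binary class code on
#' log-scaled, autoscaled VOC intensities, with the preprocessing
#' parameters frozen at training time so held-out samples are standardized
#' with training means and SDs.
#'
#' @slot vocIds VOC identifiers defining the feature space, in order.
#' @slot weights,loadings p x A X-weight and X-loading matrices.
#' @slot yLoadings length-A y-loading vector.
#' @slot coefficients regression coefficient per VOC (on the standardized
#'   scale), assembled as W (P'W)^-1 q.
#' @slot yMean training class prevalence (mean of the 0/1 code).
#' @slot center,scale per-VOC mean and SD of log2(x + 1) in the training set.
#' @slot trainingScores n x A latent score matrix of the training samples.
#' @slot trainingIds training sample ids.
#' @export
setClass("PLSDAFit", representation(
    vocIds = "character", weights = "matrix", loadings = "matrix",
    yLoadings = "numeric", coefficients = "numeric", yMean = "numeric",
    center = "numeric", scale = "numeric", trainingScores = "matrix",
    trainingIds = "character"))

#' Label-permutation false-discovery assessment
#'
#' Holds the observed family-level screening summary (minimum p-value and
#' maximum direction-agnostic AUROC over VOCs, or the count of VOCs passing
#' the dual gate) together with the fraction of label permutations that
#' achieved a similar or better value.
#'
#' @slot observed named numeric of observed summary statistics.
#' @slot fractions named numeric of permutation fractions in `[0, 1]`.
#' @slot nPerm number of permutations.
#' @slot seed RNG seed used for the permutations.
#' @slot statistic `"best"` (min p / max AUROC) or `"count"` (gate count).
#' @slot comparison comparison label.
#' @export
setClass("PermutationNull", representation(
    observed = "numeric", fractions = "numeric", nPerm = "integer",
    seed = "integer", statistic = "character", comparison = "character"))

setValidity("PermutationNull", function(object) {
    if (any(object@fractions < 0 | object@fractions > 1))
        "permutation fractions must lie in [0, 1]" else TRUE
})

#' Leave-one-out cross-validation result
#'
#' Per-sample held-out predicted probabilities from leave-one-out
#' cross-validation with in-fold feature selection, the matching in-set
#' (resubstitution) probabilities, AUROCs with DeLong 95% confidence
#' intervals, and threshold confusion matrices.
#'
#' @slot comparison comparison label.
#' @slot labels logical per sample, `TRUE` for cases.
#' @slot heldOutProb,inSetProb named numeric probabilities in `[0, 1]`.
#' @slot loocvAUC,inSetAUC length-3 numerics: AUROC, CI lower, CI upper.
#' @slot confusionLOOCV,confusionInSet 2 x 2 integer matrices, rows
#'   predicted class, columns true class.
#' @slot foldSelected list of per-fold selected VOC id vectors.
#' @slot nFallback number of folds where the gate selected nothing and the
#'   top-p fallback was used.
#' @slot threshold classification threshold used for the confusion matrices.
#' @export
setClass("BreathCV", representation(
    comparison = "character", labels = "logical",
    heldOutProb = "numeric", inSetProb = "numeric",
    loocvAUC = "numeric", inSetAUC = "numeric",
    confusionLOOCV = "matrix", confusionInSet = "matrix",
    foldSelected = "list", nFallback = "integer", threshold = "numeric"))

setValidity("BreathCV", function(object) {
    msgs <- character()
    if (length(object@heldOutProb) != length(object@labels))
        msgs <- c(msgs, "one held-out probability per sample is required")
    if (sum(object@confusionLOOCV) != length(object@labels))
        msgs <- c(msgs, "confusion-matrix cells must sum to the sample count")
    if (length(msgs)) msgs else TRUE
})
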