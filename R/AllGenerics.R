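#' Accessors for breathVOC containers
#'
#' `retentionTimes()` returns per-fragment retention times (seconds);
#' `rtCentroids()` the per-VOC retention-time centroids;
#' `memberFragments()` the `CharacterList` of fragment ids per VOC;
#' `sampleGroups()` and `cultureStatus()` the clinical group and culture
#' factors stored in `colData`.
#'
#' @param x a [FragmentExperiment-class] or [VOCExperiment-class].
#' @return A vector (or `CharacterList`) parallel to the rows or columns
#'   of `x`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("retentionTimes", function(x) standardGeneric("retentionTimes"))

#' @rdname accessors
#' @export
setGeneric("rtCentroids", function(x) standardGeneric("rtCentroids"))

#' @rdname accessors
#' @export
setGeneric("memberFragments", function(x) standardGeneric("memberFragments"))

#' @rdname accessors
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname accessors
#' @export
setGeneric("cultureStatus", function(x) standardGeneric("cultureStatus"))

#' @rdname accessors
setMethod("retentionTimes", "FragmentExperiment",
          function(x) setNames(rowData(x)$rt_s, rownames(x)))

#' @rdname accessors
setMethod("rtCentroids", "VOCExperiment",
          function(x) setNames(rowData(x)$rt_centroid_s, rownames(x)))

#' @rdname accessors
setMethod("memberFragments", "VOCExperiment",
          function(x) setNames(rowData(x)$member_fragments, rownames(x)))

.sampleGroups <- function(x)
    setNames(factor(as.character(colData(x)$group), levels = .GROUPS),
             colnames(x))
.cultureStatus <- function(x)
    setNames(factor(as.character(colData(x)$culture), levels = .CULTURE),
             colnames(x))

#' @rdname accessors
setMethod("sampleGroups", "SummarizedExperiment", .sampleGroups)

#' @rdname accessors
setMethod("cultureStatus", "SummarizedExperiment", .cultureStatus)

setMethod("show", "FragmentExperiment", function(object) {
    cat(sprintf("FragmentExperiment: %d ion fragments x %d samples\n",
                nrow(object), ncol(object)))
    if (nrow(object))
        cat(sprintf("  retention times: %.1f-%.1f s\n",
                    min(rowData(object)$rt_s), max(rowData(object)$rt_s)))
    if (ncol(object))
        cat("  groups:", paste(sprintf("%s=%d", levels(sampleGroups(object)),
                                       table(sampleGroups(object))),
                               collapse = " "), "\n")
})

setMethod("show", "VOCExperiment", function(object) {
    cat(sprintf("VOCExperiment: %d VOCs x %d samples\n",
                nrow(object), ncol(object)))
    if (nrow(object))
        cat(sprintf("  fragments per VOC: %d-%d (total %d)\n",
                    min(lengths(memberFragments(object))),
                    max(lengths(memberFragments(object))),
                    sum(lengths(memberFragments(object)))))
})

setMethod("show", "PLSDAFit", function(object) {
    cat(sprintf("PLSDAFit: %d components on %d VOCs, %d training samples\n",
                ncol(object@weights), length(object@vocIds),
                length(object@trainingIds)))
    cat(sprintf("  training prevalence: %.3f\n", object@yMean))
})

setMethod("show", "PermutationNull", function(object) {
    cat(sprintf("PermutationNull (%s, %d permutations, statistic = %s)\n",
                object@comparison, object@nPerm, object@statistic))
    for (nm in names(object@observed))
        cat(sprintf("  observed %s = %.4g; fraction similar-or-better = %.4f\n",
                    nm, object@observed[[nm]], object@fractions[[nm]]))
})

setMethod("show", "BreathCV", function(object) {
    cat(sprintf("BreathCV (%s): %d samples (%d cases / %d controls)\n",
                object@comparison, length(object@labels),
                sum(object@labels), sum(!object@labels)))
    cat(sprintf("  in-set AUROC %.2f (95%% CI %.2f-%.2f)\n",
                object@inSetAUC[1], object@inSetAUC[2], object@inSetAUC[3]))
    cat(sprintf("  LOOCV  AUROC %.2f (95%% CI %.2f-%.2f)\n",
                object@loocvAUC[1], object@loocvAUC[2], object@loocvAUC[3]))
    cat("In-set confusion (rows predicted, cols true):\n")
    print(object@confusionInSet)
    cat("Leave-one-out confusion:\n")
    print(object@confusionLOOCV)
})
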