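#' Rounded percentage, half-up convention
#'
#' `100 * count / total` rounded half-up at the requested number of
#' decimals (so 35.862 at one decimal prints 35.9, and 12.90 at zero
#' decimals prints 13) — the convention used when reporting cohort
#' proportions.
#'
#' @param count integer in `[0, total]`.
#' @param total positive integer.
#' @param decimals number of decimal places (default 0).
#' @return The rounded percentage as a number.
#' @examples
#' percentOf(11, 145, 1)  # 7.6
#' @export
percentOf <- function(count, total, decimals = 0L) {
    if (total <= 0) stop("'total' must be positive")
    if (count < 0 || count > total)
        stop("'count' must lie in [0, total]")
    p <- 100 * count / total
    f <- 10^decimals
    floor(p * f + 0.5) / f
}

#' Collate a machine- and human-readable study report
#'
#' Assembles the cohort composition (counts and integer percentages per
#' clinical group and culture status), the screening summaries per
#' contrast, the permutation fractions and the cross-validation results
#' into one structure, and verifies that every confusion-matrix column
#' margin equals the corresponding cohort count. A mismatch is surfaced in
#' `$checks` (and is an error under `strict = TRUE`), never silently
#' corrected.
#'
#' @param metadata sample metadata (`DataFrame` with `group`, `culture`).
#' @param screening optional named list of `DataFrame`s from
#'   [screenVOCs()] (names = comparison labels).
#' @param permutation optional named list of [PermutationNull-class]
#'   objects.
#' @param cv optional named list of [BreathCV-class] objects.
#' @param strict error on a failed consistency check instead of flagging.
#' @return A list of class `breathReport` with elements `cohort`,
#'   `screening`, `permutation`, `cv` and `checks`.
#' @export
buildStudyReport <- function(metadata, screening = NULL,
                             permutation = NULL, cv = NULL,
                             strict = FALSE) {
    grp <- factor(as.character(metadata$group), .GROUPS)
    cul <- factor(as.character(metadata$culture), .CULTURE)
    n <- length(grp)
    counts <- as.integer(table(grp))
    cohort <- list(
        total = n,
        groups = setNames(counts, .GROUPS),
        group_percent = setNames(
            vapply(counts, percentOf, numeric(1), total = n), .GROUPS),
        culture_positive = sum(cul == "positive"),
        culture_positive_percent = percentOf(sum(cul == "positive"), n))

    scr <- lapply(screening, function(s) {
        nv <- nrow(s)
        list(n_vocs = nv,
             n_significant = sum(s$p_value < 0.05),
             percent_significant = percentOf(sum(s$p_value < 0.05), nv, 1),
             n_selected = sum(s$selected),
             percent_selected = percentOf(sum(s$selected), nv, 1))
    })

    perm <- lapply(permutation, function(p)
        list(n_perm = p@nPerm, observed = as.list(p@observed),
             fractions = as.list(p@fractions)))

    checks <- list()
    cvOut <- lapply(seq_along(cv), function(i) {
        obj <- cv[[i]]
        trueCounts <- c(sum(obj@labels), sum(!obj@labels))
        list(comparison = obj@comparison,
             n = length(obj@labels),
             in_set_auroc = as.list(obj@inSetAUC),
             loocv_auroc = as.list(obj@loocvAUC),
             confusion_in_set = obj@confusionInSet,
             confusion_loocv = obj@confusionLOOCV,
             true_class_counts = trueCounts)
    })
    names(cvOut) <- names(cv)
    for (nm in names(cv)) {
        obj <- cv[[nm]]
        expected <- if (obj@comparison == "pneumonia")
            c(cohort$groups[["probable"]],  cohort$groups[["control"]])
        else c(cohort$culture_positive, n - cohort$culture_positive)
        for (mat in list(inset = obj@confusionInSet,
                         loocv = obj@confusionLOOCV)) {
            ok <- all(colSums(mat) == expected)
            checks[[paste0(nm, "_margins")]] <-
                isTRUE(checks[[paste0(nm, "_margins")]] %||% TRUE) && ok
            if (!ok && strict)
                stop("confusion-matrix margins do not match cohort counts ",
                     "for comparison '", nm, "'")
        }
    }

    structure(list(cohort = cohort, screening = scr, permutation = perm,
                   cv = cvOut, checks = checks),
              class = "breathReport")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a study report to JSON and Markdown
#'
#' @param report a `breathReport` from [buildStudyReport()].
#' @param jsonPath,mdPath output paths (either may be `NULL` to skip).
#' @return Invisibly, the report.
#' @export
writeStudyReport <- function(report, jsonPath = NULL, mdPath = NULL) {
    stopifnot(inherits(report, "breathReport"))
    if (!is.null(jsonPath))
        jsonlite::write_json(report, jsonPath, auto_unbox = TRUE,
                             digits = NA, force = TRUE, matrix = "rowmajor")
    if (!is.null(mdPath)) {
        co <- report$cohort
        lines <- c(
            "# Breath VOC study report", "",
            sprintf("Cohort: %d patients (%s).", co$total,
                    paste(sprintf("%s %d (%s%%)", names(co$groups),
                                  co$groups, co$group_percent),
                          collapse = ", ")),
            sprintf("Positive cultures: %d (%s%%).", co$culture_positive,
                    co$culture_positive_percent), "")
        for (nm in names(report$screening)) {
            s <- report$screening[[nm]]
            lines <- c(lines, sprintf(
                "Screening (%s): %d/%d VOCs with p < 0.05 (%s%%); %d passed the dual gate (%s%%).",
                nm, s$n_significant, s$n_vocs, s$percent_significant,
                s$n_selected, s$percent_selected))
        }
        for (nm in names(report$permutation)) {
            p <- report$permutation[[nm]]
            lines <- c(lines, sprintf(
                "Permutations (%s, n = %d): %s.", nm, p$n_perm,
                paste(sprintf("%s similar-or-better fraction %.4f",
                              names(p$fractions),
                              unlist(p$fractions)), collapse = "; ")))
        }
        if (!length(report$permutation))
            lines <- c(lines, "Permutations: not run.")
        for (nm in names(report$cv)) {
            v <- report$cv[[nm]]
            lines <- c(lines, "", sprintf(
                "PLS-DA (%s): in-set AUROC %.2f (95%% CI %.2f-%.2f); LOOCV AUROC %.2f (95%% CI %.2f-%.2f).",
                v$comparison, v$in_set_auroc$auroc, v$in_set_auroc$lower,
                v$in_set_auroc$upper, v$loocv_auroc$auroc,
                v$loocv_auroc$lower, v$loocv_auroc$upper))
            for (tag in c("confusion_in_set", "confusion_loocv")) {
                m <- v[[tag]]
                lines <- c(lines, sprintf("%s (rows predicted, cols true):",
                                          tag),
                           "```",
                           utils::capture.output(print(m)),
                           "```")
            }
        }
        if (length(report$checks)) {
            ok <- all(unlist(report$checks))
            lines <- c(lines, "",
                       sprintf("Consistency checks: %s.",
                               if (ok) "all margins match cohort counts"
                               else "MARGIN MISMATCH FLAGGED"))
        }
        writeLines(lines, mdPath)
    }
    invisible(report)
}
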