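## Canonical interchange formats: tab-separated UTF-8 (comma-separated
## accepted on read, chosen by file extension); matrices wide with samples
## as columns, mirroring instrument-export convention.

.sepFor <- function(path)
    if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

#' Read a sample-metadata table
#'
#' Expects columns `sample_id`, `group` (control/colonized/possible/
#' probable) and `culture` (negative/positive). Ids must be unique and
#' labels must come from the fixed vocabularies; violations are rejected
#' with a message naming the offending value.
#'
#' @param path TSV (or CSV) file path.
#' @return A [S4Vectors::DataFrame] with `group`/`culture` factors, row
#'   names = sample ids.
#' @export
readSampleMetadata <- function(path) {
    df <- utils::read.delim(path, sep = .sepFor(path),
                            stringsAsFactors = FALSE)
    need <- c("sample_id", "group", "culture")
    if (!all(need %in% colnames(df)))
        stop("metadata must have columns: ", paste(need, collapse = ", "))
    dup <- df$sample_id[duplicated(df$sample_id)]
    if (length(dup))
        stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
    bad <- setdiff(unique(df$group), .GROUPS)
    if (length(bad))
        stop("unknown group label(s): ", paste(bad, collapse = ", "))
    bad <- setdiff(unique(df$culture), .CULTURE)
    if (length(bad))
        stop("unknown culture label(s): ", paste(bad, collapse = ", "))
    out <- DataFrame(group = factor(df$group, .GROUPS),
                     culture = factor(df$culture, .CULTURE),
                     row.names = df$sample_id)
    msgs <- .checkSampleData(out)
    if (length(msgs)) stop(paste(msgs, collapse = "; "))
    out
}

#' @export
#' @rdname readSampleMetadata
#' @param metadata a sample-metadata `DataFrame` to write.
#' @param x object to write (metadata, fragment or VOC table).
writeSampleMetadata <- function(metadata, path) {
    df <- data.frame(sample_id = rownames(metadata),
                     group = as.character(metadata$group),
                     culture = as.character(metadata$culture))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.readWideMatrix <- function(path, idCol, what) {
    df <- utils::read.delim(path, sep = .sepFor(path), check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (!idCol %in% colnames(df))
        stop(what, " table must have an '", idCol, "' column")
    df
}

.numericCols <- function(df, cols, what) {
    for (cc in cols) {
        v <- suppressWarnings(as.numeric(df[[cc]]))
        if (any(is.na(v) & !is.na(df[[cc]])))
            stop("non-numeric value in column '", cc, "' of the ",
                 what, " table")
        df[[cc]] <- v
    }
    df
}

.matchSamples <- function(mat, metadata) {
    miss <- setdiff(rownames(metadata), colnames(mat))
    if (length(miss))
        stop("metadata sample(s) missing from matrix: ",
             paste(miss, collapse = ", "))
    extra <- setdiff(colnames(mat), rownames(metadata))
    if (length(extra))
        stop("matrix sample(s) missing from metadata: ",
             paste(extra, collapse = ", "))
    mat[, rownames(metadata), drop = FALSE]
}

#' Read and write fragment and VOC tables
#'
#' Fragment tables are wide TSV: `fragment_id`, `rt_s`, then one numeric
#' column per sample. VOC tables additionally carry the retention-time
#' centroid (`rt_centroid_s`) and the member fragment ids
#' (`member_fragments`, semicolon-joined). CSV input is accepted (by file
#' extension); output is always TSV. Write followed by read restores an
#' identical object.
#'
#' @param path file path.
#' @param metadata sample metadata as returned by [readSampleMetadata()];
#'   the matrix and metadata sample sets must coincide.
#' @return [readFragmentTable()] a [FragmentExperiment-class];
#'   [readVOCTable()] a [VOCExperiment-class].
#' @export
readFragmentTable <- function(path, metadata) {
    df <- .readWideMatrix(path, "fragment_id", "fragment")
    if (!"rt_s" %in% colnames(df))
        stop("fragment table must have an 'rt_s' column")
    if (anyDuplicated(df$fragment_id))
        stop("duplicated fragment id(s): ",
             paste(unique(df$fragment_id[duplicated(df$fragment_id)]),
                   collapse = ", "))
    sampleCols <- setdiff(colnames(df), c("fragment_id", "rt_s"))
    df <- .numericCols(df, c("rt_s", sampleCols), "fragment")
    mat <- as.matrix(df[, sampleCols, drop = FALSE])
    rownames(mat) <- df$fragment_id
    mat <- .matchSamples(mat, metadata)
    FragmentExperiment(mat, df$rt_s, metadata)
}

#' @rdname readFragmentTable
#' @param x a [FragmentExperiment-class] or [VOCExperiment-class].
#' @export
writeFragmentTable <- function(x, path) {
    stopifnot(is(x, "FragmentExperiment"))
    df <- data.frame(fragment_id = rownames(x),
                     rt_s = rowData(x)$rt_s,
                     as.data.frame(assay(x, "counts"),
                                   check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname readFragmentTable
#' @export
readVOCTable <- function(path, metadata) {
    df <- .readWideMatrix(path, "voc_id", "VOC")
    need <- c("rt_centroid_s", "member_fragments")
    if (!all(need %in% colnames(df)))
        stop("VOC table must have columns: ", paste(need, collapse = ", "))
    sampleCols <- setdiff(colnames(df),
                          c("voc_id", "rt_centroid_s", "member_fragments"))
    df <- .numericCols(df, c("rt_centroid_s", sampleCols), "VOC")
    mat <- as.matrix(df[, sampleCols, drop = FALSE])
    rownames(mat) <- df$voc_id
    mat <- .matchSamples(mat, metadata)
    members <- strsplit(df$member_fragments, ";", fixed = TRUE)
    VOCExperiment(mat, df$rt_centroid_s, members, metadata)
}

#' @rdname readFragmentTable
#' @export
writeVOCTable <- function(x, path) {
    stopifnot(is(x, "VOCExperiment"))
    df <- data.frame(voc_id = rownames(x),
                     rt_centroid_s = rowData(x)$rt_centroid_s,
                     member_fragments = vapply(memberFragments(x),
                                               paste, "", collapse = ";"),
                     as.data.frame(assay(x, "intensity"),
                                   check.names = FALSE),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Write screening results as volcano-plot data
#'
#' Exports the per-VOC screen as TSV with the volcano coordinates
#' (`log2_fc`, `neglog10_p`), the AUROC (dot size) and the gate flag.
#'
#' @param screening a `DataFrame` from [screenVOCs()].
#' @param path output TSV path.
#' @export
writeVolcanoTable <- function(screening, path) {
    df <- as.data.frame(screening[, c("voc_id", "log2_fc", "neglog10_p",
                                      "auroc", "selected")])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
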