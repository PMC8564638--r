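## TSV dialect shared by all readers/writers: UTF-8, tab separated, '.'
## decimal separator, no quoting, numeric cells written with 4 decimals so a
## write -> read -> write cycle is byte-stable.

.NUM_FMT <- "%.4f"

.checkExpressionMatrix <- function(x) {
    if (!is.matrix(x) || !is.numeric(x))
        stop("expression matrix must be a numeric matrix")
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("expression matrix needs probeset row names and sample column names")
    if (anyDuplicated(rownames(x)))
        stop("duplicate probeset id: ",
             rownames(x)[duplicated(rownames(x))][1L])
    if (anyDuplicated(colnames(x)))
        stop("duplicate sample id: ", colnames(x)[duplicated(colnames(x))][1L])
    if (anyNA(x) || any(!is.finite(x)))
        stop("expression matrix contains missing or non-finite values")
    if (nrow(x) < 2L || ncol(x) < 2L)
        stop("expression matrix needs at least 2 probesets and 2 samples")
    x
}

.checkSampleAnnotation <- function(ann) {
    need <- c("sample_id", "group_id", "category", "matched_normal")
    if (!is.data.frame(ann) || !all(need %in% names(ann)))
        stop("sample annotation needs columns: ", paste(need, collapse = ", "))
    ann[need] <- lapply(ann[need], function(z) {
        z <- as.character(z); z[is.na(z)] <- ""; z
    })
    if (anyDuplicated(ann$sample_id))
        stop("duplicate sample_id in annotation: ",
             ann$sample_id[duplicated(ann$sample_id)][1L])
    bad <- setdiff(unique(ann$category), .CATEGORIES)
    if (length(bad))
        stop("unknown category token(s): ", paste(bad, collapse = ", "),
             " (expected ", paste(.CATEGORIES, collapse = "|"), ")")
    grp <- ann[!duplicated(ann$group_id), c("group_id", "category",
                                            "matched_normal")]
    multi <- unique(ann$group_id[!duplicated(paste(ann$group_id,
                                                   ann$category))])
    if (length(multi) != nrow(grp))
        stop("a group_id maps to more than one category")
    normals <- grp$group_id[grp$category == "NORMAL"]
    canc <- grp[grp$category == "CANCER", , drop = FALSE]
    bad <- canc$group_id[!(canc$matched_normal %in% normals)]
    if (length(bad))
        stop("CANCER group(s) lacking a valid NORMAL matched_normal: ",
             paste(bad, collapse = ", "))
    if (any(grp$matched_normal[grp$category != "CANCER"] != ""))
        stop("matched_normal must be empty unless category is CANCER")
    if (!any(grp$category == "TARGET") || !any(grp$category == "NORMAL"))
        stop("annotation needs at least one TARGET and one NORMAL group")
    ann
}

.checkProbesetAnnotation <- function(pa, probeset_ids) {
    need <- c("probeset_id", "gene_symbol")
    if (!is.data.frame(pa) || !all(need %in% names(pa)))
        stop("probeset annotation needs columns: ",
             paste(need, collapse = ", "))
    pa$probeset_id <- as.character(pa$probeset_id)
    pa$gene_symbol <- as.character(pa$gene_symbol)
    pa$gene_symbol[is.na(pa$gene_symbol)] <- ""
    if (anyDuplicated(pa$probeset_id))
        stop("duplicate probeset_id in probeset annotation: ",
             pa$probeset_id[duplicated(pa$probeset_id)][1L])
    extra <- setdiff(pa$probeset_id, probeset_ids)
    if (length(extra))
        stop("probeset annotation references unknown probeset(s): ",
             paste(utils::head(extra, 3L), collapse = ", "))
    pa
}

#' Read a log2 expression matrix from TSV
#'
#' Expects a header row of sample ids whose first field is literally
#' `probeset_id`, one row per probeset, and numeric cells ('.' decimal).
#' Row and column order are preserved.
#'
#' @param path path to a TSV file.
#' @return validated numeric matrix, probesets x samples.
#' @export
readExpressionMatrix <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 2L || hdr[1L] != "probeset_id")
        stop("expression matrix header must start with 'probeset_id'")
    sample_ids <- hdr[-1L]
    if (anyDuplicated(sample_ids))
        stop("duplicate sample id in header: ",
             sample_ids[duplicated(sample_ids)][1L])
    df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = c("character", rep("numeric",
                                                     length(sample_ids))),
                     quote = "", comment.char = "")
    x <- as.matrix(df[, -1L, drop = FALSE])
    rownames(x) <- df[[1L]]
    storage.mode(x) <- "double"
    .checkExpressionMatrix(x)
}

#' Write a log2 expression matrix as TSV
#'
#' Inverse of [readExpressionMatrix()]; values are written with four decimals
#' so write/read cycles are byte-stable.
#'
#' @param x numeric matrix, probesets x samples, with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    x <- .checkExpressionMatrix(x)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(c("probeset_id", colnames(x)), collapse = "\t"), con)
    body <- vapply(seq_len(nrow(x)), function(i)
        paste(c(rownames(x)[i], sprintf(.NUM_FMT, x[i, ])), collapse = "\t"),
        "")
    writeLines(body, con)
    invisible(path)
}

#' Read a sample annotation table from TSV
#'
#' Columns: `sample_id`, `group_id`, `category` (`TARGET|NORMAL|CANCER`),
#' `matched_normal` (empty unless CANCER, else an existing NORMAL group) and
#' optionally `label`. Referential integrity is enforced.
#'
#' @param path path to a TSV file.
#' @return validated data.frame.
#' @export
readSampleAnnotation <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ann <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                      comment.char = "", colClasses = "character")
    .checkSampleAnnotation(ann)
}

#' @rdname readSampleAnnotation
#' @param ann data.frame as returned by [readSampleAnnotation()].
#' @export
writeSampleAnnotation <- function(ann, path) {
    ann <- .checkSampleAnnotation(ann)
    if (!"label" %in% names(ann)) ann$label <- ann$group_id
    .writeTsv(ann[c("sample_id", "group_id", "category", "matched_normal",
                    "label")], path)
}

#' Read a probeset-to-gene annotation table from TSV
#'
#' Columns `probeset_id`, `gene_symbol`; an empty symbol marks an unmapped
#' probeset. `probeset_ids`, when given, is used to reject annotations that
#' reference probesets absent from the matrix.
#'
#' @param path path to a TSV file.
#' @param probeset_ids optional character vector of valid probeset ids.
#' @return data.frame with columns `probeset_id`, `gene_symbol`.
#' @export
readProbesetAnnotation <- function(path, probeset_ids = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    pa <- read.delim(path, header = TRUE, sep = "\t", quote = "",
                     comment.char = "", colClasses = "character")
    if (is.null(probeset_ids)) probeset_ids <- pa$probeset_id
    .checkProbesetAnnotation(pa, probeset_ids)
}

#' @rdname readProbesetAnnotation
#' @param pa data.frame with columns `probeset_id`, `gene_symbol`.
#' @export
writeProbesetAnnotation <- function(pa, path) {
    pa <- .checkProbesetAnnotation(pa, pa$probeset_id)
    .writeTsv(pa[c("probeset_id", "gene_symbol")], path)
}

#' Assemble a CTExperiment from the three TSV inputs
#'
#' @param matrixPath expression matrix TSV (see [readExpressionMatrix()]).
#' @param samplePath sample annotation TSV (see [readSampleAnnotation()]).
#' @param probesetPath optional probeset annotation TSV.
#' @return a [CTExperiment-class].
#' @export
readCTExperiment <- function(matrixPath, samplePath, probesetPath = NULL) {
    x <- readExpressionMatrix(matrixPath)
    ann <- readSampleAnnotation(samplePath)
    pa <- if (!is.null(probesetPath))
        readProbesetAnnotation(probesetPath, rownames(x))
    CTExperiment(x, ann, pa)
}

## write a character/numeric data.frame as unquoted TSV, formatting numeric
## columns with the shared dialect and logical columns as 0/1
.writeTsv <- function(df, path) {
    df <- as.data.frame(df)
    for (j in seq_along(df)) {
        if (is.logical(df[[j]])) df[[j]] <- as.integer(df[[j]])
        if (is.numeric(df[[j]]) && !is.integer(df[[j]]))
            df[[j]] <- .fmtNum(df[[j]])
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste(names(df), collapse = "\t"), con)
    if (nrow(df))
        writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
    invisible(path)
}

## significant but compact numeric formatting for result tables (p/q values
## need scientific notation; signals are plain)
.fmtNum <- function(z) {
    out <- ifelse(is.na(z), "NA",
           ifelse(z == 0, "0",
           ifelse(abs(z) >= 1e-3 & abs(z) < 1e6, sprintf("%.4f", z),
                  sprintf("%.4e", z))))
    out
}
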