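#' Cancer-upregulation classification
#'
#' For every (probeset, cancer subtype) pair, sets the four upregulation
#' flags from the subtype's summary signal, its matched normal tissue's
#' summary, and the subtype-vs-matched-normal moderated-t contrast:
#'
#' * `uc`  — upregulated in the cancer subtype: subtype signal strictly above
#'   the BEC, log2 fold change (subtype summary minus matched-normal summary)
#'   at least `foldChangeLog2`, and contrast q <= `qCutoff`;
#' * `uhec` — `uc` and subtype signal in the upper quartile (>= `qHigh`);
#' * `ucndh` — `uc` and matched-normal signal strictly below the BEC
#'   (not detected in the healthy tissue of origin);
#' * `uhecndh` — `uhec` and `ucndh`.
#'
#' Group summaries (medians) drive the detection and fold-change gates;
#' per-sample values drive the significance test, whose q-values are adjusted
#' within each subtype contrast separately.
#'
#' @param summaries probeset x group summary matrix from [groupSummaries()].
#' @param annot a [CTExperiment-class] or sample-annotation data.frame.
#' @param thresholds a [GlobalThresholds-class].
#' @param contrasts named list, one [moderatedTTest()] result per CANCER
#'   group, cancer samples vs matched-normal samples.
#' @param params a [ctParams()] list.
#' @return data.frame with one row per (probeset, cancer group):
#'   `probeset_id`, `cancer_group`, `uc`, `uhec`, `ucndh`, `uhecndh`
#'   (logical), `cancer_signal`, `normal_signal`, `log2fc`, `q`.
#' @export
classifyCancer <- function(summaries, annot, thresholds, contrasts,
                           params = ctParams()) {
    mn <- .annotMatchedNormals(annot)
    if (!length(mn)) stop("annotation has no CANCER groups")
    miss <- setdiff(names(mn), names(contrasts))
    if (length(miss))
        stop("missing contrast for cancer group(s): ",
             paste(miss, collapse = ", "))
    becv <- bec(thresholds); qh <- qHigh(thresholds)
    out <- lapply(names(mn), function(cg) {
        ctr <- contrasts[[cg]]
        missp <- setdiff(rownames(summaries), ctr$probeset_id)
        if (length(missp))
            stop("contrast for ", cg, " is missing probeset(s): ",
                 paste(utils::head(missp, 3L), collapse = ", "))
        q <- ctr$q[match(rownames(summaries), ctr$probeset_id)]
        cs <- summaries[, cg]
        ns <- summaries[, mn[[cg]]]
        fc <- cs - ns
        uc <- cs > becv & fc >= params$foldChangeLog2 & q <= params$qCutoff
        uhec <- uc & cs >= qh
        ucndh <- uc & ns < becv
        data.frame(probeset_id = rownames(summaries),
                   cancer_group = cg,
                   uc = unname(uc),
                   uhec = unname(uhec),
                   ucndh = unname(ucndh),
                   uhecndh = unname(uhec & ucndh),
                   cancer_signal = unname(cs),
                   normal_signal = unname(ns),
                   log2fc = unname(fc),
                   q = unname(q),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
}

#' Aggregate cancer flags over subtypes
#'
#' Per-probeset tallies across cancer subtypes: in how many subtypes the
#' probeset is UC / UCNDH, and whether it is UCNDH in at least one subtype —
#' the criterion the CT caller intersects with testis specificity.
#'
#' @param records data.frame from [classifyCancer()].
#' @return data.frame with columns `probeset_id`, `n_subtypes_uc`,
#'   `n_subtypes_ucndh`, `any_ucndh`, one row per probeset.
#' @export
aggregateCancerFlags <- function(records) {
    need <- c("probeset_id", "uc", "ucndh")
    if (!all(need %in% names(records)))
        stop("records must contain columns: ", paste(need, collapse = ", "))
    ids <- unique(records$probeset_id)
    f <- factor(records$probeset_id, levels = ids)
    data.frame(probeset_id = ids,
               n_subtypes_uc = as.integer(tapply(records$uc, f, sum)),
               n_subtypes_ucndh = as.integer(tapply(records$ucndh, f, sum)),
               any_ucndh = as.logical(tapply(records$ucndh, f, any)),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname classifyCancer
#' @param records data.frame from [classifyCancer()].
#' @param path output path.
#' @export
writeCancerClasses <- function(records, path) {
    .writeTsv(records[c("probeset_id", "cancer_group", "uc", "uhec", "ucndh",
                        "uhecndh", "cancer_signal", "normal_signal", "log2fc",
                        "q")], path)
}
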