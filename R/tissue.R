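#' Classifier parameters
#'
#' Bundles the tunable cutoffs of both classifiers: the fold-change threshold
#' on the log2 scale (1.0 = twofold), the FDR-adjusted significance cutoff
#' (q <= 0.01), the exception budget for preferential expression (up to 3
#' somatic tissues may violate the detection/fold-change criteria), and the
#' somatic detection range that defines intermediate expression (4-10
#' tissues).
#'
#' @param foldChangeLog2 minimum log2 difference counted as a change
#'   (default 1.0, i.e. twofold).
#' @param qCutoff FDR-adjusted significance cutoff in (0, 1] (default 0.01).
#' @param exceptionBudget maximum somatic exceptions for PE classes
#'   (default 3).
#' @param ieRange integer length-2: somatic detection counts classed as
#'   intermediate expression (default `c(4, 10)`).
#' @return a validated list of class `ctParams`.
#' @export
ctParams <- function(foldChangeLog2 = 1.0, qCutoff = 0.01,
                     exceptionBudget = 3L, ieRange = c(4L, 10L)) {
    stopifnot(length(foldChangeLog2) == 1L, foldChangeLog2 >= 0,
              length(qCutoff) == 1L, qCutoff > 0, qCutoff <= 1,
              length(exceptionBudget) == 1L, exceptionBudget >= 0,
              length(ieRange) == 2L, ieRange[1L] <= ieRange[2L])
    structure(list(foldChangeLog2 = as.numeric(foldChangeLog2),
                   qCutoff = as.numeric(qCutoff),
                   exceptionBudget = as.integer(exceptionBudget),
                   ieRange = as.integer(ieRange)),
              class = "ctParams")
}

#' Tissue-specificity classification
#'
#' Assigns each probeset exactly one of seven classes from its per-group
#' summary signals, the global thresholds, and the target-vs-somatic contrast:
#'
#' * `SET` / `SEHET`: specifically expressed in the target compartment —
#'   target signal above the BEC, significant (q <= cutoff), and **no** normal
#'   somatic group is an exception; `SEHET` additionally has target signal in
#'   the upper quartile (>= `qHigh`).
#' * `PET` / `PEHET`: preferentially expressed — as above but with 1 up to
#'   `exceptionBudget` somatic exceptions.
#' * `IE`: fails SE/PE but is detected (summary > BEC) in `ieRange` somatic
#'   tissues.
#' * `UE`: detected in every normal somatic group.
#' * `OTHER`: any remaining profile.
#'
#' A somatic group is an *exception* when its summary exceeds the BEC **or**
#' lies within the fold-change window of the target signal
#' (`target - summary < foldChangeLog2`); a single shared budget covers both
#' criteria. The target signal is the maximum of the TARGET group summaries,
#' so expression confined to one germ-cell compartment still counts. IE/UE
#' are detection-count classes only and do not consult the contrast. When the
#' somatic detection count satisfies both the IE range and "all groups"
#' (possible only with few normal groups), IE takes precedence.
#'
#' @param summaries probeset x group summary matrix from [groupSummaries()].
#' @param annot a [CTExperiment-class] or a data.frame of sample annotation
#'   (used for group categories).
#' @param thresholds a [GlobalThresholds-class].
#' @param contrast data.frame with columns `probeset_id`, `q` for the
#'   target-vs-pooled-somatic contrast (see [moderatedTTest()]).
#' @param params a [ctParams()] list.
#' @return data.frame with columns `probeset_id`, `class_label`,
#'   `target_signal`, `n_somatic_detected`, `n_exceptions`, `q`.
#' @export
classifyTissue <- function(summaries, annot, thresholds, contrast,
                           params = ctParams()) {
    cat <- .annotCategories(annot)
    tg <- names(cat)[cat == "TARGET"]
    ng <- names(cat)[cat == "NORMAL"]
    if (!all(c(tg, ng) %in% colnames(summaries)))
        stop("summaries lack TARGET/NORMAL group columns")
    miss <- setdiff(rownames(summaries), contrast$probeset_id)
    if (length(miss))
        stop("contrast is missing probeset(s): ",
             paste(utils::head(miss, 3L), collapse = ", "))
    q <- contrast$q[match(rownames(summaries), contrast$probeset_id)]

    becv <- bec(thresholds); qh <- qHigh(thresholds)
    tsig <- apply(summaries[, tg, drop = FALSE], 1L, max)
    som <- summaries[, ng, drop = FALSE]
    detected <- som > becv
    nDet <- rowSums(detected)
    exception <- detected | (tsig - som < params$foldChangeLog2)
    nExc <- rowSums(exception)

    sepeBase <- tsig > becv & q <= params$qCutoff
    se <- sepeBase & nExc == 0L
    pe <- sepeBase & nExc >= 1L & nExc <= params$exceptionBudget
    he <- tsig >= qh
    cls <- rep("OTHER", nrow(summaries))
    cls[se & he] <- "SEHET"
    cls[se & !he] <- "SET"
    cls[pe & he] <- "PEHET"
    cls[pe & !he] <- "PET"
    rest <- !(se | pe)
    cls[rest & nDet >= params$ieRange[1L] & nDet <= params$ieRange[2L]] <- "IE"
    cls[rest & cls == "OTHER" & nDet == length(ng)] <- "UE"
    data.frame(probeset_id = rownames(summaries),
               class_label = cls,
               target_signal = unname(tsig),
               n_somatic_detected = unname(as.integer(nDet)),
               n_exceptions = unname(as.integer(nExc)),
               q = unname(q),
               stringsAsFactors = FALSE)
}

#' Class distribution summary
#'
#' Counts and percentages of the tissue classes over all classified probesets
#' or a user-supplied subset (e.g. the probesets referenced in the CT
#' database, for a pie-chart style breakdown).
#'
#' @param records data.frame from [classifyTissue()].
#' @param subset optional character vector of probeset ids.
#' @return data.frame with columns `class_label`, `count`, `fraction`,
#'   `percent` (percent rounded to the nearest integer), one row per class in
#'   canonical order.
#' @export
summarizeClassDistribution <- function(records, subset = NULL) {
    if (!is.null(subset)) {
        bad <- setdiff(subset, records$probeset_id)
        if (length(bad))
            stop("subset contains unclassified probeset(s): ",
                 paste(utils::head(bad, 3L), collapse = ", "))
        records <- records[records$probeset_id %in% subset, , drop = FALSE]
    }
    if (!nrow(records)) stop("empty subset: nothing to summarize")
    n <- nrow(records)
    cnt <- table(factor(records$class_label, levels = .TISSUE_CLASSES))
    data.frame(class_label = .TISSUE_CLASSES,
               count = as.integer(cnt),
               fraction = as.numeric(cnt) / n,
               percent = as.integer(round(100 * as.numeric(cnt) / n)),
               stringsAsFactors = FALSE)
}

## accept a CTExperiment or a sample-annotation data.frame
.annotCategories <- function(annot) {
    if (is(annot, "SummarizedExperiment")) return(groupCategories(annot))
    ann <- .checkSampleAnnotation(annot)
    g <- !duplicated(ann$group_id)
    setNames(ann$category[g], ann$group_id[g])
}

.annotMatchedNormals <- function(annot) {
    if (is(annot, "SummarizedExperiment")) return(matchedNormals(annot))
    ann <- .checkSampleAnnotation(annot)
    k <- ann$category == "CANCER" & !duplicated(ann$group_id)
    setNames(ann$matched_normal[k], ann$group_id[k])
}

#' @rdname classifyTissue
#' @param path output path.
#' @param records data.frame from [classifyTissue()].
#' @export
writeTissueClasses <- function(records, path) {
    .writeTsv(records[c("probeset_id", "class_label", "target_signal",
                        "n_somatic_detected", "n_exceptions", "q")], path)
}
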