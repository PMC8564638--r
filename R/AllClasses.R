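#' @import methods
#' @importFrom stats median quantile var pt pnorm rnorm rchisq runif setNames
#' @importFrom utils read.delim write.table
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData rowData
#' @importFrom S4Vectors DataFrame
NULL

.CATEGORIES <- c("TARGET", "NORMAL", "CANCER")
.TISSUE_CLASSES <- c("SET", "SEHET", "PET", "PEHET", "IE", "UE", "OTHER")
.TESTIS_CLASSES <- c("SET", "SEHET", "PET", "PEHET")
.CORE_CLASSES <- c("SET", "SEHET")

#' CTExperiment: a multi-tissue expression compendium
#'
#' `CTExperiment` extends [SummarizedExperiment::SummarizedExperiment] with the
#' sample structure the CT screen requires: every sample belongs to a group
#' (a tissue, a germ-cell compartment, or a cancer subtype), every group has a
#' category (`TARGET`, `NORMAL` or `CANCER`), and every `CANCER` group names
#' the `NORMAL` group of its tissue of origin. The single assay `"exprs"`
#' holds finite log2-scale intensities, probesets in rows and samples in
#' columns. `rowData` carries the optional `gene_symbol` mapping (empty string
#' = unmapped probeset).
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]; no extra slots.
#' @aliases CTExperiment-class
#' @exportClass CTExperiment
setClass("CTExperiment", contains = "SummarizedExperiment")

.validCTExperiment <- function(object) {
    msg <- character()
    if (!"exprs" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'exprs' is missing")
    else {
        x <- SummarizedExperiment::assay(object, "exprs")
        if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
            msg <- c(msg, "assay 'exprs' must be numeric, finite, no NAs")
        if (nrow(x) < 2L || ncol(x) < 2L)
            msg <- c(msg, "need at least 2 probesets and 2 samples")
    }
    ids <- rownames(object)
    if (is.null(ids) || anyDuplicated(ids))
        msg <- c(msg, "probeset ids must be present and unique")
    sid <- colnames(object)
    if (is.null(sid) || anyDuplicated(sid))
        msg <- c(msg, "sample ids must be present and unique")
    cd <- SummarizedExperiment::colData(object)
    need <- c("group_id", "category", "matched_normal")
    if (!all(need %in% colnames(cd))) {
        msg <- c(msg, sprintf("colData must contain columns: %s",
                              paste(need, collapse = ", ")))
        if (length(msg)) return(msg)
    }
    if (!all(cd$category %in% .CATEGORIES))
        msg <- c(msg, sprintf("category tokens must be one of %s",
                              paste(.CATEGORIES, collapse = "|")))
    ## one category per group
    bygrp <- split(as.character(cd$category), as.character(cd$group_id))
    if (any(vapply(bygrp, function(z) length(unique(z)), 1L) > 1L))
        msg <- c(msg, "a group_id maps to more than one category")
    grp_cat <- vapply(bygrp, `[`, "", 1L)
    if (!any(grp_cat == "TARGET") || !any(grp_cat == "NORMAL"))
        msg <- c(msg, "need at least one TARGET and one NORMAL group")
    ## CANCER groups must match an existing NORMAL group
    canc <- cd[cd$category == "CANCER", , drop = FALSE]
    if (nrow(canc)) {
        mn <- vapply(split(as.character(canc$matched_normal),
                           as.character(canc$group_id)), `[`, "", 1L)
        bad <- names(mn)[is.na(mn) | mn == "" |
                         is.na(grp_cat[mn]) | grp_cat[mn] != "NORMAL"]
        if (length(bad))
            msg <- c(msg, sprintf(
                "CANCER group(s) without a valid NORMAL matched_normal: %s",
                paste(bad, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
}
setValidity("CTExperiment", .validCTExperiment)

#' Construct a CTExperiment
#'
#' @param exprs numeric matrix of log2 intensities, probesets x samples, with
#'   unique non-empty dimnames.
#' @param sampleAnnotation data.frame with columns `sample_id`, `group_id`,
#'   `category` (`TARGET|NORMAL|CANCER`), `matched_normal` (empty unless
#'   CANCER) and optionally `label`; one row per sample of `exprs`.
#' @param probesetAnnotation optional data.frame with columns `probeset_id`,
#'   `gene_symbol` mapping probesets to genes (empty symbol = unmapped).
#'   Probesets absent from the table are treated as unmapped.
#' @return a validated [CTExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12, 5), 3, 4,
#'             dimnames = list(paste0("ps", 1:3), paste0("s", 1:4)))
#' ann <- data.frame(sample_id = colnames(m),
#'                   group_id = c("testis", "testis", "liver", "liver"),
#'                   category = c("TARGET", "TARGET", "NORMAL", "NORMAL"),
#'                   matched_normal = "")
#' ce <- CTExperiment(m, ann)
#' @export
CTExperiment <- function(exprs, sampleAnnotation, probesetAnnotation = NULL) {
    exprs <- .checkExpressionMatrix(exprs)
    ann <- .checkSampleAnnotation(sampleAnnotation)
    if (!setequal(ann$sample_id, colnames(exprs)) ||
        nrow(ann) != ncol(exprs))
        stop("sampleAnnotation must cover every matrix sample exactly once")
    ann <- ann[match(colnames(exprs), ann$sample_id), , drop = FALSE]
    cd <- S4Vectors::DataFrame(group_id = ann$group_id,
                               category = ann$category,
                               matched_normal = ann$matched_normal,
                               label = if ("label" %in% names(ann)) ann$label
                                       else ann$group_id,
                               row.names = ann$sample_id)
    gene <- rep("", nrow(exprs))
    if (!is.null(probesetAnnotation)) {
        pa <- .checkProbesetAnnotation(probesetAnnotation, rownames(exprs))
        gene[match(pa$probeset_id, rownames(exprs))] <- pa$gene_symbol
    }
    rd <- S4Vectors::DataFrame(gene_symbol = gene, row.names = rownames(exprs))
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(exprs = exprs), colData = cd, rowData = rd)
    new("CTExperiment", se)
}

#' @describeIn CTExperiment named character vector mapping each sample to its
#'   group.
#' @param x a `CTExperiment`.
#' @export
sampleGroups <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    setNames(as.character(cd$group_id), rownames(cd))
}

#' @describeIn CTExperiment named character vector mapping each group to its
#'   category.
#' @export
groupCategories <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    g <- !duplicated(cd$group_id)
    setNames(as.character(cd$category)[g], as.character(cd$group_id)[g])
}

#' @describeIn CTExperiment group ids with category TARGET.
#' @export
targetGroups <- function(x) names(which(groupCategories(x) == "TARGET"))

#' @describeIn CTExperiment group ids with category NORMAL.
#' @export
normalGroups <- function(x) names(which(groupCategories(x) == "NORMAL"))

#' @describeIn CTExperiment group ids with category CANCER.
#' @export
cancerGroups <- function(x) names(which(groupCategories(x) == "CANCER"))

#' @describeIn CTExperiment named character vector mapping each CANCER group
#'   to its matched NORMAL group.
#' @export
matchedNormals <- function(x) {
    cd <- SummarizedExperiment::colData(x)
    k <- cd$category == "CANCER" & !duplicated(cd$group_id)
    setNames(as.character(cd$matched_normal)[k], as.character(cd$group_id)[k])
}

#' @describeIn CTExperiment named character vector mapping each probeset to a
#'   gene symbol ("" = unmapped).
#' @export
geneSymbols <- function(x) {
    setNames(as.character(SummarizedExperiment::rowData(x)$gene_symbol),
             rownames(x))
}

setMethod("show", "CTExperiment", function(object) {
    cat <- groupCategories(object)
    callNextMethod()
    base::cat(sprintf(
        "groups: %d TARGET, %d NORMAL, %d CANCER\n",
        sum(cat == "TARGET"), sum(cat == "NORMAL"), sum(cat == "CANCER")))
})

#' GlobalThresholds: the detection and confidence cutoffs of a matrix
#'
#' Holds the background expression cutoff (BEC, the overall median of the
#' pooled log2 matrix) and the lower/upper quartiles that bound the expression
#' confidence tiers: values below `qLow` are considered undetectable, values
#' at or above `qHigh` highly expressed.
#'
#' @slot bec numeric(1), log2 units; detection cutoff.
#' @slot qLow numeric(1), log2 units; 25th percentile.
#' @slot qHigh numeric(1), log2 units; 75th percentile.
#' @aliases GlobalThresholds-class
#' @exportClass GlobalThresholds
setClass("GlobalThresholds",
         representation(bec = "numeric", qLow = "numeric", qHigh = "numeric"))

setValidity("GlobalThresholds", function(object) {
    if (length(object@bec) != 1L || length(object@qLow) != 1L ||
        length(object@qHigh) != 1L)
        return("bec, qLow, qHigh must each be length 1")
    if (anyNA(c(object@bec, object@qLow, object@qHigh)))
        return("thresholds must be non-missing")
    if (!(object@qLow <= object@bec && object@bec <= object@qHigh))
        return("must satisfy qLow <= bec <= qHigh")
    TRUE
})

#' @describeIn GlobalThresholds-class constructor.
#' @param bec,qLow,qHigh numeric(1) log2-scale cutoffs, qLow <= bec <= qHigh.
#' @export
globalThresholds <- function(bec, qLow = bec, qHigh = bec)
    new("GlobalThresholds", bec = as.numeric(bec), qLow = as.numeric(qLow),
        qHigh = as.numeric(qHigh))

#' @describeIn GlobalThresholds-class background expression cutoff.
#' @param x a `GlobalThresholds`.
#' @export
bec <- function(x) x@bec

#' @describeIn GlobalThresholds-class lower quartile cutoff.
#' @export
qLow <- function(x) x@qLow

#' @describeIn GlobalThresholds-class upper quartile cutoff.
#' @export
qHigh <- function(x) x@qHigh

setMethod("show", "GlobalThresholds", function(object) {
    base::cat(sprintf(
        "GlobalThresholds: bec = %.4g, qLow = %.4g, qHigh = %.4g (log2)\n",
        object@bec, object@qLow, object@qHigh))
})

#' PriorEstimate: empirical-Bayes variance prior
#'
#' Hyperparameters of the scaled inverse-chi-square prior on per-probeset
#' residual variances used by the moderated t-statistic: `d0` prior degrees of
#' freedom (may be `Inf` when the observed log-variances show no spread beyond
#' their sampling expectation) and `s0Sq` prior variance (squared log2 units).
#' `d0 = 0` disables moderation, reducing the statistic to the classical
#' pooled t.
#'
#' @slot d0 numeric(1) >= 0, possibly Inf.
#' @slot s0Sq numeric(1) > 0.
#' @aliases PriorEstimate-class
#' @exportClass PriorEstimate
setClass("PriorEstimate", representation(d0 = "numeric", s0Sq = "numeric"))

setValidity("PriorEstimate", function(object) {
    if (length(object@d0) != 1L || length(object@s0Sq) != 1L)
        return("d0 and s0Sq must be length 1")
    if (is.na(object@d0) || object@d0 < 0)
        return("d0 must be >= 0 (Inf allowed)")
    if (is.na(object@s0Sq) || object@s0Sq <= 0 || !is.finite(object@s0Sq))
        return("s0Sq must be finite and > 0")
    TRUE
})

#' @describeIn PriorEstimate-class constructor.
#' @param d0 prior degrees of freedom (>= 0, Inf allowed).
#' @param s0Sq prior variance (> 0).
#' @export
priorEstimate <- function(d0, s0Sq)
    new("PriorEstimate", d0 = as.numeric(d0), s0Sq = as.numeric(s0Sq))

#' @describeIn PriorEstimate-class prior degrees of freedom.
#' @param x a `PriorEstimate`.
#' @export
priorDf <- function(x) x@d0

#' @describeIn PriorEstimate-class prior variance.
#' @export
priorVar <- function(x) x@s0Sq

setMethod("show", "PriorEstimate", function(object) {
    base::cat(sprintf("PriorEstimate: d0 = %.4g, s0Sq = %.4g\n",
                      object@d0, object@s0Sq))
})
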