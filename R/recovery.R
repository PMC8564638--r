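#' Score recovery of planted truth
#'
#' Joins pipeline calls against the simulator's truth table and tallies, per
#' planted class, how many probesets/genes were recovered. Sensitivity is
#' recovered/planted, precision is true/called (NA when nothing was called).
#'
#' @param truth truth data.frame from [generateDataset()].
#' @param calls `ctCalls` from [callCT()].
#' @param tissueRecords data.frame from [classifyTissue()] (probeset-level
#'   class confusion); optional.
#' @param cancerAggregate data.frame from [aggregateCancerFlags()]
#'   (any-UCNDH recovery); optional.
#' @return list of class `ctRecovery` with elements:
#'   `classStats` (per planted class: planted/called/tp counts, sensitivity,
#'   precision, probeset level), `confusion` (planted x called class matrix),
#'   `geneCT` (gene-level sensitivity/precision for `ct_candidate` and
#'   `core_ct`), `ucndh` (probeset-level any-UCNDH sensitivity/precision).
#'   Elements needing an omitted input are `NULL`.
#' @export
evaluateRecovery <- function(truth, calls, tissueRecords = NULL,
                             cancerAggregate = NULL) {
    psTruth <- .expandTruth(truth)
    if (!setequal(psTruth$probeset_id, calls$probesets$probeset_id))
        stop("truth and calls cover different probeset sets")

    out <- list(classStats = NULL, confusion = NULL, geneCT = NULL,
                ucndh = NULL)

    if (!is.null(tissueRecords)) {
        called <- tissueRecords$class_label[
            match(psTruth$probeset_id, tissueRecords$probeset_id)]
        planted <- ifelse(psTruth$class == "BACKGROUND", "OTHER",
                          psTruth$class)
        lev <- .TISSUE_CLASSES
        out$confusion <- table(planted = factor(planted, levels = lev),
                               called = factor(called, levels = lev))
        tp <- diag(out$confusion)
        nPlanted <- rowSums(out$confusion)
        nCalled <- colSums(out$confusion)
        out$classStats <- data.frame(
            class_label = lev,
            planted = as.integer(nPlanted),
            called = as.integer(nCalled),
            tp = as.integer(tp),
            sensitivity = ifelse(nPlanted > 0, tp / nPlanted, NA_real_),
            precision = ifelse(nCalled > 0, tp / nCalled, NA_real_),
            stringsAsFactors = FALSE, row.names = NULL)
    }

    ## gene-level CT-call recovery
    isCT <- truth$class %in% .TESTIS_CLASSES &
        truth$derepressed_subtypes != ""
    isCore <- truth$class %in% .CORE_CLASSES &
        truth$derepressed_subtypes != ""
    g <- calls$genes
    candCalled <- truth$gene_symbol %in% g$gene_symbol[g$ct_candidate]
    coreCalled <- truth$gene_symbol %in% g$gene_symbol[g$core_ct]
    out$geneCT <- data.frame(
        flag = c("ct_candidate", "core_ct"),
        planted = c(sum(isCT), sum(isCore)),
        called = c(sum(candCalled), sum(coreCalled)),
        tp = c(sum(isCT & candCalled), sum(isCore & coreCalled)),
        stringsAsFactors = FALSE)
    out$geneCT$sensitivity <- ifelse(out$geneCT$planted > 0,
                                     out$geneCT$tp / out$geneCT$planted,
                                     NA_real_)
    out$geneCT$precision <- ifelse(out$geneCT$called > 0,
                                   out$geneCT$tp / out$geneCT$called,
                                   NA_real_)

    if (!is.null(cancerAggregate)) {
        truthPos <- psTruth$gene_symbol %in%
            truth$gene_symbol[truth$derepressed_subtypes != ""]
        calledPos <- cancerAggregate$any_ucndh[
            match(psTruth$probeset_id, cancerAggregate$probeset_id)]
        tp <- sum(truthPos & calledPos)
        out$ucndh <- data.frame(
            planted = sum(truthPos), called = sum(calledPos), tp = tp,
            sensitivity = if (sum(truthPos)) tp / sum(truthPos) else NA_real_,
            precision = if (sum(calledPos)) tp / sum(calledPos) else NA_real_)
    }
    structure(out, class = "ctRecovery")
}

#' @export
print.ctRecovery <- function(x, ...) {
    cat("Planted-truth recovery\n")
    if (!is.null(x$geneCT)) {
        for (i in seq_len(nrow(x$geneCT)))
            cat(sprintf("  %-12s gene-level: sensitivity %.3f, precision %.3f (%d planted)\n",
                        x$geneCT$flag[i], x$geneCT$sensitivity[i],
                        x$geneCT$precision[i], x$geneCT$planted[i]))
    }
    if (!is.null(x$classStats)) {
        keep <- x$classStats$planted > 0
        for (i in which(keep))
            cat(sprintf("  class %-6s sensitivity %.3f, precision %.3f (%d planted probesets)\n",
                        x$classStats$class_label[i],
                        x$classStats$sensitivity[i],
                        x$classStats$precision[i], x$classStats$planted[i]))
    }
    invisible(x)
}

## one row per (probeset, gene, planted class)
.expandTruth <- function(truth) {
    ps <- strsplit(truth$probesets, ",", fixed = TRUE)
    data.frame(probeset_id = unlist(ps, use.names = FALSE),
               gene_symbol = rep(truth$gene_symbol, lengths(ps)),
               class = rep(truth$class, lengths(ps)),
               stringsAsFactors = FALSE)
}
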