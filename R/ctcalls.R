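#' Intersect tissue and cancer screens into CT calls
#'
#' A probeset is a *CT candidate* when its tissue class is testis-restricted
#' (`SET`, `SEHET`, `PET` or `PEHET`) **and** it is UCNDH in at least one
#' cancer subtype; it is *core CT* when the tissue class is strictly
#' testis-specific (`SET` or `SEHET`) and UCNDH in at least one subtype.
#' Probeset calls are collapsed to gene level by the any-probeset rule: a
#' gene carries a flag iff at least one of its probesets does. Unmapped
#' probesets (empty gene symbol) are counted at probeset level only and
#' flagged `unmapped`.
#'
#' @param tissueRecords data.frame from [classifyTissue()].
#' @param cancerAggregate data.frame from [aggregateCancerFlags()].
#' @param geneSymbols named character vector probeset -> gene symbol ("" or
#'   missing = unmapped), e.g. from [geneSymbols()]; `NULL` = all unmapped.
#' @return list of class `ctCalls` with elements `probesets` (one row per
#'   probeset: `probeset_id`, `gene_symbol`, `tissue_class`, `any_ucndh`,
#'   `ct_candidate`, `core_ct`, `unmapped`) and `genes` (one row per mapped
#'   gene: `gene_symbol`, `n_probesets`, `n_ct_probesets`, `ct_candidate`,
#'   `core_ct`).
#' @export
callCT <- function(tissueRecords, cancerAggregate, geneSymbols = NULL) {
    if (!setequal(tissueRecords$probeset_id, cancerAggregate$probeset_id))
        stop("tissue and cancer tables cover different probeset sets")
    ids <- tissueRecords$probeset_id
    anyU <- cancerAggregate$any_ucndh[match(ids, cancerAggregate$probeset_id)]
    cls <- tissueRecords$class_label
    cand <- cls %in% .TESTIS_CLASSES & anyU
    core <- cls %in% .CORE_CLASSES & anyU
    sym <- rep("", length(ids))
    if (!is.null(geneSymbols)) {
        m <- geneSymbols[ids]
        m[is.na(m)] <- ""
        sym <- unname(m)
    }
    probesets <- data.frame(probeset_id = ids,
                            gene_symbol = sym,
                            tissue_class = cls,
                            any_ucndh = anyU,
                            ct_candidate = cand,
                            core_ct = core,
                            unmapped = sym == "",
                            stringsAsFactors = FALSE)
    mapped <- probesets[!probesets$unmapped, , drop = FALSE]
    if (nrow(mapped)) {
        f <- factor(mapped$gene_symbol, levels = unique(mapped$gene_symbol))
        genes <- data.frame(
            gene_symbol = levels(f),
            n_probesets = as.integer(table(f)),
            n_ct_probesets = as.integer(tapply(mapped$ct_candidate, f, sum)),
            ct_candidate = as.logical(tapply(mapped$ct_candidate, f, any)),
            core_ct = as.logical(tapply(mapped$core_ct, f, any)),
            stringsAsFactors = FALSE, row.names = NULL)
    } else {
        genes <- data.frame(gene_symbol = character(), n_probesets = integer(),
                            n_ct_probesets = integer(),
                            ct_candidate = logical(), core_ct = logical())
    }
    structure(list(probesets = probesets, genes = genes), class = "ctCalls")
}

## count probesets and distinct mapped genes in a probeset subset
.psGeneCount <- function(probesets, keep) {
    sub <- probesets[keep, , drop = FALSE]
    c(probesets = nrow(sub),
      genes = length(unique(sub$gene_symbol[!sub$unmapped])))
}

#' Flowchart-style count report
#'
#' Mirrors the screening flowchart: step 1 (testis-restricted probesets and
#' genes), step 2 (UCNDH in at least one subtype), their intersection (CT
#' candidates), the core subset, and the tissue class distribution.
#'
#' @param calls a `ctCalls` list from [callCT()].
#' @param tissueRecords data.frame from [classifyTissue()].
#' @return list of class `ctReport` with elements `n_probesets`, `step1`,
#'   `step2`, `ct_candidate`, `core_ct` (each `c(probesets=, genes=)`) and
#'   `class_distribution`.
#' @export
flowchartReport <- function(calls, tissueRecords) {
    ps <- calls$probesets
    out <- list(
        n_probesets = nrow(ps),
        step1_testis = .psGeneCount(ps, ps$tissue_class %in% .TESTIS_CLASSES),
        step2_ucndh = .psGeneCount(ps, ps$any_ucndh),
        ct_candidate = .psGeneCount(ps, ps$ct_candidate),
        core_ct = .psGeneCount(ps, ps$core_ct),
        class_distribution = summarizeClassDistribution(tissueRecords))
    structure(out, class = "ctReport")
}

#' @describeIn flowchartReport flat `key=value` lines for machine parsing.
#' @param report a `ctReport`.
#' @export
formatReport <- function(report) {
    kv <- c(sprintf("n_probesets=%d", report$n_probesets),
            unlist(lapply(c("step1_testis", "step2_ucndh", "ct_candidate",
                            "core_ct"), function(k)
                sprintf("%s_%s=%d", k, names(report[[k]]), report[[k]]))),
            sprintf("class_%s_count=%d", report$class_distribution$class_label,
                    report$class_distribution$count))
    unname(kv)
}

#' @export
print.ctReport <- function(x, ...) {
    cat("CT screening report\n")
    cat(sprintf("  probesets analyzed:        %d\n", x$n_probesets))
    fmt <- function(v) sprintf("%d probesets (%d genes)", v[1L], v[2L])
    cat(sprintf("  step 1, testis-restricted: %s\n", fmt(x$step1_testis)))
    cat(sprintf("  step 2, UCNDH >= 1 subtype: %s\n", fmt(x$step2_ucndh)))
    cat(sprintf("  intersection, CT candidates: %s\n", fmt(x$ct_candidate)))
    cat(sprintf("  core CT (SET/SEHET & UCNDH): %s\n", fmt(x$core_ct)))
    cat("  tissue class distribution:\n")
    cd <- x$class_distribution
    for (i in seq_len(nrow(cd)))
        cat(sprintf("    %-6s %6d  (%d%%)\n", cd$class_label[i], cd$count[i],
                    cd$percent[i]))
    invisible(x)
}

#' @export
print.ctCalls <- function(x, ...) {
    cat(sprintf("CT calls: %d probesets, %d mapped genes; %d candidate / %d core probesets\n",
                nrow(x$probesets), nrow(x$genes), sum(x$probesets$ct_candidate),
                sum(x$probesets$core_ct)))
    invisible(x)
}

#' @rdname callCT
#' @param calls a `ctCalls` list.
#' @param path output path for the probeset-level table; the gene-level table
#'   is written alongside with suffix `_genes.tsv`.
#' @export
writeCTCalls <- function(calls, path) {
    .writeTsv(calls$probesets[c("probeset_id", "gene_symbol", "tissue_class",
                                "any_ucndh", "ct_candidate", "core_ct")],
              path)
    .writeTsv(calls$genes, sub("\\.tsv$", "_genes.tsv", path))
    invisible(path)
}
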