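## End-to-end screen: thresholds -> summaries -> contrasts -> tissue classes
## -> cancer flags -> CT calls -> flowchart report, with every stage table
## written to an output directory plus a manifest that records parameters and
## input checksums. Outputs contain no timestamps, so identical inputs give
## byte-identical output trees.

## contrast-independent variance prior: per-probeset within-group pooled
## variance across every group with replication
.globalPrior <- function(x, groups) {
    idx <- split(seq_len(ncol(x)), groups)
    idx <- idx[lengths(idx) >= 2L]
    if (!length(idx)) stop("no group with >= 2 samples: cannot fit a prior")
    rss <- 0; df <- 0
    for (j in idx) {
        sub <- x[, j, drop = FALSE]
        rss <- rss + rowSums((sub - rowMeans(sub))^2)
        df <- df + length(j) - 1L
    }
    estimateVariancePrior(rss / df, df)
}

## two-group contrast that degrades gracefully when one side has < 2 samples
.contrast <- function(x, aCols, bCols, fallbackPrior) {
    a <- x[, aCols, drop = FALSE]
    b <- x[, bCols, drop = FALSE]
    if (length(aCols) < 2L || length(bCols) < 2L)
        moderatedTTest(a, b, prior = fallbackPrior,
                       smallGroupFallback = TRUE)
    else moderatedTTest(a, b)
}

#' Run the full CT screen
#'
#' Executes every stage on a [CTExperiment-class] (or the three input TSVs):
#' global thresholds, per-group summaries, the target-vs-pooled-somatic
#' moderated-t contrast, tissue-specificity classification, one
#' cancer-vs-matched-normal contrast per cancer subtype, cancer-upregulation
#' flags, CT-candidate/core-CT intersection with gene collapsing, and the
#' flowchart count report. All stage tables are written to `outDir` together
#' with a manifest recording parameters, thresholds, the percentile
#' convention and input checksums.
#'
#' Thresholds are recomputed from the matrix by default; pass a
#' [GlobalThresholds-class] to pin them (e.g. the reference compendium's
#' 5.5/4.4/6.9, or [tierThresholds()] for simulated panels). Contrasts whose
#' groups lack replication fall back to the prior-only test using a
#' variance prior fitted across all replicated groups, and are flagged.
#'
#' @param experiment a [CTExperiment-class], or `NULL` to read from paths.
#' @param matrixPath,samplePath,probesetPath input TSVs, used when
#'   `experiment` is `NULL`.
#' @param outDir output directory (created; existing files overwritten).
#' @param params a [ctParams()] list.
#' @param thresholds optional [GlobalThresholds-class] override.
#' @param ctList optional character vector of probeset ids for an additional
#'   class-distribution summary (e.g. CT-database probesets), written as
#'   `ct_list_distribution.tsv`.
#' @param verbose log per-stage row counts to the message stream.
#' @return invisibly, a list with every stage result: `experiment`,
#'   `thresholds`, `summaries`, `tissueContrast`, `tissueRecords`,
#'   `cancerContrasts`, `cancerRecords`, `cancerAggregate`, `calls`,
#'   `report`.
#' @export
runPipeline <- function(experiment = NULL, matrixPath = NULL,
                        samplePath = NULL, probesetPath = NULL,
                        outDir, params = ctParams(), thresholds = NULL,
                        ctList = NULL, verbose = TRUE) {
    say <- function(...) if (verbose) message(sprintf(...))
    inputSums <- character()
    if (is.null(experiment)) {
        if (is.null(matrixPath) || is.null(samplePath))
            stop("provide either an experiment or matrixPath + samplePath")
        experiment <- readCTExperiment(matrixPath, samplePath, probesetPath)
        paths <- c(matrixPath, samplePath, probesetPath)
        inputSums <- tools::md5sum(paths)
    }
    stopifnot(is(experiment, "CTExperiment"))
    validObject(experiment)
    x <- SummarizedExperiment::assay(experiment, "exprs")
    say("input: %d probesets x %d samples", nrow(x), ncol(x))

    pinned <- !is.null(thresholds)
    if (!pinned) thresholds <- computeGlobalThresholds(x)
    say("thresholds: bec %.3f, qLow %.3f, qHigh %.3f%s", bec(thresholds),
        qLow(thresholds), qHigh(thresholds),
        if (pinned) " (pinned)" else " (recomputed)")

    groups <- sampleGroups(experiment)
    summaries <- groupSummaries(experiment)
    prior <- .globalPrior(x, groups)

    cat <- groupCategories(experiment)
    tCols <- which(groups %in% names(cat)[cat == "TARGET"])
    nCols <- which(groups %in% names(cat)[cat == "NORMAL"])
    tissueContrast <- .contrast(x, tCols, nCols, prior)
    tissueRecords <- classifyTissue(summaries, experiment, thresholds,
                                    tissueContrast, params)
    say("tissue classes: %s",
        paste(sprintf("%s=%d", names(table(tissueRecords$class_label)),
                      table(tissueRecords$class_label)), collapse = " "))

    mn <- matchedNormals(experiment)
    cancerContrasts <- lapply(names(mn), function(cg)
        .contrast(x, which(groups == cg), which(groups == mn[[cg]]), prior))
    names(cancerContrasts) <- names(mn)
    cancerRecords <- classifyCancer(summaries, experiment, thresholds,
                                    cancerContrasts, params)
    cancerAggregate <- aggregateCancerFlags(cancerRecords)
    say("cancer flags: %d probesets UCNDH in >= 1 of %d subtypes",
        sum(cancerAggregate$any_ucndh), length(mn))

    calls <- callCT(tissueRecords, cancerAggregate, geneSymbols(experiment))
    report <- flowchartReport(calls, tissueRecords)
    say("CT candidates: %d probesets (%d genes); core: %d probesets (%d genes)",
        report$ct_candidate[1L], report$ct_candidate[2L],
        report$core_ct[1L], report$core_ct[2L])

    ## ---- outputs ----
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(outDir, f)
    .writeTsv(data.frame(key = c("bec", "q_low", "q_high"),
                         value = c(bec(thresholds), qLow(thresholds),
                                   qHigh(thresholds))), out("thresholds.tsv"))
    writeContrastResult(tissueContrast, out("tissue_contrast.tsv"))
    writeTissueClasses(tissueRecords, out("tissue_classes.tsv"))
    for (cg in names(cancerContrasts))
        writeContrastResult(cancerContrasts[[cg]],
                            out(sprintf("cancer_contrast_%s.tsv", cg)))
    writeCancerClasses(cancerRecords, out("cancer_classes.tsv"))
    .writeTsv(cancerAggregate, out("cancer_aggregate.tsv"))
    writeCTCalls(calls, out("ct_calls.tsv"))
    if (!is.null(ctList))
        .writeTsv(summarizeClassDistribution(tissueRecords, ctList),
                  out("ct_list_distribution.tsv"))
    con <- file(out("report.txt"), open = "wb")
    sink(con); print(report); sink()
    close(con)
    con <- file(out("report_kv.txt"), open = "wb")
    writeLines(formatReport(report), con)
    close(con)

    manifest <- c(
        sprintf("package=CTscreen %s",
                as.character(utils::packageVersion("CTscreen"))),
        sprintf("fold_change_log2=%s", params$foldChangeLog2),
        sprintf("q_cutoff=%s", params$qCutoff),
        sprintf("exception_budget=%d", params$exceptionBudget),
        sprintf("ie_range=%d-%d", params$ieRange[1L], params$ieRange[2L]),
        sprintf("thresholds=%s", if (pinned) "pinned" else "recomputed"),
        sprintf("bec=%s", bec(thresholds)),
        sprintf("q_low=%s", qLow(thresholds)),
        sprintf("q_high=%s", qHigh(thresholds)),
        "percentile_convention=linear interpolation (stats::quantile type 7)",
        "group_summary=median",
        sprintf("prior_d0=%s", priorDf(prior)),
        sprintf("prior_s0_sq=%s", priorVar(prior)),
        if (length(inputSums))
            sprintf("input_md5_%s=%s", basename(names(inputSums)), inputSums))
    con <- file(out("manifest.txt"), open = "wb")
    writeLines(manifest, con)
    close(con)

    invisible(list(experiment = experiment, thresholds = thresholds,
                   summaries = summaries, tissueContrast = tissueContrast,
                   tissueRecords = tissueRecords,
                   cancerContrasts = cancerContrasts,
                   cancerRecords = cancerRecords,
                   cancerAggregate = cancerAggregate,
                   calls = calls, report = report))
}
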