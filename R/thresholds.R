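#' Compute the global expression thresholds of a matrix
#'
#' Pools every entry of the log2 expression matrix and takes its median as the
#' background expression cutoff (BEC) and its 25th/75th percentiles as the
#' lower/upper bounds of the expression-confidence window. Values below the
#' lower quartile are regarded as undetectable and values in the upper
#' quartile as high expression. Percentiles use linear interpolation between
#' closest ranks (`stats::quantile` type 7); the convention is recorded in the
#' run manifest so results are reproducible across implementations.
#'
#' On the reference testis/soma/cancer compendium this yields BEC 5.5 with
#' quartile bounds 4.4 and 6.9; the values are properties of each dataset and
#' are recomputed here (use [globalThresholds()] to pin them).
#'
#' @param x a [CTExperiment-class] or a numeric matrix of log2 intensities.
#' @return a [GlobalThresholds-class].
#' @examples
#' m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
#' computeGlobalThresholds(m)
#' @export
computeGlobalThresholds <- function(x) {
    if (is(x, "SummarizedExperiment"))
        x <- SummarizedExperiment::assay(x, "exprs")
    x <- .checkExpressionMatrix(x)
    qs <- unname(quantile(as.vector(x), probs = c(0.25, 0.5, 0.75),
                          type = 7, names = FALSE))
    globalThresholds(bec = qs[2L], qLow = qs[1L], qHigh = qs[3L])
}

#' Per-(probeset, group) summary signal
#'
#' Summarizes replicate samples of each group by their median, the robust
#' per-tissue signal every downstream filter consumes. The result is invariant
#' to sample order within groups.
#'
#' @param x a [CTExperiment-class], or a numeric matrix of log2 intensities
#'   (probesets x samples) if `groups` is supplied.
#' @param groups named character vector mapping sample ids to group ids; taken
#'   from `x` when it is a `CTExperiment`.
#' @return numeric matrix, probesets x groups.
#' @export
groupSummaries <- function(x, groups = NULL) {
    if (is(x, "SummarizedExperiment")) {
        groups <- sampleGroups(x)
        x <- SummarizedExperiment::assay(x, "exprs")
    }
    x <- .checkExpressionMatrix(x)
    if (is.null(groups) || is.null(names(groups)))
        stop("groups must be a named sample_id -> group_id vector")
    if (!setequal(names(groups), colnames(x)))
        stop("groups must cover exactly the matrix samples")
    groups <- groups[colnames(x)]
    idx <- split(seq_len(ncol(x)), factor(groups, levels = unique(groups)))
    if (any(lengths(idx) == 0L)) stop("group with zero samples")
    out <- vapply(idx, function(j) {
        if (length(j) == 1L) x[, j] else apply(x[, j, drop = FALSE], 1L, median)
    }, numeric(nrow(x)))
    dimnames(out) <- list(rownames(x), names(idx))
    out
}
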