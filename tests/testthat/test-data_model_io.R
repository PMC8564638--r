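test_that("expression matrix TSV round-trips and write/read is byte-stable", {
    set.seed(11)
    x <- round(matrix(rnorm(12, 5), 3, 4,
                      dimnames = list(paste0("ps", 1:3), paste0("s", 1:4))),
               4)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeExpressionMatrix(x, f1)
    y <- readExpressionMatrix(f1)
    expect_identical(dimnames(y), dimnames(x))
    expect_equal(y, x)
    writeExpressionMatrix(y, f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
})

test_that("malformed expression matrices are rejected with informative errors", {
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("probeset_id\ts1\ts1", "a\t1\t2", "b\t3\t4"), f)
    expect_error(readExpressionMatrix(f), "s1")
    writeLines(c("probeset_id\ts1\ts2", "a\t1\tx", "b\t3\t4"), f)
    expect_error(readExpressionMatrix(f))
    writeLines(c("s1\ts2", "a\t1\t2"), f)
    expect_error(readExpressionMatrix(f), "probeset_id")
    m <- matrix(c(1, NA, 3, 4), 2, 2,
                dimnames = list(c("a", "b"), c("s1", "s2")))
    expect_error(CTExperiment(m, data.frame()), "missing|columns")
})

test_that("sample annotation validation enforces categories and matching", {
    ann <- data.frame(sample_id = c("a", "b", "c", "d"),
                      group_id = c("t", "n1", "n2", "c1"),
                      category = c("TARGET", "NORMAL", "NORMAL", "CANCER"),
                      matched_normal = c("", "", "", "n1"))
    expect_silent(CTscreen:::.checkSampleAnnotation(ann))
    bad <- ann; bad$matched_normal[4] <- "t"   # matched to a TARGET group
    expect_error(CTscreen:::.checkSampleAnnotation(bad), "matched_normal")
    bad <- ann; bad$category[1] <- "TISSUE"
    expect_error(CTscreen:::.checkSampleAnnotation(bad), "category")
    bad <- ann; bad$matched_normal[4] <- "nope"
    expect_error(CTscreen:::.checkSampleAnnotation(bad), "c1")
    f <- withr::local_tempfile(fileext = ".tsv")
    writeSampleAnnotation(ann, f)
    expect_equal(readSampleAnnotation(f)$group_id, ann$group_id)
})

test_that("CTExperiment accessors expose the group structure", {
    ex <- tinyExperiment()
    expect_s4_class(ex, "CTExperiment")
    expect_setequal(targetGroups(ex), c("tg1", "tg2"))
    expect_length(normalGroups(ex), 3)
    expect_equal(matchedNormals(ex), c(cg1 = "ng1", cg2 = "ng2"))
    expect_equal(unname(sampleGroups(ex)[1]), "tg1")
    expect_true(all(geneSymbols(ex) != ""))
    ## probeset annotation referencing unknown probesets is rejected
    expect_error(CTExperiment(
        SummarizedExperiment::assay(ex, "exprs"),
        data.frame(sample_id = colnames(ex),
                   group_id = sampleGroups(ex),
                   category = SummarizedExperiment::colData(ex)$category,
                   matched_normal = SummarizedExperiment::colData(ex)$matched_normal),
        data.frame(probeset_id = "nope", gene_symbol = "G")),
        "unknown probeset")
})

test_that("global thresholds match a brute-force percentile oracle", {
    m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
    thr <- computeGlobalThresholds(m)
    ## linear interpolation between closest ranks, computed by hand:
    ## h = (n-1)p + 1 on the sorted pooled values
    brute <- function(v, p) {
        v <- sort(v); h <- (length(v) - 1) * p + 1
        lo <- floor(h); hi <- ceiling(h)
        v[lo] + (h - lo) * (v[hi] - v[lo])
    }
    expect_equal(bec(thr), brute(1:8, 0.5))
    expect_equal(qLow(thr), brute(1:8, 0.25))
    expect_equal(qHigh(thr), brute(1:8, 0.75))
    ## degenerate distribution and permutation invariance
    const <- matrix(5, 3, 3, dimnames = list(letters[1:3], LETTERS[1:3]))
    thr2 <- computeGlobalThresholds(const)
    expect_equal(c(bec(thr2), qLow(thr2), qHigh(thr2)), c(5, 5, 5))
    set.seed(2)
    r <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("p", 1:8),
                                                 paste0("s", 1:5)))
    perm <- r[sample(8), sample(5)]
    expect_equal(computeGlobalThresholds(r), computeGlobalThresholds(perm))
    expect_true(qLow(thr) <= bec(thr) && bec(thr) <= qHigh(thr))
})

test_that("group summaries are per-group medians, order-invariant", {
    x <- matrix(c(4, 6, 8, 1, 2, 3), 2, 3, byrow = TRUE,
                dimnames = list(c("p1", "p2"), c("s1", "s2", "s3")))
    g <- c(s1 = "g1", s2 = "g1", s3 = "g1")
    expect_equal(unname(groupSummaries(x, g)[, "g1"]), c(6, 2))
    ## single-sample group passes through
    g2 <- c(s1 = "g1", s2 = "g1", s3 = "g2")
    expect_equal(unname(groupSummaries(x, g2)["p1", "g2"]), 8)
    ## brute-force per-cell check on a random fixture
    set.seed(3)
    x <- matrix(rnorm(20 * 12), 20, 12,
                dimnames = list(paste0("p", 1:20), paste0("s", 1:12)))
    g <- setNames(rep(paste0("g", 1:4), each = 3), colnames(x))
    sm <- groupSummaries(x, g)
    for (i in 1:20) for (gg in paste0("g", 1:4))
        expect_equal(sm[i, gg], median(x[i, names(g)[g == gg]]))
    ## invariant to sample order within groups
    o <- c(2, 1, 3, 6, 5, 4, 9, 8, 7, 12, 11, 10)
    expect_equal(groupSummaries(x[, o], g[o]), sm)
})
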