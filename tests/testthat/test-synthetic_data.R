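test_that("generated dataset has the dimensions the config implies", {
    cfg <- simulationConfig(seed = 42)
    sim <- generateDataset(cfg)
    ex <- sim$experiment
    nSamples <- cfg$nNormalTissues * cfg$samplesPerGroup +
        cfg$nTargetGroups * cfg$targetSamplesPerGroup +
        cfg$nCancerSubtypes * cfg$samplesPerGroup
    expect_equal(ncol(ex), nSamples)
    ## probesets: sum over genes of their planted probeset counts
    psFromTruth <- sum(lengths(strsplit(sim$truth$probesets, ",")))
    expect_equal(nrow(ex), psFromTruth)
    expect_equal(nrow(sim$truth), sum(cfg$classCounts))
    ## every truth probeset exists in the matrix
    expect_true(all(unlist(strsplit(sim$truth$probesets, ",")) %in%
                    rownames(ex)))
    ## simulator-emitted annotation always validates
    cd <- SummarizedExperiment::colData(ex)
    expect_silent(CTscreen:::.checkSampleAnnotation(
        data.frame(sample_id = rownames(cd), group_id = cd$group_id,
                   category = cd$category,
                   matched_normal = cd$matched_normal)))
})

test_that("identical seeds give byte-identical TSV output", {
    d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
    writeDataset(generateDataset(simulationConfig(seed = 99)), d1)
    writeDataset(generateDataset(simulationConfig(seed = 99)), d2)
    for (f in list.files(d1)) {
        expect_identical(readBin(file.path(d1, f), "raw",
                                 file.size(file.path(d1, f))),
                         readBin(file.path(d2, f), "raw",
                                 file.size(file.path(d2, f))),
                         label = f)
    }
    ## and a different seed changes the matrix
    d3 <- withr::local_tempdir()
    writeDataset(generateDataset(simulationConfig(seed = 100)), d3)
    expect_false(identical(
        readBin(file.path(d1, "matrix.tsv"), "raw",
                file.size(file.path(d1, "matrix.tsv"))),
        readBin(file.path(d3, "matrix.tsv"), "raw",
                file.size(file.path(d3, "matrix.tsv")))))
})

test_that("planted patterns respect their defining structure", {
    cfg <- simulationConfig(seed = 7)
    sim <- generateDataset(cfg)
    ex <- sim$experiment
    sm <- groupSummaries(ex)
    thr <- sim$thresholds
    truthPs <- CTscreen:::.expandTruth(sim$truth)
    ng <- normalGroups(ex)
    ## pooled median lies between the background and expressed modes
    med <- median(SummarizedExperiment::assay(ex, "exprs"))
    expect_gt(med, cfg$backgroundMean)
    expect_lt(med, cfg$expressedMean)
    ## planted UE probesets are detected in (essentially) every somatic
    ## tissue; group medians carry sampling noise, so bound the rate
    ue <- truthPs$probeset_id[truthPs$class == "UE"]
    expect_gt(mean(sm[ue, ng] > bec(thr)), 0.999)
    ## planted BACKGROUND probesets are detected (essentially) nowhere
    bg <- truthPs$probeset_id[truthPs$class == "BACKGROUND"]
    expect_gt(mean(sm[bg, ] < bec(thr)), 0.999)
    ## every planted CT gene has at least one derepressed subtype
    ct <- sim$truth$class %in% c("SET", "SEHET", "PET", "PEHET")
    expect_true(all(sim$truth$derepressed_subtypes[ct] != ""))
    ## derepressed subtypes of SET/SEHET genes show expressed cancer signal
    ## over a silent matched normal
    mn <- matchedNormals(ex)
    core <- sim$truth[sim$truth$class %in% c("SET", "SEHET"), ]
    for (i in seq_len(min(10, nrow(core)))) {
        ps <- strsplit(core$probesets[i], ",")[[1]][1]
        for (cg in strsplit(core$derepressed_subtypes[i], ",")[[1]]) {
            expect_gt(sm[ps, cg], bec(thr))
            expect_lt(sm[ps, mn[[cg]]], bec(thr))
        }
    }
})

test_that("a configuration without planted CT genes yields zero candidates", {
    cfg <- simulationConfig(classCounts = c(IE = 10L, UE = 10L,
                                            BACKGROUND = 30L),
                            seed = 5)
    sim <- generateDataset(cfg)
    expect_true(all(sim$truth$derepressed_subtypes == ""))
    res <- runPipeline(sim$experiment, outDir = withr::local_tempdir(),
                       thresholds = sim$thresholds, verbose = FALSE)
    expect_equal(sum(res$calls$probesets$ct_candidate), 0)
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(nCancerSubtypes = 50, nNormalTissues = 45),
                 "more cancer subtypes")
    expect_error(simulationConfig(expressedMean = 4.0), "ordered")
    expect_error(simulationConfig(backgroundSd = 0), "sds")
    expect_error(simulationConfig(derepressionProb = 1.5), "derepressionProb")
    expect_error(simulationConfig(classCounts = c(FOO = 5L)), "classCounts")
})

test_that("recovery scoring matches a brute-force tally", {
    truth <- data.frame(
        gene_symbol = c("G1", "G2", "G3"),
        class = c("SET", "UE", "PET"),
        probesets = c("a,b", "c", "d"),
        derepressed_subtypes = c("c1", "", "c2"))
    tr <- mkTissue(c("SET", "PET", "UE", "PET"), ids = c("a", "b", "c", "d"))
    agg <- mkAgg(c(TRUE, TRUE, FALSE, FALSE), ids = c("a", "b", "c", "d"))
    sym <- c(a = "G1", b = "G1", c = "G2", d = "G3")
    calls <- callCT(tr, agg, sym)
    rec <- evaluateRecovery(truth, calls, tr, agg)
    ## SET: 2 planted probesets (a, b), one called SET -> sensitivity 1/2
    cs <- rec$classStats
    expect_equal(cs$sensitivity[cs$class_label == "SET"], 0.5)
    expect_equal(rec$confusion["SET", "PET"], 1, ignore_attr = TRUE)
    ## gene-level: candidates planted G1, G3; called G1 only
    gc <- rec$geneCT
    expect_equal(gc$sensitivity[gc$flag == "ct_candidate"], 0.5)
    expect_equal(gc$precision[gc$flag == "ct_candidate"], 1.0)
    ## core: planted G1, called G1
    expect_equal(gc$sensitivity[gc$flag == "core_ct"], 1.0)
    ## ucndh probeset-level: truth-positive a,b,d; called a,b
    expect_equal(rec$ucndh$sensitivity, 2 / 3)
    expect_equal(rec$ucndh$precision, 1.0)
    ## perfect calls give sensitivity = precision = 1 for populated classes
    tr2 <- mkTissue(c("SET", "SET", "UE", "PET"),
                    ids = c("a", "b", "c", "d"))
    agg2 <- mkAgg(c(TRUE, TRUE, FALSE, TRUE), ids = c("a", "b", "c", "d"))
    rec2 <- evaluateRecovery(truth, callCT(tr2, agg2, sym), tr2, agg2)
    cs2 <- rec2$classStats[rec2$classStats$planted > 0, ]
    expect_true(all(cs2$sensitivity == 1))
    expect_true(all(cs2$precision == 1))
})
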