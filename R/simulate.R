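#' Simulation configuration
#'
#' Parameters of the planted-truth generator, which emulates the structure of
#' a testis/soma/cancer expression compendium: many normal somatic tissue
#' groups, a few target (testis/germ-cell) groups with minimal replication,
#' and cancer subtypes each matched to a tissue of origin. Log2 intensities
#' are drawn from Gaussian modes on the log2 scale: a background mode, an
#' expressed mode, and a highly-expressed mode used for the target signal of
#' planted SEHET/PEHET genes (the upper of the expression-confidence tiers).
#' Per-sample values add independent Gaussian measurement noise, so the total
#' per-sample spread around a planted tier mean is
#' `sqrt(tierSd^2 + noiseSd^2)`.
#'
#' Planted classes realize their defining pattern exactly at the mean level:
#' e.g. a planted PET gene has its exception tissues (1-3, uniform) drawn
#' from the expressed mode and every other somatic tissue from background.
#' Planted CT genes (SET/SEHET core, PET/PEHET candidate) are derepressed in
#' each cancer subtype independently with probability `derepressionProb`,
#' restricted to subtypes whose tissue of origin is background for that gene;
#' when the draw selects none, one eligible subtype is forced so every
#' planted CT gene is genuinely a CT gene. Non-derepressed cancer subtypes
#' inherit the expression state of their tissue of origin.
#'
#' @param nNormalTissues number of NORMAL somatic groups (45).
#' @param nTargetGroups number of TARGET germ-cell/testis groups (4).
#' @param nCancerSubtypes number of CANCER groups (10), matched in order to
#'   the first `nCancerSubtypes` normal tissues.
#' @param samplesPerGroup replicates per NORMAL/CANCER group (3).
#' @param targetSamplesPerGroup replicates per TARGET group (2; germ-cell
#'   compartments are typically minimally replicated).
#' @param backgroundMean,backgroundSd background mode, log2 units (4.5, 0.5).
#' @param expressedMean,expressedSd expressed mode (7.5, 0.6).
#' @param highMean,highSd highly-expressed mode (10.0, 0.6).
#' @param noiseSd per-sample measurement noise sd (0.3).
#' @param classCounts named integer vector of planted gene counts for classes
#'   `SET`, `SEHET`, `PET`, `PEHET`, `IE`, `UE`, `BACKGROUND`.
#' @param probesetsPerGeneMax probesets per gene drawn uniformly from
#'   `1:probesetsPerGeneMax` (3).
#' @param derepressionProb per-(CT gene, subtype) derepression probability
#'   (0.3).
#' @param ieDetectRange somatic detection count range for planted IE genes
#'   (4-10, uniform).
#' @param petExceptionRange exception tissue count range for planted PET and
#'   PEHET genes (1-3, uniform).
#' @param seed integer random seed, or `NULL`.
#' @return validated list of class `simulationConfig`.
#' @export
simulationConfig <- function(nNormalTissues = 45L, nTargetGroups = 4L,
                             nCancerSubtypes = 10L, samplesPerGroup = 3L,
                             targetSamplesPerGroup = 2L,
                             backgroundMean = 4.5, backgroundSd = 0.5,
                             expressedMean = 7.5, expressedSd = 0.6,
                             highMean = 10.0, highSd = 0.6, noiseSd = 0.3,
                             classCounts = c(SET = 50L, SEHET = 50L,
                                             PET = 30L, PEHET = 30L,
                                             IE = 40L, UE = 60L,
                                             BACKGROUND = 240L),
                             probesetsPerGeneMax = 3L,
                             derepressionProb = 0.3,
                             ieDetectRange = c(4L, 10L),
                             petExceptionRange = c(1L, 3L),
                             seed = NULL) {
    cc <- c(SET = 0L, SEHET = 0L, PET = 0L, PEHET = 0L, IE = 0L, UE = 0L,
            BACKGROUND = 0L)
    if (is.null(names(classCounts)) ||
        !all(names(classCounts) %in% names(cc)))
        stop("classCounts names must be among ",
             paste(names(cc), collapse = ", "))
    cc[names(classCounts)] <- as.integer(classCounts)
    cfg <- list(nNormalTissues = as.integer(nNormalTissues),
                nTargetGroups = as.integer(nTargetGroups),
                nCancerSubtypes = as.integer(nCancerSubtypes),
                samplesPerGroup = as.integer(samplesPerGroup),
                targetSamplesPerGroup = as.integer(targetSamplesPerGroup),
                backgroundMean = backgroundMean, backgroundSd = backgroundSd,
                expressedMean = expressedMean, expressedSd = expressedSd,
                highMean = highMean, highSd = highSd, noiseSd = noiseSd,
                classCounts = cc,
                probesetsPerGeneMax = as.integer(probesetsPerGeneMax),
                derepressionProb = derepressionProb,
                ieDetectRange = as.integer(ieDetectRange),
                petExceptionRange = as.integer(petExceptionRange),
                seed = if (is.null(seed)) NULL else as.integer(seed))
    with(cfg, {
        if (nNormalTissues < 1L || nTargetGroups < 1L)
            stop("need at least one NORMAL and one TARGET group")
        if (nCancerSubtypes > nNormalTissues)
            stop("more cancer subtypes than normal tissues to match")
        if (samplesPerGroup < 1L || targetSamplesPerGroup < 1L)
            stop("groups need at least one sample")
        if (!(expressedMean > backgroundMean) || !(highMean >= expressedMean))
            stop("modes must be ordered: background < expressed <= high")
        if (any(c(backgroundSd, expressedSd, highSd) <= 0) || noiseSd < 0)
            stop("mode sds must be > 0 and noiseSd >= 0")
        if (any(cc < 0L) || sum(cc) < 2L)
            stop("classCounts must be nonnegative and sum to >= 2")
        if (derepressionProb < 0 || derepressionProb > 1)
            stop("derepressionProb must be in [0, 1]")
        if (ieDetectRange[1L] < 1L || ieDetectRange[2L] > nNormalTissues ||
            petExceptionRange[1L] < 1L)
            stop("detection/exception ranges out of bounds")
    })
    structure(cfg, class = "simulationConfig")
}

#' Tier-boundary thresholds of a simulation
#'
#' The detection and high-expression cutoffs implied by the planted tiers:
#' BEC at the midpoint of the background and expressed modes, the upper
#' cutoff at the midpoint of the expressed and highly-expressed modes, and
#' the lower cutoff at the background mode. On a whole-genome matrix the
#' pooled quartiles fall at these boundaries because roughly half the values
#' are expressed; a targeted simulated panel is mostly silent, so its pooled
#' quantiles sit inside the background mode and the tier boundaries are the
#' faithful equivalents to use when classifying simulated data.
#'
#' @param config a [simulationConfig()].
#' @return a [GlobalThresholds-class].
#' @export
tierThresholds <- function(config) {
    globalThresholds(bec = (config$backgroundMean + config$expressedMean) / 2,
                     qLow = config$backgroundMean,
                     qHigh = (config$expressedMean + config$highMean) / 2)
}

#' Generate a planted-truth dataset
#'
#' Draws an expression matrix, sample/probeset annotations and the truth
#' table of planted class memberships under `config`. Identical seeds give
#' identical output.
#'
#' @param config a [simulationConfig()].
#' @param seed overrides `config$seed` when given.
#' @return list of class `ctSimulation` with elements `experiment`
#'   ([CTExperiment-class]), `truth` (data.frame: `gene_symbol`, `class`,
#'   `probesets` comma-joined, `derepressed_subtypes` comma-joined or ""),
#'   `thresholds` ([tierThresholds()]) and `config`.
#' @export
generateDataset <- function(config = simulationConfig(), seed = NULL) {
    if (!inherits(config, "simulationConfig"))
        stop("config must come from simulationConfig()")
    if (is.null(seed)) seed <- config$seed
    if (!is.null(seed)) set.seed(seed)

    normals <- sprintf("normal_%02d", seq_len(config$nNormalTissues))
    targets <- sprintf("target_%d", seq_len(config$nTargetGroups))
    cancers <- sprintf("cancer_%02d", seq_len(config$nCancerSubtypes))
    origin <- setNames(normals[seq_len(config$nCancerSubtypes)], cancers)

    groups <- c(targets, normals, cancers)
    gcat <- c(rep("TARGET", length(targets)), rep("NORMAL", length(normals)),
              rep("CANCER", length(cancers)))
    gsize <- ifelse(gcat == "TARGET", config$targetSamplesPerGroup,
                    config$samplesPerGroup)
    ann <- data.frame(
        sample_id = unlist(mapply(function(g, n) sprintf("%s_s%d", g,
                                                         seq_len(n)),
                                  groups, gsize, SIMPLIFY = FALSE),
                           use.names = FALSE),
        group_id = rep(groups, gsize),
        category = rep(gcat, gsize),
        matched_normal = rep(ifelse(gcat == "CANCER",
                                    unname(origin[groups]), ""), gsize),
        stringsAsFactors = FALSE)
    ann$matched_normal[is.na(ann$matched_normal)] <- ""
    ann$label <- ann$group_id

    cc <- config$classCounts
    classes <- rep(names(cc), cc)
    nGenes <- length(classes)
    genes <- sprintf("GENE%04d", seq_len(nGenes))

    ## tier index per (gene, group): 1 background, 2 expressed, 3 high
    tier <- matrix(1L, nGenes, length(groups),
                   dimnames = list(genes, groups))
    derep <- vector("list", nGenes)
    for (i in seq_len(nGenes)) {
        cl <- classes[i]
        if (cl %in% c("SET", "PET"))  tier[i, targets] <- 2L
        if (cl %in% c("SEHET", "PEHET")) tier[i, targets] <- 3L
        if (cl %in% c("PET", "PEHET")) {
            k <- sample(config$petExceptionRange[1L]:
                        config$petExceptionRange[2L], 1L)
            tier[i, sample(normals, k)] <- 2L
        }
        if (cl == "IE") {
            k <- sample(config$ieDetectRange[1L]:config$ieDetectRange[2L], 1L)
            tier[i, sample(normals, k)] <- 2L
        }
        if (cl == "UE") tier[i, c(targets, normals)] <- 2L
        ## cancer subtypes inherit the state of their tissue of origin
        tier[i, cancers] <- tier[i, origin[cancers]]
        if (cl %in% c("SET", "SEHET", "PET", "PEHET") &&
            length(cancers)) {
            eligible <- cancers[tier[i, origin[cancers]] == 1L]
            dr <- eligible[runif(length(eligible)) < config$derepressionProb]
            if (!length(dr) && length(eligible))
                dr <- sample(eligible, 1L)
            tier[i, dr] <- 2L
            derep[[i]] <- dr
        } else derep[[i]] <- character()
    }

    nps <- sample.int(config$probesetsPerGeneMax, nGenes, replace = TRUE)
    psGene <- rep(seq_len(nGenes), nps)
    psIds <- sprintf("%s_ps%d", genes[psGene],
                     unlist(lapply(nps, seq_len), use.names = FALSE))

    tierMeans <- c(config$backgroundMean, config$expressedMean,
                   config$highMean)
    tierSds <- sqrt(c(config$backgroundSd, config$expressedSd,
                      config$highSd)^2 + config$noiseSd^2)
    psTier <- tier[psGene, , drop = FALSE]      # probesets x groups
    sampTier <- psTier[, ann$group_id, drop = FALSE]  # probesets x samples
    vals <- rnorm(length(sampTier), mean = tierMeans[sampTier],
                  sd = tierSds[sampTier])
    x <- matrix(vals, nrow(sampTier), ncol(sampTier),
                dimnames = list(psIds, ann$sample_id))
    x <- round(x, 4L)   # match the TSV dialect so files round-trip exactly

    pa <- data.frame(probeset_id = psIds, gene_symbol = genes[psGene],
                     stringsAsFactors = FALSE)
    truth <- data.frame(
        gene_symbol = genes,
        class = classes,
        probesets = vapply(split(psIds, factor(psGene,
                                               levels = seq_len(nGenes))),
                           paste, "", collapse = ","),
        derepressed_subtypes = vapply(derep, paste, "", collapse = ","),
        stringsAsFactors = FALSE, row.names = NULL)

    structure(list(experiment = CTExperiment(x, ann, pa),
                   truth = truth,
                   thresholds = tierThresholds(config),
                   config = config),
              class = "ctSimulation")
}

#' Write a simulated dataset as TSV files
#'
#' Emits `matrix.tsv`, `samples.tsv`, `probesets.tsv`, `truth.tsv` and the
#' resolved configuration as `config.txt` (flat `key=value` lines) into
#' `dir`.
#'
#' @param sim a `ctSimulation` from [generateDataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeDataset <- function(sim, dir) {
    if (!inherits(sim, "ctSimulation")) stop("sim must be a ctSimulation")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ex <- sim$experiment
    writeExpressionMatrix(SummarizedExperiment::assay(ex, "exprs"),
                          file.path(dir, "matrix.tsv"))
    cd <- SummarizedExperiment::colData(ex)
    writeSampleAnnotation(
        data.frame(sample_id = rownames(cd), group_id = cd$group_id,
                   category = cd$category, matched_normal = cd$matched_normal,
                   label = cd$label, stringsAsFactors = FALSE),
        file.path(dir, "samples.tsv"))
    writeProbesetAnnotation(
        data.frame(probeset_id = rownames(ex),
                   gene_symbol = geneSymbols(ex), stringsAsFactors = FALSE),
        file.path(dir, "probesets.tsv"))
    .writeTsv(sim$truth, file.path(dir, "truth.tsv"))
    cfg <- sim$config
    kv <- c(vapply(setdiff(names(cfg), "classCounts"), function(k)
                sprintf("%s=%s", k, paste(cfg[[k]], collapse = ",")), ""),
            sprintf("classCounts.%s=%d", names(cfg$classCounts),
                    cfg$classCounts),
            sprintf("thresholds.bec=%s", sim$thresholds@bec),
            sprintf("thresholds.qLow=%s", sim$thresholds@qLow),
            sprintf("thresholds.qHigh=%s", sim$thresholds@qHigh))
    con <- file(file.path(dir, "config.txt"), open = "wb")
    writeLines(unname(kv), con)
    close(con)
    invisible(dir)
}
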