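## Independent brute-force evaluators of the classification criteria, written
## as literal per-probeset loops, plus small fixture builders. These stay
## deliberately separate from the package implementation.

bruteTissueClass <- function(summaries, targetGroups, normalGroups,
                             thr, q, params = ctParams()) {
    out <- character(nrow(summaries))
    for (i in seq_len(nrow(summaries))) {
        tsig <- -Inf
        for (g in targetGroups) tsig <- max(tsig, summaries[i, g])
        nDet <- 0L; nExc <- 0L
        for (g in normalGroups) {
            s <- summaries[i, g]
            if (s > bec(thr)) nDet <- nDet + 1L
            if (s > bec(thr) || (tsig - s) < params$foldChangeLog2)
                nExc <- nExc + 1L
        }
        sig <- tsig > bec(thr) && q[i] <= params$qCutoff
        he <- tsig >= qHigh(thr)
        out[i] <-
            if (sig && nExc == 0L) { if (he) "SEHET" else "SET"
            } else if (sig && nExc >= 1L && nExc <= params$exceptionBudget) {
                if (he) "PEHET" else "PET"
            } else if (nDet >= params$ieRange[1L] &&
                       nDet <= params$ieRange[2L]) "IE"
            else if (nDet == length(normalGroups)) "UE"
            else "OTHER"
    }
    out
}

bruteCancerFlags <- function(cancerSignal, normalSignal, thr, q,
                             params = ctParams()) {
    n <- length(cancerSignal)
    out <- data.frame(uc = logical(n), uhec = logical(n), ucndh = logical(n),
                      uhecndh = logical(n))
    for (i in seq_len(n)) {
        uc <- cancerSignal[i] > bec(thr) &&
            (cancerSignal[i] - normalSignal[i]) >= params$foldChangeLog2 &&
            q[i] <= params$qCutoff
        uhec <- uc && cancerSignal[i] >= qHigh(thr)
        ucndh <- uc && normalSignal[i] < bec(thr)
        out[i, ] <- c(uc, uhec, ucndh, uhec && ucndh)
    }
    out
}

## textbook pooled two-sample t, computed with explicit loops
classicalPooledT <- function(a, b) {
    n1 <- ncol(a); n2 <- ncol(b)
    t <- p <- numeric(nrow(a))
    for (i in seq_len(nrow(a))) {
        m1 <- mean(a[i, ]); m2 <- mean(b[i, ])
        sp2 <- (sum((a[i, ] - m1)^2) + sum((b[i, ] - m2)^2)) / (n1 + n2 - 2)
        t[i] <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
        p[i] <- 2 * stats::pt(-abs(t[i]), df = n1 + n2 - 2)
    }
    list(t = t, p = p)
}

## random small classification instance: summary matrix, annotation frame,
## thresholds and q-values (no expression matrix needed at this level)
randomInstance <- function(nps = sample(2:20, 1), nNormal = sample(1:4, 1),
                           nTarget = sample(1:2, 1), nCancer = sample(1:2, 1)) {
    tg <- paste0("t", seq_len(nTarget))
    ng <- paste0("n", seq_len(nNormal))
    cg <- paste0("c", seq_len(nCancer))
    groups <- c(tg, ng, cg)
    summaries <- matrix(runif(nps * length(groups), 3, 9), nps,
                        dimnames = list(paste0("ps", seq_len(nps)), groups))
    qs <- sort(runif(3, 4, 8))
    thr <- globalThresholds(bec = qs[2], qLow = qs[1], qHigh = qs[3])
    q <- ifelse(runif(nps) < 0.5, runif(nps, 0, 0.01), runif(nps))
    ann <- data.frame(
        sample_id = paste0(groups, "_s1"),
        group_id = groups,
        category = rep(c("TARGET", "NORMAL", "CANCER"),
                       c(nTarget, nNormal, nCancer)),
        matched_normal = c(rep("", nTarget + nNormal),
                           sample(ng, nCancer, replace = TRUE)),
        stringsAsFactors = FALSE)
    list(summaries = summaries, ann = ann, thr = thr, q = q,
         target = tg, normal = ng, cancer = cg)
}

## minimal classification-table builders shared across caller tests
mkTissue <- function(classes, ids = paste0("p", seq_along(classes)))
    data.frame(probeset_id = ids, class_label = classes,
               target_signal = 7, n_somatic_detected = 0L,
               n_exceptions = 0L, q = 0.001, stringsAsFactors = FALSE)

mkAgg <- function(anyU, ids = paste0("p", seq_along(anyU)))
    data.frame(probeset_id = ids, n_subtypes_uc = as.integer(anyU),
               n_subtypes_ucndh = as.integer(anyU), any_ucndh = anyU,
               stringsAsFactors = FALSE)

## tiny valid CTExperiment: 2 target, 3 normal, 2 cancer groups, n samples
## per group, planted so downstream stages have structure to find
tinyExperiment <- function(seed = 7, nps = 12, n = 3) {
    set.seed(seed)
    groups <- c(tg1 = "TARGET", tg2 = "TARGET", ng1 = "NORMAL",
                ng2 = "NORMAL", ng3 = "NORMAL", cg1 = "CANCER",
                cg2 = "CANCER")
    ann <- data.frame(
        sample_id = paste0(rep(names(groups), each = n), "_s", seq_len(n)),
        group_id = rep(names(groups), each = n),
        category = rep(unname(groups), each = n),
        matched_normal = rep(c("", "", "", "", "", "ng1", "ng2"), each = n),
        stringsAsFactors = FALSE)
    x <- matrix(rnorm(nps * nrow(ann), 5, 0.4), nps,
                dimnames = list(sprintf("ps%02d", seq_len(nps)),
                                ann$sample_id))
    ## plant one testis-specific cancer-derepressed probeset
    x[1, ann$group_id %in% c("tg1", "tg2", "cg1")] <-
        rnorm(3 * n, 9, 0.3)
    pa <- data.frame(probeset_id = rownames(x),
                     gene_symbol = rep(sprintf("G%02d", seq_len(nps / 2)),
                                       each = 2),
                     stringsAsFactors = FALSE)
    CTExperiment(x, ann, pa)
}
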