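#' Confusion counts from truth and predicted calls
#'
#' @param truth,predicted vectors of \code{"cleavage"}/\code{"non_cleavage"}
#'   calls (cleavage is the positive class).
#' @return Named list with \code{TP}, \code{TN}, \code{FP}, \code{FN}.
#' @export
confusionCounts <- function(truth, predicted) {
    stopifnot(length(truth) == length(predicted),
              all(truth %in% c("cleavage", "non_cleavage")),
              all(predicted %in% c("cleavage", "non_cleavage")))
    pos <- truth == "cleavage"
    hit <- predicted == "cleavage"
    list(TP = sum(pos & hit), TN = sum(!pos & !hit),
         FP = sum(!pos & hit), FN = sum(pos & !hit))
}

#' Sensitivity, specificity, accuracy and MCC
#'
#' \deqn{Sn = TP/(TP+FN), \quad Sp = TN/(TN+FP),}
#' \deqn{Acc = (TP+TN)/(TP+TN+FP+FN),}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' When the MCC denominator is zero (a degenerate confusion table) the
#' MCC is reported as 0 with \code{mccDefined = FALSE}; the formulas are
#' otherwise applied exactly, in double precision.
#'
#' @param cc confusion counts from [confusionCounts()] (any list/vector
#'   with TP, TN, FP, FN).
#' @return Named list with \code{Sn}, \code{Sp}, \code{Acc}, \code{MCC},
#'   \code{mccDefined}.
#' @export
computeMetrics <- function(cc) {
    tp <- as.numeric(cc$TP); tn <- as.numeric(cc$TN)
    fp <- as.numeric(cc$FP); fn <- as.numeric(cc$FN)
    total <- tp + tn + fp + fn
    if (total <= 0) stop("empty confusion table")
    denom <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    mccDefined <- denom > 0
    list(Sn = tp / (tp + fn),
         Sp = tn / (tn + fp),
         Acc = (tp + tn) / total,
         MCC = if (mccDefined) (tp * tn - fp * fn) / denom else 0,
         mccDefined = mccDefined)
}

.drawSplit <- function(ids, nTrain, nTest, seed) {
    rng <- .seededSample(seed)
    shuffled <- rng(ids)
    list(train = shuffled[seq_len(nTrain)],
         test = shuffled[nTrain + seq_len(nTest)])
}

.shufflePairLabels <- function(patterns, seed) {
    # destroy the window-label association while preserving balance:
    # each pre-miRNA's cleavage/non-cleavage pair is swapped with
    # probability 0.5
    rng <- .seededSample(seed)
    ids <- unique(patternIds(patterns))
    flip <- setNames(rng(rep(c(TRUE, FALSE), length.out = length(ids))),
                     ids)
    lab <- patternLabels(patterns)
    doFlip <- flip[patternIds(patterns)]
    lab[doFlip] <- ifelse(lab[doFlip] == "cleavage", "non_cleavage",
                          "cleavage")
    PatternSet(patternIds(patterns), patternArms(patterns), lab,
               patternWindows(patterns), patternComplements(patterns),
               patternStarts(patterns))
}

#' Repeated random-split evaluation protocol
#'
#' For each repeat: draw a random stratified split (over pre-miRNA ids,
#' so a cleavage pattern and its sibling non-cleavage pattern never
#' straddle the split), run affinity propagation on the training
#' similarity matrix, derive class features (training clusters, test
#' nearest-exemplar assignment), grid-search and fit the boosted-tree
#' classifier, and compute test-set metrics. Repeats where affinity
#' propagation fails to converge are discarded and redrawn with a fresh
#' split. The mean of the per-repeat metrics is reported.
#'
#' Because splits are drawn over ids and each id contributes one
#' cleavage and one non-cleavage pattern, \code{trainPos} must equal
#' \code{trainNeg} and \code{testPos} must equal \code{testNeg} (as in
#' the 800+800 / 156+156 protocol over 956 pre-miRNAs).
#'
#' @param patterns a [PatternSet-class] with one cleavage and one
#'   non-cleavage pattern per pre-miRNA id.
#' @param nRepeats number of retained repeats (default 10).
#' @param trainPos,trainNeg,testPos,testNeg split sizes per class
#'   (defaults 800/800/156/156).
#' @param seed master seed; per-repeat seeds are derived by fixed
#'   offsets.
#' @param grid,cvFolds,nrounds passed to [gridSearchTrain()].
#' @param damping,maxIter,convWindow passed to [affinityPropagation()];
#'   damping defaults to 0.9 here for convergence robustness on
#'   repeated runs.
#' @param preference passed to [buildSimilarityMatrix()].
#' @param shuffleLabels if \code{TRUE}, randomly swap each id's pair of
#'   labels before splitting (a null experiment: test accuracy should
#'   be near 0.5).
#' @param maxRedraws maximum redraw attempts per repeat before erroring.
#' @param keepModels if \code{TRUE}, retain the fitted models in the
#'   report.
#' @return An \code{ExperimentReport} list with \code{perRepeat}
#'   (data.frame of per-repeat metrics, hyperparameters and clustering
#'   diagnostics), \code{mean} (mean Sn/Sp/Acc/MCC), \code{importance}
#'   (per-repeat importance tables), \code{models} (if kept) and the
#'   call parameters.
#' @export
runExperiment <- function(patterns, nRepeats = 10L, trainPos = 800L,
                          trainNeg = 800L, testPos = 156L,
                          testNeg = 156L, seed = 1L,
                          grid = defaultGrid(), cvFolds = 5L,
                          nrounds = 100L, damping = 0.9,
                          maxIter = 1000L, convWindow = 50L,
                          preference = "median",
                          shuffleLabels = FALSE, maxRedraws = 20L,
                          keepModels = FALSE) {
    if (trainPos != trainNeg || testPos != testNeg)
        stop("id-level splitting requires trainPos == trainNeg and testPos == testNeg")
    ids <- unique(patternIds(patterns))
    perId <- table(patternIds(patterns), patternLabels(patterns))
    if (!all(perId == 1L))
        stop("every id must contribute exactly one cleavage and one non-cleavage pattern")
    if (trainPos + testPos > length(ids))
        stop(sprintf("need %d ids, have %d", trainPos + testPos,
                     length(ids)))
    idIndex <- split(seq_len(length(patterns)), patternIds(patterns))

    rows <- vector("list", nRepeats)
    importances <- vector("list", nRepeats)
    models <- if (keepModels) vector("list", nRepeats) else NULL
    for (r in seq_len(nRepeats)) {
        done <- FALSE
        for (attempt in seq_len(maxRedraws)) {
            repSeed <- as.integer((seed + 10007L * r + 211L * (attempt - 1L)) %%
                                      .Machine$integer.max)
            pats <- if (shuffleLabels)
                .shufflePairLabels(patterns, repSeed + 1L) else patterns
            sp <- .drawSplit(ids, trainPos, testPos, repSeed)
            stopifnot(length(intersect(sp$train, sp$test)) == 0L)
            trainIdx <- unlist(idIndex[sp$train], use.names = FALSE)
            testIdx <- unlist(idIndex[sp$test], use.names = FALSE)
            trainPS <- pats[trainIdx]
            testPS <- pats[testIdx]

            S <- buildSimilarityMatrix(trainPS, preference = preference)
            cm <- affinityPropagation(S, damping = damping,
                                      maxIter = maxIter,
                                      convWindow = convWindow)
            if (!isConverged(cm)) next

            ex <- exemplars(cm)
            classLevels <- as.character(sort(ex))
            trainTab <- buildFeatureTable(trainPS, clusterLabels(cm),
                                          classLevels = classLevels)
            testClasses <- assignClass(testPS, trainPS[ex],
                                       exemplarClasses = ex)
            testTab <- buildFeatureTable(testPS, testClasses,
                                         classLevels = classLevels)

            model <- gridSearchTrain(trainTab, grid = grid,
                                     cvFolds = cvFolds, seed = repSeed,
                                     nrounds = nrounds)
            pred <- predictCleavage(model, testTab)
            cc <- confusionCounts(patternLabels(testPS), pred$call)
            met <- computeMetrics(cc)
            rows[[r]] <- data.frame(
                repeat_ = r, seed = repSeed, attempts = attempt,
                apConverged = TRUE, apIterations = cm@iterations,
                nClusters = length(ex),
                max_depth = model@hyperparameters$max_depth,
                learning_rate = model@hyperparameters$learning_rate,
                num_leaves = model@hyperparameters$num_leaves,
                TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN,
                Sn = met$Sn, Sp = met$Sp, Acc = met$Acc, MCC = met$MCC,
                trainTestDisjoint =
                    length(intersect(patternIds(trainPS),
                                     patternIds(testPS))) == 0L)
            importances[[r]] <- model@importance
            if (keepModels) models[[r]] <- model
            done <- TRUE
            break
        }
        if (!done)
            stop(sprintf("repeat %d: affinity propagation failed to converge in %d redraws",
                         r, maxRedraws))
    }
    perRepeat <- do.call(rbind, rows)
    report <- list(
        perRepeat = perRepeat,
        mean = list(Sn = mean(perRepeat$Sn), Sp = mean(perRepeat$Sp),
                    Acc = mean(perRepeat$Acc), MCC = mean(perRepeat$MCC)),
        importance = importances,
        models = models,
        parameters = list(nRepeats = nRepeats, trainPos = trainPos,
                          trainNeg = trainNeg, testPos = testPos,
                          testNeg = testNeg, seed = seed,
                          damping = damping, preference = preference,
                          shuffleLabels = shuffleLabels))
    class(report) <- "ExperimentReport"
    report
}

#' @export
print.ExperimentReport <- function(x, ...) {
    cat(sprintf("ExperimentReport: %d repeats (train %d+%d, test %d+%d)\n",
                x$parameters$nRepeats, x$parameters$trainPos,
                x$parameters$trainNeg, x$parameters$testPos,
                x$parameters$testNeg))
    cat(sprintf("  mean Sn=%.3f Sp=%.3f Acc=%.3f MCC=%.3f\n",
                x$mean$Sn, x$mean$Sp, x$mean$Acc, x$mean$MCC))
    invisible(x)
}

#' Serialize an ExperimentReport to JSON
#'
#' @param report an \code{ExperimentReport} from [runExperiment()].
#' @param path output JSON file.
#' @export
writeExperimentReport <- function(report, path) {
    jsonlite::write_json(
        list(perRepeat = report$perRepeat, mean = report$mean,
             parameters = report$parameters),
        path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
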