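## Relational features: position i of a window contributes the ordered
## categorical pair (window[i], complement[i]) from {A,C,G,U} x
## {A,C,G,U,O} -- 20 categories per position, 14 positions (p1..p14).
## Together with the cluster-derived class feature these are the 15
## categorical inputs of the boosted-tree classifier.

#' The 20 relational pair categories
#'
#' Ordered pairs \code{(base, partner)} with base in \code{A,C,G,U} and
#' partner in \code{A,C,G,U,O}, encoded as two-character strings
#' (e.g. \code{"UA"}, \code{"GO"}). The dictionary is fixed so training
#' and test data always share factor levels.
#'
#' @return Character vector of the 20 codes.
#' @export
relationalLevels <- function() {
    as.vector(t(outer(RNA_BASES, COMPLEMENT_ALPHABET, paste0)))
}

#' Encode patterns as relational features p1..p14
#'
#' @param patterns a [PatternSet-class].
#' @return data.frame with factor columns \code{p1}..\code{p14}, one row
#'   per pattern.
#' @export
relationalEncode <- function(patterns) {
    lv <- relationalLevels()
    win <- patternWindows(patterns)
    cmp <- patternComplements(patterns)
    out <- lapply(seq_len(WINDOW_SIZE), function(i) {
        factor(paste0(substring(win, i, i), substring(cmp, i, i)),
               levels = lv)
    })
    names(out) <- paste0("p", seq_len(WINDOW_SIZE))
    df <- as.data.frame(out, stringsAsFactors = TRUE)
    if (anyNA(df)) stop("pattern contains characters outside the alphabet")
    df
}

#' Decode relational features back to window and complement strings
#'
#' Inverse of [relationalEncode()] (the encoding is a bijection).
#'
#' @param features data.frame with columns \code{p1}..\code{p14}.
#' @return data.frame with \code{window} and \code{complement} columns.
#' @export
relationalDecode <- function(features) {
    codes <- vapply(paste0("p", seq_len(WINDOW_SIZE)),
                    function(col) as.character(features[[col]]),
                    character(nrow(features)))
    codes <- matrix(codes, nrow = nrow(features))
    data.frame(
        window = apply(codes, 1L, function(x)
            paste(substring(x, 1, 1), collapse = "")),
        complement = apply(codes, 1L, function(x)
            paste(substring(x, 2, 2), collapse = "")),
        stringsAsFactors = FALSE)
}

#' Assemble the feature table for the classifier
#'
#' 14 relational features plus the categorical class feature (cluster
#' id from affinity propagation for training samples, nearest-exemplar
#' assignment for test samples) and the binary label. Train and test
#' tables must share factor levels: pass the training table's
#' \code{classLevels} attribute when building the test table. A class id
#' not present in \code{classLevels} is mapped to the reserved
#' \code{"unseen"} level with a warning.
#'
#' @param patterns a [PatternSet-class].
#' @param classIds per-pattern cluster ids.
#' @param classLevels optional character vector of allowed class ids
#'   (defaults to the sorted unique ids in \code{classIds}).
#' @return data.frame with factor columns \code{p1}..\code{p14},
#'   \code{classFeature}, and a \code{label} factor with levels
#'   \code{"0"} (non-cleavage) and \code{"1"} (cleavage); the class
#'   dictionary is stored in attribute \code{"classLevels"}.
#' @export
buildFeatureTable <- function(patterns, classIds, classLevels = NULL) {
    if (length(classIds) != length(patterns))
        stop("classIds must be parallel to patterns")
    ids <- as.character(classIds)
    if (is.null(classLevels))
        classLevels <- sort(unique(ids))
    classLevels <- setdiff(as.character(classLevels), "unseen")
    unseen <- !ids %in% classLevels
    if (any(unseen)) {
        warning(sprintf("%d sample(s) carry a class id unseen in training; mapped to 'unseen'",
                        sum(unseen)))
        ids[unseen] <- "unseen"
    }
    df <- relationalEncode(patterns)
    df$classFeature <- factor(ids, levels = c(classLevels, "unseen"))
    df$label <- factor(
        ifelse(patternLabels(patterns) == "cleavage", "1", "0"),
        levels = c("0", "1"))
    attr(df, "classLevels") <- classLevels
    df
}

#' Default hyperparameter grid
#'
#' The exhaustive 6 x 3 x 3 search grid:
#' \code{max_depth} in \{10, 20, 30, 40, 50, 60\},
#' \code{learning_rate} in \{0.05, 0.1, 0.15\},
#' \code{num_leaves} in \{200, 300, 400\}.
#'
#' @return data.frame with one row per grid point.
#' @export
defaultGrid <- function() {
    expand.grid(max_depth = c(10L, 20L, 30L, 40L, 50L, 60L),
                learning_rate = c(0.05, 0.1, 0.15),
                num_leaves = c(200L, 300L, 400L),
                KEEP.OUT.ATTRS = FALSE)
}

.featureColumns <- function(table) {
    setdiff(names(table), "label")
}

.xgbFit <- function(x, y, maxDepth, learningRate, numLeaves, nrounds,
                    seed) {
    xgboost::xgboost(
        x = x, y = y,
        nrounds = nrounds,
        max_depth = maxDepth,
        learning_rate = learningRate,
        max_leaves = numLeaves,
        grow_policy = "lossguide",
        tree_method = "hist",
        nthreads = 1L,
        seed = seed,
        verbosity = 0L)
}

.stratifiedFolds <- function(y, k, seed) {
    folds <- integer(length(y))
    rng <- .seededSample(seed)
    for (lv in levels(y)) {
        idx <- which(y == lv)
        if (length(idx) < k)
            stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                         lv, length(idx), k))
        folds[idx] <- rng(rep_len(seq_len(k), length(idx)))
    }
    folds
}

# a private, persistent RNG stream: successive calls advance the stream,
# the caller's .Random.seed is left untouched
.seededSample <- function(seed) {
    saveState <- function() {
        if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
    }
    restoreState <- function(s) {
        if (!is.null(s)) assign(".Random.seed", s, envir = globalenv())
    }
    outer <- saveState()
    set.seed(seed)
    state <- saveState()
    restoreState(outer)
    function(x, size = length(x)) {
        outer <- saveState()
        assign(".Random.seed", state, envir = globalenv())
        res <- sample(x, size)
        state <<- saveState()
        restoreState(outer)
        res
    }
}

#' Grid-search cross-validation and final model fit
#'
#' Exhaustively evaluates every grid point by stratified k-fold
#' cross-validated accuracy on the training table, picks the best
#' combination (ties broken by grid order), and refits on the full
#' training set. Categorical features are passed to the boosting
#' library natively (no one-hot expansion); trees grow leaf-wise
#' (\code{num_leaves} capping the leaf count) as in LightGBM-style
#' boosting.
#'
#' @param train feature table from [buildFeatureTable()] with balanced
#'   binary labels.
#' @param grid data.frame with columns \code{max_depth},
#'   \code{learning_rate}, \code{num_leaves}; defaults to
#'   [defaultGrid()].
#' @param cvFolds number of stratified folds (default 5).
#' @param seed integer seed controlling fold assignment and fitting.
#' @param nrounds boosting rounds (default 100, no early stopping).
#' @return A [TrainedCleavageModel-class].
#' @export
gridSearchTrain <- function(train, grid = defaultGrid(), cvFolds = 5L,
                            seed = 1L, nrounds = 100L) {
    stopifnot(nrow(grid) >= 1L,
              all(c("max_depth", "learning_rate", "num_leaves") %in%
                      names(grid)))
    y <- train$label
    if (nlevels(droplevels(y)) < 2L)
        stop("training labels are single-class")
    x <- train[.featureColumns(train)]
    folds <- .stratifiedFolds(y, cvFolds, seed)
    cvAcc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
        acc <- numeric(cvFolds)
        for (f in seq_len(cvFolds)) {
            hold <- folds == f
            if (nlevels(droplevels(y[!hold])) < 2L)
                stop("degenerate single-class fold")
            fit <- .xgbFit(x[!hold, , drop = FALSE], y[!hold],
                           grid$max_depth[g], grid$learning_rate[g],
                           grid$num_leaves[g], nrounds, seed)
            p <- predict(fit, x[hold, , drop = FALSE], type = "response")
            acc[f] <- mean((p > 0.5) == (y[hold] == "1"))
        }
        cvAcc[g] <- mean(acc)
    }
    best <- which.max(cvAcc)  # first max: deterministic tie-break
    booster <- .xgbFit(x, y, grid$max_depth[best],
                       grid$learning_rate[best], grid$num_leaves[best],
                       nrounds, seed)
    imp <- xgboost::xgb.importance(model = booster)
    importance <- data.frame(feature = names(x),
                             frequency = 0, gain = 0,
                             stringsAsFactors = FALSE)
    if (!is.null(imp) && nrow(imp) > 0L) {
        m <- match(imp$Feature, importance$feature)
        importance$frequency[m] <- imp$Frequency
        importance$gain[m] <- imp$Gain
    }
    new("TrainedCleavageModel",
        booster = booster,
        hyperparameters = list(
            max_depth = grid$max_depth[best],
            learning_rate = grid$learning_rate[best],
            num_leaves = grid$num_leaves[best],
            nrounds = nrounds, seed = seed),
        featureLevels = lapply(x, levels),
        importance = importance,
        cvAccuracy = cbind(grid, cv_accuracy = cvAcc))
}

#' Predict cleavage probabilities and calls
#'
#' @param model a [TrainedCleavageModel-class].
#' @param table feature table with the same schema (columns and factor
#'   levels) as the training table.
#' @return data.frame with \code{probability} (of cleavage) and
#'   \code{call} (\code{"cleavage"} if probability > 0.5, else
#'   \code{"non_cleavage"}).
#' @export
predictCleavage <- function(model, table) {
    x <- table[intersect(names(table), names(model@featureLevels))]
    missing <- setdiff(names(model@featureLevels), names(x))
    if (length(missing) > 0L)
        stop(sprintf("feature table is missing column(s): %s",
                     paste(missing, collapse = ", ")))
    mismatched <- names(which(!vapply(
        names(model@featureLevels),
        function(col) identical(levels(x[[col]]),
                                model@featureLevels[[col]]),
        logical(1))))
    if (length(mismatched) > 0L)
        stop(sprintf("factor levels differ from training for column(s): %s",
                     paste(mismatched, collapse = ", ")))
    x <- x[names(model@featureLevels)]
    p <- predict(model@booster, x, type = "response")
    data.frame(
        probability = as.numeric(p),
        call = ifelse(p > 0.5, "cleavage", "non_cleavage"),
        stringsAsFactors = FALSE)
}

#' Feature importance, optionally averaged over several models
#'
#' The boosting library's built-in per-feature usefulness score. Two
#' variants are reported: \code{frequency}, the number of times a
#' feature is used in a split, and \code{gain}, the total loss
#' reduction attributed to its splits. Given several models (e.g. the
#' repeats of [runExperiment()]), scores are averaged feature-wise.
#'
#' @param models a [TrainedCleavageModel-class], a list of them, or a
#'   list of per-model importance tables (as stored in the
#'   \code{importance} element of an \code{ExperimentReport}).
#' @param type \code{"frequency"} (default) or \code{"gain"}.
#' @return data.frame with \code{feature} and \code{score}, sorted by
#'   decreasing score.
#' @export
featureImportance <- function(models, type = c("frequency", "gain")) {
    type <- match.arg(type)
    if (is(models, "TrainedCleavageModel")) models <- list(models)
    tabs <- lapply(models, function(m)
        if (is(m, "TrainedCleavageModel")) m@importance else m)
    feats <- tabs[[1]]$feature
    scores <- rowMeans(vapply(tabs, function(t)
        t[[type]][match(feats, t$feature)], numeric(length(feats))))
    out <- data.frame(feature = feats, score = scores,
                      stringsAsFactors = FALSE)
    out[order(-out$score), , drop = FALSE]
}
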