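test_that("relational encoding zips window and complement position-wise", {
    fx <- fig2Fixture()
    clv <- extractCleavagePattern(fx$sequence, fig2PairTable(),
                                  fx$annotation)
    enc <- relationalEncode(clv)
    expect_identical(dim(enc), c(1L, 14L))
    want <- c("UA", "AU", "UA", "AU", "GC", "UA", "UA", "UO", "UO",
              "AO", "GC", "GC", "GC", "UO")
    expect_identical(vapply(enc, as.character, character(1),
                            USE.NAMES = FALSE), want)
    expect_true(all(vapply(enc, function(col)
        identical(levels(col), relationalLevels()), logical(1))))

    # fully unpaired pattern: every pair's second element is 'O'
    un <- PatternSet("u", "5p", "cleavage", paste0(strrep("ACGU", 3), "AC"),
                     strrep("O", 14), 1L)
    encU <- relationalEncode(un)
    expect_true(all(grepl("O$", vapply(encU, as.character,
                                       character(1)))))
})

test_that("relational encoding is a bijection", {
    set.seed(107)
    ps <- PatternSet(sprintf("p%d", 1:20), "5p", "cleavage",
                     randomRNA(20),
                     vapply(1:20, function(i)
                         paste(sample(c("A", "C", "G", "U", "O"), 14,
                                      TRUE), collapse = ""),
                         character(1)),
                     1L)
    dec <- relationalDecode(relationalEncode(ps))
    expect_identical(dec$window, patternWindows(ps))
    expect_identical(dec$complement, patternComplements(ps))
})

test_that("feature tables carry 15 shared-dictionary categorical features", {
    set.seed(108)
    ps <- PatternSet(sprintf("p%d", 1:40), "5p",
                     rep(c("cleavage", "non_cleavage"), 20),
                     randomRNA(40), randomRNA(40), 1L)
    tab <- buildFeatureTable(ps, rep(c(3L, 9L), 20))
    expect_identical(dim(tab), c(40L, 16L))
    expect_identical(names(tab),
                     c(paste0("p", 1:14), "classFeature", "label"))
    expect_identical(levels(tab$classFeature), c("3", "9", "unseen"))
    expect_identical(levels(tab$label), c("0", "1"))
    expect_false(anyNA(tab))

    # a class id unseen in the training dictionary maps to 'unseen'
    expect_warning(
        tab2 <- buildFeatureTable(ps[1:2], c(3L, 7L),
                                  classLevels = attr(tab, "classLevels")),
        "unseen")
    expect_identical(as.character(tab2$classFeature), c("3", "unseen"))
    expect_identical(levels(tab2$classFeature),
                     levels(tab$classFeature))
})

test_that("grid search picks the configuration with the best CV accuracy", {
    set.seed(109)
    ds <- generateDataset(40, hairpinSpec(motif = "UGGC",
                                          motifStrength = 1),
                          seed = 42)
    ps <- buildPatternSet(ds$sequences, ds$pairTables, ds$annotations,
                          arm = "5p")
    tab <- buildFeatureTable(ps, rep(1L, length(ps)))
    grid <- expand.grid(max_depth = c(4L, 10L), learning_rate = c(0.1),
                        num_leaves = c(31L, 200L),
                        KEEP.OUT.ATTRS = FALSE)
    model <- gridSearchTrain(tab, grid = grid, cvFolds = 3, seed = 5,
                             nrounds = 30)
    cv <- model@cvAccuracy
    best <- model@hyperparameters
    # chosen config's CV accuracy >= every grid point's (exhaustive
    # re-evaluation through the public single-point-grid path)
    for (g in seq_len(nrow(grid))) {
        single <- gridSearchTrain(tab, grid = grid[g, , drop = FALSE],
                                  cvFolds = 3, seed = 5, nrounds = 30)
        expect_equal(single@cvAccuracy$cv_accuracy, cv$cv_accuracy[g])
        expect_gte(cv$cv_accuracy[which(
            cv$max_depth == best$max_depth &
                cv$learning_rate == best$learning_rate &
                cv$num_leaves == best$num_leaves)],
            single@cvAccuracy$cv_accuracy)
    }
    expect_identical(nrow(cv), 4L)
})

test_that("training is deterministic and a size-1 grid is direct training", {
    set.seed(110)
    ps <- PatternSet(sprintf("p%d", 1:60), "5p",
                     rep(c("cleavage", "non_cleavage"), 30),
                     randomRNA(60), randomRNA(60), 1L)
    tab <- buildFeatureTable(ps, rep(1L, 60))
    g1 <- data.frame(max_depth = 6L, learning_rate = 0.1,
                     num_leaves = 31L)
    m1 <- gridSearchTrain(tab, grid = g1, cvFolds = 3, seed = 7,
                          nrounds = 20)
    m2 <- gridSearchTrain(tab, grid = g1, cvFolds = 3, seed = 7,
                          nrounds = 20)
    expect_identical(m1@hyperparameters, m2@hyperparameters)
    expect_identical(predictCleavage(m1, tab)$probability,
                     predictCleavage(m2, tab)$probability)
})

test_that("predictions are probabilities with schema checking", {
    ds <- generateDataset(30, hairpinSpec(motif = "UGGC",
                                          motifStrength = 1),
                          seed = 13)
    ps <- buildPatternSet(ds$sequences, ds$pairTables, ds$annotations,
                          arm = "3p")
    tab <- buildFeatureTable(ps, rep(1L, length(ps)))
    model <- gridSearchTrain(tab,
                             grid = data.frame(max_depth = 10L,
                                               learning_rate = 0.1,
                                               num_leaves = 200L),
                             cvFolds = 3, seed = 1, nrounds = 50)
    pred <- predictCleavage(model, tab)
    expect_true(all(pred$probability >= 0 & pred$probability <= 1))
    expect_identical(pred$call,
                     ifelse(pred$probability > 0.5, "cleavage",
                            "non_cleavage"))
    # an overfit model memorizes its training rows
    expect_gt(mean((pred$probability > 0.5) == (tab$label == "1")), 0.9)
    # identical feature rows get identical probabilities
    dup <- tab[c(1, 1, 1), ]
    expect_length(unique(predictCleavage(model, dup)$probability), 1L)
    # missing column is reported by name
    expect_error(predictCleavage(model, tab[setdiff(names(tab), "p3")]),
                 "p3")
    # mismatched factor dictionary is reported
    bad <- tab
    levels(bad$p1) <- c(levels(bad$p1)[-1], "ZZ")
    expect_error(predictCleavage(model, bad), "p1")
})

test_that("feature importance recovers a planted single-position signal", {
    set.seed(111)
    n <- 200
    win <- randomRNA(n)
    lab <- rep(c("cleavage", "non_cleavage"), n / 2)
    # only window position 8 carries the label
    substr(win, 8, 8) <- ifelse(lab == "cleavage", "G", "A")
    ps <- PatternSet(sprintf("p%d", 1:n), "5p", lab, win,
                     rep(strrep("O", 14), n), 1L)
    tab <- buildFeatureTable(ps, rep(1L, n))
    model <- gridSearchTrain(tab,
                             grid = data.frame(max_depth = 6L,
                                               learning_rate = 0.1,
                                               num_leaves = 31L),
                             cvFolds = 3, seed = 2, nrounds = 30)
    impF <- featureImportance(model, type = "frequency")
    impG <- featureImportance(model, type = "gain")
    expect_identical(impF$feature[1], "p8")
    expect_identical(impG$feature[1], "p8")
    expect_identical(nrow(impF), 15L)
    expect_true(all(impF$score >= 0))
    # averaging a model with itself changes nothing
    expect_identical(featureImportance(list(model, model))$score,
                     impF$score)
})
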