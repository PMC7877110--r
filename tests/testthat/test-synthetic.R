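test_that("a clean stem gives exact Watson-Crick complements", {
    hp <- generateHairpin(hairpinSpec(bulgeRate = 0, mismatchRate = 0),
                          seed = 1)
    ps <- buildPatternSet(setNames(hp$sequence, hp$id),
                          setNames(list(hp$pairTable), hp$id),
                          hp$annotations)
    expect_length(ps, 4L)
    wc <- c(A = "U", C = "G", G = "C", U = "A")
    for (i in seq_len(length(ps))) {
        cmp <- patternComplements(ps[i])
        expect_false(grepl("O", cmp))
        win <- strsplit(patternWindows(ps[i]), "")[[1]]
        expect_identical(strsplit(cmp, "")[[1]], unname(wc[win]))
    }
})

test_that("hairpin spec validation rejects impossible geometry", {
    expect_error(hairpinSpec(stemLength = 15), "stemLength")
    expect_error(hairpinSpec(bulgeRate = 1.5), "rates")
    expect_error(hairpinSpec(cleavageOffset = 5), "cleavageOffset")
    expect_error(hairpinSpec(motif = strrep("A", 10)), "motif")
    # degenerate all-bulge geometry is allowed and documented: windows
    # are (essentially) unpaired
    hp <- generateHairpin(hairpinSpec(bulgeRate = 1), seed = 2)
    expect_gte(mean(is.na(hp$pairTable)), 0.99)
})

test_that("generation is seed-deterministic down to the emitted files", {
    d1 <- tempfile()
    d2 <- tempfile()
    spec <- hairpinSpec(motif = "UGGC", motifStrength = 0.5)
    generateDataset(5, spec, seed = 9, dir = d1)
    generateDataset(5, spec, seed = 9, dir = d2)
    for (f in c("hairpins.fa", "hairpins.db", "annotations.tsv")) {
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)))
    }
    d3 <- tempfile()
    generateDataset(5, spec, seed = 10, dir = d3)
    expect_false(identical(readLines(file.path(d1, "hairpins.fa")),
                           readLines(file.path(d3, "hairpins.fa"))))
})

test_that("emitted files feed back through the readers losslessly", {
    d <- tempfile()
    ds <- generateDataset(6, hairpinSpec(), seed = 21, dir = d)
    seqs <- readFastaRNA(file.path(d, "hairpins.fa"))
    expect_identical(seqs, ds$sequences)
    db <- readDotBracket(file.path(d, "hairpins.db"))
    expect_identical(db$pairTables, ds$pairTables)
    ann <- readCleavageAnnotations(file.path(d, "annotations.tsv"),
                                   sequences = seqs)
    expect_identical(nrow(ann), 12L)
    ps <- buildPatternSet(seqs, db$pairTables, ann)
    expect_length(ps, 24L)
})

test_that("planted motifs appear at the scissile bond of cleavage windows", {
    ds <- generateDataset(40, hairpinSpec(motif = "UGGC",
                                          motifStrength = 1,
                                          bulgeRate = 0,
                                          mismatchRate = 0),
                          seed = 33)
    ps <- buildPatternSet(ds$sequences, ds$pairTables, ds$annotations)
    clv <- ps[patternLabels(ps) == "cleavage"]
    # motif at window offsets 7..10 in every cleavage window
    expect_true(all(substr(patternWindows(clv), 7, 10) == "UGGC"))
    # non-cleavage centres are never planted: their offsets 7..10 are
    # identical to what the same seed generates without any motif
    ds0 <- generateDataset(40, hairpinSpec(bulgeRate = 0,
                                           mismatchRate = 0),
                           seed = 33)
    ps0 <- buildPatternSet(ds0$sequences, ds0$pairTables,
                           ds0$annotations)
    non <- ps[patternLabels(ps) == "non_cleavage"]
    non0 <- ps0[patternLabels(ps0) == "non_cleavage"]
    expect_identical(substr(patternWindows(non), 7, 10),
                     substr(patternWindows(non0), 7, 10))
})

test_that("separability grows with motif strength", {
    grid <- data.frame(max_depth = 10L, learning_rate = 0.1,
                       num_leaves = 200L)
    acc <- vapply(c(0, 0.5, 1), function(strength) {
        ds <- generateDataset(
            55, hairpinSpec(motif = "UGGC", motifStrength = strength),
            seed = 55)
        ps <- buildPatternSet(ds$sequences, ds$pairTables,
                              ds$annotations, arm = "5p")
        rep <- runExperiment(ps, nRepeats = 2, trainPos = 40,
                             trainNeg = 40, testPos = 15, testNeg = 15,
                             seed = 5, grid = grid, cvFolds = 3)
        rep$mean$Acc
    }, numeric(1))
    expect_true(acc[1] < acc[3])
    expect_true(acc[2] <= acc[3] + 0.05)
    expect_gte(acc[3], 0.9)
    expect_lte(acc[1], 0.7)
})

test_that("importance concentrates on the planted window positions", {
    ds <- generateDataset(80, hairpinSpec(motif = "UGGC",
                                          motifStrength = 1),
                          seed = 77)
    ps <- buildPatternSet(ds$sequences, ds$pairTables, ds$annotations,
                          arm = "5p")
    tab <- buildFeatureTable(ps, rep(1L, length(ps)))
    model <- gridSearchTrain(tab,
                             grid = data.frame(max_depth = 10L,
                                               learning_rate = 0.1,
                                               num_leaves = 200L),
                             cvFolds = 3, seed = 4, nrounds = 50)
    imp <- featureImportance(model, type = "gain")
    positional <- imp[imp$feature %in% paste0("p", 1:14), ]
    # motif occupies window offsets 7..10: the top positional feature
    # must be one of p7..p10
    expect_true(positional$feature[1] %in% paste0("p", 7:10))
    inside <- sum(positional$score[positional$feature %in%
                                       paste0("p", 7:10)])
    expect_gt(inside, 0.5 * sum(positional$score))
})
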