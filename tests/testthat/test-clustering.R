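test_that("duplicated points collapse into a single cluster", {
    S <- matrix(0, 2, 2)
    diag(S) <- -1
    cm <- affinityPropagation(S, damping = 0.5, maxIter = 200,
                              convWindow = 15)
    expect_length(exemplars(cm), 1L)
    expect_identical(clusterLabels(cm)[1], clusterLabels(cm)[2])
})

test_that("well-separated blocks give one exemplar each, block-pure", {
    ps <- blockPatterns(k = 3, perBlock = 4)
    sm <- buildSimilarityMatrix(ps, preference = "median")
    cm <- affinityPropagation(sm, damping = 0.5, maxIter = 500,
                              convWindow = 25)
    expect_true(isConverged(cm))
    expect_length(exemplars(cm), 3L)
    block <- rep(1:3, each = 4)
    lab <- clusterLabels(cm)
    for (b in 1:3)
        expect_length(unique(lab[block == b]), 1L)
    # exemplars label themselves; every label is an exemplar
    expect_identical(lab[exemplars(cm)], exemplars(cm))
    expect_true(all(lab %in% exemplars(cm)))
})

test_that("preference drives the number of clusters monotonically", {
    set.seed(104)
    ps <- PatternSet(sprintf("p%d", 1:8), "5p",
                     rep(c("cleavage", "non_cleavage"), 4),
                     randomRNA(8), randomRNA(8), 1L)
    smLow <- buildSimilarityMatrix(ps, preference = -1000)
    cmLow <- affinityPropagation(smLow, damping = 0.5, maxIter = 500,
                                 convWindow = 25)
    expect_length(exemplars(cmLow), 1L)
    smHigh <- buildSimilarityMatrix(ps, preference = 0)
    cmHigh <- affinityPropagation(smHigh, damping = 0.5, maxIter = 500,
                                  convWindow = 25)
    expect_gte(length(exemplars(cmHigh)), length(exemplars(cmLow)))
    expect_identical(length(exemplars(cmHigh)), 8L)
})

test_that("affinity propagation matches the cross-language reference loop", {
    set.seed(105)
    for (t in 1:5) {
        n <- 20
        S <- -as.matrix(dist(matrix(rnorm(2 * n), n, 2)))^2
        diag(S) <- median(S[row(S) != col(S)])
        cm <- affinityPropagation(S, damping = 0.7, maxIter = 500,
                                  convWindow = 30)
        ref <- runApOracle("ap_reference.py", S, 0.7, 500, 30)
        expect_identical(sort(exemplars(cm)), ref$exemplars)
        expect_identical(clusterLabels(cm), ref$labels)
    }
})

test_that("non-convergence is flagged, not an error", {
    # an adversarial symmetric matrix with heavy ties and one sweep
    S <- matrix(-1, 4, 4)
    diag(S) <- -10
    cm <- affinityPropagation(S, damping = 0.5, maxIter = 2,
                              convWindow = 50)
    expect_false(isConverged(cm))
    expect_error(affinityPropagation(matrix(c(NaN, 0, 0, 0), 2, 2)),
                 "NA/NaN")
    expect_error(affinityPropagation(S, damping = 1.2), "damping")
})

test_that("test samples inherit the nearest exemplar's class", {
    ex <- PatternSet(c("ea", "eb", "ec"), "5p", "cleavage",
                     c(strrep("A", 14), strrep("C", 14), strrep("G", 14)),
                     strrep("O", 14), 1L)
    cls <- c(10L, 20L, 30L)
    # a test pattern equal to an exemplar gets that exemplar's class
    expect_identical(assignClass(ex[2], ex, cls), 20L)
    # distance 1 vs distance >1
    near <- PatternSet("t", "5p", "cleavage",
                       paste0("C", strrep("A", 13)), strrep("O", 14), 1L)
    expect_identical(assignClass(near, ex, cls), 10L)
    # exact tie: the lowest exemplar position wins
    tie <- PatternSet(c("e1", "e2"), "5p", "cleavage",
                      c(strrep("A", 14), strrep("C", 14)),
                      rep(strrep("O", 14), 2), 1L)
    half <- PatternSet("t", "5p", "cleavage",
                       paste0(strrep("A", 7), strrep("C", 7)),
                       strrep("O", 14), 1L)
    expect_identical(assignClass(half, tie, c(1L, 2L)), 1L)
    expect_error(assignClass(half, tie[0], integer(0)), "exemplar")
})

test_that("nearest-exemplar assignment matches a linear-scan oracle", {
    set.seed(106)
    ex <- PatternSet(sprintf("e%d", 1:6), "5p", "cleavage",
                     randomRNA(6), randomRNA(6), 1L)
    tests <- PatternSet(sprintf("t%d", 1:50), "5p", "non_cleavage",
                        randomRNA(50), randomRNA(50), 1L)
    got <- assignClass(tests, ex, seq_len(6))
    want <- vapply(seq_len(50), function(i) {
        d <- vapply(seq_len(6), function(j)
            patternDistance(tests[i], ex[j]), integer(1))
        which.min(d)
    }, integer(1))
    expect_identical(got, want)
    # deterministic and idempotent
    expect_identical(assignClass(tests, ex, seq_len(6)), got)
})

test_that("cleavage ratios and label bins follow the interval partition", {
    lab <- c(rep("cleavage", 10),
             rep("cleavage", 3), rep("non_cleavage", 7),
             rep("cleavage", 1), rep("non_cleavage", 4))
    cls <- c(rep(1L, 10), rep(2L, 10), rep(3L, 5))
    out <- classRatioSummary(cls, lab)
    expect_identical(out$classes$ratio, c(1.0, 0.3, 0.2))
    expect_identical(out$classes$bin, c(5L, 2L, 1L))  # 0.2 closes bin 1
    expect_identical(sum(out$classes$nCleavage +
                             out$classes$nNonCleavage), length(lab))
    expect_identical(out$bins$nClasses, c(1L, 1L, 0L, 0L, 1L))
    expect_identical(out$bins$nSamples, c(5L, 10L, 0L, 0L, 10L))
    # boundary cases of every bin edge
    edges <- classRatioSummary(1:5, c("non_cleavage", "cleavage",
                                      "cleavage", "cleavage",
                                      "cleavage"))
    expect_identical(edges$classes$bin,
                     as.integer(cut(c(0, 1, 1, 1, 1),
                                    c(0, .2, .4, .6, .8, 1),
                                    include.lowest = TRUE)))
})
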