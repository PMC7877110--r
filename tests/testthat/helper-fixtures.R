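# Shared fixtures and independent oracles used across the suite.

# A hand-built hairpin whose 5p cleavage window reproduces the let-7-style
# worked example: window "UAUAGUUUUAGGGU" (cleavage_pos 13, window 7..20),
# complement "AUAUCAAOOOCCCO", and non-cleavage window "AGGUUGUAUAGUUU"
# (shift -6). Pairing: positions 7..13 pair with 34..28, 17..19 with
# 27..25; everything else unpaired.
fig2Fixture <- function() {
    list(
        id = "fig2",
        sequence = "AGGUUGUAUAGUUUUAGGGUGAAACCCAACUAUA",
        dotbracket = "......(((((((...(((.....))))))))))",
        annotation = data.frame(id = "fig2", arm = "5p",
                                cleavage_pos = 13L,
                                stringsAsFactors = FALSE)
    )
}

fig2PairTable <- function() {
    dotBracketToPairTable(fig2Fixture()$dotbracket)
}

# Iterative-deepening brute force over edit scripts: is `a` convertible
# into `b` with at most k single-character operations? Distance = the
# smallest k that succeeds. Independent of the DP implementation.
bruteEditDistance <- function(a, b) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    reachable <- function(i, j, k) {
        na <- length(av); nb <- length(bv)
        while (i <= na && j <= nb && av[i] == bv[j]) {
            i <- i + 1L; j <- j + 1L
        }
        if (i > na && j > nb) return(TRUE)
        if (k == 0L) return(FALSE)
        (i <= na && j <= nb && reachable(i + 1L, j + 1L, k - 1L)) ||
            (i <= na && reachable(i + 1L, j, k - 1L)) ||
            (j <= nb && reachable(i, j + 1L, k - 1L))
    }
    k <- 0L
    while (!reachable(1L, 1L, k)) k <- k + 1L
    k
}

# MCC as the Pearson correlation between the 0/1 truth and prediction
# vectors a confusion table expands to.
mccByCorrelation <- function(cc) {
    truth <- c(rep(1, cc$TP), rep(1, cc$FN), rep(0, cc$TN), rep(0, cc$FP))
    pred <- c(rep(1, cc$TP), rep(0, cc$FN), rep(0, cc$TN), rep(1, cc$FP))
    stats::cor(truth, pred)
}

randomRNA <- function(n, len = 14) {
    vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "U"), len, replace = TRUE),
              collapse = ""),
        character(1))
}

# PatternSet of `perBlock` near-duplicates of each of `k` well-separated
# random windows: members differ from their block base by one
# substitution at a member-specific position (exact duplicates make the
# message-passing degenerate through symmetric ties).
blockPatterns <- function(k = 3, perBlock = 4, seed = 1) {
    rng <- local({
        old <- if (exists(".Random.seed", envir = globalenv()))
            get(".Random.seed", envir = globalenv()) else NULL
        set.seed(seed)
        on.exit(if (!is.null(old))
            assign(".Random.seed", old, envir = globalenv()))
        lapply(seq_len(k), function(b)
            sample(c("A", "C", "G", "U"), 14, replace = TRUE))
    })
    rotate <- c(A = "C", C = "G", G = "U", U = "A")
    win <- unlist(lapply(seq_len(k), function(b)
        vapply(seq_len(perBlock), function(m) {
            chars <- rng[[b]]
            chars[m] <- rotate[[chars[m]]]
            paste(chars, collapse = "")
        }, character(1))))
    PatternSet(
        id = sprintf("b%d-%d", rep(seq_len(k), each = perBlock),
                     rep(seq_len(perBlock), k)),
        arm = "5p",
        label = rep(c("cleavage", "non_cleavage"),
                    length.out = k * perBlock),
        window = win,
        complement = strrep("O", 14),
        windowStart = 1L)
}

oraclePath <- function(script) {
    p <- system.file("oracle", script, package = "dicercleave")
    stopifnot(nzchar(p))
    p
}

runApOracle <- function(script, S, damping, maxIter, convWindow,
                        preference = NULL) {
    f <- tempfile(fileext = ".tsv")
    on.exit(unlink(f))
    utils::write.table(S, f, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
    args <- if (identical(script, "ap_sklearn.py")) {
        c(oraclePath(script), f, damping, preference, maxIter, convWindow)
    } else {
        c(oraclePath(script), f, damping, maxIter, convWindow)
    }
    out <- system2("python", as.character(args), stdout = TRUE)
    list(exemplars = as.integer(strsplit(out[1], ",")[[1]]),
         labels = as.integer(strsplit(out[2], ",")[[1]]))
}

# similarity matrix of `n` 2-d points in `k` tight blocks (negated
# squared Euclidean distances, median preference)
blockSimilarity <- function(n = 20, k = 4, sd = 0.5, spread = 10) {
    centers <- matrix(stats::rnorm(2 * k, sd = spread), k, 2)
    X <- centers[rep(seq_len(k), length.out = n), ] +
        matrix(stats::rnorm(2 * n, sd = sd), n, 2)
    S <- -as.matrix(dist(X))^2
    pref <- stats::median(S[row(S) != col(S)])
    diag(S) <- pref
    list(S = S, preference = pref)
}

smallGrid <- function() {
    expand.grid(max_depth = c(10L, 20L), learning_rate = 0.1,
                num_leaves = c(200L, 300L), KEEP.OUT.ATTRS = FALSE)
}
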