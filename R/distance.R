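#' Levenshtein edit distance
#'
#' Classic dynamic-programming edit distance with unit insertion,
#' deletion and substitution costs: base case \eqn{D(i,j) = \max(i,j)}
#' when \eqn{\min(i,j) = 0}, otherwise the minimum of deletion,
#' insertion and (mis)match moves. The loop/bulge symbol \code{O} in
#' complementary strands is an ordinary character with unit
#' substitution cost. Vectorized over pairs; length-1 arguments are
#' recycled.
#'
#' @param a,b character vectors.
#' @return Integer vector of distances.
#' @export
#' @examples
#' editDistance("UAUAGUUUUAGGGU", "UAUGGUUUAGAGUU") # 4
editDistance <- function(a, b) {
    a <- as.character(a)
    b <- as.character(b)
    if (length(a) == 1L && length(b) > 1L) a <- rep(a, length(b))
    if (length(b) == 1L && length(a) > 1L) b <- rep(b, length(a))
    if (length(a) != length(b))
        stop("'a' and 'b' must have the same length (or length 1)")
    if (anyNA(a) || anyNA(b)) stop("NA strings are not allowed")
    .editDistancePairs(a, b)
}

#' Pattern distance: window plus complement edit distance
#'
#' The input distance used for clustering:
#' \eqn{D_{similar}(E,F) = D_{edit}(E_1,F_1) + D_{edit}(E_2,F_2)}, the
#' sum of the edit distance between the two 14-nt windows and the edit
#' distance between their complementary strands.
#'
#' @param e,f [PatternSet-class] objects of equal length (or length 1,
#'   recycled).
#' @return Integer vector of distances.
#' @export
patternDistance <- function(e, f) {
    editDistance(patternWindows(e), patternWindows(f)) +
        editDistance(patternComplements(e), patternComplements(f))
}

#' All-pairs pattern distances between two PatternSets
#'
#' @param e,f [PatternSet-class] objects.
#' @return An \code{length(e)} x \code{length(f)} integer matrix of
#'   pattern distances.
#' @export
patternDistanceMatrix <- function(e, f = e) {
    .editDistanceCross(patternWindows(e), patternWindows(f)) +
        .editDistanceCross(patternComplements(e), patternComplements(f))
}

#' Build the similarity matrix for affinity propagation
#'
#' Off-diagonal entries are the negated pattern distances,
#' \eqn{s(i,j) = -D_{similar}(i,j)}; the diagonal is set to the
#' preference, which controls how readily points become exemplars.
#'
#' @param patterns a [PatternSet-class] with at least 2 patterns.
#' @param preference \code{"median"} (median of the off-diagonal
#'   similarities, the usual affinity-propagation default),
#'   \code{"min"} (their minimum, favouring few clusters), or a numeric
#'   scalar.
#' @return A [SimilarityMatrix-class].
#' @export
buildSimilarityMatrix <- function(patterns, preference = "median") {
    n <- length(patterns)
    if (n < 2L)
        stop("need at least 2 patterns to build a similarity matrix")
    S <- -patternDistanceMatrix(patterns, patterns)
    storage.mode(S) <- "double"
    off <- S[row(S) != col(S)]
    pref <- if (is.numeric(preference)) {
        as.numeric(preference[1])
    } else if (identical(preference, "median")) {
        median(off)
    } else if (identical(preference, "min")) {
        min(off)
    } else {
        stop("preference must be 'median', 'min' or a numeric scalar")
    }
    diag(S) <- pref
    new("SimilarityMatrix", similarity = S, preference = pref)
}

#' Export a similarity matrix as TSV
#'
#' @param x a [SimilarityMatrix-class].
#' @param path output file.
#' @export
writeSimilarityMatrix <- function(x, path) {
    write.table(similarity(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
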