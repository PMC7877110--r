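## Affinity propagation (message passing between responsibility and
## availability matrices) implemented from scratch in matrix form:
##   r(i,k) <- s(i,k) - max_{k' != k} { a(i,k') + s(i,k') }
##   a(i,k) <- min(0, r(k,k) + sum_{i' not in {i,k}} max(0, r(i',k))), i != k
##   a(k,k) <- sum_{i' != k} max(0, r(i',k))
## with damping new = lambda * old + (1 - lambda) * computed. Exemplars are
## the points with positive diag(A + R); after convergence the exemplar of
## each cluster is refined to the member maximizing the within-cluster
## similarity sum (as in the canonical reference implementation) and every
## point is labelled with its most similar exemplar.

.rowMax2 <- function(M) {
    # value of the max and the runner-up per row, plus argmax (first wins)
    n <- nrow(M)
    i1 <- max.col(M, ties.method = "first")
    idx <- cbind(seq_len(n), i1)
    m1 <- M[idx]
    M[idx] <- -Inf
    m2 <- M[cbind(seq_len(n), max.col(M, ties.method = "first"))]
    list(m1 = m1, m2 = m2, i1 = i1)
}

#' Affinity propagation clustering
#'
#' @param S a [SimilarityMatrix-class], or a square numeric matrix whose
#'   diagonal already holds the preference.
#' @param damping damping factor \eqn{\lambda \in [0.5, 1)}.
#' @param maxIter maximum number of message-passing sweeps.
#' @param convWindow number of consecutive sweeps the exemplar set must
#'   stay unchanged (with at least one exemplar) to declare convergence.
#' @return A [ClusterModel-class]. Non-convergence is not an error: the
#'   \code{converged} flag is \code{FALSE} and, if no exemplar emerged,
#'   the exemplar set is empty and labels are \code{NA}.
#' @export
affinityPropagation <- function(S, damping = 0.5, maxIter = 1000L,
                                convWindow = 50L) {
    if (is(S, "SimilarityMatrix")) S <- similarity(S)
    if (!is.matrix(S) || nrow(S) != ncol(S))
        stop("S must be a square matrix or SimilarityMatrix")
    if (any(is.na(S)) || any(!is.finite(S)))
        stop("S contains NA/NaN/Inf")
    if (damping < 0.5 || damping >= 1)
        stop("damping must be in [0.5, 1)")
    n <- nrow(S)
    ## deterministic symmetry breaking: exactly tied configurations
    ## (e.g. duplicated inputs) otherwise leave every candidate exemplar
    ## at the 0-evidence boundary and the message passing degenerate --
    ## canonical implementations add random noise to S for the same
    ## reason. A strictly decreasing diagonal perturbation, ~1e-9 of the
    ## similarity scale, resolves such ties toward the lowest index
    ## without affecting non-degenerate problems.
    scale <- max(abs(S), 1)
    diag(S) <- diag(S) + 1e-9 * scale * (n - seq_len(n)) / n
    R <- matrix(0, n, n)
    A <- matrix(0, n, n)
    idxDiag <- cbind(seq_len(n), seq_len(n))
    prevE <- rep(FALSE, n)
    stableFor <- 0L
    converged <- FALSE
    it <- 0L
    while (it < maxIter) {
        it <- it + 1L
        ## responsibilities
        AS <- A + S
        mx <- .rowMax2(AS)
        Rnew <- S - mx$m1
        Rnew[cbind(seq_len(n), mx$i1)] <- S[cbind(seq_len(n), mx$i1)] -
            mx$m2
        R <- damping * R + (1 - damping) * Rnew
        ## availabilities
        Rp <- pmax(R, 0)
        Rp[idxDiag] <- R[idxDiag]
        colTotal <- colSums(Rp)
        Anew <- matrix(colTotal, n, n, byrow = TRUE) - Rp
        dA <- Anew[idxDiag]
        Anew <- pmin(Anew, 0)
        Anew[idxDiag] <- dA
        A <- damping * A + (1 - damping) * Anew
        ## convergence on the exemplar set
        E <- (diag(A) + diag(R)) > 0
        if (identical(E, prevE)) {
            stableFor <- stableFor + 1L
        } else {
            stableFor <- 0L
        }
        prevE <- E
        if (stableFor >= convWindow && any(E)) {
            converged <- TRUE
            break
        }
    }
    ex <- which(prevE)
    if (length(ex) == 0L) {
        return(new("ClusterModel", exemplars = integer(0),
                   labels = rep(NA_integer_, n), converged = FALSE,
                   iterations = it, responsibility = R, availability = A))
    }
    ## canonical final assignment + exemplar refinement
    cl <- max.col(S[, ex, drop = FALSE], ties.method = "first")
    cl[ex] <- seq_along(ex)
    for (k in seq_along(ex)) {
        members <- which(cl == k)
        if (length(members) > 0L) {
            within <- colSums(S[members, members, drop = FALSE])
            ex[k] <- members[which.max(within)]
        }
    }
    cl <- max.col(S[, ex, drop = FALSE], ties.method = "first")
    cl[ex] <- seq_along(ex)
    labels <- ex[cl]
    ex <- sort(unique(labels))
    new("ClusterModel", exemplars = as.integer(ex),
        labels = as.integer(labels), converged = converged,
        iterations = it, responsibility = R, availability = A)
}

#' Assign test patterns to the class of the nearest exemplar
#'
#' Each test pattern receives the cluster label of the exemplar with the
#' minimum pattern distance (window + complement edit distance, the same
#' distance used to build the training similarity matrix). Ties are
#' broken by the lowest exemplar position in \code{exemplarPatterns}.
#'
#' @param test a [PatternSet-class] of test patterns.
#' @param exemplarPatterns a [PatternSet-class] of cluster exemplars.
#' @param exemplarClasses class ids parallel to \code{exemplarPatterns};
#'   defaults to their position.
#' @return Vector of class ids, one per test pattern.
#' @export
assignClass <- function(test, exemplarPatterns,
                        exemplarClasses = seq_len(length(exemplarPatterns))) {
    if (length(exemplarPatterns) == 0L)
        stop("need at least one exemplar")
    if (length(exemplarClasses) != length(exemplarPatterns))
        stop("exemplarClasses must be parallel to exemplarPatterns")
    D <- patternDistanceMatrix(test, exemplarPatterns)
    nearest <- apply(D, 1L, which.min)  # which.min: first (lowest) index wins
    exemplarClasses[nearest]
}

#' Cleavage ratio and label bins per cluster
#'
#' For every cluster \eqn{i}, computes
#' \eqn{ratio_i = N_i(cleavage) / (N_i(cleavage) + N_i(non\mbox{-}cleavage))}
#' and assigns bin label 1..5 for
#' \eqn{ratio_i \in [0,0.2], (0.2,0.4], (0.4,0.6], (0.6,0.8], (0.8,1]}
#' (closed upper edges; a ratio of exactly 0.2 falls in bin 1). Clusters
#' in bins 1 and 5 are dominated by one class and indicate that the
#' cluster id is informative about cleavage.
#'
#' @param clusterLabels per-sample cluster ids.
#' @param patternLabels per-sample \code{"cleavage"}/\code{"non_cleavage"}
#'   labels, parallel to \code{clusterLabels}.
#' @return A list with \code{classes} (per-cluster data.frame:
#'   \code{class}, \code{nCleavage}, \code{nNonCleavage}, \code{ratio},
#'   \code{bin}) and \code{bins} (per-bin data.frame: \code{bin},
#'   \code{nClasses}, \code{nSamples}).
#' @export
classRatioSummary <- function(clusterLabels, patternLabels) {
    stopifnot(length(clusterLabels) == length(patternLabels),
              all(patternLabels %in% c("cleavage", "non_cleavage")))
    cls <- sort(unique(clusterLabels))
    nClv <- vapply(cls, function(k)
        sum(clusterLabels == k & patternLabels == "cleavage"), integer(1))
    nNon <- vapply(cls, function(k)
        sum(clusterLabels == k & patternLabels == "non_cleavage"),
        integer(1))
    ratio <- nClv / (nClv + nNon)
    bin <- as.integer(cut(ratio, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                          include.lowest = TRUE, right = TRUE))
    classes <- data.frame(class = cls, nCleavage = nClv,
                          nNonCleavage = nNon, ratio = ratio, bin = bin)
    bins <- data.frame(
        bin = 1:5,
        nClasses = vapply(1:5, function(b) sum(bin == b), integer(1)),
        nSamples = vapply(1:5, function(b)
            sum((nClv + nNon)[bin == b]), integer(1)))
    list(classes = classes, bins = bins)
}
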