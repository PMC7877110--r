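#' PatternSet: 14-nt cleavage/non-cleavage windows with complementary strands
#'
#' Container for the windows extracted around (putative) Dicer scissile
#' bonds. Each element holds the pre-miRNA id, the arm (\code{"5p"} or
#' \code{"3p"}), the label (\code{"cleavage"} or \code{"non_cleavage"}),
#' the 14-nt window sequence, its complementary strand over
#' \code{A,C,G,U,O} (\code{O} marks a position with no pairing partner),
#' and the 1-based start of the window in the pre-miRNA.
#'
#' @slot id character, pre-miRNA identifiers.
#' @slot arm character, \code{"5p"} or \code{"3p"}.
#' @slot label character, \code{"cleavage"} or \code{"non_cleavage"}.
#' @slot window character, 14-nt sequences over \code{A,C,G,U}.
#' @slot complement character, 14-character strings over \code{A,C,G,U,O}.
#' @slot windowStart integer, 1-based window start positions.
#'
#' @aliases PatternSet
#' @exportClass PatternSet
setClass("PatternSet",
    representation(
        id = "character",
        arm = "character",
        label = "character",
        window = "character",
        complement = "character",
        windowStart = "integer"
    )
)

setValidity("PatternSet", function(object) {
    n <- length(object@id)
    lens <- c(length(object@arm), length(object@label),
              length(object@window), length(object@complement),
              length(object@windowStart))
    if (any(lens != n))
        return("all slots must have equal length")
    if (n == 0L)
        return(TRUE)
    if (!all(object@arm %in% c("5p", "3p")))
        return("arm must be '5p' or '3p'")
    if (!all(object@label %in% c("cleavage", "non_cleavage")))
        return("label must be 'cleavage' or 'non_cleavage'")
    if (any(nchar(object@window) != WINDOW_SIZE) ||
        any(nchar(object@complement) != WINDOW_SIZE))
        return(sprintf("window and complement must be %d characters",
                       WINDOW_SIZE))
    if (any(grepl(sprintf("[^%s]", paste(RNA_BASES, collapse = "")),
                  object@window)))
        return("window may contain only A/C/G/U")
    if (any(grepl(sprintf("[^%s]", paste(COMPLEMENT_ALPHABET, collapse = "")),
                  object@complement)))
        return("complement may contain only A/C/G/U/O")
    TRUE
})

#' Construct a PatternSet
#'
#' @param id,arm,label,window,complement,windowStart parallel vectors, see
#'   the class description.
#' @return A [PatternSet-class] object.
#' @export
PatternSet <- function(id = character(), arm = character(),
                       label = character(), window = character(),
                       complement = character(),
                       windowStart = integer()) {
    n <- max(length(id), length(arm), length(label), length(window),
             length(complement), length(windowStart))
    r <- function(x) if (length(x) == 1L && n > 1L) rep(x, n) else x
    new("PatternSet", id = r(as.character(id)), arm = r(as.character(arm)),
        label = r(as.character(label)), window = r(as.character(window)),
        complement = r(as.character(complement)),
        windowStart = r(as.integer(windowStart)))
}

#' SimilarityMatrix: negated pattern distances for affinity propagation
#'
#' An \eqn{n \times n} matrix with off-diagonal entries
#' \eqn{s(i,j) = -D_{similar}(i,j)}, where the pattern distance is the sum
#' of the edit distances between the two windows and between the two
#' complementary strands. The diagonal holds the affinity-propagation
#' preference.
#'
#' @slot similarity numeric matrix.
#' @slot preference numeric scalar, the shared diagonal value.
#'
#' @aliases SimilarityMatrix
#' @exportClass SimilarityMatrix
setClass("SimilarityMatrix",
    representation(similarity = "matrix", preference = "numeric")
)

setValidity("SimilarityMatrix", function(object) {
    S <- object@similarity
    if (nrow(S) != ncol(S))
        return("similarity matrix must be square")
    if (nrow(S) < 2L)
        return("similarity matrix needs at least 2 samples")
    if (any(!is.finite(S)))
        return("similarity matrix must be finite")
    if (!isSymmetric(unname(S)))
        return("similarity matrix must be symmetric")
    off <- S[row(S) != col(S)]
    if (any(off > 0))
        return("off-diagonal similarities must be <= 0 (negated distances)")
    if (length(object@preference) != 1L)
        return("preference must be a scalar")
    if (any(diag(S) != object@preference))
        return("diagonal must equal the preference")
    TRUE
})

#' ClusterModel: result of affinity propagation
#'
#' @slot exemplars integer, indices of the cluster exemplars (ascending).
#' @slot labels integer, per-sample exemplar index (cluster id); exemplars
#'   label themselves.
#' @slot converged logical, whether the exemplar set was stable for the
#'   convergence window before the iteration cap.
#' @slot iterations integer, message-passing sweeps executed.
#' @slot responsibility,availability numeric matrices, final messages.
#'
#' @aliases ClusterModel
#' @exportClass ClusterModel
setClass("ClusterModel",
    representation(
        exemplars = "integer",
        labels = "integer",
        converged = "logical",
        iterations = "integer",
        responsibility = "matrix",
        availability = "matrix"
    )
)

setValidity("ClusterModel", function(object) {
    k <- object@exemplars
    lab <- object@labels
    if (length(k) > 0L) {
        if (!all(lab %in% k))
            return("every label must be an exemplar index")
        if (!all(lab[k] == k))
            return("exemplars must label themselves")
    }
    TRUE
})

#' TrainedCleavageModel: fitted gradient-boosted cleavage classifier
#'
#' @slot booster the fitted boosting model.
#' @slot hyperparameters list with \code{max_depth}, \code{learning_rate},
#'   \code{num_leaves} chosen by grid search, plus \code{nrounds}.
#' @slot featureLevels named list of factor levels per feature column,
#'   shared between training and prediction.
#' @slot importance data.frame with per-feature \code{frequency} (number of
#'   splits using the feature) and \code{gain} scores.
#' @slot cvAccuracy data.frame, cross-validated accuracy per grid point.
#'
#' @aliases TrainedCleavageModel
#' @exportClass TrainedCleavageModel
setClass("TrainedCleavageModel",
    representation(
        booster = "ANY",
        hyperparameters = "list",
        featureLevels = "list",
        importance = "data.frame",
        cvAccuracy = "data.frame"
    )
)

## ---- generics ----

#' @rdname PatternSet-accessors
#' @export
setGeneric("patternIds", function(x) standardGeneric("patternIds"))
#' @rdname PatternSet-accessors
#' @export
setGeneric("patternArms", function(x) standardGeneric("patternArms"))
#' @rdname PatternSet-accessors
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))
#' @rdname PatternSet-accessors
#' @export
setGeneric("patternWindows", function(x) standardGeneric("patternWindows"))
#' @rdname PatternSet-accessors
#' @export
setGeneric("patternComplements",
           function(x) standardGeneric("patternComplements"))
#' @rdname PatternSet-accessors
#' @export
setGeneric("patternStarts", function(x) standardGeneric("patternStarts"))

#' @rdname SimilarityMatrix-accessors
#' @export
setGeneric("similarity", function(x) standardGeneric("similarity"))
#' @rdname SimilarityMatrix-accessors
#' @export
setGeneric("preference", function(x) standardGeneric("preference"))

#' @rdname ClusterModel-accessors
#' @export
setGeneric("exemplars", function(x) standardGeneric("exemplars"))
#' @rdname ClusterModel-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ClusterModel-accessors
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

## ---- PatternSet methods ----

#' Accessors for PatternSet
#'
#' @param x a [PatternSet-class].
#' @name PatternSet-accessors
#' @aliases patternIds,PatternSet-method patternArms,PatternSet-method
#'   patternLabels,PatternSet-method patternWindows,PatternSet-method
#'   patternComplements,PatternSet-method patternStarts,PatternSet-method
NULL

#' @rdname PatternSet-accessors
setMethod("patternIds", "PatternSet", function(x) x@id)
#' @rdname PatternSet-accessors
setMethod("patternArms", "PatternSet", function(x) x@arm)
#' @rdname PatternSet-accessors
setMethod("patternLabels", "PatternSet", function(x) x@label)
#' @rdname PatternSet-accessors
setMethod("patternWindows", "PatternSet", function(x) x@window)
#' @rdname PatternSet-accessors
setMethod("patternComplements", "PatternSet", function(x) x@complement)
#' @rdname PatternSet-accessors
setMethod("patternStarts", "PatternSet", function(x) x@windowStart)

#' @describeIn PatternSet number of patterns
#' @param x a PatternSet
#' @export
setMethod("length", "PatternSet", function(x) length(x@id))

#' @describeIn PatternSet subset patterns
#' @param i index vector
#' @param j,drop ignored
#' @param ... ignored
#' @export
setMethod("[", "PatternSet", function(x, i, j, ..., drop = TRUE) {
    PatternSet(x@id[i], x@arm[i], x@label[i], x@window[i],
               x@complement[i], x@windowStart[i])
})

#' Combine PatternSet objects
#' @param x,... PatternSet objects.
#' @export
setMethod("c", "PatternSet", function(x, ...) {
    objs <- c(list(x), list(...))
    PatternSet(
        unlist(lapply(objs, patternIds)),
        unlist(lapply(objs, patternArms)),
        unlist(lapply(objs, patternLabels)),
        unlist(lapply(objs, patternWindows)),
        unlist(lapply(objs, patternComplements)),
        unlist(lapply(objs, patternStarts))
    )
})

#' Coerce a PatternSet to data.frame
#' @param x a PatternSet.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "PatternSet", function(x, ...) {
    data.frame(id = x@id, arm = x@arm, label = x@label,
               window = x@window, complement = x@complement,
               window_start = x@windowStart,
               stringsAsFactors = FALSE)
})

setMethod("show", "PatternSet", function(object) {
    cat(sprintf("PatternSet with %d patterns (%d cleavage, %d non-cleavage)\n",
                length(object),
                sum(object@label == "cleavage"),
                sum(object@label == "non_cleavage")))
    if (length(object) > 0L) {
        n <- min(3L, length(object))
        for (i in seq_len(n))
            cat(sprintf("  %s %s %s %s | %s\n", object@id[i], object@arm[i],
                        object@label[i], object@window[i],
                        object@complement[i]))
        if (length(object) > n) cat("  ...\n")
    }
})

## ---- SimilarityMatrix methods ----

#' Accessors for SimilarityMatrix
#' @param x a [SimilarityMatrix-class].
#' @name SimilarityMatrix-accessors
#' @aliases similarity,SimilarityMatrix-method
#'   preference,SimilarityMatrix-method
NULL

#' @rdname SimilarityMatrix-accessors
setMethod("similarity", "SimilarityMatrix", function(x) x@similarity)
#' @rdname SimilarityMatrix-accessors
setMethod("preference", "SimilarityMatrix", function(x) x@preference)

#' @describeIn SimilarityMatrix dimensions of the underlying matrix
#' @param x a SimilarityMatrix
#' @export
setMethod("dim", "SimilarityMatrix", function(x) dim(x@similarity))

setMethod("show", "SimilarityMatrix", function(object) {
    cat(sprintf("SimilarityMatrix: %d samples, preference %.3f\n",
                nrow(object@similarity), object@preference))
})

## ---- ClusterModel methods ----

#' Accessors for ClusterModel
#' @param x a [ClusterModel-class].
#' @name ClusterModel-accessors
#' @aliases exemplars,ClusterModel-method clusterLabels,ClusterModel-method
#'   isConverged,ClusterModel-method
NULL

#' @rdname ClusterModel-accessors
setMethod("exemplars", "ClusterModel", function(x) x@exemplars)
#' @rdname ClusterModel-accessors
setMethod("clusterLabels", "ClusterModel", function(x) x@labels)
#' @rdname ClusterModel-accessors
setMethod("isConverged", "ClusterModel", function(x) x@converged)

setMethod("show", "ClusterModel", function(object) {
    cat(sprintf(
        "ClusterModel: %d clusters over %d samples (%s after %d sweeps)\n",
        length(object@exemplars), length(object@labels),
        if (object@converged) "converged" else "not converged",
        object@iterations))
})

setMethod("show", "TrainedCleavageModel", function(object) {
    hp <- object@hyperparameters
    cat(sprintf(paste0("TrainedCleavageModel: max_depth=%s, ",
                       "learning_rate=%s, num_leaves=%s, nrounds=%s\n"),
                hp$max_depth, hp$learning_rate, hp$num_leaves, hp$nrounds))
    cat(sprintf("  %d features\n", length(object@featureLevels)))
})
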