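## Extraction of the 14-nt cleavage and non-cleavage windows and their
## structure-derived complementary strands. The scissile bond sits between
## window offsets 7 and 8 (7 nt on each side); cleavage_pos is the last
## nucleotide 5' of the bond, so the window spans cleavage_pos - 6 ..
## cleavage_pos + 7. The non-cleavage window centre is displaced 6 nt
## toward the arm's free terminus (5' for the 5p arm, 3' for the 3p arm),
## away from the hairpin loop.

.windowStartFromPos <- function(cleavagePos) {
    as.integer(cleavagePos) - (HALF_WINDOW - 1L)
}

.substrWindow <- function(sequence, start) {
    substr(sequence, start, start + WINDOW_SIZE - 1L)
}

#' Complementary strand of a window under a secondary structure
#'
#' For each window position, the base paired with it according to the
#' pair table, or \code{O} when the position is unpaired (loop/bulge).
#' G-U wobble pairs are reported as written in the structure.
#'
#' @param start 1-based start of the window in the pre-miRNA.
#' @param pairTable integer pair table (see [dotBracketToPairTable()]).
#' @param sequence the pre-miRNA sequence.
#' @return A 14-character string over \code{A,C,G,U,O}.
#' @export
#' @examples
#' pt <- dotBracketToPairTable("((((((((((((((..))))))))))))))")
#' seq <- "GGGGGGGGGGGGGGAACCCCCCCCCCCCCC"
#' complementOfWindow(1, pt, seq)
complementOfWindow <- function(start, pairTable, sequence) {
    start <- as.integer(start)
    if (start < 1L || start + WINDOW_SIZE - 1L > nchar(sequence))
        stop("window does not fit inside the sequence")
    pos <- start:(start + WINDOW_SIZE - 1L)
    partners <- pairTable[pos]
    out <- ifelse(is.na(partners), "O",
                  substring(sequence, partners, partners))
    paste(out, collapse = "")
}

.makePattern <- function(id, arm, label, sequence, pairTable, start) {
    if (start < 1L || start + WINDOW_SIZE - 1L > nchar(sequence))
        stop(sprintf("window [%d,%d] does not fit in '%s' (length %d)",
                     start, start + WINDOW_SIZE - 1L, id, nchar(sequence)))
    PatternSet(id = id, arm = arm, label = label,
               window = .substrWindow(sequence, start),
               complement = complementOfWindow(start, pairTable, sequence),
               windowStart = start)
}

#' Extract the cleavage pattern of a pre-miRNA arm
#'
#' The 14-nt window centred on the scissile bond (bond between window
#' offsets 7 and 8), together with its complementary strand.
#'
#' @param sequence pre-miRNA RNA sequence.
#' @param pairTable integer pair table for the sequence.
#' @param annotation list or one-row data.frame with \code{id},
#'   \code{arm} and \code{cleavage_pos}.
#' @return A length-1 [PatternSet-class].
#' @export
extractCleavagePattern <- function(sequence, pairTable, annotation) {
    .makePattern(annotation$id, annotation$arm, "cleavage", sequence,
                 pairTable, .windowStartFromPos(annotation$cleavage_pos))
}

#' Extract the non-cleavage pattern of a pre-miRNA arm
#'
#' Same-size window whose centre is 6 nt away from the cleavage centre,
#' shifted toward the arm's free terminus: the 5p window moves 6 nt
#' toward the 5' end, the 3p window 6 nt toward the 3' end, so both move
#' away from the hairpin loop.
#'
#' @inheritParams extractCleavagePattern
#' @return A length-1 [PatternSet-class].
#' @export
extractNonCleavagePattern <- function(sequence, pairTable, annotation) {
    shift <- if (annotation$arm == "5p") -NONCLEAVAGE_SHIFT else
        NONCLEAVAGE_SHIFT
    .makePattern(annotation$id, annotation$arm, "non_cleavage", sequence,
                 pairTable,
                 .windowStartFromPos(annotation$cleavage_pos) + shift)
}

#' Build the pattern dataset from sequences, structures and annotations
#'
#' For every valid annotation, one cleavage and one non-cleavage pattern
#' are produced, so the dataset is balanced by construction. Annotations
#' whose id has no sequence or structure are skipped with a warning; if
#' either window would cross a sequence boundary, both patterns of that
#' annotation are dropped (with a warning) to preserve class balance.
#'
#' @param sequences named character vector of pre-miRNA sequences.
#' @param pairTables named list of pair tables.
#' @param annotations data.frame from [readCleavageAnnotations()].
#' @param arm optional, restrict to \code{"5p"} or \code{"3p"}.
#' @return A [PatternSet-class].
#' @export
buildPatternSet <- function(sequences, pairTables, annotations,
                            arm = NULL) {
    if (!is.null(arm)) {
        stopifnot(arm %in% c("5p", "3p"))
        annotations <- annotations[annotations$arm == arm, , drop = FALSE]
    }
    out <- vector("list", nrow(annotations))
    nSkipMissing <- 0L
    nSkipWindow <- 0L
    for (r in seq_len(nrow(annotations))) {
        ann <- annotations[r, ]
        if (!ann$id %in% names(sequences) ||
            !ann$id %in% names(pairTables)) {
            nSkipMissing <- nSkipMissing + 1L
            next
        }
        seq <- sequences[[ann$id]]
        pt <- pairTables[[ann$id]]
        if (length(pt) != nchar(seq))
            stop(sprintf("pair table length %d != sequence length %d for '%s'",
                         length(pt), nchar(seq), ann$id))
        pats <- tryCatch(
            c(extractCleavagePattern(seq, pt, ann),
              extractNonCleavagePattern(seq, pt, ann)),
            error = function(e) NULL)
        if (is.null(pats)) {
            nSkipWindow <- nSkipWindow + 1L
            next
        }
        out[[r]] <- pats
    }
    if (nSkipMissing > 0L)
        warning(sprintf("skipped %d annotation(s) without sequence/structure",
                        nSkipMissing))
    if (nSkipWindow > 0L)
        warning(sprintf("dropped %d pre-miRNA record(s) whose window crosses a boundary",
                        nSkipWindow))
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) return(PatternSet())
    do.call(c, out)
}

#' Write a PatternSet as TSV
#'
#' @param patterns a [PatternSet-class].
#' @param path output file.
#' @export
writePatterns <- function(patterns, path) {
    write.table(as.data.frame(patterns), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read a PatternSet from TSV
#'
#' @param path file written by [writePatterns()].
#' @return A [PatternSet-class].
#' @export
readPatterns <- function(path) {
    df <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    PatternSet(df$id, df$arm, df$label, df$window, df$complement,
               df$window_start)
}
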