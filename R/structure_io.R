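## Readers/writers for the formats the pipeline touches: FASTA, Vienna
## dot-bracket, CT, and the cleavage-annotation TSV. Internally sequences
## are RNA character strings and structures are "pair tables": integer
## vectors with pt[i] = 1-based partner of position i, NA when unpaired.
## CT files and annotation positions are 1-based on disk as well, so only
## the unpaired encoding (0 vs NA) converts at the boundary.

.normalizeRNA <- function(seqs, what = "sequence") {
    seqs <- chartr("tu", "TU", toupper(seqs))
    seqs <- chartr("T", "U", seqs)
    bad <- grepl("[^ACGU]", seqs)
    if (any(bad)) {
        nm <- names(seqs)[bad][1]
        stop(sprintf("non-ACGU/T characters in %s '%s'", what,
                     if (is.null(nm) || is.na(nm)) which(bad)[1] else nm))
    }
    seqs
}

#' Read pre-miRNA sequences from a FASTA file
#'
#' Sequences are uppercased and DNA-style \code{T} is converted to
#' \code{U}; any other non-\code{ACGU} character is an error naming the
#' offending record. Identifiers are the header up to the first
#' whitespace.
#'
#' @param path FASTA file.
#' @return A named character vector of RNA sequences.
#' @export
readFastaRNA <- function(path) {
    x <- Biostrings::readBStringSet(path)
    seqs <- as.character(x)
    names(seqs) <- sub("\\s.*$", "", names(x))
    if (length(seqs) == 0L) return(setNames(character(), character()))
    .normalizeRNA(seqs, "FASTA record")
}

#' Write RNA sequences to a FASTA file
#'
#' @param sequences named character vector of RNA sequences.
#' @param path output file.
#' @export
writeFastaRNA <- function(sequences, path) {
    x <- Biostrings::RNAStringSet(sequences)
    Biostrings::writeXStringSet(x, path)
    invisible(path)
}

#' Convert a dot-bracket string to a pair table
#'
#' Matches \code{(} with \code{)} by stack; \code{.} is unpaired.
#'
#' @param db dot-bracket string.
#' @return Integer vector \code{pt} with \code{pt[i]} the 1-based partner
#'   of position \code{i}, \code{NA} if unpaired.
#' @export
dotBracketToPairTable <- function(db) {
    chars <- strsplit(db, "")[[1]]
    bad <- which(!chars %in% c("(", ")", "."))
    if (length(bad) > 0L)
        stop(sprintf("invalid dot-bracket character '%s' at position %d",
                     chars[bad[1]], bad[1]))
    n <- length(chars)
    pt <- rep(NA_integer_, n)
    stack <- integer(0)
    for (i in seq_len(n)) {
        if (chars[i] == "(") {
            stack <- c(stack, i)
        } else if (chars[i] == ")") {
            if (length(stack) == 0L)
                stop(sprintf("unbalanced ')' at position %d", i))
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pt[j] <- i
            pt[i] <- j
        }
    }
    if (length(stack) > 0L)
        stop(sprintf("unbalanced '(' at position %d", stack[length(stack)]))
    pt
}

#' Convert a pair table to a dot-bracket string
#'
#' @param pt integer pair table (see [dotBracketToPairTable()]).
#' @return A dot-bracket string.
#' @export
pairTableToDotBracket <- function(pt) {
    .checkPairTable(pt)
    chars <- rep(".", length(pt))
    paired <- which(!is.na(pt))
    chars[paired[pt[paired] > paired]] <- "("
    chars[paired[pt[paired] < paired]] <- ")"
    paste(chars, collapse = "")
}

.checkPairTable <- function(pt) {
    paired <- which(!is.na(pt))
    if (length(paired) > 0L) {
        if (any(pt[paired] < 1L | pt[paired] > length(pt)))
            stop("pair table partner out of range")
        if (any(pt[pt[paired]] != paired))
            stop("pair table is not symmetric")
        if (any(pt[paired] == paired))
            stop("a position cannot pair with itself")
    }
    invisible(TRUE)
}

# crossing pairs (i<k<j<l with i~j, k~l) cannot be expressed in plain
# dot-bracket and are rejected at the CT boundary
.hasPseudoknot <- function(pt) {
    op <- which(!is.na(pt) & pt > seq_along(pt))
    if (length(op) < 2L) return(FALSE)
    cl <- pt[op]
    for (a in seq_along(op)) {
        crossing <- op > op[a] & op < cl[a] & cl > cl[a]
        if (any(crossing)) return(TRUE)
    }
    FALSE
}

#' Read Vienna dot-bracket records
#'
#' Parses the three-line dialect emitted by RNA folding tools: a
#' \code{>id} header, the sequence, and the structure line with an
#' optional trailing free energy such as \code{(-12.30)}, which is
#' ignored. If a file carries several structures for the same id, only
#' the first (minimum free energy) one is kept, with a warning.
#'
#' @param path dot-bracket file.
#' @return A list with \code{sequences} (named character vector) and
#'   \code{pairTables} (named list of integer pair tables).
#' @export
readDotBracket <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sequences <- character()
    pairTables <- list()
    i <- 1L
    while (i <= length(lines)) {
        if (!startsWith(lines[i], ">"))
            stop(sprintf("expected FASTA-style header at line %d", i))
        if (i + 2L > length(lines))
            stop(sprintf("truncated record starting at line %d", i))
        id <- sub("\\s.*$", "", sub("^>", "", lines[i]))
        seq <- .normalizeRNA(trimws(lines[i + 1L]),
                             sprintf("record '%s'", id))
        struct <- trimws(sub("\\s*\\([-+0-9.]+\\)\\s*$", "",
                             trimws(lines[i + 2L])))
        if (nchar(struct) != nchar(seq))
            stop(sprintf(
                "structure length %d != sequence length %d for '%s'",
                nchar(struct), nchar(seq), id))
        pt <- tryCatch(dotBracketToPairTable(struct),
                       error = function(e)
                           stop(sprintf("record '%s': %s", id,
                                        conditionMessage(e))))
        if (id %in% names(sequences)) {
            warning(sprintf(
                "duplicate structure for '%s'; keeping the first", id))
        } else {
            sequences[id] <- seq
            pairTables[[id]] <- pt
        }
        i <- i + 3L
    }
    list(sequences = sequences, pairTables = pairTables)
}

#' Write Vienna dot-bracket records
#'
#' @param sequences named character vector of RNA sequences.
#' @param pairTables named list of pair tables, parallel to
#'   \code{sequences}.
#' @param path output file.
#' @export
writeDotBracket <- function(sequences, pairTables, path) {
    stopifnot(length(sequences) == length(pairTables))
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(sequences)) {
        writeLines(c(paste0(">", id), sequences[[id]],
                     pairTableToDotBracket(pairTables[[id]])), con)
    }
    invisible(path)
}

#' Read CT (connectivity table) secondary-structure files
#'
#' Standard six-column mfold/quickfold CT: index, base, previous, next,
#' pairing partner (0 = unpaired), original index; 1-based. Files may
#' concatenate several structures, each introduced by its own count
#' line; when several belong to the same id only the first (minimum free
#' energy) is kept. Asymmetric pairing rows are an error citing both
#' rows; crossing (pseudoknotted) pairs are rejected.
#'
#' @param path CT file.
#' @return Same shape as [readDotBracket()].
#' @export
readCT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sequences <- character()
    pairTables <- list()
    i <- 1L
    k <- 0L
    while (i <= length(lines)) {
        header <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        n <- suppressWarnings(as.integer(header[1]))
        if (is.na(n) || n < 1L)
            stop(sprintf("expected CT count line at line %d", i))
        k <- k + 1L
        id <- if (length(header) > 1L)
            paste(header[-1], collapse = " ") else sprintf("structure_%d", k)
        id <- sub("\\s.*$", "", id)
        if (i + n > length(lines))
            stop(sprintf("truncated CT structure '%s'", id))
        bases <- character(n)
        pair <- integer(n)
        for (r in seq_len(n)) {
            f <- strsplit(trimws(lines[i + r]), "\\s+")[[1]]
            if (length(f) < 6L)
                stop(sprintf("CT row %d of '%s' has %d fields (need 6)",
                             r, id, length(f)))
            idx <- as.integer(f[1])
            if (is.na(idx) || idx != r)
                stop(sprintf("CT row index %s != expected %d in '%s'",
                             f[1], r, id))
            bases[r] <- f[2]
            pair[r] <- as.integer(f[5])
        }
        if (any(pair < 0L | pair > n))
            stop(sprintf("pairing partner out of range in '%s'", id))
        pt <- ifelse(pair == 0L, NA_integer_, pair)
        paired <- which(!is.na(pt))
        badSym <- paired[pt[pt[paired]] != paired | pt[paired] == paired]
        if (length(badSym) > 0L) {
            r1 <- badSym[1]
            stop(sprintf(
                "asymmetric pairing in '%s': row %d pairs with %d but row %d pairs with %s",
                id, r1, pt[r1], pt[r1], as.character(pt[pt[r1]])))
        }
        if (.hasPseudoknot(pt))
            stop(sprintf("crossing (pseudoknotted) pairs in '%s'", id))
        seq <- .normalizeRNA(paste(bases, collapse = ""),
                             sprintf("CT structure '%s'", id))
        if (id %in% names(sequences)) {
            warning(sprintf(
                "multiple structures for '%s'; keeping the first", id))
        } else {
            sequences[id] <- seq
            pairTables[[id]] <- pt
        }
        i <- i + n + 1L
    }
    list(sequences = sequences, pairTables = pairTables)
}

#' Write CT secondary-structure files
#'
#' @inheritParams writeDotBracket
#' @export
writeCT <- function(sequences, pairTables, path) {
    stopifnot(length(sequences) == length(pairTables))
    con <- file(path, "w")
    on.exit(close(con))
    for (id in names(sequences)) {
        seq <- strsplit(sequences[[id]], "")[[1]]
        pt <- pairTables[[id]]
        n <- length(seq)
        stopifnot(length(pt) == n)
        writeLines(sprintf("%d %s", n, id), con)
        for (r in seq_len(n)) {
            writeLines(sprintf("%d %s %d %d %d %d", r, seq[r], r - 1L,
                               if (r < n) r + 1L else 0L,
                               if (is.na(pt[r])) 0L else pt[r], r), con)
        }
    }
    invisible(path)
}

#' Read a cleavage-annotation table
#'
#' Tab-separated with a header line and columns \code{id}, \code{arm}
#' (\code{5p}/\code{3p}) and \code{cleavage_pos} (1-based position of the
#' nucleotide 5' of the scissile bond). Rows with an invalid arm or
#' non-positive position are skipped with a warning. When
#' \code{sequences} is supplied, rows whose 14-nt window does not fit
#' (\code{cleavage_pos < 7} or \code{cleavage_pos + 7 > length}) or whose
#' id has no sequence are also skipped with a warning.
#'
#' @param path annotation TSV.
#' @param sequences optional named character vector for window-fit
#'   validation.
#' @return data.frame with columns \code{id}, \code{arm},
#'   \code{cleavage_pos}.
#' @export
readCleavageAnnotations <- function(path, sequences = NULL) {
    df <- read.delim(path, sep = "\t", header = TRUE,
                     stringsAsFactors = FALSE)
    need <- c("id", "arm", "cleavage_pos")
    if (!all(need %in% names(df)))
        stop(sprintf("annotation file must have columns %s",
                     paste(need, collapse = ", ")))
    df <- df[need]
    df$cleavage_pos <- suppressWarnings(as.integer(df$cleavage_pos))
    bad <- !(df$arm %in% c("5p", "3p")) | is.na(df$cleavage_pos) |
        df$cleavage_pos < 1L
    if (any(bad)) {
        warning(sprintf("skipping %d annotation row(s) with invalid arm or position",
                        sum(bad)))
        df <- df[!bad, , drop = FALSE]
    }
    if (!is.null(sequences)) {
        len <- unname(nchar(sequences)[match(df$id, names(sequences))])
        unfit <- is.na(len) | df$cleavage_pos < HALF_WINDOW |
            df$cleavage_pos + HALF_WINDOW > len
        if (any(unfit)) {
            warning(sprintf(
                "skipping %d annotation row(s): missing sequence or window does not fit",
                sum(unfit)))
            df <- df[!unfit, , drop = FALSE]
        }
    }
    rownames(df) <- NULL
    df
}

#' Write a cleavage-annotation table
#'
#' @param annotations data.frame with \code{id}, \code{arm},
#'   \code{cleavage_pos}.
#' @param path output TSV.
#' @export
writeCleavageAnnotations <- function(annotations, path) {
    write.table(annotations[c("id", "arm", "cleavage_pos")], path,
                sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
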