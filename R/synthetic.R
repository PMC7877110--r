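## Synthetic structure-annotated hairpins. The generator builds a
## stem-loop from the outside in: a random 5' strand, a loop, and a 3'
## strand that is the Watson-Crick reverse complement of the 5' strand,
## with bulges (an extra unpaired base on one strand) and mismatches
## (both bases kept but unpaired) injected at given per-position rates.
## The ground-truth pair table comes from the generative process itself,
## so no folding tool is involved. Cleavage bonds are placed at a fixed
## offset from each free terminus, mirroring where Dicer cuts relative
## to the hairpin ends, and an optional sequence motif is planted across
## the scissile bond of cleavage windows to create learnable signal at a
## known location.

#' Specification of a synthetic pre-miRNA hairpin
#'
#' @param stemLength number of stem pair positions (>= 21 so that both
#'   the cleavage window and the 6-nt-shifted non-cleavage window fit
#'   on each arm; default 30).
#' @param loopLength loop size in nt (default 8).
#' @param bulgeRate per-stem-position probability of a single-strand
#'   bulge (default 0.05).
#' @param mismatchRate per-stem-position probability of a non-paired
#'   mismatch (default 0.05).
#' @param motif optional RNA string planted across the scissile bond of
#'   cleavage windows (window offsets 7 onward), e.g. \code{"UGGC"}.
#' @param motifStrength probability that the motif is planted in a
#'   given cleavage window (default 0 = never).
#' @param cleavageOffset 1-based distance of the nucleotide 5' of the
#'   scissile bond from the arm's free terminus (default 21).
#' @return A validated list of class \code{HairpinSpec}.
#' @export
hairpinSpec <- function(stemLength = 30L, loopLength = 8L,
                        bulgeRate = 0.05, mismatchRate = 0.05,
                        motif = NULL, motifStrength = 0,
                        cleavageOffset = 21L) {
    stemLength <- as.integer(stemLength)
    loopLength <- as.integer(loopLength)
    cleavageOffset <- as.integer(cleavageOffset)
    if (stemLength < 21L)
        stop("stemLength must be >= 21 so both windows fit on each arm")
    if (loopLength < 3L) stop("loopLength must be >= 3")
    if (bulgeRate < 0 || bulgeRate > 1 || mismatchRate < 0 ||
        mismatchRate > 1)
        stop("rates must be in [0, 1]")
    if (motifStrength < 0 || motifStrength > 1)
        stop("motifStrength must be in [0, 1]")
    if (!is.null(motif)) {
        motif <- .normalizeRNA(motif, "motif")
        if (nchar(motif) > HALF_WINDOW)
            stop(sprintf("motif longer than %d nt would leave the window",
                         HALF_WINDOW))
    }
    if (cleavageOffset < 2L * NONCLEAVAGE_SHIFT + 1L ||
        cleavageOffset + HALF_WINDOW > stemLength)
        stop(sprintf(
            "cleavageOffset must lie in [%d, stemLength - %d] so both windows fit",
            2L * NONCLEAVAGE_SHIFT + 1L, HALF_WINDOW))
    structure(list(stemLength = stemLength, loopLength = loopLength,
                   bulgeRate = bulgeRate, mismatchRate = mismatchRate,
                   motif = motif, motifStrength = motifStrength,
                   cleavageOffset = cleavageOffset),
              class = "HairpinSpec")
}

#' Generate one synthetic hairpin with ground-truth structure
#'
#' @param spec a [hairpinSpec()].
#' @param seed integer seed (the generator uses a private RNG stream).
#' @param id identifier for the hairpin.
#' @return List with \code{id}, \code{sequence}, \code{pairTable}
#'   (ground truth from the generative process) and \code{annotations}
#'   (data.frame with one 5p and one 3p cleavage row).
#' @export
generateHairpin <- function(spec, seed = 1L, id = "synth-mir-1") {
    stopifnot(inherits(spec, "HairpinSpec"))
    rng <- .seededSample(seed)
    draw <- function(v) rng(v, 1L)
    five <- character(0)      # 5' arm, outside -> in
    three <- character(0)     # 3' arm, outside -> in (built reversed)
    link5 <- integer(0)       # index into `three` paired with five[i], NA if unpaired
    for (i in seq_len(spec$stemLength)) {
        u <- draw(seq_len(10000L)) / 10000
        if (u < spec$bulgeRate) {
            # single-strand bulge on a random strand
            if (draw(c(TRUE, FALSE))) {
                five <- c(five, draw(RNA_BASES))
                link5 <- c(link5, NA_integer_)
            } else {
                three <- c(three, draw(RNA_BASES))
            }
        } else if (u < spec$bulgeRate + spec$mismatchRate) {
            b5 <- draw(RNA_BASES)
            five <- c(five, b5)
            link5 <- c(link5, NA_integer_)
            three <- c(three, draw(setdiff(RNA_BASES, WC_PARTNER[[b5]])))
        } else {
            b5 <- draw(RNA_BASES)
            five <- c(five, b5)
            three <- c(three, WC_PARTNER[[b5]])
            link5 <- c(link5, length(three))
        }
    }
    loop <- vapply(seq_len(spec$loopLength), function(i) draw(RNA_BASES),
                   character(1))
    n5 <- length(five)
    n3 <- length(three)
    L <- n5 + spec$loopLength + n3
    # 3' arm runs inside -> out in the final sequence: three[j] sits at
    # absolute position n5 + loopLength + (n3 - j + 1)
    seqChars <- c(five, loop, rev(three))
    pt <- rep(NA_integer_, L)
    paired <- which(!is.na(link5))
    pos3 <- n5 + spec$loopLength + (n3 - link5[paired] + 1L)
    pt[paired] <- pos3
    pt[pos3] <- paired

    pos5 <- spec$cleavageOffset
    pos3c <- L - spec$cleavageOffset
    ann <- data.frame(id = id, arm = c("5p", "3p"),
                      cleavage_pos = c(pos5, pos3c),
                      stringsAsFactors = FALSE)
    if (any(ann$cleavage_pos < 2L * NONCLEAVAGE_SHIFT + 1L) ||
        any(ann$cleavage_pos + HALF_WINDOW + NONCLEAVAGE_SHIFT > L))
        stop("generated hairpin too short for the cleavage windows")

    if (!is.null(spec$motif) && spec$motifStrength > 0) {
        for (r in seq_len(nrow(ann))) {
            u <- draw(seq_len(10000L)) / 10000
            if (u <= spec$motifStrength) {
                # plant across the scissile bond: window offsets 7..(6+|motif|)
                at <- ann$cleavage_pos[r]
                mot <- strsplit(spec$motif, "")[[1]]
                seqChars[at:(at + length(mot) - 1L)] <- mot
            }
        }
    }
    list(id = id, sequence = paste(seqChars, collapse = ""),
         pairTable = pt, annotations = ann)
}

#' Generate a synthetic hairpin dataset
#'
#' @param nHairpins number of hairpins.
#' @param spec a [hairpinSpec()].
#' @param seed master seed; hairpin \code{i} uses \code{seed + i}.
#' @param dir optional directory: when given, \code{hairpins.fa},
#'   \code{hairpins.db} (dot-bracket) and \code{annotations.tsv} are
#'   written there in the exact formats the readers consume.
#' @return List with \code{sequences} (named character vector),
#'   \code{pairTables} (named list) and \code{annotations} (data.frame,
#'   two rows per hairpin); when \code{dir} is given, also \code{files}.
#' @export
generateDataset <- function(nHairpins, spec = hairpinSpec(), seed = 1L,
                            dir = NULL) {
    stopifnot(nHairpins >= 1L)
    hairpins <- lapply(seq_len(nHairpins), function(i)
        generateHairpin(spec, seed = as.integer((seed + i) %%
                                                    .Machine$integer.max),
                        id = sprintf("synth-mir-%04d", i)))
    sequences <- setNames(vapply(hairpins, `[[`, character(1), "sequence"),
                          vapply(hairpins, `[[`, character(1), "id"))
    pairTables <- setNames(lapply(hairpins, `[[`, "pairTable"),
                           names(sequences))
    annotations <- do.call(rbind, lapply(hairpins, `[[`, "annotations"))
    out <- list(sequences = sequences, pairTables = pairTables,
                annotations = annotations)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        files <- c(
            fasta = writeFastaRNA(sequences, file.path(dir, "hairpins.fa")),
            dotbracket = writeDotBracket(sequences, pairTables,
                                         file.path(dir, "hairpins.db")),
            annotations = writeCleavageAnnotations(
                annotations, file.path(dir, "annotations.tsv")))
        out$files <- files
    }
    out
}
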