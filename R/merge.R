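# Overlap merging of amplicon read pairs into consensus reads.

#' Consensus base call for one overlapping position
#'
#' Combines the two mates' observations of a single position. On
#' agreement the base is kept and the qualities add (capped at Phred 60);
#' on disagreement the higher-quality mate wins and the consensus quality
#' is the absolute quality difference; a quality tie at a disagreement
#' keeps mate 1's base at quality 2.
#'
#' @param b1,b2 single bases (`A`/`C`/`G`/`T`/`N`).
#' @param q1,q2 Phred qualities (integers). Vectorized over all
#'   arguments.
#' @return A list with `base` and `qual` vectors.
#' @examples
#' consensusBase("A", 30, "A", 30)  # agreement: quality 60
#' consensusBase("A", 40, "C", 20)  # disagreement: A at quality 20
#' @export
consensusBase <- function(b1, q1, b2, q2) {
    agree <- b1 == b2
    base <- ifelse(agree, b1, ifelse(q1 > q2, b1, ifelse(q2 > q1, b2, b1)))
    qual <- ifelse(agree, pmin(q1 + q2, 60L),
                   ifelse(q1 == q2, 2L, abs(q1 - q2)))
    list(base = base, qual = as.integer(qual))
}

#' Merge an overlapping read pair into a consensus read
#'
#' Aligns read 1 against the reverse complement of read 2 with
#' Smith-Waterman. If the overlap reaches `minOverlap` alignment columns
#' at `minOverlapIdentity` identity, a consensus spanning the union of
#' the two reads is built: overlapping positions are resolved with
#' [consensusBase()], non-overlapping flanks are copied verbatim with
#' their qualities, and bases private to one read inside the overlap
#' (alignment gaps) are carried over from the read that has them.
#'
#' @param seq1,seq2 mate sequences (read 2 as sequenced, i.e. reverse
#'   strand).
#' @param qual1,qual2 integer Phred qualities, same lengths as the
#'   sequences.
#' @param params [MergeParams()].
#' @param id read identifier carried through to the result.
#' @return A list of class `MergedRead` with `seq`, `qual`,
#'   `overlapLen`, `sourceId`; or `NULL` if the pair is unmergeable.
#' @examples
#' s <- "ACGTACGTACGTACGTACGT"
#' m <- mergePair(s, as.character(Biostrings::reverseComplement(
#'     Biostrings::DNAString(s))), rep(30L, 20), rep(30L, 20))
#' m$seq == s
#' @export
mergePair <- function(seq1, seq2, qual1, qual2, params = MergeParams(),
                      id = "") {
    stopifnot(nchar(seq1) == length(qual1), nchar(seq2) == length(qual2))
    b <- revcomp(seq2)
    bq <- rev(qual2)
    al <- smithWaterman(seq1, b, params)
    mergeFromAlignment(seq1, b, qual1, bq, al, params, id)
}

# Build the consensus given read 1, the reverse-complemented mate (with
# reversed qualities) and their precomputed local alignment.
mergeFromAlignment <- function(seq1, b, qual1, bq, al, params, id = "") {
    ncols <- nchar(al$aAln)
    if (ncols < params$minOverlap)
        return(NULL)
    av <- strsplit(al$aAln, "", fixed = TRUE)[[1]]
    bv <- strsplit(al$bAln, "", fixed = TRUE)[[1]]
    ident <- sum(av == bv & av != "-") / ncols
    if (ident < params$minOverlapIdentity)
        return(NULL)

    a1 <- strsplit(seq1, "", fixed = TRUE)[[1]]
    b1 <- strsplit(b, "", fixed = TRUE)[[1]]

    # left flank: whichever read extends further left of the overlap
    if (al$aStart >= al$bStart) {
        leftSeq <- a1[seq_len(al$aStart - 1L)]
        leftQual <- qual1[seq_len(al$aStart - 1L)]
    } else {
        leftSeq <- b1[seq_len(al$bStart - 1L)]
        leftQual <- bq[seq_len(al$bStart - 1L)]
    }
    # right flank: whichever read extends further right
    aTail <- nchar(seq1) - al$aEnd
    bTail <- nchar(b) - al$bEnd
    if (aTail >= bTail) {
        idx <- if (aTail > 0L) (al$aEnd + 1L):nchar(seq1) else integer(0)
        rightSeq <- a1[idx]; rightQual <- qual1[idx]
    } else {
        idx <- if (bTail > 0L) (al$bEnd + 1L):nchar(b) else integer(0)
        rightSeq <- b1[idx]; rightQual <- bq[idx]
    }

    midSeq <- character(ncols)
    midQual <- integer(ncols)
    ai <- al$aStart; bi <- al$bStart
    for (k in seq_len(ncols)) {
        if (av[k] == "-") {            # base only in read 2
            midSeq[k] <- b1[bi]; midQual[k] <- bq[bi]
            bi <- bi + 1L
        } else if (bv[k] == "-") {     # base only in read 1
            midSeq[k] <- a1[ai]; midQual[k] <- qual1[ai]
            ai <- ai + 1L
        } else {
            cb <- consensusBase(a1[ai], qual1[ai], b1[bi], bq[bi])
            midSeq[k] <- cb$base; midQual[k] <- cb$qual
            ai <- ai + 1L; bi <- bi + 1L
        }
    }

    structure(list(
        seq = paste(c(leftSeq, midSeq, rightSeq), collapse = ""),
        qual = c(leftQual, midQual, rightQual),
        overlapLen = ncols,
        sourceId = id),
        class = "MergedRead")
}
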