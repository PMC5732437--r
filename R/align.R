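# Local (Smith-Waterman) alignment with affine gaps, plus edit-operation
# extraction. The alignment itself is delegated to Biostrings; the gap
# scheme is expressed so that a gap of length L costs
# |gapOpen| + (L-1)*|gapExtend| (the opening penalty is charged on the
# first gap base).

#' Alignment and merge parameters
#'
#' Scoring parameters for Smith-Waterman alignment and thresholds for
#' read-pair overlap merging. Signs follow the usual convention: positive
#' match reward, non-positive penalties. A gap of length L costs
#' `|gapOpen| + (L-1)*|gapExtend|`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch score (<= 0).
#' @param gapOpen penalty for the first base of a gap (<= 0).
#' @param gapExtend penalty per additional gap base (<= 0).
#' @param minOverlap minimum read-pair overlap, in alignment columns,
#'   for a pair to be merged.
#' @param minOverlapIdentity minimum fraction of identical bases within
#'   the overlap.
#' @return A list of class `MergeParams`.
#' @examples
#' MergeParams()
#' @export
MergeParams <- function(match = 2L, mismatch = -2L, gapOpen = -3L,
                        gapExtend = -1L, minOverlap = 15L,
                        minOverlapIdentity = 0.90) {
    stopifnot(match > 0, mismatch <= 0, gapOpen <= 0, gapExtend <= 0,
              minOverlap >= 1, minOverlapIdentity > 0,
              minOverlapIdentity <= 1)
    structure(list(match = as.numeric(match),
                   mismatch = as.numeric(mismatch),
                   gapOpen = as.numeric(gapOpen),
                   gapExtend = as.numeric(gapExtend),
                   minOverlap = as.integer(minOverlap),
                   minOverlapIdentity = minOverlapIdentity),
              class = "MergeParams")
}

# Biostrings charges gapOpening + L*gapExtension for a gap of length L;
# our scheme charges |gapOpen| on the first base and |gapExtend| after.
swGapParams <- function(params) {
    list(opening = abs(params$gapOpen) - abs(params$gapExtend),
         extension = abs(params$gapExtend))
}

swSubstMatrix <- function(params) {
    Biostrings::nucleotideSubstitutionMatrix(match = params$match,
                                             mismatch = params$mismatch,
                                             baseOnly = FALSE)
}

emptyAlignment <- function() {
    structure(list(score = 0, aStart = 0L, aEnd = -1L, bStart = 0L,
                   bEnd = -1L, aAln = "", bAln = "",
                   ops = data.frame(op = character(0),
                                    len = integer(0))),
              class = "LocalAlignment")
}

# Derive run-length edit operations from a pair of gapped strings.
# Ops: M (match), X (mismatch), I (insertion in a relative to b, gap in
# b), D (deletion from b, gap in a).
opsFromGapped <- function(aAln, bAln) {
    if (nchar(aAln) == 0L)
        return(data.frame(op = character(0), len = integer(0)))
    av <- strsplit(aAln, "", fixed = TRUE)[[1]]
    bv <- strsplit(bAln, "", fixed = TRUE)[[1]]
    state <- ifelse(av == "-", "D", ifelse(bv == "-", "I",
                    ifelse(av == bv, "M", "X")))
    r <- rle(state)
    data.frame(op = r$values, len = r$lengths, stringsAsFactors = FALSE)
}

# Vectorized local alignment of many pattern/subject pairs in one
# Biostrings call (elementwise when b has the same length as a,
# recycled when b is a single subject). Returns a list of
# LocalAlignment objects.
batchSmithWaterman <- function(a, b, params = MergeParams()) {
    if (!length(a)) return(list())
    gp <- swGapParams(params)
    al <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::DNAStringSet(a),
        subject = if (length(b) == 1L) b else Biostrings::DNAStringSet(b),
        type = "local",
        substitutionMatrix = swSubstMatrix(params),
        gapOpening = gp$opening, gapExtension = gp$extension)
    scores <- Biostrings::score(al)
    # as.character on the Aligned*String views yields the gapped
    # alignment strings without per-element S4 extraction
    aAln <- unname(as.character(Biostrings::pattern(al)))
    bAln <- unname(as.character(Biostrings::subject(al)))
    aS <- Biostrings::start(Biostrings::pattern(al))
    aE <- Biostrings::end(Biostrings::pattern(al))
    bS <- Biostrings::start(Biostrings::subject(al))
    bE <- Biostrings::end(Biostrings::subject(al))
    lapply(seq_along(a), function(i) {
        if (scores[i] <= 0) return(emptyAlignment())
        structure(list(score = scores[i], aStart = aS[i], aEnd = aE[i],
                       bStart = bS[i], bEnd = bE[i], aAln = aAln[i],
                       bAln = bAln[i],
                       ops = opsFromGapped(aAln[i], bAln[i])),
                  class = "LocalAlignment")
    })
}

#' Smith-Waterman local alignment
#'
#' Maximal-scoring local alignment of two DNA strings under affine gap
#' penalties. Returns the aligned spans (1-based inclusive; an empty
#' alignment has span 0..-1 and score 0), the gapped alignment strings
#' and run-length edit operations (`M`/`X`/`I`/`D`, where `I` is a base
#' present in `a` but not `b`).
#'
#' @param a,b non-empty DNA strings.
#' @param params a [MergeParams()] list supplying the scores.
#' @return A list of class `LocalAlignment` with elements `score`,
#'   `aStart`, `aEnd`, `bStart`, `bEnd`, `aAln`, `bAln`, `ops`.
#' @examples
#' al <- smithWaterman("ACGTTACG", "ACGTACG", MergeParams())
#' al$score
#' al$ops
#' @export
smithWaterman <- function(a, b, params = MergeParams()) {
    if (!nzchar(a) || !nzchar(b))
        stop("smithWaterman: empty input sequence")
    gp <- swGapParams(params)
    al <- Biostrings::pairwiseAlignment(
        pattern = a, subject = b, type = "local",
        substitutionMatrix = swSubstMatrix(params),
        gapOpening = gp$opening, gapExtension = gp$extension)
    sc <- Biostrings::score(al)
    if (sc <= 0)
        return(emptyAlignment())
    aAln <- unname(as.character(Biostrings::pattern(al)))
    bAln <- unname(as.character(Biostrings::subject(al)))
    structure(list(
        score = sc,
        aStart = Biostrings::start(Biostrings::pattern(al)),
        aEnd = Biostrings::end(Biostrings::pattern(al)),
        bStart = Biostrings::start(Biostrings::subject(al)),
        bEnd = Biostrings::end(Biostrings::subject(al)),
        aAln = aAln, bAln = bAln,
        ops = opsFromGapped(aAln, bAln)),
        class = "LocalAlignment")
}
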