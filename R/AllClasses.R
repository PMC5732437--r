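#' @import methods
#' @importFrom S4Vectors mcols mcols<-
NULL

#' Transcript model for HGVS c. and p. rendering
#'
#' Holds the exon/CDS geometry and spliced sequence of one transcript.
#' Exons are genomic intervals (1-based, inclusive) sorted by genomic
#' position; for minus-strand transcripts the transcript reading order is
#' the reverse of the genomic exon order and `splicedSeq` is given on the
#' transcript strand. CDS bounds (`cdsStart`, `cdsEnd`) are transcript
#' (spliced) coordinates.
#'
#' @slot accession versioned transcript identifier, e.g. `"NM_TOY001.1"`.
#' @slot gene gene symbol.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot exons [IRanges::IRanges] of genomic exon intervals, sorted,
#'   non-overlapping.
#' @slot cdsStart,cdsEnd integer CDS bounds in transcript coordinates;
#'   the CDS length is a multiple of 3.
#' @slot splicedSeq transcript-strand DNA of the spliced transcript.
#'
#' @aliases TranscriptModel-class
#' @exportClass TranscriptModel
setClass("TranscriptModel",
    representation(
        accession  = "character",
        gene       = "character",
        chrom      = "character",
        strand     = "character",
        exons      = "IRanges",
        cdsStart   = "integer",
        cdsEnd     = "integer",
        splicedSeq = "character"
    )
)

setValidity("TranscriptModel", function(object) {
    msg <- character(0)
    if (length(object@strand) != 1L || !object@strand %in% c("+", "-"))
        msg <- c(msg, "strand must be '+' or '-'")
    ex <- object@exons
    if (length(ex) == 0L) {
        msg <- c(msg, "at least one exon required")
    } else {
        if (is.unsorted(IRanges::start(ex)))
            msg <- c(msg, "exons must be sorted by genomic start")
        if (length(ex) > 1L &&
            any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
            msg <- c(msg, "exons must be non-overlapping")
        if (sum(IRanges::width(ex)) != nchar(object@splicedSeq))
            msg <- c(msg, sprintf(
                "sum of exon lengths (%d) != spliced sequence length (%d)",
                sum(IRanges::width(ex)), nchar(object@splicedSeq)))
    }
    n <- nchar(object@splicedSeq)
    if (!(object@cdsStart >= 1L && object@cdsStart < object@cdsEnd &&
          object@cdsEnd <= n))
        msg <- c(msg, "CDS bounds must satisfy 1 <= cdsStart < cdsEnd <= length")
    else if ((object@cdsEnd - object@cdsStart + 1L) %% 3L != 0L)
        msg <- c(msg, "CDS length must be divisible by 3")
    if (!isDna(object@splicedSeq))
        msg <- c(msg, "spliced sequence contains non-DNA characters")
    if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' @param accession,gene,chrom,strand see [TranscriptModel-class].
#' @param exonStarts,exonEnds integer vectors of genomic exon bounds
#'   (1-based inclusive), sorted by genomic position.
#' @param cdsStart,cdsEnd CDS bounds in transcript (spliced) coordinates.
#' @param splicedSeq transcript-strand spliced DNA sequence.
#' @return A validated [TranscriptModel-class] object.
#' @examples
#' tx <- TranscriptModel("NM_X.1", "GENE", "chr1", "+",
#'                       exonStarts = c(101, 201), exonEnds = c(130, 230),
#'                       cdsStart = 1, cdsEnd = 60,
#'                       splicedSeq = paste(rep("ACG", 20), collapse = ""))
#' txLength(tx)
#' @export
TranscriptModel <- function(accession, gene, chrom, strand,
                            exonStarts, exonEnds, cdsStart, cdsEnd,
                            splicedSeq) {
    new("TranscriptModel",
        accession = as.character(accession), gene = as.character(gene),
        chrom = as.character(chrom), strand = as.character(strand),
        exons = IRanges::IRanges(start = as.integer(exonStarts),
                                 end = as.integer(exonEnds)),
        cdsStart = as.integer(cdsStart), cdsEnd = as.integer(cdsEnd),
        splicedSeq = toupper(as.character(splicedSeq)))
}

#' Amplicon panel: amplicons, transcripts and preferred-transcript map
#'
#' The central configuration object of the pipeline. Amplicons are stored
#' as a [GenomicRanges::GRanges] (1-based inclusive coordinates of the
#' full amplicon including primers) with metadata columns `fwdPrimer` and
#' `revPrimer`; primers are given as sequenced, i.e. the forward primer on
#' the forward genomic strand and the reverse primer on the reverse
#' strand. `refSeqs` holds the full amplicon reference sequence on the
#' forward genomic strand, one entry per amplicon, names matching.
#'
#' @slot amplicons [GenomicRanges::GRanges] with `fwdPrimer`/`revPrimer`
#'   metadata columns; names are unique amplicon identifiers.
#' @slot refSeqs [Biostrings::DNAStringSet] named by amplicon.
#' @slot transcripts named list of [TranscriptModel-class] objects,
#'   names are accessions.
#' @slot preferred named character vector mapping gene symbol to one
#'   transcript accession.
#'
#' @aliases AmpliconPanel-class
#' @exportClass AmpliconPanel
setClass("AmpliconPanel",
    representation(
        amplicons   = "GRanges",
        refSeqs     = "DNAStringSet",
        transcripts = "list",
        preferred   = "character"
    )
)

setValidity("AmpliconPanel", function(object) {
    msg <- character(0)
    amps <- object@amplicons
    nms <- names(amps)
    if (length(amps)) {
        if (is.null(nms) || anyDuplicated(nms))
            msg <- c(msg, "amplicon names must be present and unique")
        mc <- S4Vectors::mcols(amps)
        if (!all(c("fwdPrimer", "revPrimer") %in% colnames(mc)))
            return("amplicons need fwdPrimer and revPrimer metadata columns")
        if (!setequal(names(object@refSeqs), nms))
            msg <- c(msg, "refSeqs names must match amplicon names")
        for (i in seq_along(amps)) {
            nm <- nms[i]
            fwd <- mc$fwdPrimer[i]; rev <- mc$revPrimer[i]
            refseq <- as.character(object@refSeqs[[nm]])
            w <- GenomicRanges::width(amps)[i]
            if (nchar(fwd) == 0L || nchar(rev) == 0L)
                msg <- c(msg, sprintf("amplicon '%s': empty primer", nm))
            if (nchar(refseq) != w)
                msg <- c(msg, sprintf(
                    "amplicon '%s': reference length %d != interval width %d",
                    nm, nchar(refseq), w))
            if (!startsWith(refseq, fwd))
                msg <- c(msg, sprintf(
                    "amplicon '%s': reference does not start with fwd_primer",
                    nm))
            if (!endsWith(refseq, revcomp(rev)))
                msg <- c(msg, sprintf(
                    "amplicon '%s': reference does not end with revcomp(rev_primer)",
                    nm))
            if (nchar(refseq) - nchar(fwd) - nchar(rev) <= 0L)
                msg <- c(msg, sprintf(
                    "amplicon '%s': zero-length insert between primers", nm))
        }
    }
    txs <- object@transcripts
    if (length(txs)) {
        if (!all(vapply(txs, is, logical(1), "TranscriptModel")))
            msg <- c(msg, "transcripts must be TranscriptModel objects")
        accs <- vapply(txs, function(t) t@accession, character(1))
        if (anyDuplicated(accs))
            msg <- c(msg, "duplicate transcript accessions")
    }
    if (length(object@preferred)) {
        if (anyDuplicated(names(object@preferred)))
            msg <- c(msg, "preferred map has duplicate genes")
        accs <- vapply(object@transcripts, function(t) t@accession,
                       character(1))
        missing <- setdiff(object@preferred, accs)
        if (length(missing))
            msg <- c(msg, sprintf(
                "preferred transcript(s) not in transcript set: %s",
                paste(missing, collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' Construct an AmpliconPanel
#'
#' @param amplicons a `GRanges` with names and `fwdPrimer`/`revPrimer`
#'   metadata columns.
#' @param refSeqs a named `DNAStringSet` of full amplicon references.
#' @param transcripts named list of [TranscriptModel-class] objects.
#' @param preferred named character vector, gene symbol to accession.
#' @return A validated [AmpliconPanel-class] object.
#' @seealso [loadPanel()], [makePanel()]
#' @export
AmpliconPanel <- function(amplicons, refSeqs, transcripts = list(),
                          preferred = character(0)) {
    if (length(transcripts))
        names(transcripts) <- vapply(transcripts, function(t) t@accession,
                                     character(1))
    new("AmpliconPanel", amplicons = amplicons,
        refSeqs = Biostrings::DNAStringSet(refSeqs),
        transcripts = transcripts, preferred = preferred)
}

#' Set of variant calls for one sample
#'
#' `calls` is a data.frame with one row per reported record, columns
#' `chrom`, `pos`, `ref`, `alt` (VCF-style anchored), `amplicons`
#' (comma-separated supporting amplicon names), `altPairs`, `depthPairs`,
#' `vaf`, `isMnpParent`, `mnpLink` (`NA` for independent variants),
#' `filter` (`"PASS"` or semicolon-joined failure labels). Normalization
#' ([normalizeCalls()]) appends `gene`, `transcript`, `hgvsG`, `hgvsC`,
#' `hgvsP` columns.
#'
#' @slot sample sample identifier.
#' @slot calls data.frame as described above, sorted by
#'   (chrom, pos, ref, alt).
#' @slot stats named list of run statistics (pairs read, merged, assigned,
#'   unalignable, cache hits/misses and hit ratio).
#'
#' @aliases CallSet-class
#' @exportClass CallSet
setClass("CallSet",
    representation(
        sample = "character",
        calls  = "data.frame",
        stats  = "list"
    )
)

setValidity("CallSet", function(object) {
    msg <- character(0)
    need <- c("chrom", "pos", "ref", "alt", "altPairs", "depthPairs", "vaf")
    if (nrow(object@calls) && !all(need %in% colnames(object@calls)))
        msg <- c(msg, paste("calls must have columns:",
                            paste(need, collapse = ", ")))
    if (nrow(object@calls)) {
        cc <- object@calls
        if (any(cc$altPairs > cc$depthPairs))
            msg <- c(msg, "altPairs exceeds depthPairs")
        o <- order(cc$chrom, cc$pos, cc$ref, cc$alt)
        if (!identical(o, seq_len(nrow(cc))))
            msg <- c(msg, "calls must be sorted by (chrom, pos, ref, alt)")
    }
    if (length(msg)) msg else TRUE
})
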