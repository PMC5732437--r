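# Accessors and show() methods for the core classes.

#' @rdname AmpliconPanel
#' @param object,x an `AmpliconPanel`, `TranscriptModel` or `CallSet`.
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname AmpliconPanel
#' @export
setMethod("amplicons", "AmpliconPanel", function(x) x@amplicons)

#' @rdname AmpliconPanel
#' @export
setGeneric("ampliconNames", function(x) standardGeneric("ampliconNames"))

#' @rdname AmpliconPanel
#' @export
setMethod("ampliconNames", "AmpliconPanel", function(x) names(x@amplicons))

#' @rdname AmpliconPanel
#' @export
setGeneric("refSeqs", function(x) standardGeneric("refSeqs"))

#' @rdname AmpliconPanel
#' @export
setMethod("refSeqs", "AmpliconPanel", function(x) x@refSeqs)

#' @rdname AmpliconPanel
#' @export
setGeneric("transcriptModels", function(x) standardGeneric("transcriptModels"))

#' @rdname AmpliconPanel
#' @export
setMethod("transcriptModels", "AmpliconPanel", function(x) x@transcripts)

#' @rdname AmpliconPanel
#' @export
setGeneric("preferredTranscripts",
           function(x) standardGeneric("preferredTranscripts"))

#' @rdname AmpliconPanel
#' @export
setMethod("preferredTranscripts", "AmpliconPanel", function(x) x@preferred)

setMethod("show", "AmpliconPanel", function(object) {
    cat(sprintf("AmpliconPanel with %d amplicon(s), %d transcript(s)\n",
                length(object@amplicons), length(object@transcripts)))
    if (length(object@amplicons)) {
        w <- GenomicRanges::width(object@amplicons)
        cat(sprintf("  amplicon lengths: %d-%d bp\n", min(w), max(w)))
    }
    if (length(object@preferred))
        cat(sprintf("  preferred transcripts for: %s\n",
                    paste(names(object@preferred), collapse = ", ")))
})

#' @rdname TranscriptModel
#' @param x a `TranscriptModel`.
#' @export
setGeneric("txLength", function(x) standardGeneric("txLength"))

#' @rdname TranscriptModel
#' @export
setMethod("txLength", "TranscriptModel", function(x) nchar(x@splicedSeq))

#' @rdname TranscriptModel
#' @export
setGeneric("accession", function(x) standardGeneric("accession"))

#' @rdname TranscriptModel
#' @export
setMethod("accession", "TranscriptModel", function(x) x@accession)

#' @rdname TranscriptModel
#' @export
setGeneric("geneSymbol", function(x) standardGeneric("geneSymbol"))

#' @rdname TranscriptModel
#' @export
setMethod("geneSymbol", "TranscriptModel", function(x) x@gene)

setMethod("show", "TranscriptModel", function(object) {
    cat(sprintf(
        "TranscriptModel %s (%s, %s strand): %d exon(s), %d nt, CDS %d-%d\n",
        object@accession, object@gene, object@strand, length(object@exons),
        nchar(object@splicedSeq), object@cdsStart, object@cdsEnd))
})

#' @rdname CallSet
#' @param x a `CallSet`.
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname CallSet
#' @export
setMethod("calls", "CallSet", function(x) x@calls)

#' @rdname CallSet
#' @export
setGeneric("runStats", function(x) standardGeneric("runStats"))

#' @rdname CallSet
#' @export
setMethod("runStats", "CallSet", function(x) x@stats)

#' @rdname CallSet
#' @export
setGeneric("sampleName", function(x) standardGeneric("sampleName"))

#' @rdname CallSet
#' @export
setMethod("sampleName", "CallSet", function(x) x@sample)

setMethod("show", "CallSet", function(object) {
    cat(sprintf("CallSet for sample '%s': %d call record(s)\n",
                object@sample, nrow(object@calls)))
    st <- object@stats
    if (length(st))
        cat(sprintf(
            "  pairs read %s, merged %s, assigned %s, cache hit ratio %s\n",
            st$pairsRead, st$pairsMerged, st$pairsAssigned,
            if (is.null(st$cacheHitRatio) || is.na(st$cacheHitRatio)) "NA"
            else sprintf("%.1f%%", 100 * st$cacheHitRatio)))
})
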