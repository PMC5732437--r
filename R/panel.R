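# Loading and serializing the amplicon panel, transcript models and
# preferred-transcript map.
#
# File formats (all plain text, UTF-8, tab-separated with header rows):
#   * panel manifest: columns name, chrom, start, end, fwd_primer,
#     rev_primer (1-based inclusive genomic coordinates of the full
#     amplicon including primers; primers as sequenced).
#   * amplicon references: FASTA, record id == amplicon name, forward
#     genomic strand, full amplicon including primers.
#   * transcripts: columns accession, gene, chrom, strand, exon_starts,
#     exon_ends (comma-separated integer lists), cds_start, cds_end
#     (transcript coordinates), spliced_seq (transcript-strand DNA).
#   * preferred transcripts: columns gene, accession.

readTsv <- function(path, required) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    missing <- setdiff(required, colnames(df))
    if (length(missing))
        stop(sprintf("%s: missing column(s) %s", path,
                     paste(missing, collapse = ", ")))
    df
}

#' Load an amplicon panel from a manifest and reference FASTA
#'
#' Reads the panel manifest (TSV) and the per-amplicon reference FASTA,
#' cross-validates them (every manifest row must have a FASTA record of
#' the right length that starts with its forward primer and ends with the
#' reverse complement of its reverse primer) and returns a validated
#' [AmpliconPanel-class]. Transcript models and the preferred-transcript
#' map are optional.
#'
#' @param manifestPath panel manifest TSV (see Details in the package
#'   vignette; columns `name`, `chrom`, `start`, `end`, `fwd_primer`,
#'   `rev_primer`).
#' @param fastaPath FASTA of full amplicon reference sequences, ids equal
#'   to manifest names.
#' @param transcriptsPath optional transcript-model TSV
#'   (see [loadTranscripts()]).
#' @param preferredPath optional two-column gene/accession TSV
#'   (see [loadPreferred()]).
#' @return An [AmpliconPanel-class] with amplicons in manifest order.
#' @export
loadPanel <- function(manifestPath, fastaPath, transcriptsPath = NULL,
                      preferredPath = NULL) {
    man <- readTsv(manifestPath,
                   c("name", "chrom", "start", "end", "fwd_primer",
                     "rev_primer"))
    if (anyDuplicated(man$name))
        stop("duplicate amplicon name(s) in manifest: ",
             paste(unique(man$name[duplicated(man$name)]), collapse = ", "))
    fa <- Biostrings::readDNAStringSet(fastaPath)
    names(fa) <- sub("\\s.*$", "", names(fa))
    missing <- setdiff(man$name, names(fa))
    if (length(missing))
        stop("missing FASTA record for amplicon(s): ",
             paste(missing, collapse = ", "))
    start <- as.integer(man$start); end <- as.integer(man$end)
    if (any(is.na(start)) || any(is.na(end)) || any(start > end))
        stop("manifest coordinates must be integers with start <= end")
    gr <- GenomicRanges::GRanges(
        seqnames = man$chrom,
        ranges = IRanges::IRanges(start = start, end = end))
    names(gr) <- man$name
    S4Vectors::mcols(gr)$fwdPrimer <- toupper(man$fwd_primer)
    S4Vectors::mcols(gr)$revPrimer <- toupper(man$rev_primer)
    txs <- if (!is.null(transcriptsPath)) loadTranscripts(transcriptsPath)
           else list()
    pref <- if (!is.null(preferredPath)) loadPreferred(preferredPath, txs)
            else character(0)
    AmpliconPanel(amplicons = gr, refSeqs = fa[man$name],
                  transcripts = txs, preferred = pref)
}

#' Load transcript models from a flat TSV
#'
#' One row per transcript with columns `accession`, `gene`, `chrom`,
#' `strand`, `exon_starts`, `exon_ends` (comma-separated genomic
#' coordinates, 1-based inclusive, sorted by genomic position),
#' `cds_start`, `cds_end` (transcript coordinates) and `spliced_seq`
#' (transcript-strand DNA). All [TranscriptModel-class] invariants are
#' checked; duplicate accessions are rejected.
#'
#' @param path transcript TSV path.
#' @return A named list of [TranscriptModel-class] objects (names are
#'   accessions).
#' @export
loadTranscripts <- function(path) {
    df <- readTsv(path, c("accession", "gene", "chrom", "strand",
                          "exon_starts", "exon_ends", "cds_start",
                          "cds_end", "spliced_seq"))
    if (anyDuplicated(df$accession))
        stop("duplicate transcript accession(s): ",
             paste(unique(df$accession[duplicated(df$accession)]),
                   collapse = ", "))
    txs <- lapply(seq_len(nrow(df)), function(i) {
        TranscriptModel(
            accession = df$accession[i], gene = df$gene[i],
            chrom = df$chrom[i], strand = df$strand[i],
            exonStarts = as.integer(strsplit(df$exon_starts[i], ",")[[1]]),
            exonEnds = as.integer(strsplit(df$exon_ends[i], ",")[[1]]),
            cdsStart = as.integer(df$cds_start[i]),
            cdsEnd = as.integer(df$cds_end[i]),
            splicedSeq = df$spliced_seq[i])
    })
    names(txs) <- df$accession
    txs
}

#' Load the gene to preferred-transcript map
#'
#' Two-column TSV (`gene`, `accession`). Duplicate gene rows are an
#' error; every accession must be present in `transcripts`. An empty file
#' (header only) yields an empty map, in which case transcript selection
#' falls through to the closest-to-exon tie-break.
#'
#' @param path TSV path.
#' @param transcripts named list of loaded [TranscriptModel-class]
#'   objects to validate accessions against.
#' @return Named character vector mapping gene symbol to accession.
#' @export
loadPreferred <- function(path, transcripts) {
    df <- readTsv(path, c("gene", "accession"))
    if (nrow(df) == 0L)
        return(character(0))
    if (anyDuplicated(df$gene))
        stop("duplicate gene row(s) in preferred-transcript map: ",
             paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
    known <- vapply(transcripts, accession, character(1))
    missing <- setdiff(df$accession, known)
    if (length(missing))
        stop("preferred accession(s) absent from transcript set: ",
             paste(missing, collapse = ", "))
    stats::setNames(df$accession, df$gene)
}

#' Serialize a panel back to its file formats
#'
#' Writes the manifest TSV, reference FASTA and (when present) the
#' transcript TSV and preferred-transcript TSV for `panel` into `dir`.
#' `loadPanel()` on the written files reproduces the panel exactly.
#'
#' @param panel an [AmpliconPanel-class].
#' @param dir output directory (created if needed).
#' @return Named list of the written file paths (`manifest`, `fasta`,
#'   and when applicable `transcripts`, `preferred`), invisibly.
#' @export
writePanelFiles <- function(panel, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    amps <- amplicons(panel)
    man <- data.frame(
        name = names(amps),
        chrom = as.character(GenomicRanges::seqnames(amps)),
        start = GenomicRanges::start(amps),
        end = GenomicRanges::end(amps),
        fwd_primer = S4Vectors::mcols(amps)$fwdPrimer,
        rev_primer = S4Vectors::mcols(amps)$revPrimer,
        stringsAsFactors = FALSE)
    paths <- list(manifest = file.path(dir, "panel_manifest.tsv"),
                  fasta = file.path(dir, "panel_refs.fasta"))
    utils::write.table(man, paths$manifest, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    Biostrings::writeXStringSet(refSeqs(panel)[man$name], paths$fasta)
    txs <- transcriptModels(panel)
    if (length(txs)) {
        tdf <- do.call(rbind, lapply(txs, function(t) data.frame(
            accession = t@accession, gene = t@gene, chrom = t@chrom,
            strand = t@strand,
            exon_starts = paste(IRanges::start(t@exons), collapse = ","),
            exon_ends = paste(IRanges::end(t@exons), collapse = ","),
            cds_start = t@cdsStart, cds_end = t@cdsEnd,
            spliced_seq = t@splicedSeq, stringsAsFactors = FALSE)))
        paths$transcripts <- file.path(dir, "transcripts.tsv")
        utils::write.table(tdf, paths$transcripts, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    pref <- preferredTranscripts(panel)
    if (length(txs)) {
        pdf <- data.frame(gene = names(pref),
                          accession = unname(pref),
                          stringsAsFactors = FALSE)
        paths$preferred <- file.path(dir, "preferred_transcripts.tsv")
        utils::write.table(pdf, paths$preferred, sep = "\t",
                           quote = FALSE, row.names = FALSE)
    }
    invisible(paths)
}
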