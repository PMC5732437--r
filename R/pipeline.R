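# Single-command pipeline driver: FASTQ pair -> annotated VCF (+ TSV),
# or annotate-only mode enriching an existing VCF. A thin command-line
# wrapper around runPipeline() is installed at
# system.file("scripts", "amplicall.R", package = "ampliCall").

configError <- function(...) {
    stop(structure(class = c("ampliCall_config_error", "error",
                             "condition"),
                   list(message = paste0(...), call = NULL)))
}

#' Run the full pipeline
#'
#' In FASTQ mode (`fastq1`/`fastq2` given) the sample is processed to a
#' [CallSet-class], every call is normalized to canonical HGVS form,
#' annotations are fetched from `backend` (when supplied) and an
#' annotated VCF (plus optionally a TSV table) is written. In VCF mode
#' (`vcf` given) the existing records are normalized and their INFO
#' fields enriched in place; all other content is preserved verbatim.
#' Run statistics (pairs read/merged/assigned, cache hit ratio) are
#' reported as a machine-parsable `STATS` line on stderr.
#'
#' @param manifest,fasta panel manifest TSV and reference FASTA paths.
#' @param fastq1,fastq2 paired FASTQ paths (FASTQ mode).
#' @param vcf input VCF path (annotate-only mode). Exactly one of the
#'   two modes must be selected.
#' @param transcripts,preferred optional transcript-model TSV and
#'   preferred-transcript TSV.
#' @param out output prefix; `<out>.vcf` (and `<out>.tsv`) are written.
#' @param fieldsFile optional file with one dotted annotation field
#'   name per line.
#' @param backend optional [AnnotationBackend-class]. If annotation
#'   fetching fails, the run continues with an unannotated VCF, a
#'   warning, and `status = 4`.
#' @param params [CallingParams()].
#' @param cacheEnabled consult the read-pair cache.
#' @param emitAll keep threshold-failing calls with FILTER labels.
#' @param tsv also write the tab-separated variant table.
#' @param sample sample name (defaults to the FASTQ/VCF basename).
#' @return A list with `status` (0 = success, 4 = annotation backend
#'   unavailable), `vcf`, `tsv` (or `NULL`) and `callset` (FASTQ mode).
#' @export
runPipeline <- function(manifest, fasta, fastq1 = NULL, fastq2 = NULL,
                        vcf = NULL, transcripts = NULL, preferred = NULL,
                        out = "amplicall_out", fieldsFile = NULL,
                        backend = NULL, params = CallingParams(),
                        cacheEnabled = TRUE, emitAll = FALSE,
                        tsv = FALSE, sample = NULL) {
    fastqMode <- !is.null(fastq1) || !is.null(fastq2)
    vcfMode <- !is.null(vcf)
    if (fastqMode == vcfMode)
        configError("exactly one of (fastq1+fastq2) or vcf must be given")
    if (fastqMode && (is.null(fastq1) || is.null(fastq2)))
        configError("FASTQ mode needs both fastq1 and fastq2")
    for (p in c(manifest, fasta, fastq1, fastq2, vcf, transcripts,
                preferred, fieldsFile))
        if (!file.exists(p))
            configError("input file not found: ", p)

    panel <- loadPanel(manifest, fasta, transcripts, preferred)
    fields <- if (!is.null(fieldsFile)) {
        f <- trimws(readLines(fieldsFile))
        f[nzchar(f)]
    } else character(0)

    status <- 0L
    fetchOrWarn <- function(ids) {
        if (is.null(backend) || !length(ids)) return(NULL)
        tryCatch(fetchAnnotations(backend, ids, fields),
                 error = function(e) {
                     warning("annotation backend failed; writing ",
                             "unannotated VCF: ", conditionMessage(e),
                             call. = FALSE)
                     status <<- 4L
                     NULL
                 })
    }

    vcfOut <- paste0(out, ".vcf")
    tsvOut <- if (tsv) paste0(out, ".tsv") else NULL

    if (fastqMode) {
        if (is.null(sample))
            sample <- sub("(_R?1)?\\.(fastq|fq)(\\.gz)?$", "",
                          basename(fastq1))
        cs <- processSample(fastq1, fastq2, panel, params,
                            cacheEnabled = cacheEnabled,
                            sample = sample, emitAll = emitAll)
        cs <- normalizeCalls(cs, panel)
        ann <- fetchOrWarn(stats::na.omit(unique(calls(cs)$hgvsG)))
        writeVcfFile(cs, vcfOut, panel = panel, annotations = ann,
                     fields = fields)
        if (tsv)
            writeVariantTsv(cs, tsvOut, annotations = ann,
                            fields = fields)
        st <- runStats(cs)
        message(sprintf(
            "STATS sample=%s pairs_read=%d pairs_merged=%d pairs_assigned=%d unalignable=%d cache_hit_ratio=%s",
            sample, st$pairsRead, st$pairsMerged, st$pairsAssigned,
            st$pairsUnalignable,
            if (is.na(st$cacheHitRatio)) "NA"
            else sprintf("%.4f", st$cacheHitRatio)))
        return(list(status = status, vcf = vcfOut, tsv = tsvOut,
                    callset = cs))
    }

    # annotate-only mode
    sv <- readVcfFile(vcf)
    df <- sv$records
    refAcc <- ampliconRefAccessor(panel)
    triples <- vector("list", nrow(df))
    for (i in seq_len(nrow(df))) {
        nv <- normalizeVariant(df$chrom[i], df$pos[i], df$ref[i],
                               df$alt[i], panel, refAcc = refAcc)
        triples[[i]] <- nv
    }
    ids <- unique(vapply(triples, function(x) x$hgvsG, character(1)))
    ann <- fetchOrWarn(ids)
    known <- vapply(sv$headerLines, function(l)
        regmatches(l, regexec("^##INFO=<ID=([^,]+),", l))[[1]][2],
        character(1))
    needDecl <- function(key, line) {
        if (!key %in% known) {
            sv$headerLines <<- c(sv$headerLines, line)
            known <<- c(known, key)
        }
    }
    needDecl("HGVSG", infoHeaderLine("HGVSG", "1", "String",
                                     "HGVS genomic name"))
    needDecl("HGVSC", infoHeaderLine("HGVSC", "1", "String",
                                     "HGVS coding name"))
    needDecl("HGVSP", infoHeaderLine("HGVSP", "1", "String",
                                     "HGVS protein consequence"))
    for (f in fields)
        needDecl(sanitizeInfoKey(f),
                 infoHeaderLine(sanitizeInfoKey(f), "1", "String",
                                paste("Annotation field", f)))
    for (i in seq_len(nrow(df))) {
        info <- parseInfoString(df$info[i])
        nv <- triples[[i]]
        a <- if (!is.null(ann)) ann[[nv$hgvsG]] else NULL
        info <- injectInfo(info, nv, if (is.null(a)) character(0) else a)
        df$info[i] <- buildInfoString(info)
    }
    sv$records <- df
    writeSimpleVcf(sv, vcfOut)
    if (tsv) {
        # rebuild a call table from the VCF records for the TSV export
        getInfo <- function(s, k) {
            v <- parseInfoString(s)
            if (k %in% names(v)) v[[k]] else NA_character_
        }
        smp <- if (length(sv$samples)) sv$samples[1L]
               else if (!is.null(sample)) sample else "sample"
        fmtIdx <- function(i, key) {
            if (!length(sv$samples)) return(NA_character_)
            keys <- strsplit(df$format[i], ":", fixed = TRUE)[[1]]
            vals <- strsplit(df[[sv$samples[1L]]][i], ":",
                             fixed = TRUE)[[1]]
            j <- match(key, keys)
            if (is.na(j) || j > length(vals)) NA_character_ else vals[j]
        }
        tdf <- data.frame(
            chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt,
            amplicons = vapply(df$info, getInfo, "", k = "AMPS"),
            altPairs = suppressWarnings(as.integer(
                vapply(seq_len(nrow(df)), fmtIdx, "", key = "VD"))),
            depthPairs = suppressWarnings(as.integer(
                vapply(seq_len(nrow(df)), fmtIdx, "", key = "DP"))),
            vaf = suppressWarnings(as.numeric(
                vapply(seq_len(nrow(df)), fmtIdx, "", key = "AF"))),
            isMnpParent = vapply(seq_len(nrow(df)), function(i)
                "MNP_PARENT" %in% names(parseInfoString(df$info[i])),
                logical(1)),
            mnpLink = vapply(df$info, getInfo, "", k = "MNP_LINK"),
            filter = df$filter,
            gene = vapply(triples, function(x) x$gene, character(1)),
            transcript = vapply(triples, function(x) x$transcript,
                                character(1)),
            hgvsG = vapply(triples, function(x) x$hgvsG, character(1)),
            hgvsC = vapply(triples, function(x) x$hgvsC, character(1)),
            hgvsP = vapply(triples, function(x) x$hgvsP, character(1)),
            stringsAsFactors = FALSE)
        tdf$vaf[is.na(tdf$vaf)] <- 0
        tdf$altPairs[is.na(tdf$altPairs)] <- 0L
        tdf$depthPairs[is.na(tdf$depthPairs)] <- 0L
        tcs <- new("CallSet", sample = smp,
                   calls = tdf[order(tdf$chrom, tdf$pos, tdf$ref,
                                     tdf$alt), , drop = FALSE],
                   stats = list())
        writeVariantTsv(tcs, tsvOut, annotations = ann, fields = fields)
    }
    list(status = status, vcf = vcfOut, tsv = tsvOut, callset = NULL)
}
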