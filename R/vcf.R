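# VCF 4.2 serialization for the calls this pipeline produces, a
# lossless reader for annotate-only mode, and the tab-separated variant
# table export. The writer emits exactly the dialect the reader parses,
# so write -> read -> write is byte-stable; unknown INFO keys read from
# foreign VCFs are preserved verbatim.

formatAf <- function(x) sprintf("%.6g", x)

parseInfoString <- function(s) {
    if (s == "." || s == "") return(stats::setNames(character(0),
                                                    character(0)))
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    eq <- regexpr("=", parts, fixed = TRUE)
    keys <- ifelse(eq > 0L, substr(parts, 1L, eq - 1L), parts)
    vals <- ifelse(eq > 0L, substr(parts, eq + 1L, nchar(parts)),
                   NA_character_)
    stats::setNames(vals, keys)
}

buildInfoString <- function(info) {
    if (!length(info)) return(".")
    paste(ifelse(is.na(info), names(info),
                 paste0(names(info), "=", info)), collapse = ";")
}

infoHeaderLine <- function(id, number, type, desc) {
    sprintf('##INFO=<ID=%s,Number=%s,Type=%s,Description="%s">',
            id, number, type, desc)
}

#' Write a CallSet as an annotated VCF 4.2 file
#'
#' Emits a single-sample VCF with contig, FILTER, INFO and FORMAT
#' declarations. Per record the INFO carries `HGVSG`/`HGVSC`/`HGVSP`,
#' `GENE`, `AMPS` (supporting amplicons), `MNP_PARENT` (flag) and
#' `MNP_LINK` for phased groups, plus one key per annotation field;
#' the sample column carries `DP` (pair depth), `VD` (variant pairs)
#' and `AF`. Records must be unique and are written sorted by
#' (chrom, pos, ref, alt).
#'
#' @param callset a (normalized) [CallSet-class].
#' @param path output path.
#' @param panel optional [AmpliconPanel-class]; provides contig lengths.
#' @param annotations named list (by HGVSg) of named character vectors,
#'   as returned by [fetchAnnotations()].
#' @param fields the requested annotation field names (declared in the
#'   header in request order).
#' @return `path`, invisibly.
#' @export
writeVcfFile <- function(callset, path, panel = NULL,
                         annotations = NULL, fields = character(0)) {
    df <- calls(callset)
    if (nrow(df)) {
        key <- variantKey(df)
        if (anyDuplicated(key))
            stop("duplicate VCF record(s): ",
                 paste(unique(key[duplicated(key)]), collapse = ", "))
        df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
    }
    h <- c("##fileformat=VCFv4.2", "##source=ampliCall")
    if (!is.null(panel) && length(amplicons(panel))) {
        amps <- amplicons(panel)
        chroms <- as.character(GenomicRanges::seqnames(amps))
        for (ch in unique(chroms))
            h <- c(h, sprintf("##contig=<ID=%s,length=%d>", ch,
                              max(GenomicRanges::end(amps)[chroms == ch])))
    } else if (nrow(df)) {
        for (ch in unique(df$chrom))
            h <- c(h, sprintf("##contig=<ID=%s,length=%d>", ch,
                              max(df$pos + nchar(df$ref) - 1L)))
    }
    h <- c(h,
        '##FILTER=<ID=LowVAF,Description="Variant allele frequency below threshold">',
        '##FILTER=<ID=LowDepth,Description="Supporting pair count below threshold">',
        infoHeaderLine("HGVSG", "1", "String", "HGVS genomic name"),
        infoHeaderLine("HGVSC", "1", "String", "HGVS coding name"),
        infoHeaderLine("HGVSP", "1", "String", "HGVS protein consequence"),
        infoHeaderLine("GENE", "1", "String", "Gene symbol"),
        infoHeaderLine("AMPS", ".", "String", "Supporting amplicons"),
        infoHeaderLine("MNP_PARENT", "0", "Flag",
                       "Compound in-phase (delins) parent record"),
        infoHeaderLine("MNP_LINK", "1", "String",
                       "Identifier shared by an MNP parent and its constituents"))
    for (f in fields)
        h <- c(h, infoHeaderLine(sanitizeInfoKey(f), "1", "String",
                                 paste("Annotation field", f)))
    h <- c(h,
        '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Merged pair depth">',
        '##FORMAT=<ID=VD,Number=1,Type=Integer,Description="Pairs supporting the variant">',
        '##FORMAT=<ID=AF,Number=1,Type=Float,Description="Variant allele frequency">',
        paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                "INFO", "FORMAT", sampleName(callset)), collapse = "\t"))

    lines <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
        info <- character(0)
        triple <- list(
            hgvsG = if ("hgvsG" %in% colnames(df)) df$hgvsG[i]
                    else NA_character_,
            hgvsC = if ("hgvsC" %in% colnames(df)) df$hgvsC[i]
                    else NA_character_,
            hgvsP = if ("hgvsP" %in% colnames(df)) df$hgvsP[i]
                    else NA_character_)
        info <- injectInfo(info, triple)
        if ("gene" %in% colnames(df) && !is.na(df$gene[i]))
            info["GENE"] <- percentEncode(df$gene[i])
        if (!is.na(df$amplicons[i]) && nzchar(df$amplicons[i]))
            info["AMPS"] <- percentEncode(df$amplicons[i],
                                          chars = c(";", "=", " ",
                                                    "\t", "\n"))
        if (isTRUE(df$isMnpParent[i]))
            info["MNP_PARENT"] <- NA_character_
        if (!is.na(df$mnpLink[i]))
            info["MNP_LINK"] <- percentEncode(df$mnpLink[i])
        if (!is.null(annotations) && !is.na(triple$hgvsG)) {
            ann <- annotations[[triple$hgvsG]]
            if (length(ann)) info <- injectInfo(info, NULL, ann)
        }
        lines[i] <- paste(
            c(df$chrom[i], df$pos[i], ".", df$ref[i], df$alt[i], ".",
              df$filter[i],
              buildInfoString(info), "DP:VD:AF",
              paste(df$depthPairs[i], df$altPairs[i],
                    formatAf(df$vaf[i]), sep = ":")),
            collapse = "\t")
    }
    writeLines(c(h, lines), path)
    invisible(path)
}

#' Read a VCF file
#'
#' Lossless for the fields this tool writes; INFO strings (including
#' unknown keys) are kept verbatim so a rewrite reproduces them.
#'
#' @param path VCF 4.x path (plain or gzipped).
#' @return A list of class `SimpleVcf` with `headerLines`, `records`
#'   (data.frame: `chrom`, `pos`, `id`, `ref`, `alt`, `qual`, `filter`,
#'   `info`, `format`, then one column per sample) and `samples`.
#' @export
readVcfFile <- function(path) {
    if (!file.exists(path))
        stop("VCF file not found: ", path)
    lines <- readLines(path)
    isMeta <- startsWith(lines, "##")
    chromIdx <- which(startsWith(lines, "#CHROM"))
    if (length(chromIdx) != 1L)
        stop("malformed VCF (no single #CHROM header line): ", path)
    headerLines <- lines[seq_len(chromIdx - 1L)][
        isMeta[seq_len(chromIdx - 1L)]]
    colLine <- strsplit(lines[chromIdx], "\t", fixed = TRUE)[[1]]
    nCols <- length(colLine)
    samples <- if (nCols > 9L) colLine[10:nCols] else character(0)
    body <- lines[seq.int(chromIdx + 1L, length.out =
                              length(lines) - chromIdx)]
    body <- body[nzchar(body)]
    recs <- vector("list", length(body))
    for (i in seq_along(body)) {
        f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
        if (length(f) != nCols)
            stop(sprintf(
                "malformed VCF record at line %d of %s (%d fields, expected %d); last good line %d",
                chromIdx + i, path, length(f), nCols, chromIdx + i - 1L))
        recs[[i]] <- f
    }
    m <- if (length(recs)) do.call(rbind, recs) else
        matrix(character(0), ncol = nCols)
    records <- data.frame(chrom = m[, 1L],
                          pos = as.integer(m[, 2L]), id = m[, 3L],
                          ref = m[, 4L], alt = m[, 5L], qual = m[, 6L],
                          filter = m[, 7L], info = m[, 8L],
                          stringsAsFactors = FALSE)
    if (nCols >= 9L && nrow(records)) records$format <- m[, 9L]
    else records$format <- character(nrow(records))
    for (j in seq_along(samples))
        records[[samples[j]]] <- m[, 9L + j]
    if (nrow(records) && any(is.na(records$pos)))
        stop("malformed VCF: non-integer POS at line ",
             chromIdx + which(is.na(records$pos))[1L])
    structure(list(headerLines = headerLines, records = records,
                   samples = samples, columnLine = lines[chromIdx]),
              class = "SimpleVcf")
}

#' Write a SimpleVcf back to disk verbatim
#'
#' @param vcf a `SimpleVcf` from [readVcfFile()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSimpleVcf <- function(vcf, path) {
    df <- vcf$records
    lines <- vapply(seq_len(nrow(df)), function(i)
        paste(unlist(df[i, c("chrom", "pos", "id", "ref", "alt", "qual",
                             "filter", "info", "format",
                             vcf$samples)]),
              collapse = "\t"), character(1))
    writeLines(c(vcf$headerLines, vcf$columnLine, lines), path)
    invisible(path)
}

#' Export the tab-separated variant table
#'
#' One row per record with columns `sample`, `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `transcript`, `hgvs_g`, `hgvs_c`, `hgvs_p`, `dp`,
#' `vd`, `af`, then one column per requested annotation field in
#' request order. Values containing tabs or newlines are
#' percent-encoded so the column count is stable.
#'
#' @param callset a normalized [CallSet-class].
#' @param path output path.
#' @param annotations named list by HGVSg, as for [writeVcfFile()].
#' @param fields annotation field names (column order).
#' @return `path`, invisibly.
#' @export
writeVariantTsv <- function(callset, path, annotations = NULL,
                            fields = character(0)) {
    df <- calls(callset)
    esc <- function(x) percentEncode(ifelse(is.na(x), "", x),
                                     chars = c("\t", "\n"))
    accFromC <- function(hc) sub(":.*$", "", hc)
    header <- c("sample", "chrom", "pos", "ref", "alt", "gene",
                "transcript", "hgvs_g", "hgvs_c", "hgvs_p", "dp", "vd",
                "af", fields)
    rows <- vapply(seq_len(nrow(df)), function(i) {
        hgvsG <- if ("hgvsG" %in% colnames(df)) df$hgvsG[i]
                 else NA_character_
        annVals <- if (length(fields) && !is.null(annotations) &&
                       !is.na(hgvsG)) {
            a <- annotations[[hgvsG]]
            vapply(fields, function(f)
                if (!is.null(a) && f %in% names(a)) a[[f]]
                else "", character(1))
        } else rep("", length(fields))
        paste(esc(c(sampleName(callset), df$chrom[i], df$pos[i],
                    df$ref[i], df$alt[i],
                    if ("gene" %in% colnames(df)) df$gene[i] else "",
                    if ("transcript" %in% colnames(df))
                        df$transcript[i] else "",
                    hgvsG,
                    if ("hgvsC" %in% colnames(df)) df$hgvsC[i] else "",
                    if ("hgvsP" %in% colnames(df)) df$hgvsP[i] else "",
                    df$depthPairs[i], df$altPairs[i],
                    formatAf(df$vaf[i]), annVals)),
              collapse = "\t")
    }, character(1))
    writeLines(c(paste(header, collapse = "\t"), rows), path)
    invisible(path)
}
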