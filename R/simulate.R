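# Synthetic panel and read simulator. Generates amplicon panels with toy
# transcript models and paired-end reads carrying planted variants at
# chosen allele fractions, so the whole pipeline is testable offline.

randomDna <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random CDS free of in-frame stop codons, ending in TAA
randomCds <- function(nCodons) {
    codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                c("A","C","G","T")), 1, paste, collapse = "")
    codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
    paste(c(sample(codons, nCodons - 1L, replace = TRUE), "TAA"),
          collapse = "")
}

#' Generate a synthetic amplicon panel with toy transcripts
#'
#' Builds a random panel on a synthetic chromosome `chrS`. When
#' `withTranscripts` is `TRUE` (and `nAmplicons >= 3`) the first three
#' amplicons are anchored to two toy transcript models:
#'
#' * `NM_TOY001.1` (gene `BRAF`), plus strand, single exon, 60 nt
#'   5'UTR + 2100 nt stop-free CDS + 60 nt 3'UTR, with codon 600
#'   (c.1798-1800) forced to `GTG` (valine). Amplicon 1 centres on that
#'   codon; amplicon 3 centres on c.21-22 (the duplication worked
#'   example).
#' * `NM_TOY002.1` (gene `MINR1`), minus strand, two exons, covering
#'   amplicon 2 - exercises minus-strand coordinate mapping.
#'
#' Remaining amplicons are placed on random, transcript-free sequence.
#' Primer uniqueness (pairwise Hamming distance > 2 x
#' `primerMismatchMax` within the forward and reverse primer sets) is
#' verified and the panel regenerated up to `maxTries` times if violated.
#'
#' @param dir optional directory; when given, panel files are written
#'   there via [writePanelFiles()].
#' @param nAmplicons number of amplicons.
#' @param insertLen length of the insert between the primers (bases).
#' @param primerLen primer length (bases).
#' @param seed integer RNG seed; fixed seed gives identical panels.
#' @param withTranscripts attach the toy transcript models.
#' @param primerMismatchMax the assignment mismatch budget the primer
#'   uniqueness check must exceed twice over.
#' @param maxTries regeneration attempts before giving up.
#' @return A list with `panel` ([AmpliconPanel-class]), `paths` (written
#'   files or `NULL`) and `landmarks` (named list: `chrom`, `codon600g`
#'   = genomic positions of c.1798-1800, `dupSiteG` = genomic positions
#'   of c.21-22, `brafAmplicon`, `dupAmplicon`, `brafTx`).
#' @examples
#' mp <- makePanel(nAmplicons = 3, seed = 7)
#' mp$panel
#' @export
makePanel <- function(dir = NULL, nAmplicons = 8L, insertLen = 120L,
                      primerLen = 20L, seed = 42L, withTranscripts = TRUE,
                      primerMismatchMax = 3L, maxTries = 20L) {
    stopifnot(nAmplicons >= 1, insertLen > 0, primerLen > 0)
    ampLen <- 2L * primerLen + insertLen
    chrom <- "chrS"
    for (attempt in seq_len(maxTries)) {
        set.seed(seed + (attempt - 1L) * 7919L)
        chromLen <- 12000L + nAmplicons * 1000L
        chromSeq <- randomDna(chromLen)

        txs <- list()
        landmarks <- list(chrom = chrom)
        special <- 0L
        if (withTranscripts && nAmplicons >= 3L) {
            # plus-strand toy: 60 UTR5 + 700 codons + 60 UTR3
            utr5 <- 60L; nCodons <- 700L; utr3 <- 60L
            cds <- randomCds(nCodons)
            # codon 600 -> GTG at c.1798-1800
            substr(cds, 1798L, 1800L) <- "GTG"
            # fixed context around c.21-22 so a tandem copy of c.21_22
            # is already maximally 3'-shifted (c.23 breaks the repeat)
            substr(cds, 19L, 24L) <- "CAAGTC"
            txSeq <- paste0(randomDna(utr5), cds, randomDna(utr3))
            txStart <- 1001L
            txEnd <- txStart + nchar(txSeq) - 1L
            substr(chromSeq, txStart, txEnd) <- txSeq
            txBraf <- TranscriptModel(
                "NM_TOY001.1", "BRAF", chrom, "+",
                exonStarts = txStart, exonEnds = txEnd,
                cdsStart = utr5 + 1L, cdsEnd = utr5 + 3L * nCodons,
                splicedSeq = txSeq)
            # minus-strand toy over two exons at 5001..5500
            ex1 <- c(5001L, 5200L); ex2 <- c(5301L, 5500L)
            gSeq <- paste0(substr1(chromSeq, ex1[1], ex1[2]),
                           substr1(chromSeq, ex2[1], ex2[2]))
            spliced <- revcomp(gSeq)
            nEx <- nchar(spliced)
            txMin <- TranscriptModel(
                "NM_TOY002.1", "MINR1", chrom, "-",
                exonStarts = c(ex1[1], ex2[1]),
                exonEnds = c(ex1[2], ex2[2]),
                cdsStart = 10L, cdsEnd = 10L + 389L,  # 390 nt CDS
                splicedSeq = spliced)
            txs <- list(txBraf, txMin)
            gOf <- function(cpos) txStart + utr5 + cpos - 1L
            landmarks$codon600g <- gOf(1798L):gOf(1800L)
            landmarks$dupSiteG <- gOf(21L):gOf(22L)
            landmarks$brafTx <- "NM_TOY001.1"
            special <- 3L
        }

        starts <- integer(nAmplicons)
        if (special == 3L) {
            half <- primerLen + insertLen %/% 2L
            starts[1L] <- landmarks$codon600g[1L] - half
            starts[2L] <- 5021L
            starts[3L] <- landmarks$dupSiteG[2L] - half
            landmarks$brafAmplicon <- "AMP001"
            landmarks$dupAmplicon <- "AMP003"
        }
        if (nAmplicons > special)
            starts[(special + 1L):nAmplicons] <-
                8000L + (seq_len(nAmplicons - special) - 1L) * 1000L

        names <- sprintf("AMP%03d", seq_len(nAmplicons))
        refs <- vapply(starts, function(s)
            substr1(chromSeq, s, s + ampLen - 1L), character(1))
        fwd <- substr(refs, 1L, primerLen)
        rev <- vapply(substr(refs, ampLen - primerLen + 1L, ampLen),
                      revcomp, character(1), USE.NAMES = FALSE)

        minD <- function(p) {
            if (length(p) < 2L) return(Inf)
            min(apply(utils::combn(seq_along(p), 2L), 2L, function(ij)
                hammingDistance(p[ij[1]], p[ij[2]])))
        }
        if (min(minD(fwd), minD(rev)) <= 2L * primerMismatchMax)
            next

        gr <- GenomicRanges::GRanges(
            seqnames = chrom,
            ranges = IRanges::IRanges(start = starts, width = ampLen))
        names(gr) <- names
        S4Vectors::mcols(gr)$fwdPrimer <- fwd
        S4Vectors::mcols(gr)$revPrimer <- rev
        refSet <- Biostrings::DNAStringSet(stats::setNames(refs, names))
        pref <- if (length(txs))
            c(BRAF = "NM_TOY001.1", MINR1 = "NM_TOY002.1")
        else character(0)
        panel <- AmpliconPanel(gr, refSet, txs, pref)
        paths <- if (!is.null(dir)) writePanelFiles(panel, dir) else NULL
        return(list(panel = panel, paths = paths, landmarks = landmarks))
    }
    stop("makePanel: could not generate a panel with pairwise-distinct ",
         "primers after ", maxTries, " attempts")
}

defaultQualityProfile <- function(readLen) {
    list(read1 = as.integer(round(seq(38, 30, length.out = readLen))),
         read2 = as.integer(round(seq(36, 26, length.out = readLen))))
}

# Substitution errors at k uniformly chosen eligible positions
mutateAt <- function(seq, positions) {
    v <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (j in positions)
        v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1L)
    paste(v, collapse = "")
}

# Vectorized error injection over `depth` copies of one template read:
# per-copy error counts are binomial over the eligible (non-primer)
# positions; only errored copies are materialized individually.
erroredCopies <- function(template, depth, rate, protectLeft,
                          protectRight) {
    out <- rep.int(template, depth)
    if (rate <= 0) return(out)
    n <- nchar(template)
    elig <- seq_len(n)
    elig <- elig[elig > protectLeft & elig <= n - protectRight]
    if (!length(elig)) return(out)
    k <- stats::rbinom(depth, length(elig), rate)
    for (p in which(k > 0L))
        out[p] <- mutateAt(template, sample(elig, k[p]))
    out
}

#' Simulate a paired-end amplicon sample with planted variants
#'
#' For every amplicon of `panel`, `depth` read pairs are generated from
#' the amplicon reference or from a variant haplotype. Each planted
#' variant (VCF-style `chrom`/`pos`/`ref`/`alt` plus a target `fraction`)
#' must fall inside the insert of exactly one amplicon; each read pair
#' carries at most one planted variant. In `exact` mode
#' `round(fraction * depth)` pairs per variant are deterministically
#' assigned to the variant haplotype; in `binomial` mode every pair draws
#' its haplotype independently. Sequencing errors are injected per base
#' at `errorRate` (never inside primer regions, so amplicon assignment
#' stays unambiguous), and base qualities follow a cycle-dependent
#' declining profile (read 2 lower than read 1). Qualities are a pure
#' function of the cycle, so identical sequence pairs always carry
#' identical qualities.
#'
#' @param panel an [AmpliconPanel-class].
#' @param planted data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `fraction` (may have zero rows).
#' @param depth read pairs per amplicon.
#' @param readLen read length in bases.
#' @param errorRate per-base substitution error probability.
#' @param seed integer RNG seed.
#' @param dir directory for the output files.
#' @param mode `"binomial"` (default) or `"exact"`.
#' @param sample sample name used in file names and read ids.
#' @return List with `fastq1`, `fastq2`, `truthPath` (written files) and
#'   `truth`, a data.frame per planted variant with the realized
#'   `alt_pairs` count and `depth_pairs`.
#' @export
simulateSample <- function(panel, planted, depth = 2000L, readLen = 100L,
                           errorRate = 0.001, seed = 1L,
                           dir = tempfile("sim"),
                           mode = c("binomial", "exact"),
                           sample = "sim") {
    mode <- match.arg(mode)
    stopifnot(depth >= 1, readLen >= 1)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    amps <- amplicons(panel)
    ampStart <- GenomicRanges::start(amps)
    ampEnd <- GenomicRanges::end(amps)
    ampChrom <- as.character(GenomicRanges::seqnames(amps))
    fwdLen <- nchar(S4Vectors::mcols(amps)$fwdPrimer)
    revLen <- nchar(S4Vectors::mcols(amps)$revPrimer)

    planted <- as.data.frame(planted, stringsAsFactors = FALSE)
    nV <- nrow(planted)
    if (nV) {
        stopifnot(all(c("chrom", "pos", "ref", "alt", "fraction") %in%
                      colnames(planted)))
        stopifnot(all(planted$fraction >= 0 & planted$fraction <= 1))
        planted$ampIdx <- vapply(seq_len(nV), function(i) {
            vEnd <- planted$pos[i] + nchar(planted$ref[i]) - 1L
            hit <- which(ampChrom == planted$chrom[i] &
                         planted$pos[i] >= ampStart + fwdLen &
                         vEnd <= ampEnd - revLen)
            if (!length(hit))
                stop("planted variant at ", planted$chrom[i], ":",
                     planted$pos[i], " is outside every amplicon insert")
            hit[1L]
        }, integer(1))
        planted$altPairs <- 0L
    }

    seq1 <- character(0); seq2 <- character(0); ids <- character(0)
    qp <- defaultQualityProfile(readLen)
    for (a in seq_along(amps)) {
        refseq <- as.character(refSeqs(panel)[[names(amps)[a]]])
        vIdx <- if (nV) which(planted$ampIdx == a) else integer(0)
        haps <- c(list(refseq), lapply(vIdx, function(i) {
            applyEdit(refseq, planted$pos[i] - ampStart[a] + 1L,
                      planted$ref[i], planted$alt[i])
        }))
        fr <- if (length(vIdx)) planted$fraction[vIdx] else numeric(0)
        if (sum(fr) > 1)
            stop("planted fractions on amplicon ", names(amps)[a],
                 " sum to more than 1")
        if (mode == "exact") {
            nAlt <- as.integer(round(fr * depth))
            hapOf <- rep.int(seq_along(haps),
                             c(depth - sum(nAlt), nAlt))
        } else {
            hapOf <- apply(stats::rmultinom(depth, 1L,
                                            c(1 - sum(fr), fr)),
                           2L, which.max)
        }
        if (length(vIdx))
            planted$altPairs[vIdx] <- planted$altPairs[vIdx] +
                vapply(seq_along(vIdx), function(k)
                    sum(hapOf == k + 1L), integer(1))
        r1 <- character(depth); r2 <- character(depth)
        for (h in seq_along(haps)) {
            sel <- which(hapOf == h)
            if (!length(sel)) next
            hap <- haps[[h]]
            hl <- nchar(hap)
            t1 <- substr1(hap, 1L, min(readLen, hl))
            t2 <- revcomp(substr1(hap, max(1L, hl - readLen + 1L), hl))
            r1[sel] <- erroredCopies(t1, length(sel), errorRate,
                                     fwdLen[a],
                                     max(0L, nchar(t1) - (hl - revLen[a])))
            r2[sel] <- erroredCopies(t2, length(sel), errorRate,
                                     revLen[a],
                                     max(0L, nchar(t2) - (hl - fwdLen[a])))
        }
        seq1 <- c(seq1, r1); seq2 <- c(seq2, r2)
        ids <- c(ids, sprintf("%s_%s_%06d", sample, names(amps)[a],
                              seq_len(depth)))
    }

    fq1 <- file.path(dir, paste0(sample, "_R1.fastq.gz"))
    fq2 <- file.path(dir, paste0(sample, "_R2.fastq.gz"))
    writeFastq(seq1, lapply(nchar(seq1), function(n) qp$read1[seq_len(n)]),
               ids, fq1)
    writeFastq(seq2, lapply(nchar(seq2), function(n) qp$read2[seq_len(n)]),
               ids, fq2)

    truth <- if (nV)
        data.frame(chrom = planted$chrom, pos = planted$pos,
                   ref = planted$ref, alt = planted$alt,
                   fraction = planted$fraction,
                   alt_pairs = planted$altPairs,
                   depth_pairs = depth, stringsAsFactors = FALSE)
    else
        data.frame(chrom = character(0), pos = integer(0),
                   ref = character(0), alt = character(0),
                   fraction = numeric(0), alt_pairs = integer(0),
                   depth_pairs = integer(0))
    truthPath <- file.path(dir, paste0(sample, "_truth.tsv"))
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fastq1 = fq1, fastq2 = fq2, truthPath = truthPath, truth = truth)
}

writeFastq <- function(seqs, quals, ids, path) {
    if (!length(seqs)) {
        con <- if (endsWith(path, ".gz")) gzfile(path, "w")
               else file(path, "w")
        close(con)
        return(invisible(path))
    }
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::PhredQuality(IRanges::IntegerList(quals))
    qs <- Biostrings::QualityScaledDNAStringSet(x, q)
    # Biostrings warns about dropping (empty) mcols on the input set
    suppressWarnings(Biostrings::writeQualityScaledXStringSet(
        qs, path, compress = endsWith(path, ".gz")))
    invisible(path)
}

#' Read a (possibly gzipped) paired FASTQ into sequences and qualities
#'
#' @param path FASTQ file, plain or gzip-compressed, Phred+33 qualities.
#' @return List with `seq` (character), `qual` (list of integer
#'   vectors) and `id` (character).
#' @export
readFastq <- function(path) {
    # Biostrings warns about dropping (empty) mcols during construction
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(
        path, quality.scoring = "phred"))
    list(seq = as.character(x),
         qual = as.list(as(Biostrings::quality(x), "IntegerList")),
         id = names(x))
}
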