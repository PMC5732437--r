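# HGVS normalization engine: parsimonious trimming, transcript-directed
# 3' shifting, ins->dup classification, transcript selection and
# rendering of HGVS g./c./p. names. Works entirely from local reference
# material (the panel's amplicon sequences and transcript models); no
# remote service is involved.

#' Reference accessor over the panel's amplicon sequences
#'
#' Returns a function `f(chrom, start, end)` yielding the forward-strand
#' reference sequence for any interval fully contained in one amplicon,
#' or `NA` outside the panel. Used by the normalization engine to
#' examine reference context while shifting.
#'
#' @param panel an [AmpliconPanel-class].
#' @return A function of `(chrom, start, end)`.
#' @export
ampliconRefAccessor <- function(panel) {
    amps <- amplicons(panel)
    chroms <- as.character(GenomicRanges::seqnames(amps))
    starts <- GenomicRanges::start(amps)
    ends <- GenomicRanges::end(amps)
    seqs <- as.character(refSeqs(panel))[names(amps)]
    function(chrom, start, end) {
        if (end < start) return("")
        i <- which(chroms == chrom & starts <= start & ends >= end)
        if (!length(i)) return(NA_character_)
        i <- i[1L]
        substr1(seqs[[i]], start - starts[i] + 1L, end - starts[i] + 1L)
    }
}

#' Trim a variant to its most parsimonious anchored form
#'
#' Removes the shared suffix, then the shared prefix, of `ref`/`alt`,
#' keeping one anchoring reference base for indels, and adjusts the
#' position. Substitutions and balanced delins lose all shared context.
#'
#' @param chrom,pos,ref,alt VCF-style variant tuple (1-based `pos`,
#'   non-empty `ref`/`alt`).
#' @return A list (`chrom`, `pos`, `ref`, `alt`) in minimal anchored
#'   form.
#' @examples
#' trimParsimonious("chr1", 100, "CTT", "CT")   # 1-base deletion
#' trimParsimonious("chr1", 50, "ACAC", "AC")   # 2-base deletion
#' @export
trimParsimonious <- function(chrom, pos, ref, alt) {
    if (ref == alt)
        stop("ref == alt: not a variant")
    pos <- as.integer(pos)
    # shared suffix, never emptying either allele
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
    }
    # shared prefix
    p <- 0L
    maxP <- min(nchar(ref), nchar(alt))
    while (p < maxP && substr(ref, p + 1L, p + 1L) ==
           substr(alt, p + 1L, p + 1L))
        p <- p + 1L
    if (p == nchar(alt) && p > 0L) {
        # deletion: anchor on the last shared base
        list(chrom = chrom, pos = pos + p - 1L,
             ref = substr(ref, p, nchar(ref)),
             alt = substr(ref, p, p))
    } else if (p == nchar(ref) && p > 0L) {
        # insertion
        list(chrom = chrom, pos = pos + p - 1L,
             ref = substr(ref, p, p),
             alt = substr(alt, p, nchar(alt)))
    } else {
        list(chrom = chrom, pos = pos + p,
             ref = substr(ref, p + 1L, nchar(ref)),
             alt = substr(alt, p + 1L, nchar(alt)))
    }
}

# Unanchored edit view of a minimal anchored variant. Indels may be
# anchored on either side (a shared leading or trailing base); both
# readings describe the same edit.
# type "del": start = first deleted base, seq = deleted bases.
# type "ins": start = base BEFORE the insertion point, seq = inserted.
# type "sub"/"delins": start = first ref base.
asEdit <- function(v) {
    nr <- nchar(v$ref); na <- nchar(v$alt)
    firstShared <- substr(v$ref, 1L, 1L) == substr(v$alt, 1L, 1L)
    lastShared <- substr(v$ref, nr, nr) == substr(v$alt, na, na)
    if (nr > na && na == 1L && firstShared)
        list(type = "del", start = v$pos + 1L,
             seq = substr(v$ref, 2L, nr))
    else if (nr > na && na == 1L && lastShared)
        list(type = "del", start = v$pos,
             seq = substr(v$ref, 1L, nr - 1L))
    else if (na > nr && nr == 1L && firstShared)
        list(type = "ins", start = v$pos,
             seq = substr(v$alt, 2L, na))
    else if (na > nr && nr == 1L && lastShared)
        list(type = "ins", start = v$pos - 1L,
             seq = substr(v$alt, 1L, na - 1L))
    else if (nr == 1L && na == 1L)
        list(type = "sub", start = v$pos, seq = v$alt)
    else
        list(type = "delins", start = v$pos, seq = v$alt)
}

# Re-anchor a pure-indel edit as a VCF-style tuple using the accessor.
anchorEdit <- function(chrom, edit, refAcc) {
    if (edit$type == "del") {
        a <- refAcc(chrom, edit$start - 1L, edit$start - 1L)
        if (is.na(a)) return(NULL)
        list(chrom = chrom, pos = edit$start - 1L,
             ref = paste0(a, edit$seq), alt = a)
    } else {
        a <- refAcc(chrom, edit$start, edit$start)
        if (is.na(a)) return(NULL)
        list(chrom = chrom, pos = edit$start, ref = a,
             alt = paste0(a, edit$seq))
    }
}

#' Shift a parsimonious indel to its most 3' position
#'
#' Among all equivalent representations of a pure insertion or deletion,
#' returns the one at the maximal position in the reading direction of
#' `tx` (genomic right for plus-strand transcripts, genomic left for
#' minus-strand ones; genomic right when no transcript is supplied).
#' Substitutions and delins are returned unchanged. The result carries a
#' logical attribute `shifted`.
#'
#' @param v a minimal anchored variant (list with `chrom`, `pos`,
#'   `ref`, `alt`), as produced by [trimParsimonious()].
#' @param tx a [TranscriptModel-class] or `NULL`.
#' @param refAcc reference accessor, see [ampliconRefAccessor()].
#' @return The shifted variant in the same anchored form.
#' @export
shift3Prime <- function(v, tx = NULL, refAcc) {
    edit <- asEdit(v)
    if (!edit$type %in% c("del", "ins")) {
        attr(v, "shifted") <- FALSE
        return(v)
    }
    dirRight <- is.null(tx) || tx@strand == "+"
    L <- nchar(edit$seq)
    s <- edit$start
    seqv <- edit$seq
    moved <- FALSE
    repeat {
        if (edit$type == "del") {
            if (dirRight) {
                nxt <- refAcc(v$chrom, s + L, s + L)
                if (is.na(nxt) || nxt != substr(seqv, 1L, 1L)) break
                seqv <- paste0(substr(seqv, 2L, L), nxt)
                s <- s + 1L
            } else {
                prv <- refAcc(v$chrom, s - 1L, s - 1L)
                if (is.na(prv) || prv != substr(seqv, L, L)) break
                seqv <- paste0(prv, substr(seqv, 1L, L - 1L))
                s <- s - 1L
            }
        } else {                       # insertion after position s
            if (dirRight) {
                nxt <- refAcc(v$chrom, s + 1L, s + 1L)
                if (is.na(nxt) || nxt != substr(seqv, 1L, 1L)) break
                seqv <- paste0(substr(seqv, 2L, L), substr(seqv, 1L, 1L))
                s <- s + 1L
            } else {
                cur <- refAcc(v$chrom, s, s)
                if (is.na(cur) || cur != substr(seqv, L, L)) break
                seqv <- paste0(substr(seqv, L, L),
                               substr(seqv, 1L, L - 1L))
                s <- s - 1L
            }
        }
        moved <- TRUE
    }
    # always re-anchor on the 5' side so every equivalent encoding
    # (including right-anchored ones) lands on one canonical tuple
    out <- v
    anch <- anchorEdit(v$chrom, list(type = edit$type, start = s,
                                     seq = seqv), refAcc)
    if (!is.null(anch)) out <- anch
    attr(out, "shifted") <- moved
    out
}

#' Classify a 3'-shifted insertion as ins or dup
#'
#' An insertion is a duplication iff the inserted sequence equals the
#' reference immediately 5' (in transcript direction) of the insertion
#' point.
#'
#' @param v a minimal anchored, 3'-shifted variant.
#' @param tx a [TranscriptModel-class] or `NULL` (plus-strand
#'   convention).
#' @param refAcc reference accessor.
#' @return `"dup"` or `"ins"`; other variant classes return their own
#'   kind (`"sub"`, `"del"`, `"delins"`).
#' @export
classifyDup <- function(v, tx = NULL, refAcc) {
    edit <- asEdit(v)
    if (edit$type != "ins") return(edit$type)
    L <- nchar(edit$seq)
    p <- edit$start
    minus <- !is.null(tx) && tx@strand == "-"
    side <- if (minus) refAcc(v$chrom, p + 1L, p + L)
            else refAcc(v$chrom, p - L + 1L, p)
    if (!is.na(side) && side == edit$seq) "dup" else "ins"
}

txSpan <- function(tx) {
    c(start = min(IRanges::start(tx@exons)),
      end = max(IRanges::end(tx@exons)))
}

# distance (genomic bases) from a variant span to the nearest exon; 0 if
# overlapping an exon
exonDistance <- function(tx, pos, end) {
    es <- IRanges::start(tx@exons); ee <- IRanges::end(tx@exons)
    if (any(pos <= ee & end >= es)) return(0L)
    min(pmin(abs(es - end), abs(pos - ee)))
}

#' Select the reporting transcript for a variant
#'
#' Among transcripts whose genomic span overlaps the variant, a
#' transcript named in the preferred map wins; with several preferred
#' candidates the one whose nearest exon is closest to the variant is
#' chosen (distance 0 if exonic), with a remaining tie broken by the
#' lexicographically smallest accession. With no preferred candidate the
#' same distance/accession rule applies to all overlapping transcripts.
#'
#' @param chrom,pos,ref variant location (anchored tuple).
#' @param txs named list of [TranscriptModel-class] objects.
#' @param preferred named character vector (gene to accession).
#' @return A [TranscriptModel-class], or `NULL` if no transcript
#'   overlaps (intergenic).
#' @export
selectTranscript <- function(chrom, pos, ref, txs,
                             preferred = character(0)) {
    if (!length(txs)) return(NULL)
    vEnd <- pos + max(nchar(ref), 1L) - 1L
    overlapping <- Filter(function(t) {
        sp <- txSpan(t)
        t@chrom == chrom && pos <= sp[["end"]] && vEnd >= sp[["start"]]
    }, txs)
    if (!length(overlapping)) return(NULL)
    accs <- vapply(overlapping, accession, character(1))
    prefHit <- overlapping[accs %in% preferred]
    cand <- if (length(prefHit)) prefHit else overlapping
    if (length(cand) == 1L) return(cand[[1L]])
    d <- vapply(cand, function(t) as.numeric(exonDistance(t, pos, vEnd)),
                numeric(1))
    cand <- cand[d == min(d)]
    cand[[order(vapply(cand, accession, character(1)))[1L]]]
}

# ---- transcript coordinate mapping -----------------------------------

# Map a genomic position to transcript coordinates. Returns
# list(n, offset): n is the transcript position of the nearest exonic
# base, offset the intronic distance in transcript direction (0 when
# exonic); NULL when outside the transcript span.
genomicToTx <- function(tx, g) {
    es <- IRanges::start(tx@exons); ee <- IRanges::end(tx@exons)
    K <- length(es)
    w <- ee - es + 1L
    if (g < es[1L] || g > ee[K]) return(NULL)
    plus <- tx@strand == "+"
    cumBefore <- cumsum(c(0L, w))[seq_len(K)]       # widths left of exon i
    cumAfter <- rev(cumsum(c(0L, rev(w))))[-1L]     # widths right of exon i
    hit <- which(g >= es & g <= ee)
    if (length(hit)) {
        i <- hit[1L]
        n <- if (plus) cumBefore[i] + (g - es[i] + 1L)
             else cumAfter[i] + (ee[i] - g + 1L)
        return(list(n = n, offset = 0L))
    }
    i <- max(which(ee < g))                          # intron after exon i
    dLeft <- g - ee[i]; dRight <- es[i + 1L] - g
    if (plus) {
        nL <- cumBefore[i] + w[i]                    # last base of exon i
        if (dLeft <= dRight) list(n = nL, offset = dLeft)
        else list(n = nL + 1L, offset = -dRight)
    } else {
        nR <- cumAfter[i + 1L] + w[i + 1L]           # tx end of exon i+1
        if (dRight <= dLeft) list(n = nR, offset = dRight)
        else list(n = nR + 1L, offset = -dLeft)
    }
}

# CDS-relative c. position string for transcript position n (+offset)
cNotation <- function(tx, n, offset = 0L) {
    base <- if (n < tx@cdsStart) as.character(n - tx@cdsStart)
            else if (n > tx@cdsEnd) paste0("*", n - tx@cdsEnd)
            else as.character(n - tx@cdsStart + 1L)
    if (offset > 0L) paste0(base, "+", offset)
    else if (offset < 0L) paste0(base, offset)
    else base
}

aa1to3 <- c(A="Ala", R="Arg", N="Asn", D="Asp", C="Cys", Q="Gln",
            E="Glu", G="Gly", H="His", I="Ile", L="Leu", K="Lys",
            M="Met", F="Phe", P="Pro", S="Ser", T="Thr", W="Trp",
            Y="Tyr", V="Val", "*"="Ter")

aaName <- function(aa, oneLetter = TRUE) {
    if (oneLetter) aa
    else paste(unname(aa1to3[strsplit(aa, "", fixed = TRUE)[[1]]]),
               collapse = "")
}

translateCds <- function(seq) {
    n <- nchar(seq) %/% 3L
    if (n == 0L) return("")
    codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
    paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Predict the protein consequence of a coding edit
#'
#' Applies an edit (CDS coordinates) to the transcript's coding sequence
#' and renders the HGVS p. consequence: substitutions and in-frame
#' delins by translating the mutated CDS, frameshifts as
#' `p.Xpos Yfs*N` with `N` the distance to the first downstream stop,
#' synonymous changes as `p.X{pos}=`, and edits disrupting the initiator
#' codon as `p.?`.
#'
#' @param tx a [TranscriptModel-class].
#' @param cdsStart,cdsEnd 1-based CDS coordinates of the replaced
#'   reference span; for a pure insertion after base `p` pass
#'   `cdsStart = p + 1`, `cdsEnd = p`.
#' @param altSeq replacement sequence on the transcript strand (may be
#'   empty for a deletion).
#' @param oneLetter one-letter (default) or three-letter amino-acid
#'   codes.
#' @return The `p.` string.
#' @export
predictProtein <- function(tx, cdsStart, cdsEnd, altSeq,
                           oneLetter = TRUE) {
    cds <- substr1(tx@splicedSeq, tx@cdsStart, tx@cdsEnd)
    L <- nchar(cds)
    stopifnot(cdsStart >= 1L, cdsEnd <= L, cdsStart <= cdsEnd + 1L)
    mut <- paste0(substr1(cds, 1L, cdsStart - 1L), altSeq,
                  substr1(cds, cdsEnd + 1L, L))
    refAA <- translateCds(cds)
    if (cdsStart <= 3L && mut != cds &&
        substr(mut, 1L, 3L) != substr(cds, 1L, 3L))
        return("p.?")
    refLen <- cdsEnd - cdsStart + 1L
    frameshift <- (nchar(altSeq) - refLen) %% 3L != 0L
    mutAA <- translateCds(mut)
    if (frameshift) {
        # first codon whose translation changes
        i <- 1L
        nMin <- min(nchar(refAA), nchar(mutAA))
        while (i <= nMin && substr(refAA, i, i) == substr(mutAA, i, i))
            i <- i + 1L
        if (i > nchar(mutAA))
            return(sprintf("p.%s%d?fs", aaName(substr(refAA, i, i),
                                               oneLetter), i))
        newAA <- substr(mutAA, i, i)
        if (newAA == "*")
            return(sprintf("p.%s%d%s", aaName(substr(refAA, i, i),
                                              oneLetter), i,
                           aaName("*", oneLetter)))
        stopRel <- regexpr("*", substr(mutAA, i, nchar(mutAA)),
                           fixed = TRUE)
        fsTail <- if (stopRel > 0L) sprintf("fs*%d", as.integer(stopRel))
                  else "fs*?"
        return(sprintf("p.%s%d%s%s", aaName(substr(refAA, i, i),
                                            oneLetter), i,
                       aaName(newAA, oneLetter), fsTail))
    }
    if (mutAA == refAA) {
        i <- (cdsStart - 1L) %/% 3L + 1L
        return(sprintf("p.%s%d=", aaName(substr(refAA, i, i), oneLetter),
                       i))
    }
    # strip shared prefix/suffix of the two protein strings
    i <- 1L
    nMin <- min(nchar(refAA), nchar(mutAA))
    while (i <= nMin && substr(refAA, i, i) == substr(mutAA, i, i))
        i <- i + 1L
    jR <- nchar(refAA); jM <- nchar(mutAA)
    while (jR >= i && jM >= i &&
           substr(refAA, jR, jR) == substr(mutAA, jM, jM)) {
        jR <- jR - 1L; jM <- jM - 1L
    }
    refSeg <- substr1(refAA, i, jR)
    mutSeg <- substr1(mutAA, i, jM)
    if (nchar(refSeg) == 1L && nchar(mutSeg) == 1L)
        return(sprintf("p.%s%d%s", aaName(refSeg, oneLetter), i,
                       aaName(mutSeg, oneLetter)))
    if (nchar(mutSeg) == 0L) {
        if (nchar(refSeg) == 1L)
            return(sprintf("p.%s%ddel", aaName(refSeg, oneLetter), i))
        return(sprintf("p.%s%d_%s%ddel",
                       aaName(substr(refSeg, 1L, 1L), oneLetter), i,
                       aaName(substr(refSeg, nchar(refSeg),
                                     nchar(refSeg)), oneLetter), jR))
    }
    if (nchar(refSeg) == 0L) {
        # pure amino-acid insertion between i-1 and i
        return(sprintf("p.%s%d_%s%dins%s",
                       aaName(substr(refAA, i - 1L, i - 1L), oneLetter),
                       i - 1L,
                       aaName(substr(refAA, i, i), oneLetter), i,
                       aaName(mutSeg, oneLetter)))
    }
    if (nchar(refSeg) == 1L)
        return(sprintf("p.%s%ddelins%s", aaName(refSeg, oneLetter), i,
                       aaName(mutSeg, oneLetter)))
    sprintf("p.%s%d_%s%ddelins%s",
            aaName(substr(refSeg, 1L, 1L), oneLetter), i,
            aaName(substr(refSeg, nchar(refSeg), nchar(refSeg)),
                   oneLetter), jR,
            aaName(mutSeg, oneLetter))
}

# ---- full rendering ---------------------------------------------------

renderHgvs <- function(v, kind, tx, refAcc, oneLetter = TRUE) {
    edit <- asEdit(v)
    chrom <- v$chrom
    minus <- !is.null(tx) && tx@strand == "-"
    txSeq <- function(s) if (minus) revcomp(s) else s

    # genomic name (coordinates follow the transcript-matched, i.e.
    # cDNA-shifted, position)
    hgvsG <- switch(kind,
        sub = sprintf("%s:g.%d%s>%s", chrom, edit$start, v$ref, v$alt),
        del = {
            e <- edit$start + nchar(edit$seq) - 1L
            if (e == edit$start) sprintf("%s:g.%ddel", chrom, edit$start)
            else sprintf("%s:g.%d_%ddel", chrom, edit$start, e)
        },
        ins = sprintf("%s:g.%d_%dins%s", chrom, edit$start,
                      edit$start + 1L, edit$seq),
        dup = {
            L <- nchar(edit$seq)
            a <- if (minus) edit$start + 1L else edit$start - L + 1L
            b <- a + L - 1L
            if (a == b) sprintf("%s:g.%ddup", chrom, a)
            else sprintf("%s:g.%d_%ddup", chrom, a, b)
        },
        delins = {
            e <- edit$start + nchar(v$ref) - 1L
            sprintf("%s:g.%d_%ddelins%s", chrom, edit$start, e, v$alt)
        })

    if (is.null(tx))
        return(list(hgvsG = hgvsG, hgvsC = NA_character_,
                    hgvsP = NA_character_))

    mapOrNull <- function(g) genomicToTx(tx, g)
    cPart <- function(m) cNotation(tx, m$n, m$offset)
    acc <- tx@accession

    # genomic endpoints of the edit in plus-strand order
    gRange <- switch(kind,
        sub = c(edit$start, edit$start),
        del = c(edit$start, edit$start + nchar(edit$seq) - 1L),
        ins = c(edit$start, edit$start + 1L),
        dup = {
            L <- nchar(edit$seq)
            a <- if (minus) edit$start + 1L else edit$start - L + 1L
            c(a, a + L - 1L)
        },
        delins = c(edit$start, edit$start + nchar(v$ref) - 1L))
    m1 <- mapOrNull(gRange[1L]); m2 <- mapOrNull(gRange[2L])
    if (is.null(m1) || is.null(m2))
        return(list(hgvsG = hgvsG, hgvsC = NA_character_,
                    hgvsP = NA_character_))
    if (minus) { tmp <- m1; m1 <- m2; m2 <- tmp }   # transcript order

    hgvsC <- switch(kind,
        sub = sprintf("%s:c.%s%s>%s", acc, cPart(m1), txSeq(v$ref),
                      txSeq(v$alt)),
        del = if (gRange[1L] == gRange[2L])
                  sprintf("%s:c.%sdel", acc, cPart(m1))
              else sprintf("%s:c.%s_%sdel", acc, cPart(m1), cPart(m2)),
        ins = sprintf("%s:c.%s_%sins%s", acc, cPart(m1), cPart(m2),
                      txSeq(edit$seq)),
        dup = if (gRange[1L] == gRange[2L])
                  sprintf("%s:c.%sdup", acc, cPart(m1))
              else sprintf("%s:c.%s_%sdup", acc, cPart(m1), cPart(m2)),
        delins = sprintf("%s:c.%s_%sdelins%s", acc, cPart(m1),
                         cPart(m2), txSeq(v$alt)))

    # protein consequence only for fully exonic, fully coding edits
    hgvsP <- NA_character_
    coding <- m1$offset == 0L && m2$offset == 0L &&
        m1$n >= tx@cdsStart && m2$n <= tx@cdsEnd
    if (coding) {
        c1 <- m1$n - tx@cdsStart + 1L
        c2 <- m2$n - tx@cdsStart + 1L
        pr <- switch(kind,
            sub = predictProtein(tx, c1, c2, txSeq(v$alt), oneLetter),
            del = predictProtein(tx, c1, c2, "", oneLetter),
            ins = predictProtein(tx, c1 + 1L, c1, txSeq(edit$seq),
                                 oneLetter),
            dup = predictProtein(tx, c2 + 1L, c2, txSeq(edit$seq),
                                 oneLetter),
            delins = predictProtein(tx, c1, c2, txSeq(v$alt), oneLetter))
        hgvsP <- paste0(acc, ":", pr)
    }
    list(hgvsG = hgvsG, hgvsC = hgvsC, hgvsP = hgvsP)
}

#' Normalize a variant and render its HGVS names
#'
#' Full normalization: parsimonious trimming, transcript selection,
#' transcript-directed 3' shifting, ins/dup classification and HGVS
#' g./c./p. rendering. The operation is idempotent: normalizing its own
#' canonical output changes nothing.
#'
#' @param chrom,pos,ref,alt VCF-style variant tuple.
#' @param panel an [AmpliconPanel-class] supplying reference sequence,
#'   transcript models and the preferred-transcript map.
#' @param oneLetter use one-letter amino-acid codes in p. names.
#' @return A list of class `NormalizedVariant`: canonical `chrom`,
#'   `pos`, `ref`, `alt` (anchored VCF form), `kind` (`sub`, `del`,
#'   `ins`, `dup`, `delins`), `shifted`, `transcript`, `gene`, `hgvsG`,
#'   `hgvsC`, `hgvsP`.
#' @examples
#' mp <- makePanel(nAmplicons = 3, seed = 7)
#' g <- mp$landmarks$codon600g[1]
#' acc <- ampliconRefAccessor(mp$panel)
#' ref <- acc("chrS", g, g)
#' alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
#' normalizeVariant("chrS", g, ref, alt, mp$panel)$hgvsC
#' @param refAcc optional prebuilt [ampliconRefAccessor()] (avoids
#'   rebuilding it when normalizing many variants).
#' @export
normalizeVariant <- function(chrom, pos, ref, alt, panel,
                             oneLetter = TRUE, refAcc = NULL) {
    if (is.null(refAcc)) refAcc <- ampliconRefAccessor(panel)
    v <- trimParsimonious(chrom, pos, ref, alt)
    tx <- selectTranscript(v$chrom, v$pos, v$ref,
                           transcriptModels(panel),
                           preferredTranscripts(panel))
    v <- shift3Prime(v, tx, refAcc)
    shifted <- isTRUE(attr(v, "shifted"))
    kind <- classifyDup(v, tx, refAcc)
    hg <- renderHgvs(v, kind, tx, refAcc, oneLetter)
    structure(list(chrom = v$chrom, pos = v$pos, ref = v$ref,
                   alt = v$alt, kind = kind, shifted = shifted,
                   transcript = if (is.null(tx)) NA_character_
                                else tx@accession,
                   gene = if (is.null(tx)) NA_character_ else tx@gene,
                   hgvsG = hg$hgvsG, hgvsC = hg$hgvsC,
                   hgvsP = hg$hgvsP),
              class = "NormalizedVariant")
}

#' Normalize all calls of a CallSet
#'
#' Applies [normalizeVariant()] to every record, replaces the raw tuple
#' with the canonical one and appends `gene`, `transcript`, `hgvsG`,
#' `hgvsC`, `hgvsP` and `kind` columns. Records whose canonical tuples
#' coincide (different raw encodings of the same variant) are combined:
#' supporting pairs are summed and the depth taken as the maximum, so
#' the reported VAF reflects all contributing read sets.
#'
#' @param callset a [CallSet-class].
#' @param panel an [AmpliconPanel-class].
#' @return The normalized, re-sorted [CallSet-class].
#' @export
normalizeCalls <- function(callset, panel) {
    df <- calls(callset)
    if (!nrow(df)) {
        df$gene <- character(0); df$transcript <- character(0)
        df$hgvsG <- character(0); df$hgvsC <- character(0)
        df$hgvsP <- character(0); df$kind <- character(0)
        return(new("CallSet", sample = sampleName(callset), calls = df,
                   stats = runStats(callset)))
    }
    refAcc <- ampliconRefAccessor(panel)
    nv <- lapply(seq_len(nrow(df)), function(i)
        normalizeVariant(df$chrom[i], df$pos[i], df$ref[i], df$alt[i],
                         panel, refAcc = refAcc))
    df$pos <- vapply(nv, function(x) x$pos, integer(1))
    df$ref <- vapply(nv, function(x) x$ref, character(1))
    df$alt <- vapply(nv, function(x) x$alt, character(1))
    df$gene <- vapply(nv, function(x) x$gene, character(1))
    df$transcript <- vapply(nv, function(x) x$transcript, character(1))
    df$hgvsG <- vapply(nv, function(x) x$hgvsG, character(1))
    df$hgvsC <- vapply(nv, function(x) x$hgvsC, character(1))
    df$hgvsP <- vapply(nv, function(x) x$hgvsP, character(1))
    df$kind <- vapply(nv, function(x) x$kind, character(1))

    key <- variantKey(df)
    if (anyDuplicated(key)) {
        pieces <- split(df, key)
        df <- do.call(rbind, lapply(pieces, function(p) {
            if (nrow(p) == 1L) return(p)
            out <- p[1L, , drop = FALSE]
            out$altPairs <- sum(p$altPairs)
            out$depthPairs <- max(p$depthPairs)
            out$vaf <- if (out$depthPairs > 0)
                out$altPairs / out$depthPairs else 0
            out$amplicons <- paste(sort(unique(unlist(
                strsplit(p$amplicons, ",")))), collapse = ",")
            out$isMnpParent <- any(p$isMnpParent)
            out
        }))
    }
    df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
    rownames(df) <- NULL
    new("CallSet", sample = sampleName(callset), calls = df,
        stats = runStats(callset))
}
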