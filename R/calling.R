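# Amplicon assignment, per-read variant extraction, in-phase (MNP)
# grouping, read-pair caching and aggregation to threshold-filtered
# variant calls.

#' Variant-calling parameters
#'
#' @param phaseWindow maximum number of reference bases strictly between
#'   two variants on one merged read for them to be combined into a
#'   compound in-phase (delins) variant.
#' @param minVaf minimum variant allele frequency for a call to be
#'   retained (inclusive).
#' @param minAltReads minimum number of supporting merged pairs
#'   (inclusive).
#' @param primerMismatchMax maximum Hamming mismatches tolerated between
#'   a read prefix and an amplicon primer during assignment.
#' @param merge a [MergeParams()] list; also supplies the alignment
#'   scores used for read-to-reference alignment.
#' @return A list of class `CallingParams`.
#' @export
CallingParams <- function(phaseWindow = 15L, minVaf = 0.20,
                          minAltReads = 5L, primerMismatchMax = 3L,
                          merge = MergeParams()) {
    stopifnot(phaseWindow >= 0, minVaf >= 0, minVaf <= 1, minAltReads >= 0)
    structure(list(phaseWindow = as.integer(phaseWindow),
                   minVaf = minVaf,
                   minAltReads = as.integer(minAltReads),
                   primerMismatchMax = as.integer(primerMismatchMax),
                   merge = merge),
              class = "CallingParams")
}

#' Assign a read pair to an amplicon by primer matching
#'
#' The forward primer is compared against the prefix of read 1 and the
#' reverse primer against the prefix of read 2 (Hamming distance over the
#' primer length). An amplicon matches when both distances are at most
#' `primerMismatchMax`; among several matches the smallest total distance
#' wins, and a remaining tie leaves the pair unassigned.
#'
#' @param seq1,seq2 mate sequences.
#' @param panel an [AmpliconPanel-class].
#' @param params [CallingParams()].
#' @return The matching amplicon name, or `NA_character_`.
#' @export
assignAmplicon <- function(seq1, seq2, panel, params = CallingParams()) {
    assignAmpliconView(seq1, seq2, panelView(panel), params)
}

# Plain-list snapshot of the panel for the per-read hot paths (S4
# accessor dispatch is too costly inside read loops).
panelView <- function(panel) {
    amps <- amplicons(panel)
    mc <- S4Vectors::mcols(amps)
    nms <- names(amps)
    list(names = nms,
         chrom = as.character(GenomicRanges::seqnames(amps)),
         start = GenomicRanges::start(amps),
         end = GenomicRanges::end(amps),
         fwd = as.character(mc$fwdPrimer),
         rev = as.character(mc$revPrimer),
         ref = as.character(refSeqs(panel))[nms])
}

assignAmpliconView <- function(seq1, seq2, view, params) {
    total <- rep(NA_integer_, length(view$names))
    for (i in seq_along(view$names)) {
        f <- view$fwd[i]; r <- view$rev[i]
        if (nchar(seq1) < nchar(f) || nchar(seq2) < nchar(r)) next
        d1 <- hammingDistance(substr(seq1, 1L, nchar(f)), f)
        if (d1 > params$primerMismatchMax) next
        d2 <- hammingDistance(substr(seq2, 1L, nchar(r)), r)
        if (d2 > params$primerMismatchMax) next
        total[i] <- d1 + d2
    }
    if (all(is.na(total))) return(NA_character_)
    best <- which(total == min(total, na.rm = TRUE))
    if (length(best) != 1L) return(NA_character_)
    view$names[best]
}

emptyVariants <- function() {
    data.frame(chrom = character(0), pos = integer(0),
               ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
}

#' Call raw variants from one merged read
#'
#' Aligns the merged consensus read against the amplicon reference with
#' Smith-Waterman and walks the edit operations: every mismatched column
#' becomes one substitution, every insertion/deletion run one anchored
#' VCF-style indel with its genomic position derived from the amplicon
#' start. Variants whose reference span touches a primer-binding region
#' are dropped (primer bases are synthetic). A read whose alignment
#' covers less than half of its length is discarded as unalignable.
#'
#' @param merged a `MergedRead` from [mergePair()] (or any list with a
#'   `seq` element).
#' @param amplicon amplicon name in `panel`.
#' @param panel an [AmpliconPanel-class].
#' @param params [CallingParams()].
#' @return `NULL` if unalignable, otherwise a list with `variants` (a
#'   data.frame of `chrom`, `pos`, `ref`, `alt`, sorted by position) and
#'   `cov` (genomic `start`/`end` the alignment covers).
#' @export
callRead <- function(merged, amplicon, panel, params = CallingParams()) {
    view <- panelView(panel)
    i <- match(amplicon, view$names)
    if (is.na(i)) stop("unknown amplicon: ", amplicon)
    al <- smithWaterman(merged$seq, view$ref[i], params$merge)
    callFromAlignment(merged$seq, al, view, i)
}

# Variant extraction given a precomputed read-vs-reference alignment.
callFromAlignment <- function(seq, al, view, i) {
    merged <- list(seq = seq)
    refseq <- view$ref[i]
    readSpan <- al$aEnd - al$aStart + 1L
    if (readSpan < 0.5 * nchar(merged$seq))
        return(NULL)
    ampStart <- view$start[i]
    ampEnd <- view$end[i]
    chrom <- view$chrom[i]
    fwdLen <- nchar(view$fwd[i]); revLen <- nchar(view$rev[i])

    av <- strsplit(al$aAln, "", fixed = TRUE)[[1]]
    bv <- strsplit(al$bAln, "", fixed = TRUE)[[1]]
    pos <- integer(0); ref <- character(0); alt <- character(0)
    rdPos <- al$aStart; rfPos <- al$bStart
    k <- 1L
    ops <- al$ops
    rd <- strsplit(merged$seq, "", fixed = TRUE)[[1]]
    rf <- strsplit(refseq, "", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(ops))) {
        op <- ops$op[j]; len <- ops$len[j]
        if (op == "M") {
            rdPos <- rdPos + len; rfPos <- rfPos + len
        } else if (op == "X") {
            for (t in seq_len(len)) {
                pos <- c(pos, rfPos); ref <- c(ref, rf[rfPos])
                alt <- c(alt, rd[rdPos])
                rdPos <- rdPos + 1L; rfPos <- rfPos + 1L
            }
        } else if (op == "I") {        # insertion relative to reference
            anchor <- rfPos - 1L
            if (anchor >= 1L) {
                insSeq <- paste(rd[rdPos:(rdPos + len - 1L)],
                                collapse = "")
                pos <- c(pos, anchor); ref <- c(ref, rf[anchor])
                alt <- c(alt, paste0(rf[anchor], insSeq))
            }
            rdPos <- rdPos + len
        } else if (op == "D") {        # deletion from reference
            anchor <- rfPos - 1L
            if (anchor >= 1L) {
                delSeq <- paste(rf[anchor:(rfPos + len - 1L)],
                                collapse = "")
                pos <- c(pos, anchor); ref <- c(ref, delSeq)
                alt <- c(alt, rf[anchor])
            }
            rfPos <- rfPos + len
        }
        k <- k + len
    }
    vars <- data.frame(chrom = rep(chrom, length(pos)),
                       pos = ampStart + pos - 1L,
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
    if (nrow(vars)) {
        spanEnd <- vars$pos + nchar(vars$ref) - 1L
        inPrimer <- vars$pos <= ampStart + fwdLen - 1L |
                    spanEnd >= ampEnd - revLen + 1L
        vars <- vars[!inPrimer, , drop = FALSE]
        vars <- vars[order(vars$pos, vars$ref, vars$alt), , drop = FALSE]
        rownames(vars) <- NULL
    }
    list(variants = vars,
         cov = c(start = ampStart + al$bStart - 1L,
                 end = ampStart + al$bEnd - 1L),
         chrom = chrom)
}

#' Group proximate variants of one merged read into compound MNPs
#'
#' Variants from a single merged read are transitively grouped whenever
#' the number of reference bases strictly between one variant's
#' reference span and the next variant's span is at most `window`
#' (variants on one merged read derive from one DNA strand, so they are
#' in phase). Each group of two or more yields a parent delins spanning
#' the first to last reference base with the read's observed alternate
#' sequence; the constituents are retained and reported individually as
#' well.
#'
#' @param variants data.frame (`chrom`, `pos`, `ref`, `alt`) from
#'   [callRead()], one merged read, sorted by position.
#' @param amplicon amplicon name (source of the reference sequence for
#'   the parent span).
#' @param panel an [AmpliconPanel-class].
#' @param window phasing window in bases.
#' @return A list with `singles` (data.frame of independent variants)
#'   and `groups` (list of lists with `parent` — one-row data.frame —
#'   and `constituents`).
#' @export
phaseVariants <- function(variants, amplicon, panel, window = 15L) {
    view <- panelView(panel)
    phaseVariantsView(variants, match(amplicon, view$names), view,
                      window)
}

phaseVariantsView <- function(variants, i, view, window = 15L) {
    if (nrow(variants) <= 1L)
        return(list(singles = variants, groups = list()))
    variants <- variants[order(variants$pos), , drop = FALSE]
    ampStart <- view$start[i]
    refseq <- view$ref[i]
    spanEnd <- variants$pos + nchar(variants$ref) - 1L
    gap <- variants$pos[-1L] - spanEnd[-nrow(variants)] - 1L
    grp <- cumsum(c(0L, as.integer(gap > window)))
    singles <- emptyVariants()
    groups <- list()
    for (g in unique(grp)) {
        idx <- which(grp == g)
        if (length(idx) == 1L) {
            singles <- rbind(singles, variants[idx, , drop = FALSE])
            next
        }
        cons <- variants[idx, , drop = FALSE]
        first <- cons$pos[1L]
        last <- max(cons$pos + nchar(cons$ref) - 1L)
        # splice the observed alternates into the reference span
        parts <- character(0)
        cur <- first
        for (r in seq_len(nrow(cons))) {
            lp <- cons$pos[r] - ampStart + 1L
            if (cons$pos[r] > cur)
                parts <- c(parts, substr1(refseq, cur - ampStart + 1L,
                                          lp - 1L))
            parts <- c(parts, cons$alt[r])
            cur <- cons$pos[r] + nchar(cons$ref[r])
        }
        if (cur <= last)
            parts <- c(parts, substr1(refseq, cur - ampStart + 1L,
                                      last - ampStart + 1L))
        parent <- data.frame(
            chrom = cons$chrom[1L], pos = first,
            ref = substr1(refseq, first - ampStart + 1L,
                          last - ampStart + 1L),
            alt = paste(parts, collapse = ""), stringsAsFactors = FALSE)
        groups[[length(groups) + 1L]] <-
            list(parent = parent, constituents = cons)
    }
    rownames(singles) <- NULL
    list(singles = singles, groups = groups)
}

variantKey <- function(df) {
    sprintf("%s:%d:%s:%s", df$chrom, df$pos, df$ref, df$alt)
}

#' Process one sample: FASTQ pair to aggregated variant calls
#'
#' Runs the full calling stage: for every read pair, a cache keyed by the
#' raw sequence pair is consulted; on a miss the pair is assigned to an
#' amplicon by primer matching, merged into a consensus read, aligned to
#' the amplicon reference, its variants extracted and phased, and the
#' result stored. Per-variant supporting pair counts and per-locus pair
#' depths are then aggregated (summed across amplicons when inserts
#' overlap) and thresholds applied: a call is retained iff
#' `vaf >= minVaf` and `altPairs >= minAltReads`. MNP parents and their
#' constituents are aggregated as separate records sharing an `mnpLink`;
#' each record counts exactly the pairs exhibiting it.
#'
#' @param fastq1,fastq2 paired FASTQ paths (gzipped or plain).
#' @param panel an [AmpliconPanel-class].
#' @param params [CallingParams()].
#' @param cacheEnabled consult/populate the read-pair cache.
#' @param sample sample identifier.
#' @param emitAll keep calls failing the thresholds, labelled `LowVAF`
#'   and/or `LowDepth` in the `filter` column, instead of dropping them.
#' @return A [CallSet-class].
#' @export
processSample <- function(fastq1, fastq2, panel,
                          params = CallingParams(), cacheEnabled = TRUE,
                          sample = "sample", emitAll = FALSE) {
    r1 <- readFastq(fastq1)
    r2 <- readFastq(fastq2)
    n <- length(r1$seq)
    if (n != length(r2$seq))
        stop(sprintf("mate-count mismatch: %d reads in %s, %d in %s",
                     n, fastq1, length(r2$seq), fastq2))

    # The read-pair cache: with caching on, every distinct raw sequence
    # pair is processed once and its result reused with the pair's
    # multiplicity; the first-seen qualities resolve the consensus.
    pairKeys <- paste0(r1$seq, "\x01", r2$seq)
    if (cacheEnabled && n > 0L) {
        uIdx <- which(!duplicated(pairKeys))
        mult <- as.integer(table(factor(pairKeys,
                                        levels = pairKeys[uIdx])))
        hits <- n - length(uIdx); misses <- length(uIdx)
    } else {
        uIdx <- seq_len(n)
        mult <- rep(1L, n)
        hits <- 0L; misses <- n
    }
    nu <- length(uIdx)
    s1 <- r1$seq[uIdx]; s2 <- r2$seq[uIdx]

    view <- panelView(panel)
    ampName <- vapply(seq_len(nu), function(j)
        assignAmpliconView(s1[j], s2[j], view, params), character(1))
    assignedJ <- which(!is.na(ampName))
    assigned <- sum(mult[assignedJ])

    # batch merge of all assigned unique pairs
    mergedReads <- vector("list", nu)
    if (length(assignedJ)) {
        bAll <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAStringSet(s2[assignedJ])))
        als <- batchSmithWaterman(s1[assignedJ], bAll, params$merge)
        for (k in seq_along(assignedJ)) {
            j <- assignedJ[k]
            mergedReads[[j]] <- mergeFromAlignment(
                s1[j], bAll[k], r1$qual[[uIdx[j]]],
                rev(r2$qual[[uIdx[j]]]), als[[k]], params$merge)
        }
    }
    mergedJ <- which(!vapply(mergedReads, is.null, logical(1)))
    merged <- sum(mult[mergedJ])

    # batch read-vs-reference alignment, one call per amplicon
    callRes <- vector("list", nu)
    for (ampIdx in seq_along(view$names)) {
        aj <- mergedJ[ampName[mergedJ] == view$names[ampIdx]]
        if (!length(aj)) next
        seqs <- vapply(mergedReads[aj], function(m) m$seq, character(1))
        als <- batchSmithWaterman(seqs, view$ref[ampIdx], params$merge)
        for (k in seq_along(aj))
            callRes[[aj[k]]] <- callFromAlignment(seqs[k], als[[k]],
                                                  view, ampIdx)
    }
    unalignableJ <- mergedJ[vapply(mergedJ, function(j)
        is.null(callRes[[j]]), logical(1))]
    unalignable <- sum(mult[unalignableJ])

    # aggregation accumulators
    altCount <- new.env(parent = emptyenv())   # key -> pair count
    keyInfo <- new.env(parent = emptyenv())    # key -> row/parent/link/amps
    covCount <- new.env(parent = emptyenv())   # "chrom:start:end" -> count

    for (j in setdiff(mergedJ, unalignableJ)) {
        cr <- callRes[[j]]
        w <- mult[j]
        ck <- paste(cr$chrom, cr$cov[["start"]], cr$cov[["end"]],
                    sep = ":")
        covCount[[ck]] <- (if (is.null(covCount[[ck]])) 0L
                           else covCount[[ck]]) + w
        if (!nrow(cr$variants)) next
        ph <- phaseVariantsView(cr$variants,
                                match(ampName[j], view$names), view,
                                params$phaseWindow)
        recs <- ph$singles
        if (nrow(recs)) {
            recs$parent <- FALSE
            recs$link <- NA_character_
        } else {
            recs <- cbind(recs, data.frame(parent = logical(0),
                                           link = character(0)))
        }
        for (g in ph$groups) {
            link <- variantKey(g$parent)
            pr <- g$parent; pr$parent <- TRUE; pr$link <- link
            co <- g$constituents; co$parent <- FALSE; co$link <- link
            recs <- rbind(recs, pr, co)
        }
        keys <- variantKey(recs)
        for (q in seq_len(nrow(recs))) {
            kk <- keys[q]
            altCount[[kk]] <- (if (is.null(altCount[[kk]])) 0L
                               else altCount[[kk]]) + w
            info <- keyInfo[[kk]]
            if (is.null(info))
                info <- list(row = recs[q, c("chrom", "pos", "ref",
                                             "alt")],
                             parent = FALSE, link = NA_character_,
                             amps = character(0))
            info$parent <- info$parent || recs$parent[q]
            if (is.na(info$link) && !is.na(recs$link[q]))
                info$link <- recs$link[q]
            info$amps <- union(info$amps, ampName[j])
            keyInfo[[kk]] <- info
        }
    }

    keys <- ls(altCount)
    covKeys <- ls(covCount)
    covDf <- if (length(covKeys)) {
        parts <- strsplit(covKeys, ":", fixed = TRUE)
        data.frame(chrom = vapply(parts, `[`, "", 1L),
                   start = as.integer(vapply(parts, `[`, "", 2L)),
                   end = as.integer(vapply(parts, `[`, "", 3L)),
                   n = vapply(covKeys, function(k) covCount[[k]],
                              integer(1)),
                   stringsAsFactors = FALSE)
    } else data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n = integer(0))

    callsDf <- data.frame(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          amplicons = character(0), altPairs = integer(0),
                          depthPairs = integer(0), vaf = numeric(0),
                          isMnpParent = logical(0),
                          mnpLink = character(0), filter = character(0),
                          stringsAsFactors = FALSE)
    if (length(keys)) {
        rows <- lapply(keys, function(kk) {
            info <- keyInfo[[kk]]
            v <- info$row
            vEnd <- v$pos + nchar(v$ref) - 1L
            depth <- sum(covDf$n[covDf$chrom == v$chrom &
                                 covDf$start <= v$pos &
                                 covDf$end >= vEnd])
            altN <- altCount[[kk]]
            data.frame(chrom = v$chrom, pos = v$pos, ref = v$ref,
                       alt = v$alt,
                       amplicons = paste(sort(info$amps), collapse = ","),
                       altPairs = altN, depthPairs = depth,
                       vaf = if (depth > 0) altN / depth else 0,
                       isMnpParent = info$parent, mnpLink = info$link,
                       stringsAsFactors = FALSE)
        })
        callsDf <- do.call(rbind, rows)
        lowVaf <- callsDf$vaf < params$minVaf
        lowDepth <- callsDf$altPairs < params$minAltReads
        callsDf$filter <- ifelse(!lowVaf & !lowDepth, "PASS",
            vapply(seq_len(nrow(callsDf)), function(j)
                paste(c("LowVAF"[lowVaf[j]], "LowDepth"[lowDepth[j]]),
                      collapse = ";"), character(1)))
        if (!emitAll)
            callsDf <- callsDf[callsDf$filter == "PASS", , drop = FALSE]
        # constituents keep an mnpLink only when their parent is reported
        parentLinks <- callsDf$mnpLink[callsDf$isMnpParent]
        orphan <- !callsDf$isMnpParent & !is.na(callsDf$mnpLink) &
                  !(callsDf$mnpLink %in% parentLinks)
        callsDf$mnpLink[orphan] <- NA_character_
        callsDf <- callsDf[order(callsDf$chrom, callsDf$pos, callsDf$ref,
                                 callsDf$alt), , drop = FALSE]
        rownames(callsDf) <- NULL
    }

    stats <- list(pairsRead = n, pairsMerged = merged,
                  pairsAssigned = assigned, pairsUnalignable = unalignable,
                  cacheHits = hits, cacheMisses = misses,
                  cacheHitRatio = if (hits + misses > 0)
                      hits / (hits + misses) else NA_real_)
    new("CallSet", sample = sample, calls = callsDf, stats = stats)
}

#' Compare a call set against a truth table
#'
#' Calls and truth variants are matched on their (chrom, pos, ref, alt)
#' tuples (both sides in the same, normalized representation). MNP
#' parent records are excluded from the comparison unless the truth
#' table itself contains the parent tuple.
#'
#' @param callset a [CallSet-class] (or a data.frame of calls).
#' @param truth data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return A list with `TP`, `FP`, `FN`, `sensitivity`, `precision`
#'   (sensitivity is `NA` for empty truth).
#' @export
evaluateCalls <- function(callset, truth) {
    df <- if (is(callset, "CallSet")) calls(callset) else callset
    calledKeys <- if (nrow(df)) {
        keep <- if ("isMnpParent" %in% colnames(df)) {
            truthKeys0 <- if (nrow(truth)) variantKey(truth) else character(0)
            !df$isMnpParent | variantKey(df) %in% truthKeys0
        } else rep(TRUE, nrow(df))
        unique(variantKey(df[keep, , drop = FALSE]))
    } else character(0)
    truthKeys <- if (nrow(truth)) unique(variantKey(truth)) else character(0)
    tp <- length(intersect(calledKeys, truthKeys))
    fp <- length(setdiff(calledKeys, truthKeys))
    fn <- length(setdiff(truthKeys, calledKeys))
    list(TP = tp, FP = fp, FN = fn,
         sensitivity = if (length(truthKeys)) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
}
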