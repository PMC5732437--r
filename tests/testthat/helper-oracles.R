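# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths.

# Full-matrix affine-gap local alignment score (Gotoh), with the gap
# scheme "gapOpen on the first gap base, gapExtend per further base".
swScoreOracle <- function(a, b, match = 2, mismatch = -2, gapOpen = -3,
                          gapExtend = -1) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    n <- length(av); m <- length(bv)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)
    X <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
    Y <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            s <- if (av[i] == bv[j]) match else mismatch
            diag <- max(M[i, j], X[i, j], Y[i, j], 0)
            M[i + 1, j + 1] <- diag + s
            X[i + 1, j + 1] <- max(M[i, j + 1] + gapOpen,
                                   X[i, j + 1] + gapExtend)
            Y[i + 1, j + 1] <- max(M[i + 1, j] + gapOpen,
                                   Y[i + 1, j] + gapExtend)
            if (M[i + 1, j + 1] > best) best <- M[i + 1, j + 1]
        }
    }
    best
}

randomDnaStr <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
          collapse = "")
}

# Apply a VCF-style edit to a local (1-based) reference string.
applyLocalEdit <- function(seq, pos, ref, alt) {
    stopifnot(substr(seq, pos, pos + nchar(ref) - 1L) == ref)
    paste0(substr(seq, 1L, pos - 1L), alt,
           substr(seq, pos + nchar(ref), nchar(seq)))
}

# Enumerate every VCF encoding (position + ref/alt strings, both
# non-empty) within a window that produces the same mutated sequence as
# the given edit. This is the padding/shift enumeration oracle: it
# finds anchored paddings and all shift-equivalent placements alike.
enumerateEncodings <- function(refSeq, pos, ref, alt, window = 8L,
                               maxRefLen = NULL) {
    target <- applyLocalEdit(refSeq, pos, ref, alt)
    n <- nchar(refSeq); nt <- nchar(target)
    if (is.null(maxRefLen)) maxRefLen <- nchar(ref) + 3L
    out <- list()
    for (p in max(1L, pos - window):min(n, pos + window)) {
        for (len in seq_len(maxRefLen)) {       # VCF needs non-empty ref
            if (p + len - 1L > n) next
            altLen <- len + (nt - n)
            if (altLen < 1L || p + altLen - 1L > nt) next
            refC <- substr(refSeq, p, p + len - 1L)
            altC <- substr(target, p, p + altLen - 1L)
            if (refC == altC) next
            cand <- paste0(substr(refSeq, 1L, p - 1L), altC,
                           substr(refSeq, p + len, n))
            if (cand == target)
                out[[length(out) + 1L]] <- list(pos = p, ref = refC,
                                                alt = altC)
        }
    }
    out
}

# Deterministic quality profiles matching the simulator's defaults.
flatQuals <- function(n, q = 30L) rep(as.integer(q), n)

# Build an error-free read pair from a haplotype string (read 2 as
# sequenced, i.e. reverse-complemented tail).
readPairFromHap <- function(hap, readLen = 100L) {
    hl <- nchar(hap)
    r1 <- substr(hap, 1L, min(readLen, hl))
    tail <- substr(hap, max(1L, hl - readLen + 1L), hl)
    r2 <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(tail)))
    list(seq1 = r1, seq2 = r2,
         qual1 = flatQuals(nchar(r1)), qual2 = flatQuals(nchar(r2)))
}

revcompStr <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
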