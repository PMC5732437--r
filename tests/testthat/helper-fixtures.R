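# Shared fixtures, built once per test session.

.fixtureEnv <- new.env()

# Standard toy panel: 4 amplicons, BRAF-like plus-strand transcript
# (codon 600 = GTG at c.1798-1800), minus-strand 2-exon transcript over
# amplicon 2, dup landmark at c.21-22 in amplicon 3.
toyPanel <- function() {
    if (is.null(.fixtureEnv$toy))
        .fixtureEnv$toy <- makePanel(nAmplicons = 4, seed = 7)
    .fixtureEnv$toy
}

# A hand-built single-amplicon panel around a chosen insert sequence.
# The amplicon spans [start, start + len - 1] on chromosome "chrT".
miniPanel <- function(insert, primerLen = 20L, start = 501L,
                      seed = 99L) {
    set.seed(seed)
    fwd <- randomDnaStr(primerLen)
    revP <- randomDnaStr(primerLen)
    refseq <- paste0(fwd, insert, revcompStr(revP))
    gr <- GenomicRanges::GRanges(
        "chrT", IRanges::IRanges(start = start, width = nchar(refseq)))
    names(gr) <- "MINI1"
    S4Vectors::mcols(gr)$fwdPrimer <- fwd
    S4Vectors::mcols(gr)$revPrimer <- revP
    AmpliconPanel(gr, Biostrings::DNAStringSet(c(MINI1 = refseq)))
}

# Write an explicit list of read pairs (with the simulator's default
# quality profiles) to a FASTQ pair in a temp dir.
writePairFastq <- function(pairs, dir = tempfile("rp")) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    qp <- ampliCall:::defaultQualityProfile(
        max(vapply(pairs, function(p) nchar(p$seq1), integer(1))))
    s1 <- vapply(pairs, function(p) p$seq1, character(1))
    s2 <- vapply(pairs, function(p) p$seq2, character(1))
    ids <- sprintf("pair%04d", seq_along(pairs))
    f1 <- file.path(dir, "R1.fastq.gz")
    f2 <- file.path(dir, "R2.fastq.gz")
    ampliCall:::writeFastq(
        s1, lapply(nchar(s1), function(n) qp$read1[seq_len(n)]), ids, f1)
    ampliCall:::writeFastq(
        s2, lapply(nchar(s2), function(n) qp$read2[seq_len(n)]), ids, f2)
    list(fastq1 = f1, fastq2 = f2)
}

# Insert (local coordinates within the amplicon reference) of a panel's
# i-th amplicon as a plain string.
ampRefStr <- function(panel, i = 1L) {
    as.character(refSeqs(panel)[[i]])
}
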